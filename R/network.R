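#' Pearson co-occurrence network for one age group
#'
#' Pairwise Pearson correlations between taxa over one group's samples,
#' with two-sided p-values from the t transform
#' `t = r * sqrt((n-2) / (1-r^2))` on `n - 2` degrees of freedom. An edge
#' is retained only when `p < alpha` and `|r| > r_min` — both strict.
#' Taxa with zero variance within the group are excluded (logged in
#' attribute `"dropped_taxa"`); correlations of exactly +/-1 get p = 0,
#' are kept, and are flagged.
#'
#' @param t A [taxa_table()] (relative abundance recommended).
#' @param samples Sample ids (or logical/integer index) delimiting the
#'   group; default all samples.
#' @param r_min Strict lower bound on `|r|`.
#' @param alpha Strict upper bound on p.
#' @param group Label stored on the network.
#' @return A `co_network`: list with `edges` (tibble: taxon_a, taxon_b,
#'   r, p, perfect), `nodes` (tibble: taxon_id, kingdom), `params`,
#'   `n_samples`, `group`.
#' @export
correlation_network <- function(t, samples = NULL, r_min = 0.3,
                                alpha = 0.05, group = NA_character_) {
  stopifnot(inherits(t, "taxa_table"))
  v <- t$values
  if (!is.null(samples)) v <- v[samples, , drop = FALSE]
  n <- nrow(v)
  if (n < 4) stop("need >= 4 samples to build a correlation network")
  sds <- apply(v, 2, stats::sd)
  dropped <- colnames(v)[sds == 0]
  v <- v[, sds > 0, drop = FALSE]
  cm <- stats::cor(v)
  df <- n - 2
  r <- cm[upper.tri(cm)]
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  perfect <- abs(r) >= 1 - 1e-12
  tstat <- r * sqrt(df / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[perfect] <- 0
  keep <- p < alpha & abs(r) > r_min
  edges <- tibble::tibble(
    taxon_a = colnames(v)[idx[keep, 1]],
    taxon_b = colnames(v)[idx[keep, 2]],
    r = r[keep], p = p[keep], perfect = perfect[keep]
  )
  nodes <- tibble::tibble(taxon_id = colnames(v),
                          kingdom = unname(t$kingdom[colnames(v)]))
  out <- structure(
    list(edges = edges, nodes = nodes,
         params = list(r_min = r_min, alpha = alpha),
         n_samples = n, group = group),
    class = "co_network"
  )
  attr(out, "dropped_taxa") <- dropped
  out
}

#' Build a co-occurrence network from an explicit edge list
#'
#' Mainly for planted-structure benchmarks and custom graphs; the usual
#' entry point is [correlation_network()].
#'
#' @param edges Tibble/data frame with columns `taxon_a`, `taxon_b` and
#'   optionally `r`, `p`.
#' @param nodes Optional tibble with `taxon_id` (and `kingdom`); default
#'   is the union of edge endpoints with kingdom `"bacteria"`.
#' @param group,r_min,alpha Stored as construction metadata.
#' @param n_samples Number of samples the edges were derived from.
#' @return A `co_network`.
#' @export
make_network <- function(edges, nodes = NULL, group = NA_character_,
                         r_min = 0.3, alpha = 0.05, n_samples = NA_integer_) {
  edges <- tibble::as_tibble(edges)
  if (!"r" %in% names(edges)) edges$r <- 1
  if (!"p" %in% names(edges)) edges$p <- 0
  if (!"perfect" %in% names(edges)) edges$perfect <- FALSE
  if (is.null(nodes)) {
    ids <- unique(c(edges$taxon_a, edges$taxon_b))
    nodes <- tibble::tibble(taxon_id = ids, kingdom = "bacteria")
  }
  if (!"kingdom" %in% names(nodes)) nodes$kingdom <- "bacteria"
  structure(
    list(edges = edges, nodes = tibble::as_tibble(nodes),
         params = list(r_min = r_min, alpha = alpha),
         n_samples = n_samples, group = group),
    class = "co_network"
  )
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf("<co_network%s> %d nodes, %d edges (|r| > %g, p < %g, n = %d)\n",
              if (is.na(x$group)) "" else paste0(" ", x$group),
              nrow(x$nodes), nrow(x$edges),
              x$params$r_min, x$params$alpha, x$n_samples))
  invisible(x)
}

co_network_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("taxon_a", "taxon_b", "r", "p")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes$taxon_id,
                          kingdom = net$nodes$kingdom)
  )
}

#' Walktrap community detection on a co-occurrence network
#'
#' Runs Pons-Latapy walktrap ([igraph::cluster_walktrap()]) on the
#' thresholded (unweighted) graph, cutting the merge tree at maximum
#' modularity. Nodes without edges become singleton clusters. Clusters
#' with more than `membership_min` members (strict) are the "large"
#' clusters used downstream.
#'
#' @param net A [correlation_network()] result.
#' @param steps Random-walk length.
#' @param membership_min A cluster is "large" when its size is strictly
#'   greater than this.
#' @return A `cluster_partition`: `membership` (tibble: taxon_id,
#'   cluster), `sizes` (tibble: cluster, n, large), `large_clusters`
#'   (ids), `modularity`, `steps`, `membership_min`, `group`.
#' @export
walktrap_communities <- function(net, steps = 4, membership_min = 10) {
  stopifnot(inherits(net, "co_network"))
  if (!nrow(net$nodes)) stop("empty network")
  g <- co_network_igraph(net)
  if (!igraph::ecount(g)) {
    warning("edgeless network: every node is a singleton cluster")
    memb <- stats::setNames(seq_len(igraph::vcount(g)),
                            igraph::V(g)$name)
    mod <- 0
  } else {
    wt <- igraph::cluster_walktrap(g, steps = steps, weights = NULL)
    memb <- stats::setNames(igraph::membership(wt),
                            igraph::V(g)$name)
    mod <- igraph::modularity(g, memb)
  }
  membership <- tibble::tibble(taxon_id = names(memb),
                               cluster = as.integer(memb))
  sizes <- dplyr::count(membership, .data$cluster, name = "n")
  sizes$large <- sizes$n > membership_min
  structure(
    list(membership = membership, sizes = sizes,
         large_clusters = sizes$cluster[sizes$large],
         modularity = mod, steps = steps,
         membership_min = membership_min, group = net$group),
    class = "cluster_partition"
  )
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf(
    "<cluster_partition%s> %d nodes, %d clusters (%d large > %d), Q = %.3f\n",
    if (is.na(x$group)) "" else paste0(" ", x$group),
    nrow(x$membership), nrow(x$sizes), length(x$large_clusters),
    x$membership_min, x$modularity
  ))
  invisible(x)
}

#' Network and partition summary counts
#'
#' @param net A `co_network`.
#' @param partition The matching `cluster_partition`.
#' @return One-row tibble: `group`, `n_nodes`, `n_edges`,
#'   `n_clusters`, `n_large_clusters`, `modularity`.
#' @export
network_summary <- function(net, partition) {
  tibble::tibble(
    group = net$group,
    n_nodes = nrow(net$nodes),
    n_edges = nrow(net$edges),
    n_clusters = nrow(partition$sizes),
    n_large_clusters = length(partition$large_clusters),
    modularity = partition$modularity
  )
}

#' Write a network with cluster and kingdom annotation to GraphML
#'
#' @param net A `co_network`.
#' @param partition Optional `cluster_partition`; adds a `cluster`
#'   vertex attribute.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path, partition = NULL) {
  g <- co_network_igraph(net)
  if (!is.null(partition)) {
    cl <- partition$membership$cluster[
      match(igraph::V(g)$name, partition$membership$taxon_id)]
    g <- igraph::set_vertex_attr(g, "cluster", value = cl)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_edge_list <- function(net, path) {
  readr::write_tsv(net$edges[, c("taxon_a", "taxon_b", "r", "p")], path)
  invisible(path)
}
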