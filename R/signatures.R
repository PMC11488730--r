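#' Hypergeometric enrichment of DAMs in network clusters
#'
#' Over-representation analysis of a differentially-abundant-microbe set
#' within each large cluster of a network partition. The background is,
#' by default, the union of all large-cluster nodes with the DAM set
#' (`"clusters_union_dams"`); alternatives restrict to all network nodes
#' (`"all_nodes"`, union with DAMs) or use each cluster plus the DAM set
#' separately (`"per_cluster"`). The upper-tail p is
#' `P[X >= k]`, `X ~ Hypergeom(N, K, n)`, BH-adjusted across clusters;
#' clusters with `q < alpha` are flagged age-related.
#'
#' @param partition A [walktrap_communities()] result.
#' @param dam_set Character vector of DAM taxon ids (non-empty).
#' @param background_mode One of `"clusters_union_dams"`, `"all_nodes"`,
#'   `"per_cluster"`.
#' @param alpha Flagging threshold on the q-value.
#' @return An `enrichment_result` tibble: `cluster`, `k` (overlap), `n`
#'   (cluster size), `K` (background DAMs), `N` (background size), `p`,
#'   `q`, `flagged`.
#' @export
cluster_enrichment <- function(partition, dam_set,
                               background_mode = c("clusters_union_dams",
                                                   "all_nodes",
                                                   "per_cluster"),
                               alpha = 0.05) {
  background_mode <- match.arg(background_mode)
  if (!length(dam_set)) stop("dam_set must be non-empty")
  dam_set <- unique(dam_set)
  memb <- partition$membership
  large <- partition$large_clusters
  if (!length(large)) {
    warning("no large clusters: empty enrichment result")
    out <- tibble::tibble(cluster = integer(), k = integer(),
                          n = integer(), K = integer(), N = integer(),
                          p = numeric(), q = numeric(),
                          flagged = logical())
    class(out) <- c("enrichment_result", class(out))
    return(out)
  }
  large_nodes <- memb$taxon_id[memb$cluster %in% large]
  global_bg <- switch(
    background_mode,
    clusters_union_dams = union(large_nodes, dam_set),
    all_nodes = union(memb$taxon_id, dam_set),
    per_cluster = NULL
  )
  rows <- purrr::map_dfr(large, function(cl) {
    nodes <- memb$taxon_id[memb$cluster == cl]
    bg <- if (is.null(global_bg)) union(nodes, dam_set) else global_bg
    N <- length(bg)
    K <- length(intersect(dam_set, bg))
    n <- length(intersect(nodes, bg))
    k <- length(intersect(nodes, dam_set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(cluster = cl, k = k, n = n, K = K, N = N, p = p)
  })
  rows$q <- bh_adjust(rows$p)
  rows$flagged <- rows$q < alpha
  class(rows) <- c("enrichment_result", class(rows))
  rows
}

#' Classify age-stage microbial signatures
#'
#' A taxon is a signature of age group G when (a) it is a DAM
#' (`q < q_threshold`, strict) in at least one pairwise comparison
#' involving G, and (b) its mean abundance in G strictly exceeds its
#' mean in each other group. Each taxon can satisfy (b) for at most one
#' group, so signature sets are disjoint by construction.
#'
#' @param da_results Named list of `da_result` tibbles, one per pairwise
#'   comparison, names like `"Y_vs_E"`; all three pairwise comparisons
#'   of `groups` must be present.
#' @param t A [taxa_table()] on the scale whose group means define
#'   clause (b) (batch-corrected relative abundance recommended).
#' @param groups Group label per sample of `t`.
#' @param q_threshold DAM threshold.
#' @return A `signature_set` tibble: `group`, `taxon_id`, `kingdom`,
#'   `evidence` (comma-joined significant comparisons), and the
#'   per-group mean columns.
#' @export
classify_signatures <- function(da_results, t, groups,
                                q_threshold = 0.25) {
  glev <- unique(as.character(groups))
  expected <- utils::combn(glev, 2, function(p) paste0(p[1], "_vs_", p[2]))
  have <- names(da_results)
  ok <- vapply(expected, function(cmp) {
    parts <- strsplit(cmp, "_vs_")[[1]]
    any(have %in% c(cmp, paste0(parts[2], "_vs_", parts[1])))
  }, logical(1))
  if (!all(ok)) {
    stop("missing comparison: ", paste(expected[!ok], collapse = ", "))
  }
  dams <- dplyr::bind_rows(da_results)
  dams <- dams[dams$q_value < q_threshold, ]

  v <- t$values
  means <- vapply(glev, function(g) {
    colMeans(v[groups == g, , drop = FALSE])
  }, numeric(ncol(v)))
  rows <- purrr::map_dfr(glev, function(g) {
    others <- setdiff(glev, g)
    # clause (a): significant in >= 1 comparison involving g
    involving <- grepl(paste0("(^", g, "_vs_)|(_vs_", g, "$)"),
                       dams$comparison)
    cand <- unique(dams$taxon_id[involving])
    cand <- intersect(cand, rownames(means))
    if (!length(cand)) return(NULL)
    m <- means[cand, , drop = FALSE]
    highest <- m[, g] > apply(m[, others, drop = FALSE], 1, max)
    cand <- cand[highest]
    if (!length(cand)) return(NULL)
    ev <- vapply(cand, function(tx) {
      paste(sort(unique(dams$comparison[dams$taxon_id == tx & involving])),
            collapse = ",")
    }, character(1))
    out <- tibble::tibble(group = g, taxon_id = cand,
                          kingdom = unname(t$kingdom[cand]),
                          evidence = unname(ev))
    for (gg in glev) out[[paste0("mean_", gg)]] <- unname(means[cand, gg])
    out
  })
  if (!nrow(rows)) {
    rows <- tibble::tibble(group = character(), taxon_id = character(),
                           kingdom = character(), evidence = character())
    for (gg in glev) rows[[paste0("mean_", gg)]] <- numeric()
  }
  if (anyDuplicated(rows$taxon_id)) {
    stop("internal error: signature sets are not disjoint")
  }
  class(rows) <- c("signature_set", class(rows))
  rows
}

#' Neighbors of a focal taxon within its own cluster
#'
#' Restricts the focal taxon's network neighborhood to the members of
#' its walktrap cluster and reports the kingdom breakdown — the quantity
#' whose change across age-group networks defines an interaction shift.
#' Absence of the focal taxon from the network is a reportable outcome,
#' not an error.
#'
#' @param net A `co_network`.
#' @param partition Its `cluster_partition`.
#' @param focal_taxon Taxon id.
#' @return A list: `present`, `cluster` (id or NA), `cluster_small`
#'   (TRUE when the cluster is not "large"), `neighbors` (tibble:
#'   taxon_id, kingdom), `degree_in_cluster`, `kingdom_breakdown`
#'   (named counts).
#' @export
signature_neighbors <- function(net, partition, focal_taxon) {
  memb <- partition$membership
  if (!focal_taxon %in% memb$taxon_id) {
    return(list(present = FALSE, cluster = NA_integer_,
                cluster_small = NA,
                neighbors = tibble::tibble(taxon_id = character(),
                                           kingdom = character()),
                degree_in_cluster = 0L,
                kingdom_breakdown = integer()))
  }
  cl <- memb$cluster[memb$taxon_id == focal_taxon]
  cluster_nodes <- memb$taxon_id[memb$cluster == cl]
  e <- net$edges
  nb <- unique(c(e$taxon_b[e$taxon_a == focal_taxon],
                 e$taxon_a[e$taxon_b == focal_taxon]))
  nb <- intersect(nb, cluster_nodes)
  kgd <- net$nodes$kingdom[match(nb, net$nodes$taxon_id)]
  breakdown <- table(factor(kgd, levels = valid_kingdoms))
  list(present = TRUE, cluster = cl,
       cluster_small = !cl %in% partition$large_clusters,
       neighbors = tibble::tibble(taxon_id = nb, kingdom = kgd),
       degree_in_cluster = length(nb),
       kingdom_breakdown = stats::setNames(as.integer(breakdown),
                                           names(breakdown)))
}

#' Interaction shift of a focal taxon across age-group networks
#'
#' Compares the focal taxon's within-cluster neighbor sets between the
#' per-group networks: presence, degree, kingdom breakdown, and pairwise
#' Jaccard overlap of the neighbor sets (0 against any group where the
#' taxon is absent).
#'
#' @param nets Named list of `co_network`s (one per group).
#' @param partitions Named list of matching `cluster_partition`s.
#' @param focal_taxon Taxon id.
#' @return An `interaction_shift` list: `focal_taxon`, `per_group`
#'   (named list of [signature_neighbors()] results), `summary` (tibble:
#'   group, present, degree, kingdom counts), `jaccard` (tibble:
#'   group_a, group_b, jaccard).
#' @export
interaction_shift <- function(nets, partitions, focal_taxon) {
  stopifnot(length(nets) >= 2, identical(names(nets), names(partitions)))
  per_group <- purrr::map2(nets, partitions, signature_neighbors,
                           focal_taxon = focal_taxon)
  summary <- purrr::imap_dfr(per_group, function(x, g) {
    kb <- x$kingdom_breakdown
    row <- tibble::tibble(group = g, present = x$present,
                          degree = x$degree_in_cluster)
    for (k in valid_kingdoms) {
      row[[k]] <- if (length(kb)) unname(kb[k]) else 0L
    }
    row
  })
  pairs <- utils::combn(names(nets), 2, simplify = FALSE)
  jac <- purrr::map_dfr(pairs, function(pr) {
    a <- per_group[[pr[1]]]$neighbors$taxon_id
    b <- per_group[[pr[2]]]$neighbors$taxon_id
    u <- length(union(a, b))
    tibble::tibble(group_a = pr[1], group_b = pr[2],
                   jaccard = if (u == 0) 0 else
                     length(intersect(a, b)) / u)
  })
  structure(list(focal_taxon = focal_taxon, per_group = per_group,
                 summary = summary, jaccard = jac),
            class = "interaction_shift")
}

#' @export
print.interaction_shift <- function(x, ...) {
  cat(sprintf("<interaction_shift> %s\n", x$focal_taxon))
  print(x$summary)
  print(x$jaccard)
  invisible(x)
}
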