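#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods for pipeline result objects
#'
#' Broom-style accessors: `tidy()` returns the per-unit table of a
#' result (per-sample centroid distances, per-cluster sizes, network
#' edges, ordination coordinates), `glance()` a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name agemicro-tidiers
NULL

#' @rdname agemicro-tidiers
#' @method tidy permanova_result
#' @export
tidy.permanova_result <- function(x, ...) {
  tibble::tibble(
    term = c("between", "within"),
    df = as.integer(x$df),
    statistic = c(x$pseudo_F, NA_real_),
    R2 = c(x$R2, 1 - x$R2),
    p_value = c(x$p_value, NA_real_)
  )
}

#' @rdname agemicro-tidiers
#' @method glance permanova_result
#' @export
glance.permanova_result <- function(x, ...) {
  tibble::tibble(pseudo_F = x$pseudo_F, R2 = x$R2, p_value = x$p_value,
                 n_permutations = x$n_permutations, seed = x$seed)
}

#' @rdname agemicro-tidiers
#' @method tidy betadisper_result
#' @export
tidy.betadisper_result <- function(x, ...) x$distances

#' @rdname agemicro-tidiers
#' @method glance betadisper_result
#' @export
glance.betadisper_result <- function(x, ...) {
  tibble::tibble(statistic = x$F, p_value = x$p_value,
                 n_permutations = x$n_permutations, seed = x$seed)
}

#' @rdname agemicro-tidiers
#' @method tidy co_network
#' @export
tidy.co_network <- function(x, ...) x$edges

#' @rdname agemicro-tidiers
#' @method glance co_network
#' @export
glance.co_network <- function(x, ...) {
  tibble::tibble(group = x$group, n_nodes = nrow(x$nodes),
                 n_edges = nrow(x$edges), r_min = x$params$r_min,
                 alpha = x$params$alpha, n_samples = x$n_samples)
}

#' @rdname agemicro-tidiers
#' @method tidy cluster_partition
#' @export
tidy.cluster_partition <- function(x, ...) x$membership

#' @rdname agemicro-tidiers
#' @method glance cluster_partition
#' @export
glance.cluster_partition <- function(x, ...) {
  tibble::tibble(group = x$group, n_clusters = nrow(x$sizes),
                 n_large_clusters = length(x$large_clusters),
                 modularity = x$modularity, steps = x$steps)
}

#' @rdname agemicro-tidiers
#' @method tidy pcoa_result
#' @export
tidy.pcoa_result <- function(x, ...) x$points

#' @rdname agemicro-tidiers
#' @method glance pcoa_result
#' @export
glance.pcoa_result <- function(x, ...) {
  tibble::tibble(
    n_positive_eig = sum(x$eigenvalues > 0),
    n_negative_eig = sum(x$eigenvalues < 0),
    rel_eig_1 = x$rel_eig[1],
    rel_eig_2 = if (length(x$rel_eig) > 1) x$rel_eig[2] else NA_real_
  )
}

#' @rdname agemicro-tidiers
#' @method tidy interaction_shift
#' @export
tidy.interaction_shift <- function(x, ...) x$summary

#' @rdname agemicro-tidiers
#' @method glance interaction_shift
#' @export
glance.interaction_shift <- function(x, ...) {
  tibble::tibble(focal_taxon = x$focal_taxon,
                 n_groups_present = sum(x$summary$present),
                 min_jaccard = min(x$jaccard$jaccard),
                 max_jaccard = max(x$jaccard$jaccard))
}
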