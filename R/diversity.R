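#' Alpha diversity: Shannon index and Chao1 richness
#'
#' `shannon()` returns the Shannon entropy (nats) of one abundance vector;
#' `chao1()` the bias-corrected Chao1 richness estimate,
#' `S_obs + F1(F1-1) / (2(F2+1))` with `F1`/`F2` the singleton/doubleton
#' counts — defined on integer counts only, since singletons are
#' meaningless after normalization. `alpha_diversity()` computes both per
#' sample.
#'
#' @param x Non-negative abundance vector.
#' @return A scalar; `alpha_diversity()` a tibble with columns
#'   `sample_id`, `shannon`, `chao1`.
#' @export
shannon <- function(x) {
  if (any(x < 0)) stop("negative abundance")
  s <- sum(x)
  if (s == 0) stop("Shannon index undefined on an all-zero row")
  p <- x[x > 0] / s
  -sum(p * log(p))
}

#' @rdname shannon
#' @export
chao1 <- function(x) {
  if (any(x < 0)) stop("negative counts")
  if (any(abs(x - round(x)) > 1e-8)) {
    stop("Chao1 requires integer counts (undefined on normalized data)")
  }
  x <- round(x)
  s_obs <- sum(x > 0)
  if (s_obs == 0) return(0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' @rdname shannon
#' @param t A counts-scale [taxa_table()].
#' @export
alpha_diversity <- function(t) {
  stopifnot(inherits(t, "taxa_table"))
  v <- t$values
  tibble::tibble(
    sample_id = rownames(v),
    shannon = apply(v, 1, shannon),
    chao1 = if (t$scale == "counts") apply(v, 1, chao1) else NA_real_
  )
}

new_dist_matrix <- function(m, metric) {
  stopifnot(isSymmetric(unname(m), tol = 1e-12))
  d <- stats::as.dist(m)
  attr(d, "metric") <- metric
  d
}

#' Beta-diversity distance matrices
#'
#' `bray_curtis_matrix()` computes Bray-Curtis dissimilarities
#' (via [vegan::vegdist()]); `aitchison_matrix()` the Aitchison distance,
#' i.e. Euclidean distance between CLR-transformed rows
#' ([clr_transform()] is applied unless the table is already CLR scale).
#'
#' @param t A [taxa_table()]; relative or counts scale for Bray-Curtis.
#' @param pseudocount Passed to [clr_transform()].
#' @return A `dist` object with a `"metric"` attribute.
#' @export
bray_curtis_matrix <- function(t) {
  stopifnot(inherits(t, "taxa_table"))
  d <- vegan::vegdist(t$values, method = "bray")
  attr(d, "metric") <- "bray_curtis"
  d
}

#' @rdname bray_curtis_matrix
#' @export
aitchison_matrix <- function(t, pseudocount = NULL) {
  stopifnot(inherits(t, "taxa_table"))
  ct <- if (t$scale == "clr") t else clr_transform(t, pseudocount)
  d <- stats::dist(ct$values)
  attr(d, "metric") <- "aitchison"
  d
}

#' Principal-coordinate analysis
#'
#' Classical scaling: eigendecomposition of the Gower-centered
#' `-0.5 * D^2` matrix. Axes with negative eigenvalues are reported in
#' `eigenvalues` but never returned as coordinates.
#'
#' @param d A `dist` or symmetric matrix.
#' @param k Number of coordinate axes (at most the number of positive
#'   eigenvalues; must be `< n`).
#' @return A `pcoa_result`: list with `points` (tibble: sample_id, axis
#'   columns), `eigenvalues` (all, descending), `rel_eig` (share of the
#'   positive eigenvalue mass).
#' @export
pcoa_ordination <- function(d, k = 2) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (n < 3) stop("PCoA needs at least 3 samples")
  if (k > n - 1) stop("k must be at most n - 1")
  g <- -0.5 * m^2
  g <- sweep(g, 1, rowMeans(g))
  g <- sweep(g, 2, colMeans(g))
  eig <- eigen((g + t(g)) / 2, symmetric = TRUE)
  pos <- which(eig$values > 1e-9 * max(abs(eig$values), 1e-12))
  k_use <- min(k, length(pos))
  pts <- eig$vectors[, pos[seq_len(k_use)], drop = FALSE] %*%
    diag(sqrt(eig$values[pos[seq_len(k_use)]]), k_use)
  colnames(pts) <- paste0("axis", seq_len(k_use))
  structure(
    list(
      points = tibble::tibble(
        sample_id = if (is.null(rownames(m))) as.character(seq_len(n))
                    else rownames(m),
        tibble::as_tibble(pts)
      ),
      eigenvalues = eig$values,
      rel_eig = pmax(eig$values, 0) / sum(pmax(eig$values, 0))
    ),
    class = "pcoa_result"
  )
}

ss_within <- function(d2, labels) {
  tot <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    tot <- tot + sum(d2[idx, idx]) / (2 * length(idx))
  }
  tot
}

permanova_stats <- function(d2, labels, n, a, ss_total) {
  ssw <- ss_within(d2, labels)
  ssb <- ss_total - ssw
  f <- (ssb / (a - 1)) / (ssw / (n - a))
  c(f = f, r2 = ssb / ss_total)
}

#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance (Anderson 2001):
#' `SS_total = sum_{i<j} d_ij^2 / N`, `SS_within` the analogous per-group
#' sums, pseudo-F `(SS_B/(a-1)) / (SS_W/(N-a))`, and a permutation p-value
#' `(1 + #{F_perm >= F_obs}) / (1 + n_perm)` over seeded label
#' permutations, so p is never exactly zero.
#'
#' @param d `dist` or symmetric distance matrix.
#' @param labels Group label per sample (>= 2 non-empty groups).
#' @param n_perm Number of label permutations (`0` skips the test and
#'   returns `p_value = NA`; the R-squared needs no permutations).
#' @param seed Integer seed for the permutation stream.
#' @return A `permanova_result` with fields `pseudo_F`, `R2`, `p_value`,
#'   `n_permutations`, `seed`, `df`. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
permanova <- function(d, labels, n_perm = 999, seed = 1) {
  m <- as.matrix(d)
  n <- nrow(m)
  labels <- as.character(labels)
  stopifnot(length(labels) == n)
  tab <- table(labels)
  a <- length(tab)
  if (a < 2) stop("need at least 2 groups")
  if (any(tab == 0)) stop("empty group")
  d2 <- m^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  if (ss_total <= 0) stop("degenerate distance matrix: SS_total is 0")
  obs <- permanova_stats(d2, labels, n, a, ss_total)
  p <- NA_real_
  if (n_perm >= 1) {
    hits <- 0L
    with_preserved_rng({
      set.seed(seed)
      for (i in seq_len(n_perm)) {
        fp <- permanova_stats(d2, sample(labels), n, a, ss_total)["f"]
        if (fp >= obs["f"] - 1e-12) hits <- hits + 1L
      }
    })
    p <- (1 + hits) / (1 + n_perm)
  }
  structure(
    list(pseudo_F = unname(obs["f"]), R2 = unname(obs["r2"]),
         p_value = p, n_permutations = n_perm, seed = seed,
         df = c(between = a - 1, within = n - a)),
    class = "permanova_result"
  )
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: F = %.4g (df %d, %d), R2 = %.4f, p = %s [%d perms]\n",
    x$pseudo_F, x$df["between"], x$df["within"], x$R2,
    format(x$p_value), x$n_permutations
  ))
  invisible(x)
}

#' Homogeneity of multivariate dispersions
#'
#' Wraps [vegan::betadisper()] (distance to group centroid in
#' principal-coordinate space, negative axes handled by signed squared
#' contributions) and its permutation test, with an explicit seed.
#'
#' @inheritParams permanova
#' @return A `betadisper_result`: per-sample centroid distances (tibble),
#'   per-group mean dispersions, observed F and permutation p.
#' @export
beta_dispersion <- function(d, labels, n_perm = 999, seed = 1) {
  dd <- stats::as.dist(as.matrix(d))
  grp <- factor(labels)
  if (sum(dd) == 0) {
    # all samples identical: every dispersion is exactly 0
    ids <- rownames(as.matrix(d)) %||% as.character(seq_along(labels))
    sizes <- table(grp)
    return(structure(
      list(distances = tibble::tibble(sample_id = ids,
                                      group = as.character(grp),
                                      dist_to_centroid = 0),
           group_means = tapply(rep(0, length(labels)), grp, mean),
           singleton_groups = names(sizes)[sizes == 1],
           F = NA_real_, p_value = 1,
           n_permutations = n_perm, seed = seed),
      class = "betadisper_result"
    ))
  }
  bd <- vegan::betadisper(dd, grp, type = "centroid")
  pt <- with_preserved_rng({
    set.seed(seed)
    vegan::permutest(bd, permutations = n_perm)
  })
  sizes <- table(grp)
  structure(
    list(
      distances = tibble::tibble(
        sample_id = names(bd$distances) %||%
          as.character(seq_along(bd$distances)),
        group = as.character(grp),
        dist_to_centroid = unname(bd$distances)
      ),
      group_means = tapply(bd$distances, grp, mean),
      singleton_groups = names(sizes)[sizes == 1],
      F = unname(pt$tab[1, "F"]),
      p_value = unname(pt$tab[1, "Pr(>F)"]),
      n_permutations = n_perm, seed = seed
    ),
    class = "betadisper_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Nonparametric group comparisons
#'
#' Thin tidy wrappers over [stats::kruskal.test()] (tie-corrected H,
#' chi-square p) and the two-tailed [stats::wilcox.test()] (exact
#' enumeration at small n without ties, normal approximation with
#' continuity and tie correction otherwise).
#'
#' @param values Numeric vector.
#' @param groups Group label per value.
#' @return A one-row tibble of statistic and p-value.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2 || any(tab == 0)) stop("need >= 2 non-empty groups")
  if (length(unique(values)) == 1) {
    # all observations tied: H is 0/0, conventionally no evidence
    return(tibble::tibble(statistic = 0, df = length(tab) - 1,
                          p_value = 1))
  }
  k <- stats::kruskal.test(values, factor(groups))
  tibble::tibble(statistic = unname(k$statistic),
                 df = unname(k$parameter),
                 p_value = k$p.value)
}

#' @rdname kruskal_wallis
#' @param a,b Numeric samples.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  w <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  tibble::tibble(statistic = unname(w$statistic), p_value = w$p.value)
}

#' Inter-study alpha-diversity homogeneity filter
#'
#' Meta-analyses should not pool studies whose alpha-diversity
#' distributions differ outright. Starting from per-sample alpha values
#' labelled by study, this removes samples greedily — at each step the
#' single sample whose removal maximizes the Kruskal-Wallis p across
#' studies — until the studies are statistically indistinguishable
#' (p >= `alpha_level`) or the removal cap is hit.
#'
#' @param df Tibble with columns `sample_id`, `study`, `value`.
#' @param alpha_level Homogeneity is declared at KW p >= this level.
#' @param max_removed_fraction Cap on the fraction of samples removed.
#' @return A list: `retained` (tibble subset of `df`), `removed` (ordered
#'   removal log with the KW p after each removal), `homogeneous`
#'   (logical), `p_value` (final KW p).
#' @export
filter_alpha_homogeneous <- function(df, alpha_level = 0.05,
                                     max_removed_fraction = 0.3) {
  stopifnot(all(c("sample_id", "study", "value") %in% names(df)))
  if (length(unique(df$study)) < 2) stop("need >= 2 studies")
  cap <- floor(nrow(df) * max_removed_fraction)
  kw_p <- function(d) kruskal_wallis(d$value, d$study)$p_value
  cur <- df
  removed <- list()
  p <- kw_p(cur)
  while (p < alpha_level && length(removed) < cap) {
    # candidate removals must leave every study non-empty
    cand_p <- vapply(seq_len(nrow(cur)), function(i) {
      rest <- cur[-i, ]
      if (length(unique(rest$study)) < 2) return(-Inf)
      kw_p(rest)
    }, numeric(1))
    best <- which.max(cand_p)
    removed[[length(removed) + 1]] <- tibble::tibble(
      sample_id = cur$sample_id[best], study = cur$study[best],
      value = cur$value[best], p_after = cand_p[best]
    )
    cur <- cur[-best, ]
    p <- kw_p(cur)
  }
  homogeneous <- p >= alpha_level
  if (!homogeneous) {
    warning("removal cap reached with studies still heterogeneous ",
            sprintf("(KW p = %.3g)", p))
  }
  removal_log <- if (length(removed)) {
    dplyr::bind_rows(removed)
  } else {
    tibble::tibble(sample_id = character(), study = character(),
                   value = numeric(), p_after = numeric())
  }
  list(retained = cur, removed = removal_log,
       homogeneous = homogeneous, p_value = p)
}

#' Within-group pairwise distance samples
#'
#' Returns, per group, the multiset of within-group pairwise distances —
#' the raw material of community-similarity density plots and of
#' Kruskal-Wallis comparisons of within-group dispersion.
#'
#' @inheritParams permanova
#' @return Tibble with columns `group`, `sample_a`, `sample_b`,
#'   `distance`; groups of size < 2 contribute no rows and are listed in
#'   attribute `"degenerate_groups"`.
#' @export
pairwise_distance_density <- function(d, labels) {
  m <- as.matrix(d)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  labels <- as.character(labels)
  out <- purrr::map_dfr(unique(labels), function(g) {
    idx <- which(labels == g)
    if (length(idx) < 2) return(NULL)
    pr <- utils::combn(idx, 2)
    tibble::tibble(group = g, sample_a = ids[pr[1, ]],
                   sample_b = ids[pr[2, ]],
                   distance = m[cbind(pr[1, ], pr[2, ])])
  })
  attr(out, "degenerate_groups") <-
    setdiff(unique(labels), unique(out$group))
  out
}
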