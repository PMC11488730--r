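#' Per-feature linear-model differential abundance
#'
#' Fits, for one pairwise group comparison, an ordinary least-squares
#' model per taxon on total-sum-scaled, log2-transformed abundances
#' (pseudocount = half the taxon's minimum nonzero relative abundance),
#' with a two-sided t-test on the group coefficient and BH-FDR across
#' taxa. Taxa below the prevalence or abundance filter are excluded
#' before testing; features with zero variance after transformation are
#' excluded and logged.
#'
#' @param t Counts-scale [taxa_table()].
#' @param meta Metadata with `sample_id` and the `group_col` column.
#' @param comparison Character pair `c(first, second)`; the coefficient
#'   is the effect of the second group relative to the first, so
#'   `direction = "enriched"` means higher in the second group.
#' @param covariates Optional metadata columns adjusted for; defaults to
#'   none.
#' @param min_prevalence Minimum fraction of samples (within the two
#'   groups) in which a taxon must be nonzero.
#' @param min_abundance Minimum mean relative abundance.
#' @param group_col Metadata column holding the group labels.
#' @return A `da_result` tibble: `taxon_id`, `kingdom`, `comparison`,
#'   `coefficient`, `p_value`, `q_value`, `direction`, `mean_first`,
#'   `mean_second` (group means of relative abundance), `n_first`,
#'   `n_second`. Excluded taxa are listed in attribute `"excluded"`.
#' @export
fit_feature_lms <- function(t, meta, comparison, covariates = NULL,
                            min_prevalence = 0.1, min_abundance = 0,
                            group_col = "age_group") {
  stopifnot(inherits(t, "taxa_table"), length(comparison) == 2)
  meta <- meta[match(rownames(t$values), meta$sample_id), ]
  grp <- as.character(meta[[group_col]])
  keep <- which(grp %in% comparison)
  if (sum(grp[keep] == comparison[1]) < 3 ||
      sum(grp[keep] == comparison[2]) < 3) {
    stop("both groups need >= 3 samples")
  }
  rel <- to_relative(t)$values[keep, , drop = FALSE]
  grp <- grp[keep]
  prev <- colMeans(rel > 0)
  ab <- colMeans(rel)
  sel <- prev >= min_prevalence & ab >= min_abundance
  excluded <- tibble::tibble(
    taxon_id = colnames(rel)[!sel],
    reason = ifelse(prev[!sel] < min_prevalence, "prevalence", "abundance")
  )
  rel <- rel[, sel, drop = FALSE]
  if (!ncol(rel)) stop("no taxa pass the filters")

  # MaAsLin2-style transform: per-feature half-min-nonzero pseudocount
  pseudo <- apply(rel, 2, function(x) {
    nz <- x[x > 0]
    if (length(nz)) min(nz) / 2 else 1e-9
  })
  y <- log2(sweep(rel, 2, pseudo, `+`))

  is_second <- as.numeric(grp == comparison[2])
  x_df <- data.frame(.group = is_second)
  if (!is.null(covariates)) {
    for (cv in covariates) x_df[[cv]] <- meta[[cv]][keep]
  }
  x <- stats::model.matrix(~ ., data = x_df)
  coef_idx <- 2L  # .group is the first term after the intercept
  n <- nrow(x)
  rank_x <- qr(x)$rank
  df_res <- n - rank_x

  zero_var <- apply(y, 2, function(col) stats::var(col) == 0)
  fit <- stats::lm.fit(x, y[, !zero_var, drop = FALSE])
  res <- as.matrix(fit$residuals)
  sigma2 <- colSums(res^2) / df_res
  xtx_inv <- chol2inv(chol(crossprod(x)))
  se <- sqrt(sigma2 * xtx_inv[coef_idx, coef_idx])
  beta <- fit$coefficients[coef_idx, ]
  tstat <- ifelse(se > 0, beta / se, 0)
  p <- 2 * stats::pt(-abs(tstat), df_res)
  p[se == 0] <- 1

  taxa <- colnames(y)[!zero_var]
  q <- bh_adjust(p)
  mean_first <- colMeans(rel[grp == comparison[1], taxa, drop = FALSE])
  mean_second <- colMeans(rel[grp == comparison[2], taxa, drop = FALSE])
  out <- tibble::tibble(
    taxon_id = taxa,
    kingdom = unname(t$kingdom[taxa]),
    comparison = paste0(comparison[1], "_vs_", comparison[2]),
    coefficient = unname(beta),
    p_value = unname(p),
    q_value = unname(q),
    direction = ifelse(beta >= 0, "enriched", "depleted"),
    mean_first = unname(mean_first),
    mean_second = unname(mean_second),
    n_first = sum(grp == comparison[1]),
    n_second = sum(grp == comparison[2])
  )
  if (any(zero_var)) {
    excluded <- dplyr::bind_rows(
      excluded,
      tibble::tibble(taxon_id = colnames(y)[zero_var],
                     reason = "zero variance")
    )
  }
  attr(out, "excluded") <- excluded
  class(out) <- c("da_result", class(out))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' order-preserving with the input (delegates to
#' [stats::p.adjust()]).
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially abundant microbes (DAMs)
#'
#' A taxon is a DAM for a comparison when its BH-adjusted p-value is
#' strictly below the threshold (default 0.25).
#'
#' @param results A `da_result` tibble (or a row-bound set of them).
#' @param q_threshold Strict upper bound on the q-value.
#' @return Tibble of DAMs: `comparison`, `taxon_id`, `kingdom`,
#'   `direction`, `q_value`.
#' @export
call_dams <- function(results, q_threshold = 0.25) {
  if (q_threshold <= 0 || q_threshold > 1) {
    stop("q_threshold must be in (0, 1]")
  }
  out <- dplyr::filter(results, .data$q_value < q_threshold)
  tibble::as_tibble(out[, c("comparison", "taxon_id", "kingdom",
                            "direction", "q_value")])
}

#' Venn overlap of per-comparison DAM sets
#'
#' @param sets Named list of taxon-id character vectors (one per
#'   comparison), or a DAM tibble from [call_dams()] (split on
#'   `comparison`).
#' @return A list: `intersection` (taxa common to all sets),
#'   `exclusive` (named list of taxa unique to each set), `counts`
#'   (tibble of region sizes).
#' @export
dam_overlap <- function(sets) {
  if (is.data.frame(sets)) {
    sets <- split(sets$taxon_id, sets$comparison)
  }
  sets <- lapply(sets, unique)
  inter <- Reduce(intersect, sets)
  excl <- lapply(seq_along(sets), function(i) {
    setdiff(sets[[i]], unique(unlist(sets[-i])))
  })
  names(excl) <- names(sets)
  counts <- tibble::tibble(
    region = c(names(sets), "intersection"),
    n = c(vapply(excl, length, integer(1)), length(inter))
  )
  list(intersection = inter, exclusive = excl, counts = counts)
}

#' Fold changes and heatmap values for selected taxa
#'
#' Log2 fold changes on the count scale with pseudocount 1 —
#' `log2((mean_A + 1) / (mean_B + 1))` — for every pairwise group
#' comparison, plus the per-sample heatmap values `log2(count + 1)`.
#'
#' @param t Counts-scale [taxa_table()].
#' @param groups Group label per sample.
#' @param selected_taxa Taxa to tabulate.
#' @return A list: `fold_changes` (tibble: taxon_id, comparison,
#'   log2_fc) and `heatmap` (tibble: sample_id, group, taxon_id,
#'   log2_reads).
#' @export
fold_change_table <- function(t, groups, selected_taxa) {
  unknown <- setdiff(selected_taxa, colnames(t$values))
  if (length(unknown)) stop("unknown taxon: ", unknown[1])
  groups <- as.character(groups)
  v <- t$values[, selected_taxa, drop = FALSE]
  glev <- unique(groups)
  means <- vapply(glev, function(g) {
    colMeans(v[groups == g, , drop = FALSE])
  }, numeric(length(selected_taxa)))
  if (length(selected_taxa) == 1) {
    means <- matrix(means, nrow = 1,
                    dimnames = list(selected_taxa, glev))
  }
  pairs <- utils::combn(glev, 2, simplify = FALSE)
  fc <- purrr::map_dfr(pairs, function(pr) {
    tibble::tibble(
      taxon_id = selected_taxa,
      comparison = paste0(pr[1], "_vs_", pr[2]),
      log2_fc = unname(log2((means[, pr[1]] + 1) / (means[, pr[2]] + 1)))
    )
  })
  heat <- tibble::tibble(
    sample_id = rep(rownames(v), times = ncol(v)),
    group = rep(groups, times = ncol(v)),
    taxon_id = rep(colnames(v), each = nrow(v)),
    log2_reads = log2(as.vector(v) + 1)
  )
  list(fold_changes = fc, heatmap = heat)
}
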