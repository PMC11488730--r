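#' Configure the quantile-matching batch correction
#'
#' @param reference_batch Batch id whose distributions are the target;
#'   it is returned unchanged by the correction.
#' @param covariates Metadata columns defining the strata within which
#'   distributions are matched. `"reads_tertile"` is derived from
#'   `raw_reads` (tertile discretization of the sequencing depth).
#' @param min_stratum Minimum samples a (stratum, batch) cell needs for
#'   correction; smaller cells are left uncorrected and logged.
#' @param quantile_grid Number of probability points used when checking
#'   quantile alignment (not the mapping itself, which uses the full
#'   empirical CDF).
#' @return A `correction_config` list.
#' @export
correction_config <- function(reference_batch,
                              covariates = c("age_group", "gender",
                                             "reads_tertile"),
                              min_stratum = 2,
                              quantile_grid = 101) {
  if (min_stratum < 2) stop("min_stratum must be >= 2")
  structure(list(reference_batch = reference_batch,
                 covariates = covariates,
                 min_stratum = min_stratum,
                 quantile_grid = quantile_grid),
            class = "correction_config")
}

stratum_labels <- function(meta, covariates) {
  cols <- lapply(covariates, function(cv) {
    if (cv == "reads_tertile") {
      if (!"raw_reads" %in% names(meta)) {
        stop("covariate reads_tertile needs a raw_reads column")
      }
      # tertiles are taken within batch: depth differs systematically
      # between cohorts, and an absolute cut would confound the stratum
      # with the very batch label being corrected
      tert <- rep(NA_character_, nrow(meta))
      for (b in unique(meta$batch_id)) {
        idx <- which(meta$batch_id == b)
        r <- rank(meta$raw_reads[idx], ties.method = "first")
        tert[idx] <- as.character(ceiling(3 * r / length(idx)))
      }
      tert
    } else {
      if (!cv %in% names(meta)) stop("covariate missing from metadata: ", cv)
      as.character(meta[[cv]])
    }
  })
  do.call(paste, c(cols, sep = "|"))
}

#' Two-part stratified quantile batch correction
#'
#' A simplified conditional-quantile alignment of per-taxon count
#' distributions across batches, within covariate strata (age group,
#' gender, read-depth tertile by default). Per taxon and stratum: the
#' zero part moves each non-reference batch's zero fraction toward the
#' reference batch's zero fraction (zeroing the smallest nonzero values,
#' or seeding zeros with reference quantiles, by seeded random choice of
#' which cells to toggle); the nonzero part maps each non-reference
#' batch's remaining nonzero values through its empirical CDF onto the
#' reference batch's empirical quantile function. The reference batch is
#' returned bit-identical. Counts-scale outputs are rounded to
#' non-negative integers; other scales are corrected in place without
#' rounding.
#'
#' @param t A [taxa_table()].
#' @param meta Metadata tibble with `sample_id`, `batch_id` and the
#'   configured covariates.
#' @param cfg A [correction_config()].
#' @param seed Integer seed for the zero-part toggling.
#' @return A corrected `taxa_table` on the input scale, with attribute
#'   `"uncorrected_cells"` logging (taxon, stratum, batch) cells left
#'   untouched for want of data.
#' @export
quantile_batch_correct <- function(t, meta, cfg, seed = 1) {
  stopifnot(inherits(t, "taxa_table"), inherits(cfg, "correction_config"))
  meta <- meta[match(rownames(t$values), meta$sample_id), ]
  if (anyNA(meta$sample_id)) stop("metadata missing for some samples")
  batches <- unique(meta$batch_id)
  if (length(batches) < 2) {
    warning("single batch: table returned unchanged")
    return(t)
  }
  if (!cfg$reference_batch %in% batches) {
    stop("reference batch not present: ", cfg$reference_batch)
  }
  strata <- stratum_labels(meta, cfg$covariates)
  v <- t$values
  out <- v
  skipped <- list()
  with_preserved_rng({
    set.seed(seed)
    for (s in unique(strata)) {
      in_s <- which(strata == s)
      ref_idx <- in_s[meta$batch_id[in_s] == cfg$reference_batch]
      other_batches <- setdiff(unique(meta$batch_id[in_s]),
                               cfg$reference_batch)
      for (b in other_batches) {
        b_idx <- in_s[meta$batch_id[in_s] == b]
        if (length(ref_idx) < cfg$min_stratum ||
            length(b_idx) < cfg$min_stratum) {
          skipped[[length(skipped) + 1]] <-
            tibble::tibble(stratum = s, batch = b,
                           reason = "stratum below min size")
          next
        }
        for (j in seq_len(ncol(v))) {
          out[b_idx, j] <- correct_cell(v[b_idx, j], v[ref_idx, j],
                                        integer_out =
                                          t$scale == "counts")
        }
      }
    }
  })
  if (is.integer(v) && t$scale == "counts") storage.mode(out) <- "integer"
  res <- t
  res$values <- out
  attr(res, "uncorrected_cells") <- dplyr::bind_rows(skipped)
  res
}

# Align one batch's values for one taxon in one stratum onto the
# reference distribution: zero-fraction shrinkage, then ECDF->quantile
# mapping of the nonzero part.
correct_cell <- function(x, ref, integer_out) {
  n <- length(x)
  z_x <- mean(x == 0)
  z_ref <- mean(ref == 0)
  ref_nz <- sort(ref[ref > 0])
  y <- x
  if (z_x > z_ref) {
    if (length(ref_nz)) {
      zeros <- which(y == 0)
      n_fill <- round((z_x - z_ref) * n)
      if (n_fill > 0) {
        fill <- sample(zeros, min(n_fill, length(zeros)))
        y[fill] <- stats::quantile(ref_nz, stats::runif(length(fill)),
                                   names = FALSE, type = 7)
      }
    }
  } else if (z_x < z_ref) {
    nz <- which(y > 0)
    n_zero <- round((z_ref - z_x) * n)
    if (n_zero > 0 && length(nz)) {
      # zero out the smallest nonzero values: mass-preserving direction
      ord <- nz[order(y[nz])]
      y[ord[seq_len(min(n_zero, length(ord)))]] <- 0
    }
  }
  nz <- which(y > 0)
  if (length(nz) && length(ref_nz)) {
    u <- (rank(y[nz], ties.method = "average") - 0.5) / length(nz)
    y[nz] <- stats::quantile(ref_nz, u, names = FALSE, type = 7)
  }
  if (integer_out) y <- round(y)
  pmax(y, 0)
}

eval_representations <- c("taxa_reads", "corrected_taxa_reads", "rpm",
                          "corrected_rpm", "rpm_after_correction")

#' PERMANOVA evaluation grid for batch correction
#'
#' Quantifies, for five data representations (raw counts, corrected
#' counts, RPM, RPM corrected directly, and RPM of the corrected counts),
#' how much community variation is explained by batch versus by age
#' group, under Bray-Curtis and Aitchison distances. A correction that
#' works drives the batch R-squared down while retaining the age-group
#' R-squared.
#'
#' @param raw Counts-scale [taxa_table()].
#' @param corrected Its corrected counterpart (same samples); pass the
#'   output of [quantile_batch_correct()] or any externally corrected
#'   table.
#' @param meta Metadata with `batch_id` and `age_group`.
#' @param n_perm,seed Permutation settings for the PERMANOVAs.
#' @param cfg,corrected_rpm Optional: config used to correct the RPM
#'   representation directly (defaults to re-using `cfg`); or a
#'   pre-corrected RPM table.
#' @return An `eval_grid` tibble: one row per (representation, metric,
#'   factor) with columns `R2` and `p_value`.
#' @export
evaluate_batch_grid <- function(raw, corrected, meta, n_perm = 199,
                                seed = 1, cfg = NULL,
                                corrected_rpm = NULL) {
  stopifnot(identical(rownames(raw$values), rownames(corrected$values)))
  meta <- meta[match(rownames(raw$values), meta$sample_id), ]
  if (!"age_group" %in% names(meta) || anyNA(meta$age_group)) {
    stop("metadata must carry a complete age_group column")
  }
  rpm_raw <- to_rpm(raw)
  if (is.null(corrected_rpm)) {
    corrected_rpm <- if (!is.null(cfg)) {
      quantile_batch_correct(rpm_raw, meta, cfg, seed = seed)
    } else {
      NULL
    }
  }
  reps <- list(
    taxa_reads = raw,
    corrected_taxa_reads = corrected,
    rpm = rpm_raw,
    corrected_rpm = corrected_rpm,
    rpm_after_correction = to_rpm(corrected)
  )
  rows <- list()
  for (rep_name in names(reps)) {
    tab <- reps[[rep_name]]
    if (is.null(tab)) next
    for (metric in c("bray_curtis", "aitchison")) {
      d <- if (metric == "bray_curtis") bray_curtis_matrix(tab)
           else aitchison_matrix(tab)
      for (fac in c("batch_id", "age_group")) {
        pr <- permanova(d, meta[[fac]], n_perm = n_perm, seed = seed)
        rows[[length(rows) + 1]] <- tibble::tibble(
          representation = rep_name, metric = metric,
          factor = if (fac == "batch_id") "batch" else "age_group",
          R2 = pr$R2, pseudo_F = pr$pseudo_F, p_value = pr$p_value
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$representation <- factor(out$representation,
                               levels = eval_representations)
  class(out) <- c("eval_grid", class(out))
  out
}

#' Taxon counts and kingdom balance before/after correction
#'
#' Counts, per age group, how many taxa have nonzero total abundance
#' before and after a correction, and the kingdom proportions among them.
#'
#' @param before,after [taxa_table()]s over the same samples.
#' @param groups Group label per sample.
#' @return A list of tibbles: `taxon_counts` (group, stage, n_taxa) and
#'   `kingdom_proportions` (group, stage, kingdom, proportion).
#' @export
taxa_count_shift <- function(before, after, groups) {
  stopifnot(identical(rownames(before$values), rownames(after$values)))
  groups <- as.character(groups)
  per_stage <- function(t, stage) {
    purrr::map_dfr(unique(groups), function(g) {
      present <- colSums(t$values[groups == g, , drop = FALSE]) > 0
      kt <- table(factor(t$kingdom[present], levels = valid_kingdoms))
      tibble::tibble(group = g, stage = stage,
                     n_taxa = sum(present),
                     kingdom = names(kt),
                     n_kingdom = as.integer(kt))
    })
  }
  long <- dplyr::bind_rows(per_stage(before, "before"),
                           per_stage(after, "after"))
  counts <- dplyr::distinct(long, .data$group, .data$stage, .data$n_taxa)
  props <- dplyr::mutate(
    long,
    proportion = ifelse(.data$n_taxa > 0,
                        .data$n_kingdom / .data$n_taxa, 0)
  )[, c("group", "stage", "kingdom", "n_kingdom", "proportion")]
  list(taxon_counts = counts, kingdom_proportions = props)
}
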