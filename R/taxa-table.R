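#' Construct a taxa abundance table
#'
#' The central container of the pipeline: a samples-by-taxa matrix of
#' non-negative counts or abundances, with a kingdom annotation per taxon
#' and a scale tag recording which representation the values are on.
#'
#' @param values Numeric matrix, samples in rows, taxa in columns. Row and
#'   column names are used as sample and taxon identifiers and must be
#'   unique.
#' @param kingdom Named character vector mapping every taxon id to one of
#'   `"bacteria"`, `"fungi"`, `"archaea"`, `"viruses"`.
#' @param scale One of `"counts"`, `"rpm"`, `"relative"`, `"clr"`.
#'
#' @return A `taxa_table` object.
#' @export
taxa_table <- function(values, kingdom,
                       scale = c("counts", "rpm", "relative", "clr")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have sample row names and taxon column names")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicate taxon ids")
  if (scale != "clr" && any(values < 0)) {
    stop("negative values are not allowed on scale '", scale, "'")
  }
  kingdom <- validate_kingdom(kingdom, colnames(values))
  if (scale == "relative") {
    rs <- rowSums(values)
    bad <- abs(rs - 1) > 1e-9 & rs > 0
    if (any(bad)) {
      stop("relative-scale rows must sum to 1: ",
           paste(rownames(values)[bad][seq_len(min(3, sum(bad)))],
                 collapse = ", "))
    }
  }
  structure(
    list(values = values, scale = scale, kingdom = kingdom),
    class = "taxa_table"
  )
}

valid_kingdoms <- c("bacteria", "fungi", "archaea", "viruses")

validate_kingdom <- function(kingdom, taxa) {
  if (is.null(names(kingdom))) stop("`kingdom` must be named by taxon id")
  missing <- setdiff(taxa, names(kingdom))
  if (length(missing)) {
    stop("taxa without kingdom annotation: ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  kingdom <- kingdom[taxa]
  bad <- !kingdom %in% valid_kingdoms
  if (any(bad)) {
    stop("unknown kingdom value(s): ",
         paste(unique(kingdom[bad]), collapse = ", "))
  }
  kingdom
}

#' @export
print.taxa_table <- function(x, ...) {
  cat(sprintf(
    "<taxa_table> %d samples x %d taxa [scale: %s]\n",
    nrow(x$values), ncol(x$values), x$scale
  ))
  kt <- table(factor(x$kingdom, levels = valid_kingdoms))
  cat("  kingdoms:", paste(sprintf("%s %d", names(kt), kt), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.taxa_table <- function(x) dim(x$values)

#' @rdname taxa_table
#' @export
sample_ids <- function(t) rownames(t$values)

#' @rdname taxa_table
#' @export
taxon_ids <- function(t) colnames(t$values)

#' Convert a taxa table to a long tibble
#'
#' One row per (sample, taxon) pair, carrying the kingdom and the value on
#' the table's current scale.
#'
#' @param x A `taxa_table`.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `taxon_id`, `kingdom`,
#'   `value`, `scale`.
#' @method as_tibble taxa_table
#' @export
as_tibble.taxa_table <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(rownames(x$values), times = ncol(x$values)),
    taxon_id = rep(colnames(x$values), each = nrow(x$values)),
    kingdom = rep(unname(x$kingdom), each = nrow(x$values)),
    value = as.vector(x$values),
    scale = x$scale
  )
}

#' Read per-sample species report files into a taxa table
#'
#' Parses one tab-separated species report per sample (bracken-style),
#' takes the union of all taxa across files, and zero-fills taxa absent
#' from a sample. The species-name column and estimated-read-count column
#' are located by the header names `name` and `new_est_reads` when present,
#' otherwise the first column and last numeric column are used.
#'
#' @param paths Character vector of report paths; names, if set, become
#'   sample ids (otherwise the file base name is used).
#' @param kingdom Named character vector mapping taxa to kingdoms.
#' @return A counts-scale [taxa_table()] with samples in input order.
#' @export
read_bracken_reports <- function(paths, kingdom) {
  if (anyDuplicated(paths)) {
    stop("duplicate report path: ", paths[duplicated(paths)][1])
  }
  ids <- if (!is.null(names(paths)) && all(nzchar(names(paths)))) {
    names(paths)
  } else {
    sub("\\.[^.]*$", "", basename(paths))
  }
  per_sample <- lapply(seq_along(paths), function(i) {
    p <- paths[i]
    if (!file.exists(p)) stop("missing report file: ", p)
    df <- utils::read.delim(p, check.names = FALSE,
                            stringsAsFactors = FALSE)
    nm <- tolower(names(df))
    name_col <- if ("name" %in% nm) which(nm == "name")[1] else 1L
    cnt_col <- if ("new_est_reads" %in% nm) {
      which(nm == "new_est_reads")[1]
    } else {
      numeric_cols <- which(vapply(df, is.numeric, logical(1)))
      if (!length(numeric_cols)) stop("no count column found in ", p)
      numeric_cols[length(numeric_cols)]
    }
    counts <- df[[cnt_col]]
    if (any(counts < 0)) {
      stop("negative count in ", p, " at row ", which(counts < 0)[1])
    }
    stats::setNames(as.numeric(counts), as.character(df[[name_col]]))
  })
  all_taxa <- unique(unlist(lapply(per_sample, names)))
  mat <- matrix(0, nrow = length(paths), ncol = length(all_taxa),
                dimnames = list(ids, all_taxa))
  for (i in seq_along(per_sample)) {
    mat[i, names(per_sample[[i]])] <- per_sample[[i]]
  }
  zero_rows <- rowSums(mat) == 0
  if (any(zero_rows)) {
    warning("sample(s) with zero total counts: ",
            paste(ids[zero_rows], collapse = ", "))
  }
  taxa_table(mat, kingdom, scale = "counts")
}

#' Read and write a merged count matrix
#'
#' The merged dialect is a TSV with samples as rows, taxa as columns and
#' the sample identifier in the first column (`sample_id`). A kingdom
#' sidecar TSV has columns `taxon_id` and `kingdom`.
#'
#' @param path File path.
#' @param kingdom Named character vector (e.g. from [read_kingdom_map()]).
#' @param scale Value scale of the stored matrix.
#' @return `read_taxa_table()` returns a [taxa_table()];
#'   `write_taxa_table()` returns `path` invisibly.
#' @export
read_taxa_table <- function(path, kingdom, scale = "counts") {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (names(df)[1] != "sample_id") {
    stop("first column of a merged matrix must be 'sample_id'")
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- as.character(df[[1]])
  taxa_table(mat, kingdom, scale = scale)
}

#' @rdname read_taxa_table
#' @param t A `taxa_table`.
#' @export
write_taxa_table <- function(t, path) {
  df <- data.frame(sample_id = rownames(t$values), t$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_taxa_table
#' @export
read_kingdom_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("taxon_id", "kingdom") %in% names(df))) {
    stop("kingdom sidecar must have columns taxon_id, kingdom")
  }
  stats::setNames(df$kingdom, df$taxon_id)
}

#' @rdname read_taxa_table
#' @export
write_kingdom_map <- function(kingdom, path) {
  utils::write.table(
    data.frame(taxon_id = names(kingdom), kingdom = unname(kingdom)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a sample metadata table
#'
#' Required columns: `sample_id`, `age`, `gender`, `batch_id`. Optional
#' recognized columns: `run_id`, `platform`, `raw_reads`, `assigned_reads`,
#' `age_group`; any further columns are carried through untouched.
#'
#' @param path TSV path.
#' @return A tibble, one row per sample.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  required <- c("sample_id", "age", "gender", "batch_id")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing column: ", paste(missing, collapse = ", "))
  }
  age_num <- suppressWarnings(as.numeric(df$age))
  if (anyNA(age_num)) {
    stop("non-numeric age for sample: ",
         paste(df$sample_id[is.na(age_num)], collapse = ", "))
  }
  df$age <- age_num
  if (any(df$age <= 0)) {
    stop("age must be positive; offending sample: ",
         df$sample_id[df$age <= 0][1])
  }
  if (all(c("raw_reads", "assigned_reads") %in% names(df))) {
    bad <- df$assigned_reads > df$raw_reads | df$assigned_reads < 0
    if (any(bad)) {
      stop("assigned_reads must satisfy 0 <= assigned <= raw for sample: ",
           df$sample_id[bad][1])
    }
  }
  tibble::as_tibble(df)
}

#' @rdname read_metadata
#' @param meta Metadata tibble.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Age-group schemes
#'
#' An age-group scheme is an ordered set of non-overlapping half-open
#' intervals `[min_age, max_age)`; samples falling outside every interval
#' stay unassigned. Two schemes are bundled: `scheme_wrc()` — W (< 62),
#' R (62 to < 89), C (>= 89), the whole-cohort stratification — and
#' `scheme_yec()` — Y (< 55), E (strictly between 66 and 90), C (> 95),
#' the post-filtering analysis strata. The pipeline never picks one
#' silently: `pipeline_config()` requires an explicit choice.
#'
#' @param labels Character vector of unique group labels.
#' @param min_age,max_age Numeric vectors of interval bounds, inclusive
#'   lower, exclusive upper.
#' @return A tibble with class `age_group_scheme`.
#' @export
age_group_scheme <- function(labels, min_age, max_age) {
  stopifnot(length(labels) == length(min_age),
            length(labels) == length(max_age))
  if (anyDuplicated(labels)) stop("scheme labels must be unique")
  if (any(max_age <= min_age)) stop("empty interval in scheme")
  sch <- tibble::tibble(label = labels, min_age = min_age,
                        max_age = max_age)
  sch <- sch[order(sch$min_age), ]
  if (any(sch$max_age[-nrow(sch)] > sch$min_age[-1] + 1e-12)) {
    stop("scheme intervals overlap")
  }
  class(sch) <- c("age_group_scheme", class(sch))
  sch
}

#' @rdname age_group_scheme
#' @export
scheme_wrc <- function() {
  age_group_scheme(c("W", "R", "C"), c(0, 62, 89), c(62, 89, Inf))
}

#' @rdname age_group_scheme
#' @export
scheme_yec <- function() {
  # E is "66 < age < 90", C is "age > 95": open lower bounds, so shift by
  # one year on the integer age scale
  age_group_scheme(c("Y", "E", "C"), c(0, 67, 96), c(55, 90, Inf))
}

#' Assign samples to age groups
#'
#' @param meta Metadata tibble with an `age` column.
#' @param scheme An [age_group_scheme()].
#' @return `meta` with an `age_group` column (`NA` when unassigned); the
#'   per-label counts are attached as attribute `"age_group_counts"`.
#' @export
assign_age_groups <- function(meta, scheme) {
  lab <- rep(NA_character_, nrow(meta))
  for (i in seq_len(nrow(scheme))) {
    hit <- meta$age >= scheme$min_age[i] & meta$age < scheme$max_age[i]
    lab[hit] <- scheme$label[i]
  }
  out <- dplyr::mutate(meta, age_group = lab)
  attr(out, "age_group_counts") <-
    table(factor(lab, levels = scheme$label), useNA = "ifany")
  out
}

#' Abundance transformations
#'
#' `to_relative()` rescales each sample to proportions (total-sum
#' scaling); `to_rpm()` to reads per million; `clr_transform()` applies the
#' centered log-ratio after adding a pseudocount. All-zero rows stay zero
#' under TSS/RPM (with a warning) and are an error under CLR, where the
#' transform is undefined.
#'
#' @param t A counts-scale `taxa_table` (CLR also accepts relative scale).
#' @return A `taxa_table` on the requested scale.
#' @export
to_relative <- function(t) {
  if (t$scale != "counts") stop("to_relative expects a counts-scale table")
  rescale_rows(t, 1, "relative")
}

#' @rdname to_relative
#' @export
to_rpm <- function(t) {
  if (t$scale != "counts") stop("to_rpm expects a counts-scale table")
  rescale_rows(t, 1e6, "rpm")
}

rescale_rows <- function(t, factor, scale) {
  rs <- rowSums(t$values)
  if (any(rs == 0)) {
    warning("all-zero sample(s) left as zero: ",
            paste(rownames(t$values)[rs == 0], collapse = ", "))
  }
  v <- t$values / ifelse(rs == 0, 1, rs) * factor
  out <- t
  out$values <- v
  out$scale <- scale
  out
}

#' @rdname to_relative
#' @param pseudocount Pseudocount added before the log. The default
#'   `NULL` uses half the smallest nonzero relative abundance in the whole
#'   table, a standard compositional-data convention that keeps
#'   zero-handling deterministic.
#' @export
clr_transform <- function(t, pseudocount = NULL) {
  if (!t$scale %in% c("counts", "relative", "rpm")) {
    stop("clr_transform expects counts, rpm or relative scale")
  }
  rs <- rowSums(t$values)
  if (any(rs == 0)) {
    stop("CLR undefined for all-zero sample: ",
         rownames(t$values)[rs == 0][1])
  }
  rel <- t$values / rs
  if (is.null(pseudocount)) {
    nz <- rel[rel > 0]
    pseudocount <- min(nz) / 2
  }
  lg <- log(rel + pseudocount)
  v <- lg - rowMeans(lg)
  out <- t
  out$values <- v
  out$scale <- "clr"
  out
}
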