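#' Configure a full pipeline run
#'
#' Collects every stage's settings into one validated object. Either
#' `simulation` (a [synthetic_config()]) or all three of
#' `counts_path`/`metadata_path`/`kingdom_path` must be given. The
#' age-group scheme is an explicit choice — there is no silent default
#' between the whole-cohort (W/R/C) and analysis (Y/E/C) stratifications.
#'
#' @param seed Global seed; every stochastic stage is re-seeded from it
#'   by a fixed stage-name derivation, so stages are independently
#'   reproducible.
#' @param out_dir Output directory, created if needed.
#' @param simulation Optional [synthetic_config()].
#' @param counts_path,metadata_path,kingdom_path Input TSVs when not
#'   simulating.
#' @param scheme An [age_group_scheme()], or `NULL` when the metadata
#'   (or simulator) already carries `age_group`.
#' @param reference_batch Reference for [quantile_batch_correct()];
#'   default: first batch id in the metadata.
#' @param correction_covariates,min_stratum Correction settings.
#' @param q_threshold,min_prevalence,da_covariates Differential
#'   abundance settings.
#' @param r_min,network_alpha,walktrap_steps,membership_min Network
#'   settings.
#' @param background_mode,enrichment_alpha Enrichment settings.
#' @param focal_taxa Taxa for interaction-shift analysis; default: up to
#'   3 recovered signatures (one per group).
#' @param homogeneity_alpha,max_removed_fraction Alpha-homogeneity
#'   filter settings (the "studies" are the batches).
#' @param n_perm Permutations for PERMANOVA/betadisper stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed, out_dir,
                            simulation = NULL,
                            counts_path = NULL, metadata_path = NULL,
                            kingdom_path = NULL,
                            scheme = NULL,
                            reference_batch = NULL,
                            correction_covariates = c("age_group",
                                                      "gender",
                                                      "reads_tertile"),
                            min_stratum = 2,
                            q_threshold = 0.25,
                            min_prevalence = 0.1,
                            da_covariates = NULL,
                            r_min = 0.3, network_alpha = 0.05,
                            walktrap_steps = 4, membership_min = 10,
                            background_mode = "clusters_union_dams",
                            enrichment_alpha = 0.05,
                            focal_taxa = NULL,
                            homogeneity_alpha = 0.05,
                            max_removed_fraction = 0.3,
                            n_perm = 199) {
  if (missing(seed)) stop("`seed` is mandatory")
  if (is.null(simulation) &&
      (is.null(counts_path) || is.null(metadata_path) ||
       is.null(kingdom_path))) {
    stop("either `simulation` or all three input paths must be given")
  }
  for (thr in c(q_threshold, min_prevalence, network_alpha,
                enrichment_alpha, homogeneity_alpha,
                max_removed_fraction)) {
    if (thr < 0 || thr > 1) stop("threshold out of [0, 1]: ", thr)
  }
  if (r_min < 0 || r_min >= 1) stop("r_min must be in [0, 1)")
  structure(
    list(seed = as.integer(seed), out_dir = out_dir,
         simulation = simulation, counts_path = counts_path,
         metadata_path = metadata_path, kingdom_path = kingdom_path,
         scheme = scheme, reference_batch = reference_batch,
         correction_covariates = correction_covariates,
         min_stratum = min_stratum,
         q_threshold = q_threshold, min_prevalence = min_prevalence,
         da_covariates = da_covariates,
         r_min = r_min, network_alpha = network_alpha,
         walktrap_steps = walktrap_steps,
         membership_min = membership_min,
         background_mode = background_mode,
         enrichment_alpha = enrichment_alpha,
         focal_taxa = focal_taxa,
         homogeneity_alpha = homogeneity_alpha,
         max_removed_fraction = max_removed_fraction,
         n_perm = n_perm,
         version = 1L),
    class = "pipeline_config"
  )
}

# Deterministic per-stage seed: global seed folded with a stage-name
# hash, kept under 2^31.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (seed * 1009L + as.integer(h)) %% 2147483647L
}

write_result_tsv <- function(df, path, params) {
  if (!ncol(df)) df <- data.frame(note = "empty result")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# params: ", params), con)
  utils::write.table(as.data.frame(df), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full meta-analysis pipeline
#'
#' Executes the stages in order — simulate/load, batch correction plus
#' evaluation grid, diversity with the inter-study homogeneity filter,
#' pairwise differential abundance with DAM calling and Venn overlap,
#' per-group co-occurrence networks with walktrap clustering, cluster
#' enrichment, age-stage signature calling, and interaction shifts for
#' the focal taxa — writing every result table under `cfg$out_dir` and
#' returning a manifest with parameters, per-stage seeds and output
#' checksums. Re-running with an identical config reproduces
#' byte-identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return The manifest (list), invisibly written to
#'   `manifest.json` as well. The `results` element holds the in-memory
#'   stage outputs.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character()
  res <- list()
  pfx <- function(name) file.path(cfg$out_dir, name)

  # -- stage 1: inputs ------------------------------------------------
  if (!is.null(cfg$simulation)) {
    sim_cfg <- cfg$simulation
    sim_cfg$seed <- stage_seed(cfg$seed, "simulate")
    sim <- generate_cohort(sim_cfg)
    counts <- sim$counts
    meta <- sim$metadata
    write_taxa_table(counts, pfx("counts.tsv"))
    write_kingdom_map(counts$kingdom, pfx("kingdom.tsv"))
    ground_truth_report(sim$truth, pfx("ground_truth.json"))
    res$truth <- sim$truth
  } else {
    kingdom <- read_kingdom_map(cfg$kingdom_path)
    counts <- read_taxa_table(cfg$counts_path, kingdom)
    meta <- read_metadata(cfg$metadata_path)
    meta <- meta[match(rownames(counts$values), meta$sample_id), ]
  }
  if (!is.null(cfg$scheme)) {
    meta <- assign_age_groups(meta, cfg$scheme)
  }
  if (!"age_group" %in% names(meta) || all(is.na(meta$age_group))) {
    stop("stage inputs: no age_group available; supply a scheme")
  }
  assigned <- !is.na(meta$age_group)
  meta <- meta[assigned, ]
  counts$values <- counts$values[meta$sample_id, , drop = FALSE]
  write_metadata(meta, pfx("metadata.tsv"))
  stages <- c(stages, "inputs")

  # -- stage 2: batch correction + evaluation grid --------------------
  ref <- cfg$reference_batch %||% meta$batch_id[1]
  ccfg <- correction_config(ref, cfg$correction_covariates,
                            cfg$min_stratum)
  corrected <- quantile_batch_correct(counts, meta, ccfg,
                                      seed = stage_seed(cfg$seed,
                                                        "correct"))
  write_taxa_table(corrected, pfx("corrected_counts.tsv"))
  grid <- evaluate_batch_grid(counts, corrected, meta,
                              n_perm = cfg$n_perm,
                              seed = stage_seed(cfg$seed, "grid"),
                              cfg = ccfg)
  write_result_tsv(grid, pfx("eval_grid.tsv"),
                   sprintf("n_perm=%d reference_batch=%s", cfg$n_perm,
                           ref))
  res$eval_grid <- grid
  res$shift <- taxa_count_shift(counts, corrected, meta$age_group)
  write_result_tsv(res$shift$taxon_counts, pfx("taxa_count_shift.tsv"),
                   "per-group nonzero taxon counts")
  stages <- c(stages, "batch_correction")

  # -- stage 3: diversity + homogeneity filter ------------------------
  alpha <- alpha_diversity(corrected)
  write_result_tsv(alpha, pfx("alpha_diversity.tsv"), "corrected counts")
  filt <- filter_alpha_homogeneous(
    tibble::tibble(sample_id = alpha$sample_id,
                   study = meta$batch_id,
                   value = alpha$shannon),
    alpha_level = cfg$homogeneity_alpha,
    max_removed_fraction = cfg$max_removed_fraction
  )
  keep_ids <- filt$retained$sample_id
  write_result_tsv(
    filt$removed,
    pfx("homogeneity_removals.tsv"),
    sprintf("alpha=%g cap=%g homogeneous=%s", cfg$homogeneity_alpha,
            cfg$max_removed_fraction, filt$homogeneous)
  )
  meta <- meta[meta$sample_id %in% keep_ids, ]
  corrected$values <- corrected$values[meta$sample_id, , drop = FALSE]
  rel <- to_relative(corrected)
  d_bc <- bray_curtis_matrix(rel)
  perm <- permanova(d_bc, meta$age_group, n_perm = cfg$n_perm,
                    seed = stage_seed(cfg$seed, "permanova"))
  disp <- beta_dispersion(d_bc, meta$age_group, n_perm = cfg$n_perm,
                          seed = stage_seed(cfg$seed, "betadisper"))
  write_result_tsv(
    dplyr::bind_rows(glance(perm), glance(disp)),
    pfx("beta_diversity_tests.tsv"),
    "bray-curtis on corrected relative abundance; rows: permanova, betadisper"
  )
  dens <- pairwise_distance_density(d_bc, meta$age_group)
  write_result_tsv(dens, pfx("within_group_distances.tsv"), "bray-curtis")
  res$permanova <- perm
  res$betadisper <- disp
  stages <- c(stages, "diversity")

  # -- stage 4: differential abundance --------------------------------
  glev <- unique(meta$age_group)
  cmps <- utils::combn(glev, 2, simplify = FALSE)
  da <- lapply(cmps, function(cmp) {
    fit_feature_lms(corrected, meta, cmp,
                    covariates = cfg$da_covariates,
                    min_prevalence = cfg$min_prevalence)
  })
  names(da) <- vapply(cmps, function(cmp) {
    paste0(cmp[1], "_vs_", cmp[2])
  }, character(1))
  for (nm in names(da)) {
    write_result_tsv(da[[nm]], pfx(paste0("da_", nm, ".tsv")),
                     sprintf("q_threshold=%g min_prevalence=%g",
                             cfg$q_threshold, cfg$min_prevalence))
  }
  dams <- call_dams(dplyr::bind_rows(da), cfg$q_threshold)
  write_result_tsv(dams, pfx("dams.tsv"),
                   sprintf("q<%g strict", cfg$q_threshold))
  venn <- dam_overlap(split(dams$taxon_id, dams$comparison))
  jsonlite::write_json(venn, pfx("dam_venn.json"), auto_unbox = FALSE,
                       pretty = TRUE, digits = NA)
  if (nrow(dams)) {
    fct <- fold_change_table(corrected, meta$age_group,
                             unique(dams$taxon_id))
    write_result_tsv(fct$fold_changes, pfx("fold_changes.tsv"),
                     "log2((mean+1)/(mean+1)) on corrected counts")
    write_result_tsv(fct$heatmap, pfx("heatmap_log2_reads.tsv"),
                     "log2(count+1)")
  }
  res$da <- da
  res$dams <- dams
  stages <- c(stages, "differential_abundance")

  # -- stage 5: per-group networks ------------------------------------
  nets <- list()
  parts <- list()
  for (g in glev) {
    net <- correlation_network(rel, meta$sample_id[meta$age_group == g],
                               r_min = cfg$r_min,
                               alpha = cfg$network_alpha, group = g)
    part <- walktrap_communities(net, steps = cfg$walktrap_steps,
                                 membership_min = cfg$membership_min)
    nets[[g]] <- net
    parts[[g]] <- part
    write_edge_list(net, pfx(paste0("network_", g, "_edges.tsv")))
    write_result_tsv(part$membership,
                     pfx(paste0("network_", g, "_clusters.tsv")),
                     sprintf("walktrap steps=%d", cfg$walktrap_steps))
    write_network_graphml(net, pfx(paste0("network_", g, ".graphml")),
                          part)
  }
  summaries <- purrr::map2_dfr(nets, parts, network_summary)
  write_result_tsv(summaries, pfx("network_summary.tsv"),
                   sprintf("|r|>%g p<%g membership>%d", cfg$r_min,
                           cfg$network_alpha, cfg$membership_min))
  res$networks <- nets
  res$partitions <- parts
  res$network_summary <- summaries
  stages <- c(stages, "networks")

  # -- stage 6: cluster enrichment ------------------------------------
  enr <- list()
  for (g in glev) {
    for (cmp in names(da)) {
      ds <- dams$taxon_id[dams$comparison == cmp]
      if (!length(ds)) next
      e <- cluster_enrichment(parts[[g]], ds,
                              background_mode = cfg$background_mode,
                              alpha = cfg$enrichment_alpha)
      if (nrow(e)) {
        e$network <- g
        e$dam_set <- cmp
        enr[[paste(g, cmp)]] <- e
      }
    }
  }
  enr_tbl <- dplyr::bind_rows(enr)
  write_result_tsv(enr_tbl, pfx("cluster_enrichment.tsv"),
                   sprintf("background=%s alpha=%g", cfg$background_mode,
                           cfg$enrichment_alpha))
  res$enrichment <- enr_tbl
  stages <- c(stages, "enrichment")

  # -- stage 7: signatures + interaction shifts -----------------------
  sig <- classify_signatures(da, rel, meta$age_group, cfg$q_threshold)
  write_result_tsv(sig, pfx("signatures.tsv"),
                   sprintf("q<%g + strictly highest group mean",
                           cfg$q_threshold))
  res$signatures <- sig
  focal <- cfg$focal_taxa
  if (is.null(focal) && nrow(sig)) {
    focal <- sig$taxon_id[!duplicated(sig$group)]
  }
  shifts <- lapply(focal, function(tx) {
    interaction_shift(nets, parts, tx)
  })
  names(shifts) <- focal
  for (tx in focal) {
    jsonlite::write_json(
      list(focal_taxon = tx,
           summary = shifts[[tx]]$summary,
           jaccard = shifts[[tx]]$jaccard),
      pfx(paste0("interaction_shift_", gsub("[^A-Za-z0-9_]", "_", tx),
                 ".json")),
      auto_unbox = FALSE, pretty = TRUE, digits = NA
    )
  }
  res$shifts <- shifts
  stages <- c(stages, "signatures")

  # -- manifest -------------------------------------------------------
  outputs <- sort(setdiff(list.files(cfg$out_dir), "manifest.json"))
  manifest <- list(
    config = config_as_list(cfg),
    stage_seeds = stats::setNames(
      lapply(c("simulate", "correct", "grid", "permanova", "betadisper"),
             function(s) stage_seed(cfg$seed, s)),
      c("simulate", "correct", "grid", "permanova", "betadisper")),
    stages_complete = stages,
    outputs = stats::setNames(
      as.list(unname(tools::md5sum(file.path(cfg$out_dir, outputs)))),
      outputs)
  )
  jsonlite::write_json(manifest, pfx("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  manifest$results <- res
  invisible(manifest)
}

config_as_list <- function(cfg) {
  out <- unclass(cfg)
  out$simulation <- if (!is.null(cfg$simulation)) {
    sim <- unclass(cfg$simulation)
    sim$samples_per_cell <- as.vector(sim$samples_per_cell)
    sim$group_effects <- as.data.frame(sim$group_effects)
    # YAML keeps names only for lists, not atomic vectors
    sim$n_taxa <- as.list(sim$n_taxa)
    sim$base_kingdom_shift <- as.list(sim$base_kingdom_shift)
    if (!is.null(sim$base_shift)) sim$base_shift <- as.list(sim$base_shift)
    sim$taxa <- NULL
    sim$kingdom <- NULL
    sim
  }
  out$scheme <- if (!is.null(cfg$scheme)) as.data.frame(cfg$scheme)
  out
}

#' Read and write a pipeline configuration as YAML
#'
#' The flat-file form of [pipeline_config()]; round-trippable, and the
#' manifest records the config version.
#'
#' @param cfg A `pipeline_config`.
#' @param path File path.
#' @return `read_pipeline_config()` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(config_as_list(cfg), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- if (!is.null(x$simulation)) {
    s <- x$simulation
    do.call(synthetic_config, list(
      seed = s$seed, groups = s$groups,
      samples_per_cell = matrix(unlist(s$samples_per_cell),
                                nrow = s$n_batches),
      n_batches = s$n_batches,
      n_taxa = unlist(s$n_taxa),
      lib_median = unlist(s$lib_median), lib_sdlog = s$lib_sdlog,
      sigma_batch = s$sigma_batch,
      zero_inflation = unlist(s$zero_inflation),
      group_effects = if (length(s$group_effects$taxon))
        tibble::as_tibble(lapply(s$group_effects, unlist)),
      blocks = lapply(s$blocks, function(b) {
        list(taxa = unlist(b$taxa), loading = b$loading,
             groups = unlist(b$groups))
      }),
      sigma_noise = s$sigma_noise,
      base_kingdom_shift = unlist(s$base_kingdom_shift),
      base_shift = if (!is.null(s$base_shift)) unlist(s$base_shift),
      base_sdlog = s$base_sdlog,
      age_ranges = lapply(s$age_ranges, unlist)
    ))
  }
  scheme <- if (!is.null(x$scheme)) {
    age_group_scheme(x$scheme$label, x$scheme$min_age, x$scheme$max_age)
  }
  pipeline_config(
    seed = x$seed, out_dir = x$out_dir, simulation = sim,
    counts_path = x$counts_path, metadata_path = x$metadata_path,
    kingdom_path = x$kingdom_path, scheme = scheme,
    reference_batch = x$reference_batch,
    correction_covariates = unlist(x$correction_covariates),
    min_stratum = x$min_stratum, q_threshold = x$q_threshold,
    min_prevalence = x$min_prevalence,
    da_covariates = x$da_covariates,
    r_min = x$r_min, network_alpha = x$network_alpha,
    walktrap_steps = x$walktrap_steps,
    membership_min = x$membership_min,
    background_mode = x$background_mode,
    enrichment_alpha = x$enrichment_alpha,
    focal_taxa = if (!is.null(x$focal_taxa)) unlist(x$focal_taxa),
    homogeneity_alpha = x$homogeneity_alpha,
    max_removed_fraction = x$max_removed_fraction,
    n_perm = x$n_perm
  )
}
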