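#' Configure the multi-cohort synthetic generator
#'
#' Builds the configuration for a logistic-normal multinomial simulator of
#' multi-kingdom stool metagenome count tables. Counts for sample i arise
#' as multinomial draws of the sample's library size from a softmax
#' composition over per-taxon log-intensities
#' `base + group effect + batch shift + block loading * latent factor +
#' noise`; per-batch excess zero-inflation is applied afterwards. The
#' latent-factor blocks survive compositional closure, which is what the
#' co-occurrence network stage needs.
#'
#' Defaults emulate a three-cohort, three-age-group design of 20 samples
#' per cell and 300 species (220 bacteria, 40 viruses, 25 fungi, 15
#' archaea — roughly the kingdom balance of species-level gut profiles).
#' Library-size medians (1.2e5, 2e5, 5e4 reads) keep the cohorts' relative
#' depth spread at tractable scale.
#'
#' @param seed Integer seed; mandatory, the generator is fully seeded.
#' @param groups Age-group labels; ages are drawn uniformly from
#'   `age_ranges` so the labels are recoverable from the metadata.
#' @param samples_per_cell Samples for each (batch, group) cell; scalar or
#'   an `n_batches x n_groups` matrix.
#' @param n_taxa Named integer vector of taxa per kingdom.
#' @param lib_median,lib_sdlog Per-batch log-normal library-size medians
#'   and a common sdlog.
#' @param sigma_batch SD of the per-(batch, taxon) multiplicative
#'   log-shift; batch 1 is the undistorted reference.
#' @param zero_inflation Per-batch extra probability of zeroing a count.
#' @param group_effects Tibble/data frame with columns `taxon`, `group`,
#'   `log2fc`: planted differential abundance.
#' @param blocks List of correlation blocks, each
#'   `list(taxa =, loading =, groups =)`; a block contributes
#'   `loading * z_i` to its member taxa for samples whose group is in
#'   `groups` (`z_i` a standard-normal latent factor per sample).
#' @param sigma_noise SD of the i.i.d. log-intensity noise.
#' @param base_kingdom_shift Named mean log-intensity offset per kingdom
#'   (bacteria dominate real profiles).
#' @param base_shift Optional named per-taxon log-intensity offset added
#'   to the random baseline. Pushing effect-carrying taxa down keeps the
#'   compositional footprint of planted fold changes small, so the
#'   remaining taxa stay genuinely null under total-sum scaling.
#' @param base_sdlog SD of the random per-taxon baseline log-intensity;
#'   together with the kingdom offsets the default spreads species
#'   abundances over roughly four orders of magnitude.
#' @param age_ranges Named list of `c(min, max)` integer age ranges.
#'
#' @return A `synthetic_config` list, validated.
#' @export
synthetic_config <- function(seed,
                             groups = c("Y", "E", "C"),
                             samples_per_cell = 20,
                             n_batches = 3,
                             n_taxa = c(bacteria = 220, viruses = 40,
                                        fungi = 25, archaea = 15),
                             lib_median = c(1.2e5, 2e5, 5e4),
                             lib_sdlog = 0.35,
                             sigma_batch = 1.0,
                             zero_inflation = c(0, 0.05, 0.1),
                             group_effects = NULL,
                             blocks = list(),
                             sigma_noise = 0.5,
                             base_kingdom_shift = c(bacteria = 2,
                                                    viruses = 0.5,
                                                    fungi = 0,
                                                    archaea = -0.5),
                             base_shift = NULL,
                             base_sdlog = 1,
                             age_ranges = list(Y = c(21, 54),
                                               E = c(67, 89),
                                               C = c(96, 109))) {
  if (missing(seed)) stop("`seed` is mandatory")
  seed <- as.integer(seed)
  lib_median <- rep_len(lib_median, n_batches)
  zero_inflation <- rep_len(zero_inflation, n_batches)
  if (is.matrix(samples_per_cell)) {
    stopifnot(nrow(samples_per_cell) == n_batches,
              ncol(samples_per_cell) == length(groups))
  } else {
    samples_per_cell <- matrix(samples_per_cell, n_batches, length(groups))
  }
  if (any(samples_per_cell < 1)) stop("each cell needs >= 1 sample")
  taxa <- unlist(lapply(names(n_taxa), function(k) {
    sprintf("%s_sp_%03d", k, seq_len(n_taxa[[k]]))
  }))
  kingdom <- stats::setNames(
    rep(names(n_taxa), times = n_taxa), taxa
  )
  if (!all(names(n_taxa) %in% valid_kingdoms)) {
    stop("n_taxa names must be kingdoms")
  }
  if (is.null(group_effects)) {
    group_effects <- tibble::tibble(taxon = character(),
                                    group = character(),
                                    log2fc = numeric())
  }
  group_effects <- tibble::as_tibble(group_effects)
  if (nrow(group_effects)) {
    bad <- setdiff(group_effects$taxon, taxa)
    if (length(bad)) stop("group effect on unknown taxon: ", bad[1])
    if (!all(is.finite(group_effects$log2fc))) {
      stop("fold changes must be finite")
    }
    if (!all(group_effects$group %in% groups)) {
      stop("group effect on unknown group")
    }
  }
  for (b in blocks) {
    if (!all(c("taxa", "loading", "groups") %in% names(b))) {
      stop("each block needs taxa, loading, groups")
    }
    if (!all(b$taxa %in% taxa)) {
      stop("block member not among taxa: ",
           setdiff(b$taxa, taxa)[1])
    }
    if (!all(b$groups %in% groups)) stop("block active in unknown group")
  }
  structure(
    list(seed = seed, groups = groups, n_batches = n_batches,
         samples_per_cell = samples_per_cell, n_taxa = n_taxa,
         taxa = taxa, kingdom = kingdom,
         lib_median = lib_median, lib_sdlog = lib_sdlog,
         sigma_batch = sigma_batch, zero_inflation = zero_inflation,
         group_effects = group_effects, blocks = blocks,
         sigma_noise = sigma_noise,
         base_kingdom_shift = base_kingdom_shift,
         base_shift = base_shift, base_sdlog = base_sdlog,
         age_ranges = age_ranges),
    class = "synthetic_config"
  )
}

with_preserved_rng <- function(code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  }
  force(code)
}

#' Generate a synthetic multi-cohort dataset with ground truth
#'
#' @param cfg A [synthetic_config()].
#' @return A list with elements `counts` (counts-scale [taxa_table()]),
#'   `metadata` (tibble: sample_id, age, gender, batch_id, age_group,
#'   library_size, raw_reads, assigned_reads) and `truth` (planted DAMs
#'   per pairwise comparison with direction, block memberships per group,
#'   signature sets per group, neighbor sets per rewired taxon). Identical
#'   config (including seed) gives bit-identical output.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_preserved_rng({
    set.seed(cfg$seed)
    groups <- cfg$groups
    p <- length(cfg$taxa)

    cells <- expand.grid(batch = seq_len(cfg$n_batches),
                         group = seq_along(groups))
    n_per <- cfg$samples_per_cell[as.matrix(cells)]
    n <- sum(n_per)
    batch <- rep(cells$batch, n_per)
    grp <- groups[rep(cells$group, n_per)]
    ids <- sprintf("s%03d", seq_len(n))

    age <- vapply(grp, function(g) {
      r <- cfg$age_ranges[[g]]
      sample(seq(r[1], r[2]), 1)
    }, numeric(1))
    gender <- sample(c("female", "male"), n, replace = TRUE)
    lib <- round(stats::rlnorm(n, meanlog = log(cfg$lib_median[batch]),
                               sdlog = cfg$lib_sdlog))
    lib <- pmax(lib, 1000)

    base <- cfg$base_kingdom_shift[cfg$kingdom] +
      stats::rnorm(p, 0, cfg$base_sdlog)
    if (!is.null(cfg$base_shift)) {
      j <- match(names(cfg$base_shift), cfg$taxa)
      if (anyNA(j)) stop("base_shift on unknown taxon")
      base[j] <- base[j] + cfg$base_shift
    }
    batch_shift <- matrix(0, cfg$n_batches, p)
    if (cfg$n_batches > 1 && cfg$sigma_batch > 0) {
      # batch 1 is the undistorted reference profile
      batch_shift[-1, ] <- stats::rnorm((cfg$n_batches - 1) * p,
                                        0, cfg$sigma_batch)
    }

    loglam <- matrix(rep(base, each = n), n, p,
                     dimnames = list(ids, cfg$taxa))
    loglam <- loglam + batch_shift[batch, , drop = FALSE]
    if (nrow(cfg$group_effects)) {
      for (i in seq_len(nrow(cfg$group_effects))) {
        e <- cfg$group_effects[i, ]
        j <- match(e$taxon, cfg$taxa)
        loglam[grp == e$group, j] <-
          loglam[grp == e$group, j] + log(2) * e$log2fc
      }
    }
    for (b in cfg$blocks) {
      z <- stats::rnorm(n)
      active <- grp %in% b$groups
      j <- match(b$taxa, cfg$taxa)
      loglam[active, j] <- loglam[active, j] + b$loading * z[active]
    }
    loglam <- loglam + stats::rnorm(n * p, 0, cfg$sigma_noise)

    counts <- matrix(0L, n, p, dimnames = list(ids, cfg$taxa))
    for (i in seq_len(n)) {
      pr <- exp(loglam[i, ] - max(loglam[i, ]))
      counts[i, ] <- stats::rmultinom(1, lib[i], pr)[, 1]
    }
    zi <- cfg$zero_inflation[batch]
    if (any(zi > 0)) {
      drop <- matrix(stats::runif(n * p) < zi, n, p)
      counts[drop] <- 0L
    }

    meta <- tibble::tibble(
      sample_id = ids,
      age = age,
      gender = gender,
      batch_id = paste0("batch", batch),
      age_group = grp,
      library_size = lib,
      raw_reads = round(lib * 1.5),
      assigned_reads = rowSums(counts)
    )
    truth <- build_ground_truth(cfg, groups)
    list(counts = taxa_table(counts, cfg$kingdom, "counts"),
         metadata = meta, truth = truth)
  })
}

# Planted-effect bookkeeping: which taxa must come out of each downstream
# stage, derived from the config alone.
build_ground_truth <- function(cfg, groups) {
  comparisons <- if (length(groups) >= 2) {
    utils::combn(groups, 2, simplify = FALSE)
  } else {
    list()
  }
  empty_dams <- tibble::tibble(comparison = character(),
                               taxon = character(),
                               direction = character())
  dams <- purrr::map_dfr(comparisons, function(cmp) {
    lab <- paste0(cmp[1], "_vs_", cmp[2])
    ge <- cfg$group_effects
    hit <- ge[ge$group %in% cmp & ge$log2fc != 0, ]
    if (!nrow(hit)) {
      return(tibble::tibble(comparison = character(), taxon = character(),
                            direction = character()))
    }
    # direction is w.r.t. the second group of the comparison
    up_in_second <- (hit$group == cmp[2]) == (hit$log2fc > 0)
    tibble::tibble(comparison = lab, taxon = hit$taxon,
                   direction = ifelse(up_in_second, "enriched", "depleted"))
  })
  if (!nrow(dams)) dams <- empty_dams
  sig <- cfg$group_effects
  signatures <- if (nrow(sig)) {
    elevated <- sig[sig$log2fc > 0, ]
    one_group <- names(which(table(elevated$taxon) == 1))
    elevated <- elevated[elevated$taxon %in% one_group, ]
    stats::setNames(
      lapply(groups, function(g) elevated$taxon[elevated$group == g]),
      groups
    )
  } else {
    stats::setNames(rep(list(character()), length(groups)), groups)
  }
  blocks_per_group <- stats::setNames(lapply(groups, function(g) {
    keep <- vapply(cfg$blocks, function(b) g %in% b$groups, logical(1))
    lapply(cfg$blocks[keep], function(b) b$taxa)
  }), groups)
  # a taxon appearing in >1 block with disjoint active groups is rewired:
  # its expected neighbors differ by group
  member_of <- lapply(cfg$blocks, function(b) b$taxa)
  all_members <- unlist(member_of)
  rewired <- unique(all_members[duplicated(all_members)])
  neighbors <- stats::setNames(lapply(rewired, function(tx) {
    stats::setNames(lapply(groups, function(g) {
      nb <- unlist(lapply(cfg$blocks, function(b) {
        if (tx %in% b$taxa && g %in% b$groups) setdiff(b$taxa, tx)
        else character()
      }))
      unique(nb)
    }), groups)
  }), rewired)
  list(dams = dams, signatures = signatures,
       blocks_per_group = blocks_per_group,
       rewired_neighbors = neighbors)
}

#' Serialize ground truth to JSON
#'
#' @param truth The `truth` element of [generate_cohort()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
ground_truth_report <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname ground_truth_report
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$dams <- tibble::as_tibble(as.data.frame(x$dams))
  x
}

#' A ready-made demonstration configuration
#'
#' Three batches by three age groups, 300 taxa, a planted batch shift,
#' three planted signatures per age group (log2 fold change 3), two
#' correlation blocks shared by all groups, and one focal taxon rewired
#' between disjoint blocks in the young and centenarian groups.
#'
#' @param seed Integer seed.
#' @param samples_per_cell Samples per (batch, group) cell.
#' @return A [synthetic_config()].
#' @export
demo_config <- function(seed, samples_per_cell = 20) {
  sig_taxa <- c(Y = "bacteria_sp_001", Y2 = "archaea_sp_001",
                Y3 = "bacteria_sp_002",
                E = "bacteria_sp_003", E2 = "fungi_sp_001",
                E3 = "bacteria_sp_004",
                C = "viruses_sp_001", C2 = "bacteria_sp_005",
                C3 = "fungi_sp_002")
  ge <- tibble::tibble(
    taxon = unname(sig_taxa),
    group = rep(c("Y", "E", "C"), each = 3),
    log2fc = 3
  )
  blockA <- sprintf("bacteria_sp_%03d", 101:108)
  blockB <- sprintf("bacteria_sp_%03d", 111:118)
  focal <- "archaea_sp_010"
  blocks <- list(
    list(taxa = c(blockA, focal), loading = 1.5, groups = "Y"),
    list(taxa = c(blockB, focal), loading = 1.5, groups = "C"),
    list(taxa = sprintf("bacteria_sp_%03d", 121:130), loading = 1.5,
         groups = c("Y", "E", "C")),
    list(taxa = c(sprintf("viruses_sp_%03d", 11:14),
                  sprintf("bacteria_sp_%03d", 131:134)),
         loading = 1.5, groups = c("Y", "E", "C"))
  )
  synthetic_config(seed = seed, samples_per_cell = samples_per_cell,
                   group_effects = ge, blocks = blocks)
}
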