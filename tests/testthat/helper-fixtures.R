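# Small in-code fixtures shared across test files.

kmap <- function(taxa, kingdom = "bacteria") {
  stats::setNames(rep_len(kingdom, length(taxa)), taxa)
}

tiny_table <- function(values, kingdoms = NULL, scale = "counts") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("s%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("t%02d", seq_len(ncol(values)))
  }
  kg <- if (is.null(kingdoms)) kmap(colnames(values))
        else stats::setNames(kingdoms, colnames(values))
  taxa_table(values, kg, scale = scale)
}

# a clique edge list over the given node names
clique_edges <- function(nodes) {
  pr <- utils::combn(nodes, 2)
  tibble::tibble(taxon_a = pr[1, ], taxon_b = pr[2, ])
}

# configs used by planted-recovery checks; conditions are fixed here so
# the unit tests and the acceptance checks agree on them
da_recovery_config <- function(seed) {
  taxa <- sprintf("bacteria_sp_%03d", 1:30)
  synthetic_config(
    seed = seed, samples_per_cell = matrix(40, 1, 3), n_batches = 1,
    lib_median = 1e5, sigma_batch = 0, zero_inflation = 0,
    group_effects = tibble::tibble(taxon = taxa, group = "E",
                                   log2fc = 3 * rep(c(1, -1), 15)),
    base_shift = stats::setNames(rep(-3, 30), taxa)
  )
}

signature_recovery_config <- function(seed, plant = TRUE) {
  sig_taxa <- c("bacteria_sp_001", "bacteria_sp_002", "archaea_sp_001",
                "bacteria_sp_003", "bacteria_sp_004", "fungi_sp_001",
                "bacteria_sp_005", "bacteria_sp_006", "viruses_sp_001")
  synthetic_config(
    seed = seed, samples_per_cell = matrix(40, 1, 3), n_batches = 1,
    lib_median = 1e5, sigma_batch = 0, zero_inflation = 0,
    group_effects = if (plant) {
      tibble::tibble(taxon = sig_taxa,
                     group = rep(c("Y", "E", "C"), each = 3), log2fc = 3)
    },
    base_shift = if (plant) stats::setNames(rep(-3, 9), sig_taxa)
  )
}

signature_truth_taxa <- function() {
  c("bacteria_sp_001", "bacteria_sp_002", "archaea_sp_001",
    "bacteria_sp_003", "bacteria_sp_004", "fungi_sp_001",
    "bacteria_sp_005", "bacteria_sp_006", "viruses_sp_001")
}

rewiring_config <- function(seed) {
  blockA <- sprintf("bacteria_sp_%03d", 101:108)
  blockB <- sprintf("bacteria_sp_%03d", 111:118)
  blockC <- sprintf("bacteria_sp_%03d", 121:128)
  focal <- "archaea_sp_010"
  synthetic_config(
    seed = seed, samples_per_cell = matrix(200, 1, 3), n_batches = 1,
    n_taxa = c(bacteria = 300, viruses = 40, fungi = 25, archaea = 15),
    lib_median = 1e5, sigma_batch = 0, zero_inflation = 0,
    blocks = list(
      list(taxa = c(blockA, focal), loading = 2, groups = "Y"),
      list(taxa = c(blockB, focal), loading = 2, groups = "C"),
      list(taxa = blockC, loading = 2, groups = c("Y", "E", "C"))
    )
  )
}

batch_eval_config <- function(seed) {
  taxa <- sprintf("bacteria_sp_%03d", 1:15)
  synthetic_config(
    seed = seed, samples_per_cell = 20,
    group_effects = tibble::tibble(taxon = taxa,
                                   group = rep(c("Y", "E", "C"), each = 5),
                                   log2fc = 2),
    base_shift = stats::setNames(rep(-1, 15), taxa)
  )
}

group_networks <- function(tab, meta, ...) {
  glev <- unique(meta$age_group)
  nets <- lapply(glev, function(g) {
    correlation_network(tab, meta$sample_id[meta$age_group == g],
                        group = g, ...)
  })
  names(nets) <- glev
  parts <- lapply(nets, walktrap_communities)
  list(nets = nets, parts = parts)
}
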