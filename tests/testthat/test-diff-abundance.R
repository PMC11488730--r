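test_that("a taxon with identical group profiles has zero effect", {
  x <- c(10, 20, 30, 40, 10, 20, 30, 40)
  m <- cbind(t1 = x, t2 = 100 - x)
  rownames(m) <- paste0("s", 1:8)
  tt <- tiny_table(m)
  meta <- tibble::tibble(sample_id = rownames(m),
                         age_group = rep(c("Y", "E"), each = 4))
  res <- fit_feature_lms(tt, meta, c("Y", "E"), min_prevalence = 0)
  expect_lt(max(abs(res$coefficient)), 1e-12)
  expect_true(all(res$p_value > 0.99))
})

test_that("the group test equals a two-sample t-test on transformed values", {
  set.seed(61)
  m <- matrix(rpois(200, 40) + 1, 20, 10)
  rownames(m) <- paste0("s", 1:20)
  colnames(m) <- paste0("t", 1:10)
  tt <- tiny_table(m)
  meta <- tibble::tibble(sample_id = rownames(m),
                         age_group = rep(c("Y", "E"), each = 10))
  res <- fit_feature_lms(tt, meta, c("Y", "E"), min_prevalence = 0)
  # independent route: redo TSS + half-min-nonzero pseudocount + log2
  rel <- m / rowSums(m)
  for (j in seq_len(ncol(rel))) {
    nz <- rel[, j][rel[, j] > 0]
    y <- log2(rel[, j] + min(nz) / 2)
    tt_p <- stats::t.test(y[11:20], y[1:10], var.equal = TRUE)
    row <- res[res$taxon_id == colnames(m)[j], ]
    expect_equal(row$p_value, tt_p$p.value, tolerance = 1e-9)
    expect_equal(row$coefficient,
                 unname(tt_p$estimate[1] - tt_p$estimate[2]),
                 tolerance = 1e-9)
  }
})

test_that("planted fold changes are recovered with controlled error", {
  cfg <- da_recovery_config(62)
  sim <- generate_cohort(cfg)
  res <- fit_feature_lms(sim$counts, sim$metadata, c("Y", "E"))
  truth <- cfg$group_effects
  planted <- res[res$taxon_id %in% truth$taxon, ]
  signs <- truth$log2fc[match(planted$taxon_id, truth$taxon)]
  # enriched taxa recover the planted size; depleted ones floor at the
  # pseudocount so only sign and significance are asserted for them
  expect_true(all(abs(planted$coefficient[signs > 0] - 3) < 1))
  expect_true(all(planted$q_value < 0.25))
  expect_true(all(planted$direction[signs > 0] == "enriched"))
  expect_true(all(planted$direction[signs < 0] == "depleted"))
})

test_that("prevalence filtering and zero-variance exclusion are logged", {
  m <- cbind(a = c(5, 6, 7, 8, 9, 10), b = c(1, 0, 0, 0, 0, 0),
             c = rep(3, 6))
  rownames(m) <- paste0("s", 1:6)
  tt <- tiny_table(m)
  meta <- tibble::tibble(sample_id = rownames(m),
                         age_group = rep(c("Y", "E"), each = 3))
  res <- fit_feature_lms(tt, meta, c("Y", "E"), min_prevalence = 0.5)
  excl <- attr(res, "excluded")
  expect_true("b" %in% excl$taxon_id[excl$reason == "prevalence"])
  expect_false("b" %in% res$taxon_id)
  expect_error(fit_feature_lms(tt, meta[1:4, ], c("Y", "E")),
               ">= 3 samples")
})

test_that("BH adjustment reproduces the hand-derived step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  # order invariance
  set.seed(63)
  p <- runif(50)
  ord <- sample(50)
  expect_equal(bh_adjust(p)[ord], bh_adjust(p[ord]))
  expect_error(bh_adjust(c(0.5, 1.2)), "0,1")
})

test_that("DAM calling applies a strict threshold", {
  res <- tibble::tibble(
    comparison = "Y_vs_E",
    taxon_id = c("a", "b", "c"),
    kingdom = "bacteria",
    coefficient = 1,
    p_value = c(0.01, 0.02, 0.03),
    q_value = c(0.25, 0.249, 0.9),
    direction = "enriched"
  )
  dams <- call_dams(res)
  expect_equal(dams$taxon_id, "b")
  expect_equal(nrow(call_dams(res[0, ])), 0)
  expect_error(call_dams(res, q_threshold = 1.5), "in \\(0, 1]")
})

test_that("Venn overlap reports intersections and exclusives", {
  sets <- list(A = letters[1:5], B = letters[1:5], C = letters[1:5])
  ov <- dam_overlap(sets)
  expect_length(ov$intersection, 5)
  expect_true(all(lengths(ov$exclusive) == 0))

  sets2 <- list(A = c("a", "b"), B = c("c", "d"), C = c("e"))
  ov2 <- dam_overlap(sets2)
  expect_length(ov2$intersection, 0)
  expect_equal(lengths(ov2$exclusive), c(A = 2, B = 2, C = 1))
})

test_that("planted common DAMs appear in all three pairwise comparisons", {
  common <- sprintf("bacteria_sp_%03d", 1:5)
  effects <- dplyr::bind_rows(
    tibble::tibble(taxon = common, group = "Y", log2fc = 3),
    tibble::tibble(taxon = common, group = "C", log2fc = -3)
  )
  cfg <- synthetic_config(
    seed = 64, samples_per_cell = matrix(40, 1, 3), n_batches = 1,
    lib_median = 1e5, sigma_batch = 0, zero_inflation = 0,
    group_effects = effects,
    base_shift = stats::setNames(rep(-2, 5), common)
  )
  sim <- generate_cohort(cfg)
  cmps <- list(c("Y", "E"), c("Y", "C"), c("E", "C"))
  sets <- lapply(cmps, function(cmp) {
    call_dams(fit_feature_lms(sim$counts, sim$metadata, cmp))$taxon_id
  })
  names(sets) <- c("Y_vs_E", "Y_vs_C", "E_vs_C")
  ov <- dam_overlap(sets)
  expect_true(all(common %in% ov$intersection))
})

test_that("fold changes use pseudocount 1 on the count scale", {
  m <- cbind(tx = c(15, 15, 3, 3), ty = c(7, 9, 7, 9))
  rownames(m) <- paste0("s", 1:4)
  tt <- tiny_table(m)
  groups <- c("A", "A", "B", "B")
  out <- fold_change_table(tt, groups, c("tx", "ty"))
  fc <- out$fold_changes
  expect_equal(fc$log2_fc[fc$taxon_id == "tx" &
                            fc$comparison == "A_vs_B"], 2)
  expect_equal(fc$log2_fc[fc$taxon_id == "ty" &
                            fc$comparison == "A_vs_B"], 0)
  expect_equal(out$heatmap$log2_reads[out$heatmap$sample_id == "s3" &
                                        out$heatmap$taxon_id == "tx"],
               2)
  zero <- tiny_table(cbind(tz = c(0, 0, 0, 0)))
  expect_equal(unique(fold_change_table(zero, groups,
                                        "tz")$heatmap$log2_reads), 0)
  expect_error(fold_change_table(tt, groups, "nope"), "unknown taxon")
})

test_that("detection power is monotone in the planted effect size", {
  rates <- vapply(c(1, 2, 3), function(fc) {
    hits <- 0
    for (s in 1:3) {
      taxa <- sprintf("bacteria_sp_%03d", 1:10)
      cfg <- synthetic_config(
        seed = 650 + s, samples_per_cell = matrix(40, 1, 3),
        n_batches = 1, lib_median = 1e5, sigma_batch = 0,
        zero_inflation = 0,
        group_effects = tibble::tibble(taxon = taxa, group = "E",
                                       log2fc = fc),
        base_shift = stats::setNames(rep(-2, 10), taxa)
      )
      sim <- generate_cohort(cfg)
      dams <- call_dams(fit_feature_lms(sim$counts, sim$metadata,
                                        c("Y", "E")))
      hits <- hits + sum(dams$taxon_id %in% taxa)
    }
    hits / 30
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gte(rates[3], 0.8)
})
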