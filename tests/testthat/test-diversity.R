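test_that("Shannon index matches closed forms and is maximal when uniform", {
  expect_equal(shannon(c(1, 1, 1, 1)), log(4), tolerance = 1e-12)
  expect_equal(shannon(c(7, 0, 0)), 0)
  p <- c(5, 3, 2) / 10
  expect_equal(shannon(c(5, 3, 2)), -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(shannon(c(5, 3, 2)), 1.0297, tolerance = 1e-4)
  expect_error(shannon(c(0, 0)), "all-zero")

  set.seed(7)
  for (i in 1:20) {
    k <- sample(3:8, 1)
    x <- rgamma(k, 2) + 0.01
    expect_lte(shannon(x), shannon(rep(1, k)) + 1e-12)
  }
})

test_that("Chao1 uses the bias-corrected estimator on integer counts", {
  # S_obs = 10, F1 = 4, F2 = 2 -> 10 + 4*3/(2*3) = 12
  x <- c(rep(1, 4), rep(2, 2), rep(5, 4))
  expect_equal(chao1(x), 12)
  expect_equal(chao1(c(3, 4, 5)), 3)      # no singletons -> S_obs
  expect_equal(chao1(rep(0, 5)), 0)
  expect_error(chao1(c(0.5, 2)), "integer")
  # cross-check against vegan on random count rows
  set.seed(8)
  for (i in 1:5) {
    x <- rpois(50, 1.2)
    expect_equal(chao1(x),
                 unname(vegan::estimateR(x)["S.chao1"]),
                 tolerance = 1e-9)
  }
})

test_that("Bray-Curtis matches the min-sum formula and its bounds", {
  t1 <- tiny_table(rbind(c(0.5, 0.5, 0), c(0, 0.5, 0.5)),
                   scale = "relative")
  d <- bray_curtis_matrix(t1)
  expect_equal(as.numeric(d), 0.5)
  t2 <- tiny_table(rbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(as.numeric(bray_curtis_matrix(t2)), 0)
  t3 <- tiny_table(rbind(c(1, 1, 0, 0), c(0, 0, 2, 5)))
  expect_equal(as.numeric(bray_curtis_matrix(t3)), 1)
})

test_that("distance matrices satisfy metric axioms on random tables", {
  set.seed(9)
  for (i in 1:5) {
    m <- matrix(rpois(80, 8) + 1, 8, 10)
    tt <- tiny_table(m)
    for (d in list(bray_curtis_matrix(tt), aitchison_matrix(tt))) {
      dm <- as.matrix(d)
      expect_equal(dm, t(dm), tolerance = 1e-12)
      expect_true(all(diag(dm) == 0))
      expect_true(all(dm >= 0))
    }
    # triangle inequality for the Euclidean (Aitchison) metric
    am <- as.matrix(aitchison_matrix(tt))
    for (a in 1:6) {
      expect_lte(am[a, a + 1], am[a, a + 2] + am[a + 2, a + 1] + 1e-9)
    }
  }
})

test_that("PCoA reproduces Euclidean configurations and handles duplicates", {
  set.seed(10)
  pts <- matrix(rnorm(8), 4, 2)
  d <- dist(pts)
  ord <- pcoa_ordination(d, k = 3)
  rec <- dist(as.matrix(ord$points[, -1]))
  expect_equal(as.numeric(rec), as.numeric(d), tolerance = 1e-9)

  # equidistant simplex: all positive eigenvalues equal
  m <- matrix(1, 4, 4) - diag(4)
  eq <- pcoa_ordination(m, k = 3)
  pos <- eq$eigenvalues[eq$eigenvalues > 1e-9]
  expect_equal(max(pos) - min(pos), 0, tolerance = 1e-9)

  # duplicated sample gets identical coordinates
  pts2 <- rbind(pts, pts[1, ])
  ord2 <- pcoa_ordination(dist(pts2), k = 2)
  expect_equal(as.numeric(ord2$points[1, -1]),
               as.numeric(ord2$points[5, -1]), tolerance = 1e-9)
  expect_error(pcoa_ordination(d, k = 4), "at most")
})

test_that("PERMANOVA matches the closed-form decomposition and oracles", {
  # two groups of 3: within-distance 0, between-distance 1 -> R2 = 1
  m <- matrix(1, 6, 6)
  m[1:3, 1:3] <- 0
  m[4:6, 4:6] <- 0
  lab <- rep(c("a", "b"), each = 3)
  pr <- permanova(m, lab, n_perm = 0)
  expect_equal(pr$R2, 1, tolerance = 1e-12)
  # exhaustive enumeration oracle gives p = 2/20
  expect_equal(oracle_permanova_exhaustive_p(m, lab), 0.1)

  # random instances: R2/F equal the Gower-trace oracle and vegan
  set.seed(11)
  for (i in 1:5) {
    pts <- matrix(rnorm(14), 7, 2)
    d <- dist(pts)
    lab <- sample(rep(c("a", "b", "c"), times = c(3, 2, 2)))
    pr <- permanova(d, lab, n_perm = 99, seed = i)
    orc <- oracle_permanova_stats(d, lab)
    expect_equal(pr$R2, orc$R2, tolerance = 1e-12)
    expect_equal(pr$pseudo_F, orc$F, tolerance = 1e-12)
    vg <- vegan::adonis2(d ~ g, data = data.frame(g = lab),
                         permutations = 2)
    expect_equal(pr$R2, vg$R2[1], tolerance = 1e-8)
    expect_equal(pr$pseudo_F, vg$F[1], tolerance = 1e-8)
  }

  expect_error(permanova(m, rep("a", 6)), "2 groups")
  expect_error(permanova(matrix(0, 4, 4), rep(c("a", "b"), 2)),
               "degenerate")
  # seeded permutations reproduce exactly
  dd <- dist(matrix(rnorm(12), 6, 2))
  p1 <- permanova(dd, rep(c("a", "b"), 3), n_perm = 199, seed = 5)
  p2 <- permanova(dd, rep(c("a", "b"), 3), n_perm = 199, seed = 5)
  expect_identical(p1$p_value, p2$p_value)
  tl <- tidy(p1)
  expect_equal(tl$R2[1] + tl$R2[2], 1)
})

test_that("sampled PERMANOVA p agrees with exhaustive enumeration", {
  set.seed(12)
  for (i in 1:3) {
    n <- 6
    d <- dist(matrix(rnorm(n * 2), n, 2))
    lab <- rep(c("a", "b"), each = 3)
    p_ex <- oracle_permanova_exhaustive_p(d, lab)
    pr <- permanova(d, lab, n_perm = 5000, seed = i)
    se <- sqrt(p_ex * (1 - p_ex) / 5000)
    expect_lt(abs(pr$p_value - p_ex), 3 * se + 2 / 5001)
  }
})

test_that("dispersion test matches hand-computed centroid distances", {
  # six points on a line: group a tight, group b spread
  x <- c(0, 0.1, -0.1, 10, 13, 7)
  d <- dist(cbind(x, 0))
  lab <- rep(c("a", "b"), each = 3)
  bd <- beta_dispersion(d, lab, n_perm = 99, seed = 1)
  cent_dist <- c(abs(x[1:3] - mean(x[1:3])), abs(x[4:6] - mean(x[4:6])))
  expect_equal(bd$distances$dist_to_centroid, cent_dist,
               tolerance = 1e-9)
  f_hand <- anova(lm(cent_dist ~ lab))$`F value`[1]
  expect_equal(bd$F, f_hand, tolerance = 1e-9)

  # mirror-copy groups: equal dispersion, p high
  y <- c(0, 1, 3, 10, 11, 13)
  bd2 <- beta_dispersion(dist(cbind(y, 0)), lab, n_perm = 199, seed = 2)
  expect_equal(unname(diff(bd2$group_means)), 0, tolerance = 1e-9)
  expect_gt(bd2$p_value, 0.9)

  # all-identical samples: zero dispersions
  bd3 <- beta_dispersion(matrix(0, 4, 4), rep(c("a", "b"), 2),
                         n_perm = 19, seed = 1)
  expect_equal(max(bd3$distances$dist_to_centroid), 0)
})

test_that("rank tests match their classical references", {
  set.seed(21)
  v <- rnorm(15)
  g <- sample(rep(c("a", "b", "c"), each = 5))
  expect_equal(kruskal_wallis(v, g)$p_value,
               kruskal.test(v, factor(g))$p.value)
  # identical value multisets in all three groups
  ident <- kruskal_wallis(rep(c(1, 2, 3), 3),
                          rep(c("a", "b", "c"), each = 3))
  expect_equal(ident$statistic, 0, tolerance = 1e-12)
  expect_equal(ident$p_value, 1)
  tied <- kruskal_wallis(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(tied$statistic, 0)
  expect_error(kruskal_wallis(1:3, rep("a", 3)), "2 non-empty")

  # exact two-tailed enumeration: all C(6,3) splits
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p_value, 0.1, tolerance = 1e-12)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("homogeneity filter removes the sample that restores agreement", {
  # identical study distributions: nothing removed
  df <- tibble::tibble(
    sample_id = paste0("s", 1:20),
    study = rep(c("A", "B"), each = 10),
    value = rep(seq(1, 10), 2)
  )
  out <- filter_alpha_homogeneous(df)
  expect_true(out$homogeneous)
  expect_equal(nrow(out$removed), 0)
  expect_equal(nrow(out$retained), 20)

  # a contaminated study subset: the filter removes samples one at a
  # time, each step maximizing the KW p, until the studies agree
  set.seed(13)
  base <- rnorm(10, 5, 0.3)
  contam <- c(7.1, 7.3, 7.0, 7.2, 6.9, 7.4)
  df2 <- tibble::tibble(
    sample_id = paste0("s", 1:26),
    study = rep(c("A", "B"), times = c(10, 16)),
    value = c(base, base, contam)
  )
  lvl <- 0.15
  expect_lt(kruskal_wallis(df2$value, df2$study)$p_value, lvl)
  out2 <- filter_alpha_homogeneous(df2, alpha_level = lvl)
  expect_true(out2$homogeneous)
  expect_gt(nrow(out2$removed), 0)
  expect_lte(nrow(out2$removed), floor(0.3 * 26))
  # the ordered removal log reports the p achieved after each removal
  expect_equal(out2$removed$p_after[nrow(out2$removed)], out2$p_value)
  # re-running KW on the retained set confirms homogeneity
  expect_gte(kruskal_wallis(out2$retained$value,
                            out2$retained$study)$p_value, lvl)

  # disjoint ranges cannot be fixed under a 10% cap
  df3 <- tibble::tibble(
    sample_id = paste0("s", 1:40),
    study = rep(c("A", "B"), each = 20),
    value = c(1:20, 101:120)
  )
  expect_warning(out3 <- filter_alpha_homogeneous(
    df3, max_removed_fraction = 0.1), "heterogeneous")
  expect_false(out3$homogeneous)
})

test_that("within-group distance multisets have the right cardinality", {
  m <- as.matrix(dist(cbind(c(0, 1, 2, 5, 5), 0)))
  rownames(m) <- colnames(m) <- paste0("s", 1:5)
  lab <- c("g1", "g1", "g1", "g2", "g2")
  out <- pairwise_distance_density(m, lab)
  expect_equal(sum(out$group == "g1"), 3)  # C(3,2)
  expect_equal(out$distance[out$group == "g2"], 0)
  out2 <- pairwise_distance_density(m, c("g1", "g1", "g1", "g2", "g3"))
  expect_setequal(attr(out2, "degenerate_groups"), c("g2", "g3"))
})
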