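test_that("hypergeometric enrichment matches the combinatorial sum", {
  part <- list(
    membership = tibble::tibble(
      taxon_id = paste0("t", 1:100),
      cluster = rep(1:5, each = 20)
    ),
    sizes = tibble::tibble(cluster = 1:5, n = 20, large = TRUE),
    large_clusters = 1:5
  )
  class(part) <- "cluster_partition"
  dams <- paste0("t", 1:20)  # exactly cluster 1
  res <- cluster_enrichment(part, dams)
  expect_equal(res$N[1], 100)
  expect_equal(res$K[1], 20)
  r1 <- res[res$cluster == 1, ]
  expect_equal(r1$k, 20)
  # oracle: direct combinatorial sum
  expect_equal(r1$p, oracle_hyper_upper(20, 20, 100, 20),
               tolerance = 1e-12)
  # clusters with no DAMs have p = 1
  expect_true(all(res$p[res$k == 0] == 1))
  expect_true(r1$flagged)

  # every background node a DAM: p = 1 everywhere
  res_all <- cluster_enrichment(part, paste0("t", 1:100))
  expect_true(all(res_all$p == 1))
  expect_error(cluster_enrichment(part, character()), "non-empty")
})

test_that("enrichment p equals the exact sum on arbitrary instances", {
  # N = 100, K = 20, n = 10, k = 5 and random instances
  expect_equal(stats::phyper(4, 20, 80, 10, lower.tail = FALSE),
               oracle_hyper_upper(5, 20, 100, 10), tolerance = 1e-12)
  set.seed(91)
  for (i in 1:10) {
    N <- sample(30:200, 1)
    K <- sample(5:(N - 5), 1)
    n <- sample(5:(N - 5), 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 oracle_hyper_upper(k, K, N, n), tolerance = 1e-10)
  }
})

test_that("enrichment p is monotone non-increasing in the overlap", {
  ps <- vapply(0:10, function(k) {
    stats::phyper(k - 1, 20, 80, 10, lower.tail = FALSE)
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("background modes change N as documented", {
  part <- list(
    membership = tibble::tibble(
      taxon_id = paste0("t", 1:40),
      cluster = c(rep(1, 15), rep(2, 12), rep(3, 13))
    ),
    sizes = tibble::tibble(cluster = 1:3, n = c(15, 12, 13),
                           large = c(TRUE, TRUE, FALSE)),
    large_clusters = 1:2
  )
  class(part) <- "cluster_partition"
  dams <- c("t1", "t2", "out1", "out2")
  res_union <- cluster_enrichment(part, dams, "clusters_union_dams")
  expect_equal(unique(res_union$N), 27 + 2)
  res_all <- cluster_enrichment(part, dams, "all_nodes")
  expect_equal(unique(res_all$N), 42)
  res_pc <- cluster_enrichment(part, dams, "per_cluster")
  expect_equal(res_pc$N, c(15 + 2, 12 + 4))
})

test_that("signature classification follows the two-clause rule", {
  mk_res <- function(cmp, taxa, qs) {
    tibble::tibble(taxon_id = taxa, kingdom = "bacteria",
                   comparison = cmp, coefficient = 1, p_value = qs / 2,
                   q_value = qs, direction = "enriched")
  }
  da <- list(
    Y_vs_E = mk_res("Y_vs_E", c("sigY", "sigE2", "null1"),
                    c(0.01, 0.30, 0.80)),
    Y_vs_C = mk_res("Y_vs_C", c("sigY", "null2"), c(0.02, 0.90)),
    E_vs_C = mk_res("E_vs_C", c("sigE2", "sigE"), c(0.01, 0.05))
  )
  m <- rbind(
    sigY = c(10, 1, 1), sigE2 = c(1, 8, 2), null1 = c(3, 3, 3),
    null2 = c(1, 1, 2), sigE = c(2, 9, 1)
  )
  vals <- t(m)[rep(1:3, each = 2), ]
  rownames(vals) <- paste0("s", 1:6)
  tt <- tiny_table(vals)
  groups <- rep(c("Y", "E", "C"), each = 2)
  sig <- classify_signatures(da, tt, groups)
  expect_setequal(sig$taxon_id[sig$group == "Y"], "sigY")
  # sigE is significant in E_vs_C only and highest in E -> E signature
  expect_true("sigE" %in% sig$taxon_id[sig$group == "E"])
  # sigE2 is a DAM only in E_vs_C (q 0.01) and highest in E
  expect_true("sigE2" %in% sig$taxon_id[sig$group == "E"])
  # null1 is flat and never significant
  expect_false("null1" %in% sig$taxon_id)
  # disjointness holds by construction
  expect_equal(anyDuplicated(sig$taxon_id), 0)
  expect_error(classify_signatures(da[1:2], tt, groups),
               "missing comparison")
})

test_that("planted signatures are recovered on synthetic cohorts", {
  cfg <- signature_recovery_config(95)
  sim <- generate_cohort(cfg)
  cmps <- list(c("Y", "E"), c("Y", "C"), c("E", "C"))
  da <- lapply(cmps, function(cmp) {
    fit_feature_lms(sim$counts, sim$metadata, cmp)
  })
  names(da) <- vapply(cmps, function(x) paste0(x[1], "_vs_", x[2]), "")
  sig <- classify_signatures(da, to_relative(sim$counts),
                             sim$metadata$age_group)
  truth <- signature_truth_taxa()
  expect_gte(sum(truth %in% sig$taxon_id), 8)
  # each recovered signature lands in its planted group
  planted_groups <- rep(c("Y", "E", "C"), each = 3)
  hit <- sig[sig$taxon_id %in% truth, ]
  expect_true(all(hit$group ==
                    planted_groups[match(hit$taxon_id, truth)]))
})

test_that("in-cluster neighborhoods and kingdom breakdowns are exact", {
  # star around 'hub' inside a 6-node cluster
  spokes <- c("a1", "a2", "b1", "b2", "b3")
  edges <- tibble::tibble(taxon_a = "hub", taxon_b = spokes)
  nodes <- tibble::tibble(
    taxon_id = c("hub", spokes, "other"),
    kingdom = c("bacteria", "archaea", "archaea", "bacteria", "bacteria",
                "bacteria", "viruses")
  )
  net <- make_network(edges, nodes)
  part <- walktrap_communities(net, membership_min = 3)
  sn <- signature_neighbors(net, part, "hub")
  expect_true(sn$present)
  expect_equal(sn$degree_in_cluster, 5)
  expect_equal(sn$kingdom_breakdown[["archaea"]], 2)
  expect_equal(sn$kingdom_breakdown[["bacteria"]], 3)

  absent <- signature_neighbors(net, part, "ghost")
  expect_false(absent$present)
  expect_equal(absent$degree_in_cluster, 0)
})

test_that("interaction shifts compare neighbor sets across group networks", {
  edges <- clique_edges(paste0("c", 1:5))
  nets <- list(Y = make_network(edges), E = make_network(edges),
               C = make_network(edges))
  parts <- lapply(nets, walktrap_communities)
  sh <- interaction_shift(nets, parts, "c1")
  expect_true(all(sh$jaccard$jaccard == 1))
  expect_true(all(sh$summary$present))

  # focal absent from one group: jaccard 0 against it, flag false
  netsB <- nets
  netsB$Y <- make_network(clique_edges(paste0("d", 1:4)))
  partsB <- lapply(netsB, walktrap_communities)
  shB <- interaction_shift(netsB, partsB, "c1")
  expect_false(shB$summary$present[shB$summary$group == "Y"])
  jy <- shB$jaccard$jaccard[shB$jaccard$group_a == "Y" |
                              shB$jaccard$group_b == "Y"]
  expect_true(all(jy == 0))
  expect_equal(shB$jaccard$jaccard[shB$jaccard$group_a == "E" &
                                     shB$jaccard$group_b == "C"], 1)
})

test_that("planted rewiring is detected while stable blocks persist", {
  cfg <- rewiring_config(96)
  sim <- generate_cohort(cfg)
  clr <- clr_transform(sim$counts)
  gn <- group_networks(clr, sim$metadata)
  focal <- "archaea_sp_010"
  control <- "bacteria_sp_121"
  yc <- function(sh) {
    sh$jaccard$jaccard[sh$jaccard$group_a == "Y" &
                         sh$jaccard$group_b == "C"]
  }
  sh_f <- interaction_shift(gn$nets, gn$parts, focal)
  sh_c <- interaction_shift(gn$nets, gn$parts, control)
  expect_lte(yc(sh_f), 0.1)
  expect_gte(yc(sh_c), 0.6)
  # the focal taxon's neighbors match the planted blocks per group
  truth_nb <- sim$truth$rewired_neighbors[[focal]]
  nbY <- sh_f$per_group$Y$neighbors$taxon_id
  expect_gte(length(intersect(nbY, truth_nb$Y)) /
               max(length(truth_nb$Y), 1), 0.7)
})
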