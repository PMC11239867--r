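test_that("the progression graph contains exactly the thresholded increasing edges", {
  # all-null matrix -> empty edge set
  em0 <- toy_effect_matrix(data.frame(a = "A10", b = "C10", psi = 0, se = 0.01))
  pg0 <- build_progress_graph(em0)
  expect_equal(nrow(pg0$edges), 0L)
  expect_setequal(pg0$isolated, c("A10", "C10"))
  # two qualifying edges among 3 diseases, with weights = psi
  df <- data.frame(a = c("A10", "C10", "I10"), b = c("C10", "I10", "A10"),
                   psi = c(0.05, 0.02, 0.005), se = 1e-4)
  em <- toy_effect_matrix(df, diseases = c("A10", "C10", "I10"))
  pg <- build_progress_graph(em, min_effect = 0.01)
  expect_equal(nrow(pg$edges), 2L)   # the 0.005 edge fails the threshold
  expect_setequal(pg$edges$weight, c(0.05, 0.02))
  # edge set equals an independent threshold scan of the long table
  brute <- em[em$class == "increasing" & em$psi > 0.01, c("a", "b")]
  expect_setequal(paste(pg$edges$from, pg$edges$to), paste(brute$a, brute$b))
})

test_that("self-tuning clustering separates cliques and recovers planted blocks", {
  # two cliques joined by one weak edge
  codes <- sim_disease_codes(8)
  rows <- list()
  for (i in 1:4) for (j in 1:4) if (i != j) {
    rows[[length(rows) + 1]] <- data.frame(a = codes[i], b = codes[j], psi = 0.05, se = 1e-4)
    rows[[length(rows) + 1]] <- data.frame(a = codes[i + 4], b = codes[j + 4],
                                           psi = 0.05, se = 1e-4)
  }
  rows[[length(rows) + 1]] <- data.frame(a = codes[4], b = codes[5], psi = 0.011, se = 1e-4)
  em <- toy_effect_matrix(do.call(rbind, rows), diseases = codes)
  pg <- build_progress_graph(em)
  cs <- self_tuning_cluster(pg, K_local = 3, seed = 1)
  truth <- setNames(rep(1:2, each = 4), codes)
  expect_equal(adjusted_rand_index(cs$membership, truth), 1)
  # planted 4-block graph with no between-block edges
  pb <- planted_block_em(n_blocks = 4, per_block = 10, within = 0.05,
                         between_frac = 0, seed = 2)
  pg4 <- build_progress_graph(pb$em)
  cs4 <- self_tuning_cluster(pg4, seed = 3)
  expect_equal(adjusted_rand_index(cs4$membership, pb$truth[names(cs4$membership)]), 1)
  expect_true(cs4$multiple_components)
  # node-order equivariance: permuting the matrix rows relabels but does not
  # change the partition
  em_perm <- pb$em[sample(nrow(pb$em)), ]
  attributes(em_perm)[c("diseases", "class")] <- attributes(pb$em)[c("diseases", "class")]
  cs4b <- self_tuning_cluster(build_progress_graph(em_perm), seed = 3)
  expect_equal(adjusted_rand_index(cs4$membership, cs4b$membership[names(cs4$membership)]), 1)
})

test_that("partition is invariant to uniform scaling of edge weights", {
  pb <- planted_block_em(n_blocks = 3, per_block = 8, within = 0.04,
                         between_frac = 0.04, seed = 7)
  pg1 <- build_progress_graph(pb$em)
  em2 <- pb$em
  em2$psi <- em2$psi * 3     # classes unchanged; weights scaled
  pg2 <- build_progress_graph(em2)
  cs1 <- self_tuning_cluster(pg1, seed = 5)
  cs2 <- self_tuning_cluster(pg2, seed = 5)
  expect_equal(adjusted_rand_index(cs1$membership, cs2$membership), 1)
})

test_that("hubs maximize within-constellation weighted strength", {
  # star graph: center -> 8 leaves
  codes <- sim_disease_codes(9)
  df <- data.frame(a = codes[1], b = codes[2:9], psi = 0.05, se = 1e-4)
  em <- toy_effect_matrix(df, diseases = codes)
  pg <- build_progress_graph(em)
  hubs <- identify_hubs(pg, setNames(rep(1L, 9), codes))
  expect_equal(hubs$hub, codes[1])
  # toy weighted graph: hub equals exhaustive strength maximization
  df2 <- data.frame(a = c("A10", "A10", "C10", "I10"),
                    b = c("C10", "I10", "I10", "N10"),
                    psi = c(0.02, 0.03, 0.06, 0.04), se = 1e-4)
  em2 <- toy_effect_matrix(df2, diseases = c("A10", "C10", "I10", "N10"))
  pg2 <- build_progress_graph(em2)
  mem <- setNames(rep(1L, 4), c("A10", "C10", "I10", "N10"))
  hubs2 <- identify_hubs(pg2, mem)
  strengths <- c(A10 = 0.02 + 0.03, C10 = 0.02 + 0.06, I10 = 0.03 + 0.06 + 0.04,
                 N10 = 0.04)
  expect_equal(hubs2$hub, names(which.max(strengths)))
  expect_equal(hubs2$strength, max(strengths))
  # hub table schema: one row per constellation with code + chapter
  expect_named(hubs2, c("constellation", "hub", "chapter", "strength", "size"))
  expect_equal(hubs2$chapter, map_chapter(hubs2$hub))
  # singleton constellation: its node is the hub
  mem3 <- setNames(c(1L, 1L, 1L, 2L), c("A10", "C10", "I10", "N10"))
  hubs3 <- identify_hubs(pg2, mem3)
  expect_equal(hubs3$hub[hubs3$constellation == 2], "N10")
})

test_that("kamada-kawai reaches analytic optima and never increases energy", {
  # 2-node graph with ideal length 1/0.05 = 20
  df <- data.frame(a = "A10", b = "C10", psi = 0.05, se = 1e-4)
  em <- toy_effect_matrix(df, diseases = c("A10", "C10"))
  pg <- build_progress_graph(em)
  lay <- kamada_kawai_layout(pg, tol = 1e-8)
  d <- sqrt(sum((lay$coords[1, ] - lay$coords[2, ])^2))
  expect_equal(d, 1 / 0.05, tolerance = 1e-4)
  expect_lte(lay$energy, lay$initial_energy)
  # equilateral triangle metric: pairwise distances equal within 1%
  df3 <- data.frame(a = c("A10", "C10", "I10"), b = c("C10", "I10", "A10"),
                    psi = 0.05, se = 1e-4)
  em3 <- toy_effect_matrix(df3, diseases = c("A10", "C10", "I10"))
  lay3 <- kamada_kawai_layout(build_progress_graph(em3), tol = 1e-8)
  P <- lay3$coords
  dd <- c(dist(P))
  expect_lt((max(dd) - min(dd)) / mean(dd), 0.01)
  # 6-node toy graph: optimized energy beats 100 random layouts under the
  # same energy function
  pb <- planted_block_em(n_blocks = 2, per_block = 3, within = 0.05,
                         between_frac = 0.5, seed = 13)
  pg6 <- build_progress_graph(pb$em)
  lay6 <- kamada_kawai_layout(pg6, tol = 1e-8)
  W <- morbidmap:::symmetric_weights(pg6)
  gu <- igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE)
  l <- igraph::distances(gu, weights = 1 / igraph::E(gu)$weight)
  kmat <- 1 / l^2; diag(kmat) <- 0
  set.seed(99)
  rand_e <- replicate(100, {
    Pr <- matrix(runif(12, -max(l), max(l)), 6, 2)
    morbidmap:::kk_energy(Pr, l, kmat)
  })
  expect_lte(lay6$energy, min(rand_e))
  expect_lte(lay6$energy, lay6$initial_energy)
})

test_that("adjusted Rand index matches its contingency formula and brute force", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_error(adjusted_rand_index(setNames(1:2, c("a", "b")),
                                   setNames(1:2, c("a", "c"))), "mismatched")
  # brute-force pair counting on random partitions of up to 12 nodes
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    p1 <- sample(1:3, n, replace = TRUE)
    p2 <- sample(1:4, n, replace = TRUE)
    expect_equal(adjusted_rand_index(p1, p2), pair_count_ari(p1, p2),
                 tolerance = 1e-12)
  }
  # independent random partitions have ARI centred at 0
  set.seed(23)
  aris <- replicate(100, {
    adjusted_rand_index(sample(1:5, 1000, replace = TRUE),
                        sample(1:5, 1000, replace = TRUE))
  })
  expect_lt(abs(mean(aris)), 0.02)
})

test_that("adjusted Rand index agrees with an established implementation", {
  skip_if_not_installed("mclust")
  set.seed(29)
  for (rep in 1:10) {
    p1 <- sample(1:4, 30, replace = TRUE)
    p2 <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(p1, p2),
                 mclust::adjustedRandIndex(p1, p2), tolerance = 1e-12)
  }
})

test_that("stability reports are deterministic and saturate on separated blocks", {
  pb <- planted_block_em(n_blocks = 3, per_block = 8, within = 0.05,
                         between_frac = 0.08, seed = 19)
  pg <- build_progress_graph(pb$em)
  cs <- self_tuning_cluster(pg, seed = 4)
  sr1 <- stability_report(pg, cs, n_seeds = 10, seed = 4)
  sr2 <- stability_report(pg, cs, n_seeds = 10, seed = 4)
  expect_equal(sr1$ari, sr2$ari)
  expect_true(all(sr1$ari$ari >= -1 & sr1$ari$ari <= 1))
  expect_true(all(c("kmeans_seeds", "self_tuning_spectral", "ward", "louvain")
                  %in% sr1$ari$method))
  # perfectly separated blocks: k-means reinitializations always agree
  pb0 <- planted_block_em(n_blocks = 3, per_block = 8, within = 0.05,
                          between_frac = 0, seed = 19)
  pg0 <- build_progress_graph(pb0$em)
  cs0 <- self_tuning_cluster(pg0, seed = 4)
  sr0 <- stability_report(pg0, cs0, n_seeds = 10, seed = 4)
  km <- sr0$ari$ari[sr0$ari$method == "kmeans_seeds"]
  expect_true(all(km == 1))
})
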