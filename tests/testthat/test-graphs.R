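test_that("consensus over identical subjects reproduces the common graph", {
  parc <- tiny_parcellation(12)
  scs <- make_subject_scs(parc, n_subjects = 4, inter_penalty = 1,
                          noise = 0, seed = 3)
  cons <- consensus_sc(scs, parc, recurrence_min = 0.3)
  expect_equal(cons$weights > 0, scs[[1]] > 0)
  expect_equal(cons$weights, scs[[1]] * 1.0)
})

test_that("consensus preserves single-subject intrahemispheric density", {
  fx <- fixture_sc_cohort()
  ut <- upper.tri(fx$scs[[1]])
  intra <- outer(fx$parc$hemisphere, fx$parc$hemisphere, "==")
  mean_intra <- mean(sapply(fx$scs, function(m) mean((m > 0)[ut & intra])))
  expect_lt(abs(fx$cons$density_intra - mean_intra), 0.02)
  # density accounting: overall is the support-weighted mean of the classes
  n_intra <- sum(ut & intra)
  n_inter <- sum(ut & !intra)
  expect_equal(fx$cons$density_overall,
               (fx$cons$density_intra * n_intra +
                  fx$cons$density_inter * n_inter) / (n_intra + n_inter),
               tolerance = 1e-12)
})

test_that("edges below the recurrence threshold are never retained", {
  parc <- tiny_parcellation(10)
  scs <- make_subject_scs(parc, n_subjects = 20, noise = 0, seed = 3)
  # plant an edge present in exactly 1 of 20 subjects
  empty <- which(scs[[1]] == 0 & upper.tri(scs[[1]]), arr.ind = TRUE)[1, ]
  scs[[1]][empty[1], empty[2]] <- scs[[1]][empty[2], empty[1]] <- 50
  cons <- consensus_sc(scs, parc, recurrence_min = 0.3)
  expect_equal(cons$weights[empty[1], empty[2]], 0)
})

test_that("degree-preserving rewiring keeps degrees and connectedness", {
  fx <- fixture_sc_cohort()
  deg <- rowSums(fx$cons$weights > 0)
  rew <- rewire_degree_preserving(fx$cons, n_iter_per_edge = 5, seed = 3)
  expect_identical(rowSums(rew$weights > 0), deg)
  expect_true(connsmooth:::connected_adj(rew$weights))
  expect_identical(sort(rew$weights[rew$weights > 0]),
                   sort(fx$cons$weights[fx$cons$weights > 0]))
  # zero iterations: identity; enough iterations: the support changes
  expect_identical(rewire_degree_preserving(fx$cons, 0)$weights,
                   fx$cons$weights)
  set.seed(1)
  g30 <- random_connected_graph(30, p_edge = 0.2)
  sc30 <- structural_connectome(g30, tiny_parcellation(30, seed = 8))
  rew30 <- rewire_degree_preserving(sc30, n_iter_per_edge = 100, seed = 3)
  expect_gt(sum((rew30$weights > 0) != (g30 > 0)), 0)
})

test_that("filter graph variants have the promised supports and weights", {
  fx <- fixture_sc_cohort()
  parc <- fx$parc
  ed <- roi_distances(parc)
  ut <- upper.tri(ed)
  g_sc <- build_filter_graph("sc", fx$cons, parc)
  g_full <- build_filter_graph("ed_full", fx$cons, parc)
  g_match <- build_filter_graph("ed_match", fx$cons, parc)
  g_dens <- build_filter_graph("ed_dens", fx$cons, parc)
  expect_error(build_filter_graph("nope", fx$cons, parc), "unknown")
  # supports
  expect_identical(g_match$weights > 0, fx$cons$weights > 0)
  expect_identical(sum(g_dens$weights[ut] > 0), sum(fx$cons$weights[ut] > 0))
  expect_true(all(g_full$weights[ut] > 0))
  # normalization: max off-diagonal weight is 1 for every variant
  for (g in list(g_sc, g_full, g_match, g_dens))
    expect_equal(max(g$weights[ut]), 1)
  # symmetry and zero diagonal
  for (g in list(g_sc, g_full, g_match, g_dens)) {
    expect_identical(g$weights, t(g$weights))
    expect_identical(unname(diag(g$weights)), rep(0, 68))
  }
  # strict monotone decay with distance for the dense variant
  ord <- order(ed[ut])
  w_sorted <- g_full$weights[ut][ord]
  expect_true(all(diff(w_sorted) < 0))
  # randomized control keeps the degree sequence of the consensus
  g_rand <- build_filter_graph("randomized", fx$cons, parc, seed = 4)
  expect_identical(rowSums(g_rand$weights > 0),
                   rowSums(fx$cons$weights > 0))
  expect_gt(sum((g_rand$weights > 0) != (fx$cons$weights > 0)), 0)
})

test_that("search information matches exhaustive enumeration on small graphs", {
  # 2-node forced path: zero bits; 3-node path: exactly one bit
  w2 <- matrix(c(0, 3, 3, 0), 2)
  expect_equal(search_information(w2, symmetrize = FALSE)$si[1, 2], 0)
  w3 <- matrix(0, 3, 3)
  w3[1, 2] <- w3[2, 1] <- 1
  w3[2, 3] <- w3[3, 2] <- 1
  expect_equal(search_information(w3, symmetrize = FALSE)$si[1, 3], 1)
  # random connected graphs vs the brute-force oracle
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    w <- random_connected_graph(n)
    si <- search_information(w, symmetrize = FALSE)$si
    for (s in 1:n) for (t in seq_len(n)[-s]) {
      expect_lt(abs(si[s, t] - si_oracle(w, s, t)), 1e-12)
    }
  }
})

test_that("search information is scale-free and anticorrelates with fibers", {
  fx <- fixture_sc_cohort()
  si1 <- fx$si$si
  si2 <- search_information(fx$cons$weights * 7.3)$si
  expect_equal(si1, si2, tolerance = 1e-12)
  ut <- upper.tri(si1)
  pres <- fx$cons$weights[ut] > 0
  expect_lt(cor(si1[ut][pres], fx$cons$weights[ut][pres],
                method = "spearman"), 0)
})

test_that("disconnected node pairs yield infinite search information", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  w[3, 4] <- w[4, 3] <- 1
  expect_warning(si <- search_information(w, symmetrize = FALSE),
                 "disconnected")
  expect_true(is.infinite(si$si[1, 3]))
  expect_equal(si$si[1, 2], 0)
})
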