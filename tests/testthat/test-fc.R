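sine_epoch <- function(freqs, T_s = 20, rate = 250, noise = 0, phase = NULL,
                       seed = 1) {
  set.seed(seed)
  t <- seq(0, T_s - 1 / rate, by = 1 / rate)
  if (is.null(phase)) phase <- rep(0, length(freqs))
  x <- t(mapply(function(f, ph) sin(2 * pi * f * t + ph) +
                  noise * rnorm(length(t)), freqs, phase))
  source_epoch(x, rate, "s1", 1L)
}

test_that("interval screening and artifact windows behave as specified", {
  parc <- tiny_parcellation(4)
  set.seed(2)
  mk <- function(T_s) source_epoch(matrix(rnorm(4 * T_s * 250), 4), 250)
  eps <- list(mk(25), mk(15))
  kept <- segment_and_reject(eps, min_duration_s = 19)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$duration_s, 25)
  expect_error(segment_and_reject(list(mk(10)), 19), "shorter")
  # pure Gaussian windows survive a 6-sd rule; a planted spike does not
  ep <- mk(30)
  win <- segment_and_reject(list(ep), 19, window_s = 3, reject_sd = 6)
  expect_length(win, 10)
  ep$data[2, 1000] <- mean(ep$data[2, ]) + 10 * sd(ep$data[2, ])
  win2 <- segment_and_reject(list(ep), 19, window_s = 3, reject_sd = 6)
  expect_length(win2, 9)
})

test_that("envelope FC identities: duplication, sign flip, scale invariance", {
  set.seed(3)
  x <- matrix(rnorm(4 * 250 * 30), 4)
  x[2, ] <- x[1, ]            # duplicate
  x[3, ] <- -x[1, ]           # sign flip
  x[4, ] <- 3.7 * x[1, ]      # rescale
  fc <- envelope_fc(list(source_epoch(x, 250)), band = c(8, 13))
  expect_gt(fc$values[1, 2], 1 - 1e-9)
  expect_gt(fc$values[1, 3], 1 - 1e-9)
  expect_gt(fc$values[1, 4], 1 - 1e-9)
  expect_identical(fc$values, t(fc$values))
  expect_identical(unname(diag(fc$values)), rep(1, 4))
})

test_that("independent channels give small envelope correlations", {
  # 0.5 Hz-filtered envelopes have few effective samples; the spread is
  # wide but centred on zero
  set.seed(4)
  rs <- replicate(60, {
    x <- matrix(rnorm(2 * 250 * 60), 2)
    envelope_fc(list(source_epoch(x, 250)), band = c(8, 13))$values[1, 2]
  })
  expect_lt(abs(mean(rs)), 0.1)
  expect_gt(mean(abs(rs) < 0.35), 0.9)
})

test_that("constant channels are flagged and zeroed, not propagated", {
  set.seed(5)
  x <- matrix(rnorm(3 * 250 * 20), 3)
  x[3, ] <- 0
  expect_warning(
    fc <- envelope_fc(list(source_epoch(x, 250)), band = c(8, 13)),
    "constant")
  expect_equal(fc$values[1, 3], 0)
})

test_that("duration weighting reduces to the single-interval FC when equal", {
  set.seed(6)
  x <- matrix(rnorm(3 * 250 * 20), 3)
  one <- envelope_fc(list(source_epoch(x, 250)), band = c(8, 13))
  three <- envelope_fc(list(source_epoch(x, 250), source_epoch(x, 250),
                            source_epoch(x, 250)), band = c(8, 13))
  expect_lt(max(abs(one$values - three$values)), 1e-12)
})

test_that("coherence identities: duplicated channels and quadrature phase", {
  base <- sine_epoch(c(10, 10), T_s = 21, noise = 1e-6,
                     phase = c(0, pi / 2))
  x <- rbind(base$data[1, ], base$data[1, ], base$data[2, ])
  eps <- segment_and_reject(list(source_epoch(x, 250)),
                            min_duration_s = 3, window_s = 3)
  coh <- spectral_fc(eps, c(8, 13), "coherence")
  ico <- spectral_fc(eps, c(8, 13), "icoherence")
  # duplicated channel: coherence 1, imaginary part ~0
  expect_gt(coh$values[1, 2], 1 - 1e-9)
  expect_lt(abs(ico$values[1, 2]), 1e-9)
  # quarter-cycle shift maximizes the imaginary part
  expect_gt(abs(ico$values[1, 3]), 0.9)
  expect_error(spectral_fc(list(sine_epoch(10, T_s = 0.05)), c(8, 13)),
               "short")
})

test_that("fisher z and its inverse round-trip; extremes are clipped", {
  expect_equal(fisher_z(matrix(0, 2, 2))[1, 2], 0)
  expect_equal(fisher_z(matrix(0.5, 2, 2))[1, 2], atanh(0.5))
  r <- seq(-0.999, 0.999, length.out = 21)
  expect_lt(max(abs(tanh(fisher_z(matrix(r, 3, 7))) - r)), 1e-12)
  z1 <- fisher_z(matrix(1, 2, 2))
  expect_true(all(is.finite(z1)))
})

test_that("rank-normal transform is monotone, centred and tie-safe", {
  set.seed(8)
  v <- matrix(rnorm(100), 10, 10)
  v <- (v + t(v)) / 2
  diag(v) <- 1
  rn <- rank_normal(v)
  ut <- upper.tri(v)
  expect_lt(abs(mean(rn[ut])), 1e-6)
  expect_identical(order(rn[ut]), order(v[ut]))
  expect_identical(unname(diag(rn)), rep(1, 10))
  expect_identical(rn, t(rn))
  # all-tied off-diagonal maps to all zeros
  flat <- matrix(0.3, 4, 4)
  diag(flat) <- 1
  expect_identical(unname(rank_normal(flat)[upper.tri(flat)]), rep(0, 6))
})

test_that("grid FC equals the direct smooth-then-FC route", {
  parc <- tiny_parcellation(6)
  scs <- make_subject_scs(parc, n_subjects = 2, seed = 5)
  src <- make_sources(scs[[1]], parc, duration_s = c(20, 25), seed = 3)
  g <- build_filter_graph("ed_full", structural_connectome(scs[[1]], parc),
                          parc, k = 0.02)
  grid <- study_fc_grid(list(s1 = src$epochs), g, c(0, 0.5), c(8, 13))
  direct0 <- envelope_fc(src$epochs, c(8, 13))
  sm <- lapply(src$epochs, graph_smooth, graph = g, G = 0.5)
  direct5 <- envelope_fc(sm, c(8, 13))
  expect_lt(max(abs(grid$s1[["0"]]$values - direct0$values)), 1e-9)
  expect_lt(max(abs(grid$s1[["0.5"]]$values - direct5$values)), 1e-9)
})

test_that("polyphase resampling preserves in-band content and duration", {
  t1k <- seq(0, 20 - 1/1000, by = 1/1000)
  ep <- source_epoch(rbind(sin(2 * pi * 10 * t1k), cos(2 * pi * 6 * t1k)),
                     1000, "s1", 1L)
  down <- resample_epochs(list(ep), 250)[[1]]
  expect_equal(down$rate, 250)
  expect_equal(down$duration_s, 20, tolerance = 0.01)
  # spectral fidelity (resampling leaves a small group delay, so compare
  # spectra rather than sample-wise): the 10 Hz peak survives at 10 Hz
  sp <- Mod(fft(down$data[1, ]))[1:2500]
  expect_equal(which.max(sp), 10 * 20 + 1)   # bin of 10 Hz at 1/20 Hz resolution
  expect_gt(sd(down$data[1, 200:4800]) / sd(ep$data[1, ]), 0.95)
  # same rate: untouched
  expect_identical(resample_epochs(list(ep), 1000)[[1]], ep)
})
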