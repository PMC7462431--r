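glm_fixture <- function() {
  cached("glm_fixture", {
    fx <- fixture_sc_cohort()
    set.seed(33)
    rrv_vec <- stats::setNames(runif(68, 0.2, 1), fx$parc$name)
    rrv_vec[which.max(rrv_vec)] <- 1
    tab <- build_pair_table(matrix(0, 68, 68), fx$si, fx$parc, rrv_vec,
                            fx$cons)
    list(fx = fx, tab = tab, rrv = rrv_vec)
  })
}

test_that("relative regional variance normalizes and averages as defined", {
  mk <- function(vars) {
    set.seed(9)
    list(source_epoch(diag(sqrt(vars)) %*% matrix(rnorm(2 * 20000), 2),
                      250))
  }
  # single subject with variances (4, 1) -> (1, 0.25)
  one <- rrv(list(s1 = mk(c(4, 1))))
  expect_equal(unname(one), c(1, 0.25), tolerance = 0.02)
  # group average of per-subject unit-max vectors
  two <- rrv(list(s1 = mk(c(4, 1)), s2 = mk(c(1, 4))))
  expect_equal(unname(two), c(0.625, 0.625), tolerance = 0.02)
})

test_that("pair table has M rows and consistent geometry", {
  g <- glm_fixture()
  expect_equal(nrow(g$tab), 68 * 67 / 2)
  # recompute distances row-wise from centroids
  i <- match(g$tab$roi_i, g$fx$parc$name)
  j <- match(g$tab$roi_j, g$fx$parc$name)
  d <- sqrt((g$fx$parc$x[i] - g$fx$parc$x[j])^2 +
              (g$fx$parc$y[i] - g$fx$parc$y[j])^2 +
              (g$fx$parc$z[i] - g$fx$parc$z[j])^2)
  expect_lt(max(abs(g$tab$ed - d)), 1e-9)
  expect_equal(sum(g$tab$sc_connected),
               sum(g$fx$cons$weights[upper.tri(g$fx$cons$weights)] > 0))
})

test_that("pair table is invariant to ROI relabeling up to row order", {
  g <- glm_fixture()
  perm <- sample(68)
  parc2 <- parcellation(g$fx$parc$name[perm], g$fx$parc$hemisphere[perm],
                        cbind(g$fx$parc$x, g$fx$parc$y, g$fx$parc$z)[perm, ],
                        g$fx$parc$size[perm])
  sc2 <- structural_connectome(g$fx$cons$weights[perm, perm], parc2)
  si2 <- g$fx$si$si[perm, perm]
  set.seed(12)
  fcv <- matrix(rnorm(68^2), 68)
  fcv <- (fcv + t(fcv)) / 2
  rrv_vec <- stats::setNames(runif(68, 0.5, 1), g$fx$parc$name)
  t1 <- build_pair_table(fcv, g$fx$si, g$fx$parc, rrv_vec, g$fx$cons)
  t2 <- build_pair_table(fcv[perm, perm], si2, parc2, rrv_vec[perm], sc2)
  key <- function(tt) {
    k <- apply(cbind(pmin(tt$roi_i, tt$roi_j), pmax(tt$roi_i, tt$roi_j)),
               1, paste, collapse = "|")
    tt[order(k), c("fc", "ed", "sc_si", "rrv_pair", "roi_size_pair",
                   "sc_connected")]
  }
  expect_equal(key(t1), key(t2), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("stepwise fit recovers an exact linear truth in distance", {
  g <- glm_fixture()
  tab <- g$tab
  tab$fc <- 3 - 0.02 * tab$ed
  res <- stepwise_glm(tab)
  expect_equal(res$steps$term[1], "ed")
  expect_equal(res$r2_final, 1, tolerance = 1e-9)
})

test_that("stepwise fit recovers a planted interaction model", {
  g <- glm_fixture()
  z <- function(x) (x - mean(x)) / sd(x)
  tab <- g$tab
  hits <- sapply(1:20, function(k) {
    set.seed(400 + k)
    tab$fc <- 0.5 * z(tab$ed) + 0.3 * z(tab$sc_si) +
      0.2 * z(tab$ed) * z(tab$sc_si) + rnorm(nrow(tab), 0, 0.5)
    res <- stepwise_glm(tab)
    ok_terms <- all(c("ed", "sc_si", "ed:sc_si") %in% res$terms)
    # cumulative r2 close to the full-model least-squares oracle
    X <- cbind(1, z(tab$ed), z(tab$sc_si), z(tab$ed) * z(tab$sc_si))
    r2_oracle <- 1 - sum(lm.fit(X, tab$fc)$residuals^2) /
      sum((tab$fc - mean(tab$fc))^2)
    ok_terms && abs(res$r2_final - r2_oracle) < 0.02
  })
  expect_gte(mean(hits), 0.95)
})

test_that("stepwise r2 path is nondecreasing over additions", {
  g <- glm_fixture()
  z <- function(x) (x - mean(x)) / sd(x)
  tab <- g$tab
  set.seed(77)
  tab$fc <- 0.4 * z(tab$ed) + 0.2 * z(tab$rrv_pair) + rnorm(nrow(tab), 0, 1)
  res <- stepwise_glm(tab)
  adds <- res$steps[res$steps$action == "add", ]
  expect_true(all(diff(adds$r2_cumulative) >= -1e-12))
})

test_that("pure-noise FC rarely admits any predictor", {
  g <- glm_fixture()
  tab <- g$tab
  entered <- sapply(1:60, function(k) {
    set.seed(800 + k)
    tab$fc <- rnorm(nrow(tab))
    length(stepwise_glm(tab)$terms) > 0
  })
  expect_lte(mean(entered), 0.15)
})

test_that("matched comparison balances bins and is calibrated under the null", {
  g <- glm_fixture()
  tab <- g$tab
  # per-bin counts equal by construction: check via a deterministic run
  tabs <- lapply(1:6, function(s) {
    set.seed(s)
    t <- tab
    t$fc <- rnorm(nrow(t))
    t
  })
  res <- matched_sc_comparison(tabs, n_resamples = 3, seed = 1)
  expect_true(is.finite(res$p_raw))
  expect_gt(res$n_bins_used, 0)
  # type-I calibration at alpha = 0.05 over seeded null simulations
  rej <- sapply(1:120, function(k) {
    set.seed(1000 + k)
    tt <- lapply(1:18, function(s) {
      t <- tab
      t$fc <- rnorm(nrow(t))
      t
    })
    matched_sc_comparison(tt, n_resamples = 5, seed = k)$p_raw < 0.05
  })
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.11)
})

test_that("a planted connected-pair offset is detected across subjects", {
  g <- glm_fixture()
  tab <- g$tab
  tt <- lapply(1:18, function(s) {
    set.seed(2000 + s)
    t <- tab
    t$fc <- 0.3 * exp(-t$ed / 60) + 0.05 * t$sc_connected +
      rnorm(nrow(t), 0, 0.1)
    t
  })
  res <- matched_sc_comparison(tt, seed = 5)
  expect_lt(res$p_raw, 0.05)
  expect_gt(median(res$mean_sc_plus - res$mean_sc_minus), 0)
})
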