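# Structure-function regression: how Euclidean distance, search information,
# relative regional variance and ROI size predict FC, plus the
# distance-matched comparison of structurally connected vs unconnected pairs.

#' Relative regional variance (RRV)
#'
#' Per subject, the mean (over intervals) per-ROI signal variance, scaled so
#' the maximum over ROIs is 1; averaged over subjects. A proxy for regional
#' signal-to-noise ratio.
#'
#' @param epochs list (by subject) of lists of [source_epoch()]s.
#' @return named numeric vector in (0, 1], one entry per ROI.
#' @export
rrv <- function(epochs) {
  stopifnot(length(epochs) >= 1)
  per_subject <- lapply(epochs, function(subj) {
    v <- Reduce(`+`, lapply(subj, function(ep) apply(ep$data, 1L, var))) /
      length(subj)
    if (all(v == 0)) stop("all-zero subject", call. = FALSE)
    v / max(v)
  })
  Reduce(`+`, per_subject) / length(per_subject)
}

#' Build the pair-level predictor table
#'
#' One row per unordered ROI pair, in fixed lexicographic index order:
#' FC value, Euclidean distance, search information, pair-level RRV and ROI
#' size (mean of the two ROIs' values), and a structural-connection flag.
#'
#' @param fc an `fc_matrix` or plain symmetric matrix (dependent variable).
#' @param si a [search_information()] object or plain matrix.
#' @param parc a [parcellation()].
#' @param rrv_vec per-ROI RRV vector (see [rrv()]).
#' @param sc a [structural_connectome()].
#' @param pair_reduce `"mean"` (default) or `"min"` reduction of nodal RRV
#'   and ROI size to the pair level.
#' @return data.frame of class `pair_table` with M = N(N-1)/2 rows.
#' @export
build_pair_table <- function(fc, si, parc, rrv_vec, sc,
                             pair_reduce = c("mean", "min")) {
  pair_reduce <- match.arg(pair_reduce)
  fcv <- if (inherits(fc, "fc_matrix")) fc$values else fc
  siv <- if (inherits(si, "search_information")) si$si else si
  n <- nrow(fcv)
  if (nrow(siv) != n || nrow(parc) != n || length(rrv_vec) != n ||
      nrow(sc$weights) != n)
    stop("dimension mismatch across pair-table inputs", call. = FALSE)
  ed <- roi_distances(parc)
  ij <- which(upper.tri(fcv), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  red <- if (pair_reduce == "mean") function(a, b) (a + b) / 2 else pmin
  out <- data.frame(
    roi_i = parc$name[ij[, 1]], roi_j = parc$name[ij[, 2]],
    fc = fcv[ij], ed = ed[ij], sc_si = siv[ij],
    rrv_pair = red(rrv_vec[ij[, 1]], rrv_vec[ij[, 2]]),
    roi_size_pair = red(parc$size[ij[, 1]], parc$size[ij[, 2]]),
    sc_connected = sc$weights[ij] > 0,
    stringsAsFactors = FALSE)
  if (!all(is.finite(out$sc_si)))
    stop("non-finite search information (disconnected SC?)", call. = FALSE)
  class(out) <- c("pair_table", "data.frame")
  out
}

glm_term_columns <- function(table) {
  z <- function(x) (x - mean(x)) / sd(x)
  mains <- cbind(ed = z(table$ed), sc_si = z(table$sc_si),
                 rrv = z(table$rrv_pair), size = z(table$roi_size_pair))
  inters <- utils::combn(colnames(mains), 2)
  icols <- apply(inters, 2, function(pr) mains[, pr[1]] * mains[, pr[2]])
  colnames(icols) <- apply(inters, 2, paste, collapse = ":")
  cbind(mains, icols)
}

fit_rss <- function(y, X) {
  f <- lm.fit(cbind(`(Intercept)` = 1, X), y)
  if (any(is.na(f$coefficients))) return(NULL)   # rank deficient
  sum(f$residuals^2)
}

#' Forward-backward stepwise linear model over pair-level predictors
#'
#' Gaussian identity-link model of FC on four standardized main effects
#' (ED, search information, RRV, ROI size) and their six first-order
#' interactions. At each step the candidate with the smallest
#' deviance-difference p-value (chi-squared on the dispersion-scaled
#' deviance change) enters if p < `alpha_add`; entered terms whose removal
#' p exceeds `alpha_remove` leave. Interactions are eligible only while
#' both main effects are in the model. Also fits the four single-predictor
#' models for their individual r-squared.
#'
#' @param table a [build_pair_table()] result.
#' @param alpha_add,alpha_remove entry / removal significance levels.
#' @return object of class `stepwise_glm`: `steps` (data.frame of entered
#'   terms with entry order, deviance change, p-value and cumulative r2),
#'   `terms` (final model), `r2_single`, `r2_final`.
#' @export
stepwise_glm <- function(table, alpha_add = 0.05, alpha_remove = 0.10) {
  y <- table$fc
  X <- glm_term_columns(table)
  mains <- colnames(X)[1:4]
  all_terms <- colnames(X)
  dev_null <- sum((y - mean(y))^2)
  in_model <- character(0)
  steps <- data.frame(term = character(0), action = character(0),
                      deviance_change = numeric(0), p = numeric(0),
                      r2_cumulative = numeric(0), stringsAsFactors = FALSE)
  dev_cur <- dev_null
  repeat {
    changed <- FALSE
    # forward: candidates respecting the interaction hierarchy
    eligible <- setdiff(all_terms, in_model)
    eligible <- eligible[vapply(eligible, function(tm) {
      pr <- strsplit(tm, ":", fixed = TRUE)[[1]]
      length(pr) == 1L || all(pr %in% in_model)
    }, logical(1))]
    if (length(eligible)) {
      cand <- vapply(eligible, function(tm) {
        rss <- fit_rss(y, X[, c(in_model, tm), drop = FALSE])
        if (is.null(rss)) return(NA_real_)
        df_res <- length(y) - length(in_model) - 2L
        phi <- rss / df_res
        pchisq((dev_cur - rss) / phi, df = 1, lower.tail = FALSE)
      }, numeric(1))
      cand <- cand[!is.na(cand)]
      if (length(cand) && min(cand) < alpha_add) {
        tm <- names(cand)[which.min(cand)]
        rss <- fit_rss(y, X[, c(in_model, tm), drop = FALSE])
        steps <- rbind(steps, data.frame(
          term = tm, action = "add", deviance_change = dev_cur - rss,
          p = min(cand), r2_cumulative = 1 - rss / dev_null,
          stringsAsFactors = FALSE))
        in_model <- c(in_model, tm)
        dev_cur <- rss
        changed <- TRUE
      }
    }
    # backward: terms removable without breaking the hierarchy
    removable <- in_model[vapply(in_model, function(tm) {
      !tm %in% unlist(lapply(strsplit(grep(":", in_model, value = TRUE),
                                      ":", fixed = TRUE), identity))
    }, logical(1))]
    if (length(removable)) {
      pr <- vapply(removable, function(tm) {
        rss <- fit_rss(y, X[, setdiff(in_model, tm), drop = FALSE])
        if (is.null(rss)) return(NA_real_)
        df_res <- length(y) - length(in_model) - 1L
        phi <- dev_cur / df_res
        pchisq((rss - dev_cur) / phi, df = 1, lower.tail = FALSE)
      }, numeric(1))
      pr <- pr[!is.na(pr)]
      if (length(pr) && max(pr) > alpha_remove) {
        tm <- names(pr)[which.max(pr)]
        rss <- fit_rss(y, X[, setdiff(in_model, tm), drop = FALSE])
        steps <- rbind(steps, data.frame(
          term = tm, action = "remove", deviance_change = rss - dev_cur,
          p = max(pr), r2_cumulative = 1 - rss / dev_null,
          stringsAsFactors = FALSE))
        in_model <- setdiff(in_model, tm)
        dev_cur <- rss
        changed <- TRUE
      }
    }
    if (!changed || nrow(steps) > 50) break
  }
  r2_single <- vapply(mains, function(tm) {
    rss <- fit_rss(y, X[, tm, drop = FALSE])
    1 - rss / dev_null
  }, numeric(1))
  structure(list(steps = steps, terms = in_model, r2_single = r2_single,
                 r2_final = 1 - dev_cur / dev_null),
            class = "stepwise_glm")
}

#' @export
print.stepwise_glm <- function(x, ...) {
  cat("<stepwise_glm> final terms:", paste(x$terms, collapse = ", "),
      sprintf("(r2 = %.3f)\n", x$r2_final))
  print(x$steps)
  invisible(x)
}

#' Distance-matched comparison of connected vs unconnected FC
#'
#' Tests whether FC over structurally connected ROI pairs (SC+) exceeds FC
#' over unconnected pairs (SC-) once the two samples are matched in their
#' Euclidean-distance distribution. The pooled ED range is restricted to
#' the overlap of the SC+ and SC- supports and split into equal-count bins;
#' within each bin the larger class is repeatedly subsampled (without
#' replacement) to the smaller class's count. Per-subject class means are
#' averaged over resamplings and compared across subjects with a Wilcoxon
#' signed-rank test.
#'
#' @param tables list (by subject) of [build_pair_table()] results sharing
#'   one pair structure.
#' @param n_bins number of equal-count ED bins.
#' @param n_resamples number of matched subsamplings averaged per subject.
#' @param seed integer seed.
#' @param alpha significance level.
#' @param n_comparisons Bonferroni factor (e.g., number of bands tested).
#' @return object of class `matched_comparison`: per-subject matched means,
#'   the signed-rank statistic, raw and Bonferroni-corrected p-values, and
#'   the bin definition.
#' @export
matched_sc_comparison <- function(tables, n_bins = 10, n_resamples = 100,
                                  seed = 1L, alpha = 0.05,
                                  n_comparisons = 1L) {
  t1 <- tables[[1]]
  plus <- which(t1$sc_connected)
  minus <- which(!t1$sc_connected)
  if (!length(plus) || !length(minus))
    stop("need both connected and unconnected pairs", call. = FALSE)
  lo <- max(min(t1$ed[plus]), min(t1$ed[minus]))
  hi <- min(max(t1$ed[plus]), max(t1$ed[minus]))
  if (lo >= hi) stop("empty ED overlap between SC+ and SC-", call. = FALSE)
  in_range <- t1$ed >= lo & t1$ed <= hi
  br <- unique(quantile(t1$ed[in_range], probs = seq(0, 1,
                                                     length.out = n_bins + 1)))
  bin_of <- cut(t1$ed, breaks = br, include.lowest = TRUE)
  bins <- list()
  for (b in levels(bin_of)) {
    ip <- plus[which(bin_of[plus] == b)]
    im <- minus[which(bin_of[minus] == b)]
    if (!length(ip) || !length(im)) next   # bin has only one class: dropped
    bins[[b]] <- list(plus = ip, minus = im, m = min(length(ip), length(im)))
  }
  if (!length(bins)) stop("no ED bin contains both classes", call. = FALSE)
  n_sub <- length(tables)
  mean_plus <- numeric(n_sub)
  mean_minus <- numeric(n_sub)
  withr::with_seed(seed, {
    for (s in seq_len(n_sub)) {
      fcv <- tables[[s]]$fc
      mp <- mm <- 0
      for (r in seq_len(n_resamples)) {
        sel_p <- unlist(lapply(bins, function(b)
          if (length(b$plus) == b$m) b$plus else sample(b$plus, b$m)))
        sel_m <- unlist(lapply(bins, function(b)
          if (length(b$minus) == b$m) b$minus else sample(b$minus, b$m)))
        mp <- mp + mean(fcv[sel_p])
        mm <- mm + mean(fcv[sel_m])
      }
      mean_plus[s] <- mp / n_resamples
      mean_minus[s] <- mm / n_resamples
    }
  })
  diffs <- mean_plus - mean_minus
  if (all(diffs == 0)) {
    p <- 1
    stat <- NA_real_
  } else {
    wt <- wilcox.test(diffs, exact = TRUE)
    p <- wt$p.value
    stat <- unname(wt$statistic)
  }
  structure(list(mean_sc_plus = mean_plus, mean_sc_minus = mean_minus,
                 statistic = stat, p_raw = p,
                 p_bonferroni = min(1, p * n_comparisons),
                 significant = min(1, p * n_comparisons) < alpha,
                 bins = br, n_bins_used = length(bins)),
            class = "matched_comparison")
}
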