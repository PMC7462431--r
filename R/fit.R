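# Fit-versus-filter-weight curves against a reference FC, paired variant
# comparisons, and white-noise controls.

triangle <- function(m) m[upper.tri(m)]

#' Fit of subject FC matrices to a reference FC across filter weights
#'
#' Pearson correlation between the strict upper triangles of each subject's
#' FC and the reference, per filter weight G, stored as Fisher z. Perfect
#' correlations are clipped before the z transform and flagged.
#'
#' @param fcs_by_subject list (by subject) of named lists (by G) of
#'   `fc_matrix` objects or plain matrices.
#' @param reference_fc reference matrix (e.g., group fMRI-FC or a
#'   leakage-free synthetic reference), same N and ROI order.
#' @return object of class `fit_curve`: `curve` (data.frame subject, G, r,
#'   z, clipped) and `best` (per-subject argmax G and max z).
#' @export
fit_curve <- function(fcs_by_subject, reference_fc) {
  ref <- if (inherits(reference_fc, "fc_matrix")) reference_fc$values else
    reference_fc
  ref_tri <- triangle(ref)
  if (sd(ref_tri) == 0) stop("constant reference FC", call. = FALSE)
  rows <- list()
  for (subject in names(fcs_by_subject)) {
    for (Gname in names(fcs_by_subject[[subject]])) {
      m <- fcs_by_subject[[subject]][[Gname]]
      v <- if (inherits(m, "fc_matrix")) m$values else m
      tri <- triangle(v)
      if (sd(tri) == 0) stop("constant FC for subject ", subject,
                             call. = FALSE)
      r <- cor(tri, ref_tri)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject, G = as.numeric(Gname), r = r,
        z = atanh(clip_r(r)), clipped = abs(r) >= 1 - 1e-15,
        stringsAsFactors = FALSE)
    }
  }
  curve <- do.call(rbind, rows)
  curve <- curve[order(curve$subject, curve$G), ]
  best <- do.call(rbind, lapply(split(curve, curve$subject), function(d) {
    i <- which.max(d$z)
    data.frame(subject = d$subject[1], G_best = d$G[i], z_max = d$z[i],
               z_baseline = d$z[d$G == min(d$G)][1],
               stringsAsFactors = FALSE)
  }))
  rownames(best) <- NULL
  structure(list(curve = curve, best = best), class = "fit_curve")
}

#' Paired comparisons of maximum fits across graph variants
#'
#' Per subject, the maximum Fisher-z fit over the G grid is taken for each
#' variant; every variant is tested against the unfiltered (G = 0) baseline
#' and against every other variant with a Wilcoxon signed-rank test on the
#' within-subject differences, Bonferroni-corrected over the total number
#' of comparisons.
#'
#' @param curves named list (by variant) of [fit_curve()] results over the
#'   same subjects.
#' @return data.frame, one row per comparison: label, median difference,
#'   signed-rank statistic, raw and corrected p-values.
#' @export
compare_variants <- function(curves) {
  variants <- names(curves)
  maxz <- sapply(curves, function(fc) {
    setNames(fc$best$z_max, fc$best$subject)
  })
  subjects <- rownames(maxz)
  baseline <- setNames(curves[[1]]$best$z_baseline, curves[[1]]$best$subject)
  baseline <- baseline[subjects]
  comparisons <- c(lapply(variants, function(v) c(v, ".baseline")),
                   utils::combn(variants, 2, simplify = FALSE))
  n_comp <- length(comparisons)
  out <- lapply(comparisons, function(pr) {
    a <- maxz[, pr[1]]
    b <- if (pr[2] == ".baseline") baseline else maxz[, pr[2]]
    d <- a - b
    if (all(d == 0)) {
      p <- 1; stat <- NA_real_
    } else {
      wt <- wilcox.test(d, exact = TRUE)
      p <- wt$p.value; stat <- unname(wt$statistic)
    }
    data.frame(comparison = paste(pr[1], "vs",
                                  sub("^\\.", "", pr[2])),
               median_diff = median(d), statistic = stat, p_raw = p,
               p_bonferroni = min(1, p * n_comp),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' White-Gaussian-noise control analysis
#'
#' Generates variance-matched white-noise surrogates of every epoch, runs
#' them through the identical smoothing + FC pipeline, and reports (a) the
#' fit of the noise FCs to the reference per filter weight and (b) how
#' similar each empirical FC becomes to the best-matching noise FC as G
#' grows (filtering imprints the graph structure on any input, including
#' noise; the question is how much of the empirical fit that explains).
#'
#' @param epochs list (by subject) of lists of [source_epoch()]s (empirical).
#' @param graph a [build_filter_graph()] result.
#' @param G_grid filter weights (must include 0).
#' @param reference_fc reference matrix.
#' @param band,rate envelope-FC parameters.
#' @param seed integer seed for the noise surrogates.
#' @return list with `wgn_fit` (a [fit_curve()] of the noise FCs),
#'   `similarity` (data.frame G, mean over subjects of the maximum
#'   correlation between the subject's empirical FC and any noise FC), and
#'   the FC lists themselves.
#' @export
wgn_control <- function(epochs, graph, G_grid, reference_fc, band,
                        rate = NULL, seed = 1L) {
  subjects <- names(epochs)
  wgn_epochs <- lapply(seq_along(epochs), function(i)
    make_wgn_like(epochs[[i]], seed = seed + i))
  names(wgn_epochs) <- subjects
  fc_all <- function(eps) {
    out <- lapply(eps, function(subj) {
      res <- lapply(G_grid, function(G) {
        sm <- lapply(subj, graph_smooth, graph = graph, G = G)
        envelope_fc(sm, band = band, rate = rate)
      })
      names(res) <- as.character(G_grid)
      res
    })
    out
  }
  wgn_fcs <- fc_all(wgn_epochs)
  emp_fcs <- fc_all(epochs)
  sim <- do.call(rbind, lapply(as.character(G_grid), function(Gname) {
    max_r <- vapply(subjects, function(s) {
      emp <- triangle(emp_fcs[[s]][[Gname]]$values)
      max(vapply(subjects, function(s2)
        cor(emp, triangle(wgn_fcs[[s2]][[Gname]]$values)), numeric(1)))
    }, numeric(1))
    data.frame(G = as.numeric(Gname), mean_max_r = mean(max_r))
  }))
  list(wgn_fit = fit_curve(wgn_fcs, reference_fc), similarity = sim,
       wgn_fcs = wgn_fcs, empirical_fcs = emp_fcs)
}
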