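# Synthetic cohort generator. The premise being emulated: both volume
# conduction (instantaneous, distance-dependent mixing) and structural
# connectivity (genuine coupling along white-matter edges) imprint a
# Euclidean-distance dependence on source-space EEG functional connectivity.
# Every generator is deterministic under its seed.

#' Generate a synthetic two-hemisphere parcellation with lobes
#'
#' Centroids are sampled on two hemispheric shells separated along the x
#' axis (left hemisphere x < 0, right x > 0). Within each hemisphere, ROIs
#' cluster around `n_lobes` lobe directions (mimicking the
#' frontal/temporal/parietal/occipital organization of anatomical
#' parcellations, which gives the distance-driven connectomes built on top
#' of this geometry a realistic modular structure). Rejection sampling
#' keeps centroids at least 8 mm apart; ROI sizes are log-uniform between
#' 100 and 5000 voxels.
#'
#' @param n_rois even number of ROIs, >= 4.
#' @param seed integer seed; output is deterministic given the seed.
#' @param n_lobes number of lobe clusters per hemisphere.
#' @return a [parcellation()].
#' @export
make_parcellation <- function(n_rois = 68, seed = 1L, n_lobes = 4L) {
  if (n_rois %% 2L != 0L) stop("n_rois must be even", call. = FALSE)
  if (n_rois < 4L) stop("n_rois must be >= 4", call. = FALSE)
  half <- n_rois / 2L
  # lobe axes (unit directions before enforcing the hemisphere sign):
  # anterior-superior, posterior-superior, anterior-inferior,
  # posterior-inferior, then interpolated axes if more are asked for
  axes <- rbind(c(0.35, 0.85, 0.40), c(0.35, -0.85, 0.40),
                c(0.35, 0.60, -0.70), c(0.35, -0.60, -0.70),
                c(0.35, 0.00, 0.95), c(0.35, 0.00, -0.95))
  n_lobes <- max(1L, min(n_lobes, nrow(axes)))
  withr::with_seed(seed, {
    # left hemisphere sampled around the lobe axes; right hemisphere is its
    # mirror image with a small jitter, as in real cortices, so that ROI i
    # on the left and ROI i on the right are homotopic partners
    pts <- matrix(NA_real_, 0L, 3L)
    centre <- c(-32, 0, 0)
    lobe <- rep_len(seq_len(n_lobes), half)
    while (nrow(pts) < half) {
      ax <- axes[lobe[nrow(pts) + 1L], ]
      u <- ax + 0.45 * rnorm(3)
      u <- u / sqrt(sum(u^2))
      u[1] <- -max(abs(u[1]), 0.05)
      p <- centre + runif(1, 42, 58) * u
      if (!nrow(pts) || min(sqrt(colSums((t(pts) - p)^2))) >= 8)
        pts <- rbind(pts, p)
    }
    left <- pts
    right <- left %*% diag(c(-1, 1, 1))
    repeat {
      jit <- right + matrix(rnorm(3L * half, 0, 2), half, 3L)
      jit[, 1] <- pmax(jit[, 1], 2)
      dj <- as.matrix(stats::dist(jit))
      if (min(dj[upper.tri(dj)]) >= 8) {
        right <- jit
        break
      }
    }
    sizes <- round(exp(runif(n_rois, log(100), log(5000))))
    parcellation(
      roi_names = c(sprintf("L_roi%02d", seq_len(half)),
                    sprintf("R_roi%02d", seq_len(half))),
      hemisphere = rep(c("L", "R"), each = half),
      centroid = rbind(left, right),
      roi_size = sizes)
  })
}

#' Generate subject structural connectomes
#'
#' Edge presence probability decays exponentially with Euclidean distance
#' and is multiplied by `inter_penalty` for interhemispheric pairs, so that
#' interhemispheric connectivity is systematically sparser, as in
#' tractography-derived connectomes. A Gaussian-copula construction shares a
#' group-level edge propensity across subjects (`noise` mixes in the
#' subject-specific component), so edges recur across subjects the way real
#' fiber bundles do; `noise = 0` collapses the cohort onto identical
#' subjects. Present edges carry integer fiber counts that decrease with
#' distance, with log-normal subject-level dispersion.
#'
#' @param parc a [parcellation()].
#' @param n_subjects number of subjects.
#' @param decay_mm length scale of the distance decay, mm.
#' @param inter_penalty multiplicative presence penalty for interhemispheric
#'   pairs, in (0, 1].
#' @param noise subject-level dispersion (0 = identical subjects).
#' @param target_intra_density expected single-subject intrahemispheric
#'   connection density; the presence probabilities are scaled to hit it.
#' @param homotopic_presence presence probability for homotopic pairs
#'   (ROI i left with ROI i right), emulating the preferential callosal
#'   connectivity of mirror regions; counted inside the interhemispheric
#'   density budget.
#' @param homotopic_fibers fiber-count multiplier for homotopic edges:
#'   callosal homotopic bundles are far stronger than their Euclidean
#'   length alone would suggest.
#' @param max_fibers fiber count scale at zero distance.
#' @param seed integer seed.
#' @return list of N x N symmetric integer matrices, zero diagonal.
#' @export
make_subject_scs <- function(parc, n_subjects = 18, decay_mm = 45,
                             inter_penalty = 0.3, noise = 0.5,
                             target_intra_density = 0.39,
                             homotopic_presence = 0.75,
                             homotopic_fibers = 8, max_fibers = 200,
                             seed = 1L) {
  if (decay_mm <= 0) stop("decay_mm must be positive", call. = FALSE)
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  stopifnot(inter_penalty > 0, inter_penalty <= 1)
  ed <- roi_distances(parc)
  n <- nrow(ed)
  intra <- outer(parc$hemisphere, parc$hemisphere, "==")
  ut <- upper.tri(ed)
  base <- exp(-ed / decay_mm)
  # scale presence probabilities per class so that the expected single-
  # subject densities are target_intra_density (intra) and inter_penalty
  # times that (inter); the exponential decay shapes the ED dependence
  # within each class. Homotopic pairs (ROI i left / ROI i right, mirror
  # positions by construction of the parcellation) get a presence floor
  # drawn from the interhemispheric budget.
  half <- sum(parc$hemisphere == "L")
  hom <- matrix(FALSE, n, n)
  if (half >= 1 && 2 * half == n)
    hom[cbind(seq_len(half), seq_len(half) + half)] <- TRUE
  hom <- hom | t(hom)
  a_intra <- target_intra_density / mean(base[ut & intra])
  n_inter <- sum(ut & !intra)
  target_inter_edges <- inter_penalty * target_intra_density * n_inter
  n_hom <- sum(ut & hom)
  a_inter <- max(0, target_inter_edges - n_hom * homotopic_presence) /
    sum(base[ut & !intra & !hom])
  p <- pmin(a_intra * base, 0.98)
  p[!intra] <- pmin(a_inter * base[!intra], 0.98)
  p[hom] <- pmax(p[hom], homotopic_presence)
  w_mix <- min(noise, 1)
  withr::with_seed(seed, {
    z_group <- matrix(0, n, n)
    z_group[ut] <- rnorm(sum(ut))
    thr <- qnorm(p)
    lapply(seq_len(n_subjects), function(s) {
      e <- matrix(0, n, n)
      e[ut] <- rnorm(sum(ut))
      latent <- sqrt(1 - w_mix) * z_group + sqrt(w_mix) * e
      present <- ut & (latent < thr)
      mu <- 1 + (max_fibers - 1) * base
      mu[hom] <- mu[hom] * homotopic_fibers
      disp <- matrix(0, n, n)
      disp[ut] <- rnorm(sum(ut))
      w <- matrix(0, n, n)
      w[present] <- pmax(1, round(mu[present] *
                                    exp(noise * disp[present] - noise^2 / 2)))
      w <- w + t(w)
      dimnames(w) <- dimnames(ed)
      w
    })
  })
}

row_normalize <- function(m) {
  s <- rowSums(m)
  s[s == 0] <- 1
  m / s
}

#' Generate SC-coupled, leakage-contaminated band-limited sources
#'
#' Latent per-ROI signals are white noise zero-phase band-pass filtered to
#' the target band and amplitude-modulated by an independent slow (< 0.5 Hz)
#' positive envelope, so that envelope correlation is a meaningful coupling
#' target. Genuine coupling is created by instantaneous linear mixing along
#' the row-normalized SC (weight `coupling`); volume-conduction leakage is
#' emulated by a second instantaneous mixing step with a row-normalized
#' kernel `exp(-ED / leakage_mm)`. The leakage-free ground truth
#' (`genuine_fc`) is the envelope correlation of the pre-leakage signals,
#' computed with the same code path as [envelope_fc()].
#'
#' Additive per-ROI measurement noise (`snr` = per-ROI signal-to-noise
#' amplitude ratio, with a moderate random spread across ROIs so that
#' relative regional variance is informative) emulates the unequal noise
#' load of source-reconstructed EEG; `snr = Inf` disables it.
#'
#' @param truth_sc N x N nonnegative symmetric SC matrix driving genuine
#'   coupling.
#' @param parc a [parcellation()].
#' @param band `c(low, high)` in Hz.
#' @param coupling genuine-coupling strength, >= 0.
#' @param leakage_mm leakage length scale in mm; 0 disables leakage.
#' @param snr per-ROI signal-to-noise amplitude ratio; `Inf` = noiseless.
#' @param duration_s vector of interval durations in seconds (each >= 19).
#' @param rate sampling rate in Hz, must be >= 4 * band high edge.
#' @param subject subject identifier attached to the epochs.
#' @param seed integer seed.
#' @return list with `epochs` (leakage-contaminated, noisy
#'   [source_epoch()]s) and `truth`, a `synthetic_truth` holding
#'   `genuine_fc`, `leakage_kernel`, `subject_scs`, `genuine_epochs` and
#'   the seed.
#' @export
make_sources <- function(truth_sc, parc, band = c(8, 13), coupling = 1.2,
                         leakage_mm = 15, snr = 1, duration_s = 60,
                         rate = 250, subject = "sub01", seed = 1L) {
  if (rate < 4 * band[2])
    stop("rate must be >= 4x the band's high edge", call. = FALSE)
  if (any(duration_s < 19))
    stop("intervals must be at least 19 s", call. = FALSE)
  n <- nrow(truth_sc)
  ed <- roi_distances(parc)
  mix_sc <- diag(n) + coupling * row_normalize(truth_sc)
  kernel <- if (leakage_mm > 0) row_normalize(exp(-ed / leakage_mm)) else
    diag(n)
  dimnames(kernel) <- dimnames(ed)
  withr::with_seed(seed, {
    genuine <- lapply(seq_along(duration_s), function(k) {
      T_ <- round(duration_s[k] * rate)
      carrier <- bandpass(matrix(rnorm(n * T_), n, T_), rate, band)
      carrier <- carrier / apply(carrier, 1L, sd)
      slow <- lowpass(matrix(rnorm(n * T_), n, T_), rate, 0.3)
      slow <- slow / apply(slow, 1L, sd)
      latent <- carrier * exp(0.5 * slow)
      g <- mix_sc %*% latent
      rownames(g) <- parc$name
      source_epoch(g, rate, subject = subject, interval = k, band = "broadband")
    })
    noise_scale <- runif(n, 0.7, 1.3) / snr
    leaked <- lapply(genuine, function(ep) {
      out <- ep
      y <- kernel %*% ep$data
      if (is.finite(snr)) {
        # noise is band-limited like the signal, so snr is the in-band
        # amplitude ratio (what envelope FC actually sees)
        nz <- bandpass(matrix(rnorm(length(y)), nrow(y), ncol(y)), rate,
                       band)
        nz <- nz / apply(nz, 1L, sd)
        y <- y + (noise_scale * apply(y, 1L, sd)) * nz
      }
      out$data <- y
      rownames(out$data) <- parc$name
      out
    })
    genuine_fc <- envelope_fc(genuine, band = band, rate = rate)
    truth <- structure(list(genuine_fc = genuine_fc$values,
                            leakage_kernel = kernel,
                            subject_scs = list(truth_sc),
                            genuine_epochs = genuine,
                            seed = seed),
                       class = "synthetic_truth")
    list(epochs = leaked, truth = truth)
  })
}

#' Variance-matched white Gaussian noise surrogates
#'
#' For every epoch and every channel, returns white Gaussian noise whose
#' variance exactly equals the input channel's variance in that interval.
#' Zero-variance channels are reproduced as constant zeros (with a warning).
#'
#' @param epochs list of [source_epoch()]s.
#' @param seed integer seed.
#' @return list of [source_epoch()]s of the same shapes and rates.
#' @export
make_wgn_like <- function(epochs, seed = 1L) {
  if (!length(epochs)) stop("epochs must be nonempty", call. = FALSE)
  withr::with_seed(seed, {
    lapply(epochs, function(ep) {
      x <- ep$data
      out <- ep
      sds <- apply(x, 1L, sd)
      if (any(sds == 0))
        warning("zero-variance channel reproduced as constant zero",
                call. = FALSE)
      noise <- matrix(rnorm(length(x)), nrow(x), ncol(x))
      # rescale each row to the exact target variance
      noise <- noise - rowMeans(noise)
      nsd <- apply(noise, 1L, sd)
      out$data <- noise / nsd * sds
      dimnames(out$data) <- dimnames(x)
      out
    })
  })
}

#' Generate a complete synthetic study
#'
#' The default cohort mirrors a realistic resting-state source-space EEG
#' study: 68 ROIs, 18 subjects, 2-5 artifact-free intervals each of 20-60 s
#' at 250 Hz, genuine alpha-band coupling along each subject's own SC, and
#' instantaneous distance-dependent leakage. The leakage-free reference FC
#' is the Fisher-z group mean of the per-subject genuine FCs.
#'
#' @param n_rois,n_subjects cohort dimensions.
#' @param band frequency band of the genuine coupling, Hz.
#' @param coupling,leakage_mm,snr see [make_sources()].
#' @param decay_mm,inter_penalty,noise see [make_subject_scs()].
#' @param homotopic_presence,homotopic_fibers see [make_subject_scs()].
#' @param rate sampling rate, Hz.
#' @param seed integer seed; the study is fully reproducible from it.
#' @return object of class `synthetic_study`: parcellation, subject SCs,
#'   per-subject epochs, per-subject truths, reference FC, and parameters.
#' @export
make_cohort <- function(n_rois = 68, n_subjects = 18, band = c(8, 13),
                        coupling = 1.2, leakage_mm = 15, snr = 1,
                        decay_mm = 45, inter_penalty = 0.3, noise = 0.5,
                        homotopic_presence = 0.75, homotopic_fibers = 8,
                        rate = 250, seed = 1L) {
  parc <- make_parcellation(n_rois, seed = seed)
  scs <- make_subject_scs(parc, n_subjects = n_subjects, decay_mm = decay_mm,
                          inter_penalty = inter_penalty, noise = noise,
                          homotopic_presence = homotopic_presence,
                          homotopic_fibers = homotopic_fibers,
                          seed = seed + 1L)
  ids <- sprintf("sub%02d", seq_len(n_subjects))
  names(scs) <- ids
  epochs <- list()
  truths <- list()
  withr::with_seed(seed + 2L, {
    n_int <- sample(2:5, n_subjects, replace = TRUE)
    durs <- lapply(n_int, function(k) round(runif(k, 20, 60)))
  })
  for (s in seq_len(n_subjects)) {
    src <- make_sources(scs[[s]], parc, band = band, coupling = coupling,
                        leakage_mm = leakage_mm, snr = snr,
                        duration_s = durs[[s]], rate = rate,
                        subject = ids[s], seed = seed + 10L + s)
    epochs[[ids[s]]] <- src$epochs
    truths[[ids[s]]] <- src$truth
  }
  reference_fc <- average_fc(lapply(truths, function(tr) tr$genuine_fc))
  structure(list(parcellation = parc, subject_scs = scs, epochs = epochs,
                 truths = truths, reference_fc = reference_fc, band = band,
                 rate = rate,
                 params = list(coupling = coupling, leakage_mm = leakage_mm,
                               snr = snr, decay_mm = decay_mm,
                               inter_penalty = inter_penalty, noise = noise),
                 seed = seed),
            class = "synthetic_study")
}
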