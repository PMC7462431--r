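# Functional connectivity estimation: power-envelope correlation (primary),
# Welch coherence / imaginary coherence (comparison), Fisher z and
# rank-normal transforms.

fc_matrix <- function(values, measure, band = "broadband",
                      transform = "raw") {
  values <- (values + t(values)) / 2   # enforce exact symmetry
  structure(list(values = values, measure = measure, band = band,
                 transform = transform),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> %s (%s, %s), %d ROIs\n", x$measure,
              paste(x$band, collapse = "-"), x$transform, nrow(x$values)))
  invisible(x)
}

#' Drop short intervals, window, and reject artifact windows
#'
#' Intervals shorter than `min_duration_s` are dropped (slow envelope
#' modulations cannot be estimated reliably on shorter stretches). If
#' `window_s` is given, intervals are cut into non-overlapping windows of
#' that length, and windows in which any sample deviates from its channel
#' mean by more than `reject_sd` standard deviations (channel statistics
#' pooled over the subject) are rejected.
#'
#' @param epochs list of [source_epoch()]s for one subject.
#' @param min_duration_s minimum interval duration, s.
#' @param window_s optional window length, s.
#' @param reject_sd rejection threshold in channel standard deviations.
#' @return filtered list of epochs.
#' @export
segment_and_reject <- function(epochs, min_duration_s = 19, window_s = NULL,
                               reject_sd = 6) {
  stopifnot(length(epochs) > 0)
  kept <- Filter(function(ep) ep$duration_s >= min_duration_s, epochs)
  n_dropped <- length(epochs) - length(kept)
  if (is.null(window_s)) {
    if (!length(kept))
      stop("all ", length(epochs), " intervals shorter than ",
           min_duration_s, " s", call. = FALSE)
    return(kept)
  }
  # channel statistics pooled over the subject's retained data
  if (!length(kept))
    stop("all ", length(epochs), " intervals shorter than ",
         min_duration_s, " s", call. = FALSE)
  all_data <- do.call(cbind, lapply(kept, `[[`, "data"))
  mu <- rowMeans(all_data)
  sdv <- apply(all_data, 1L, sd)
  out <- list()
  n_rejected <- 0L
  for (ep in kept) {
    w_len <- round(window_s * ep$rate)
    n_w <- floor(ncol(ep$data) / w_len)
    for (k in seq_len(n_w)) {
      win <- ep$data[, ((k - 1) * w_len + 1):(k * w_len), drop = FALSE]
      if (any(abs(win - mu) > reject_sd * sdv)) {
        n_rejected <- n_rejected + 1L
        next
      }
      out <- c(out, list(source_epoch(win, ep$rate, subject = ep$subject,
                                      interval = length(out) + 1L,
                                      band = ep$band)))
    }
  }
  if (!length(out))
    stop("all windows rejected (", n_dropped, " short intervals, ",
         n_rejected, " rejected windows)", call. = FALSE)
  out
}

#' Power-envelope correlation FC for one subject
#'
#' Per interval: zero-phase band-pass, analytic-signal amplitude, zero-phase
#' low-pass at `envelope_cutoff` (capturing the ultraslow modulations of the
#' band-limited amplitude), then Pearson correlation over time. Per-interval
#' matrices are combined by duration-weighted averaging of their Fisher-z
#' transforms, then transformed back. Diagonal is set to 1.
#'
#' @param epochs list of [source_epoch()]s for one subject.
#' @param band `c(low, high)` in Hz.
#' @param rate sampling rate, Hz (defaults to the epochs' rate).
#' @param envelope_cutoff envelope low-pass cutoff, Hz.
#' @param min_duration_s minimum interval duration, s.
#' @return an `fc_matrix` with measure `"envelope_corr"`.
#' @export
envelope_fc <- function(epochs, band, rate = NULL, envelope_cutoff = 0.5,
                        min_duration_s = 19) {
  epochs <- Filter(function(ep) ep$duration_s >= min_duration_s, epochs)
  if (!length(epochs)) stop("no interval of sufficient duration",
                            call. = FALSE)
  zs <- list()
  durs <- numeric(0)
  for (ep in epochs) {
    r <- if (is.null(rate)) ep$rate else rate
    if (r < 2 * band[2]) stop("rate below Nyquist for band", call. = FALSE)
    env <- lowpass(envelope(bandpass(ep$data, r, band)), r, envelope_cutoff)
    cc <- safe_cor(t(env))
    zs <- c(zs, list(atanh(clip_r(cc))))
    durs <- c(durs, ep$duration_s)
  }
  z <- Reduce(`+`, Map(`*`, zs, durs)) / sum(durs)
  vals <- tanh(z)
  diag(vals) <- 1
  dimnames(vals) <- list(rownames(epochs[[1]]$data),
                         rownames(epochs[[1]]$data))
  fc_matrix(vals, "envelope_corr", band = band)
}

safe_cor <- function(x) {
  sds <- apply(x, 2L, sd)
  cc <- suppressWarnings(cor(x))
  if (any(sds == 0)) {
    warning("constant envelope channel: correlation set to 0", call. = FALSE)
    cc[is.na(cc)] <- 0
    diag(cc) <- 1
  }
  cc
}

clip_r <- function(r, eps = 1e-15) pmin(pmax(r, -(1 - eps)), 1 - eps)

#' Welch coherence / imaginary coherence FC for one subject
#'
#' Each (short) epoch is split into `n_windows` Welch segments with the
#' given overlap and a Hann taper; cross-spectra are averaged over segments;
#' coherence is `|Sxy| / sqrt(Sxx Syy)` and imaginary coherence the
#' imaginary part of the coherency, both averaged over the band's frequency
#' bins and then over epochs.
#'
#' @param epochs list of [source_epoch()]s (typically ~3 s windows).
#' @param band `c(low, high)` in Hz.
#' @param measure `"coherence"` or `"icoherence"`.
#' @param n_windows number of Welch segments per epoch.
#' @param overlap fractional segment overlap.
#' @return an `fc_matrix`.
#' @export
spectral_fc <- function(epochs, band, measure = c("coherence", "icoherence"),
                        n_windows = 5, overlap = 0.5) {
  measure <- match.arg(measure)
  acc <- NULL
  for (ep in epochs) {
    T_ <- ncol(ep$data)
    seg_len <- floor(T_ / (1 + (n_windows - 1) * (1 - overlap)))
    if (seg_len < 8)
      stop("window too short: need at least ",
           ceiling(8 * (1 + (n_windows - 1) * (1 - overlap))),
           " samples for ", n_windows, " Welch segments", call. = FALSE)
    step <- floor(seg_len * (1 - overlap))
    starts <- seq(1L, T_ - seg_len + 1L, by = step)[seq_len(n_windows)]
    taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
    freqs <- (seq_len(seg_len) - 1) / seg_len * ep$rate
    bins <- which(freqs >= band[1] & freqs <= band[2])
    if (!length(bins)) stop("no frequency bin falls in the band",
                            call. = FALSE)
    n <- nrow(ep$data)
    sxx <- array(0 + 0i, dim = c(n, n, length(bins)))
    for (s0 in starts) {
      seg <- ep$data[, s0:(s0 + seg_len - 1L), drop = FALSE]
      seg <- seg - rowMeans(seg)
      F_ <- t(apply(seg * rep(taper, each = n), 1L, fft))
      for (bi in seq_along(bins)) {
        f <- F_[, bins[bi]]
        sxx[, , bi] <- sxx[, , bi] + f %*% Conj(t(f))
      }
    }
    per_bin <- apply(sxx, 3L, function(S) {
      p <- Re(diag(S))
      cy <- S / sqrt(p %o% p)
      if (measure == "coherence") Mod(cy) else Im(cy)
    })
    m <- matrix(rowMeans(per_bin), n, n)
    acc <- if (is.null(acc)) m / length(epochs) else acc + m / length(epochs)
  }
  dimnames(acc) <- dimnames(epochs[[1]]$data)[c(1, 1)]
  diag(acc) <- if (measure == "coherence") 1 else 0
  # imaginary coherency is antisymmetric; mirror the upper triangle so the
  # stored matrix is symmetric with the sign convention of i < j
  acc[lower.tri(acc)] <- t(acc)[lower.tri(acc)]
  fc_matrix(acc, measure, band = band)
}

#' Fisher z transform of a correlation-type FC matrix
#'
#' Elementwise `atanh`; values at +-1 are clipped to +-(1 - 1e-15) first.
#'
#' @param fc an `fc_matrix` (or plain matrix).
#' @return transformed `fc_matrix` (transform `"fisher_z"`).
#' @export
fisher_z <- function(fc) {
  v <- if (inherits(fc, "fc_matrix")) fc$values else fc
  z <- atanh(clip_r(v))
  if (inherits(fc, "fc_matrix"))
    fc_matrix(z, fc$measure, fc$band, transform = "fisher_z")
  else z
}

#' Rank-normal (inverse-normal) transform of an FC matrix
#'
#' Replaces the off-diagonal entries by the standard-normal quantiles of
#' their ranks, `qnorm((rank - 0.5) / M)` with average ranks for ties,
#' applied symmetrically; the diagonal is untouched. Used to make average
#' FC matrices comparable before community analysis.
#'
#' @param fc an `fc_matrix` (or plain matrix).
#' @return transformed `fc_matrix` (transform `"rank_normal"`).
#' @export
rank_normal <- function(fc) {
  v <- if (inherits(fc, "fc_matrix")) fc$values else fc
  ut <- upper.tri(v)
  vals <- v[ut]
  rk <- rank(vals, ties.method = "average")
  q <- qnorm((rk - 0.5) / length(vals))
  out <- v
  out[ut] <- q
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  if (inherits(fc, "fc_matrix"))
    fc_matrix2 <- fc_matrix(out, fc$measure, fc$band,
                            transform = "rank_normal")
  else return(out)
  # fc_matrix() re-symmetrizes; restore untouched diagonal
  diag(fc_matrix2$values) <- diag(v)
  fc_matrix2
}

#' Fisher-z group average of FC matrices
#' @param fcs list of `fc_matrix` objects or plain matrices.
#' @param fisher average in Fisher-z space (default) or raw space.
#' @return plain symmetric matrix, unit diagonal.
#' @export
average_fc <- function(fcs, fisher = TRUE) {
  mats <- lapply(fcs, function(f) if (inherits(f, "fc_matrix")) f$values
                 else f)
  if (fisher) {
    z <- Reduce(`+`, lapply(mats, function(m) atanh(clip_r(m)))) /
      length(mats)
    out <- tanh(z)
  } else {
    out <- Reduce(`+`, mats) / length(mats)
  }
  diag(out) <- 1
  out
}

#' Envelope FC across a grid of filter weights for a whole study
#'
#' Equivalent to smoothing every epoch at every G and calling
#' [envelope_fc()], but exploits that the spatial operator commutes with
#' the (linear) band-pass, so each epoch is band-passed once.
#'
#' @param epochs list (by subject) of lists of [source_epoch()]s.
#' @param graph a [build_filter_graph()] result (or plain matrix).
#' @param G_grid vector of nonnegative filter weights.
#' @param band `c(low, high)` in Hz.
#' @param rate sampling rate override, Hz.
#' @param envelope_cutoff envelope low-pass cutoff, Hz.
#' @param min_duration_s minimum interval duration, s.
#' @return list (by subject) of named lists (by G) of `fc_matrix` objects.
#' @export
study_fc_grid <- function(epochs, graph, G_grid, band, rate = NULL,
                          envelope_cutoff = 0.5, min_duration_s = 19) {
  C <- if (inherits(graph, "filter_graph")) graph$weights else graph
  lapply(epochs, function(subj) {
    subj <- Filter(function(ep) ep$duration_s >= min_duration_s, subj)
    if (!length(subj)) stop("no interval of sufficient duration",
                            call. = FALSE)
    r <- if (is.null(rate)) subj[[1]]$rate else rate
    bp <- lapply(subj, function(ep) bandpass(ep$data, r, band))
    durs <- vapply(subj, `[[`, numeric(1), "duration_s")
    res <- lapply(G_grid, function(G) {
      zs <- lapply(bp, function(xb) {
        xf <- if (G == 0) xb else xb + G * (C %*% xb)
        env <- lowpass(envelope(xf), r, envelope_cutoff)
        atanh(clip_r(safe_cor(t(env))))
      })
      z <- Reduce(`+`, Map(`*`, zs, durs)) / sum(durs)
      vals <- tanh(z)
      diag(vals) <- 1
      dimnames(vals) <- dimnames(C)
      fc_matrix(vals, "envelope_corr", band = band)
    })
    names(res) <- as.character(G_grid)
    res
  })
}
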