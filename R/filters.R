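# Temporal filtering primitives shared by the FC and synthetic modules.
# All filters are zero-phase Hamming-windowed FIR (linear-phase symmetric
# kernels applied with exact group-delay compensation, reflection-padded at
# the edges), with order ~3x the rate over the low cutoff -- the standard
# convention for EEG band-pass filtering. Filtering is done by FFT
# convolution on all channels at once.

fir_order <- function(rate, low_edge, n_samples) {
  order <- ceiling(3 * rate / low_edge)
  if (order %% 2L == 1L) order <- order + 1L
  max_order <- floor((n_samples - 2L) / 3L)
  max_order <- max_order - max_order %% 2L
  # low cutoffs ask for kernels longer than the data; cap at a third of
  # the signal so the reflection padding stays valid
  if (order > max_order) order <- max(4L, max_order)
  order
}

# apply a symmetric odd-length FIR kernel to each row of x, zero-phase
fir_apply <- function(x, b) {
  b <- as.numeric(b)
  n_taps <- length(b)
  half <- (n_taps - 1L) %/% 2L
  T_ <- ncol(x)
  stopifnot(half < T_)
  # reflection padding on both ends
  left <- x[, half:1, drop = FALSE]
  right <- x[, T_:(T_ - half + 1L), drop = FALSE]
  xp <- cbind(left, x, right)
  Lp <- ncol(xp)
  nfft <- stats::nextn(Lp + n_taps - 1L, 2)
  B <- fft(c(b, numeric(nfft - n_taps)))
  X <- stats::mvfft(t(cbind(xp, matrix(0, nrow(x), nfft - Lp))))
  y <- Re(stats::mvfft(X * B, inverse = TRUE)) / nfft
  # convolution index t + half aligns output with input; padding adds half
  out <- t(y)[, (2L * half + 1L):(2L * half + T_), drop = FALSE]
  dimnames(out) <- dimnames(x)
  out
}

#' Zero-phase band-pass filtering of a multichannel matrix
#'
#' @param x N x T matrix, one row per channel.
#' @param rate sampling rate, Hz.
#' @param band `c(low, high)` in Hz.
#' @return filtered matrix, same shape.
#' @export
bandpass <- function(x, rate, band) {
  stopifnot(band[1] > 0, band[1] < band[2], band[2] < rate / 2)
  order <- fir_order(rate, band[1], ncol(x))
  b <- signal::fir1(order, band / (rate / 2), type = "pass")
  fir_apply(x, b)
}

#' Zero-phase low-pass filtering of a multichannel matrix
#'
#' @param x N x T matrix, one row per channel.
#' @param rate sampling rate, Hz.
#' @param cutoff cutoff frequency, Hz.
#' @return filtered matrix, same shape.
#' @export
lowpass <- function(x, rate, cutoff) {
  order <- fir_order(rate, cutoff, ncol(x))
  b <- signal::fir1(order, cutoff / (rate / 2), type = "low")
  fir_apply(x, b)
}

#' Analytic-signal amplitude envelope (per row)
#'
#' FFT-based Hilbert transform; returns the magnitude of the analytic
#' signal.
#'
#' @param x N x T matrix.
#' @return matrix of envelopes, same shape.
#' @export
envelope <- function(x) {
  n <- ncol(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- stats::mvfft(t(x)) * h
  out <- t(Mod(stats::mvfft(X, inverse = TRUE) / n))
  dimnames(out) <- dimnames(x)
  out
}

#' Resample epochs to a working rate
#'
#' Polyphase resampling with anti-alias filtering (via [signal::resample()])
#' of every channel, typically down to the 250 Hz working rate used for
#' band-limited FC so that the band of interest is not far below the
#' sampling rate.
#'
#' @param epochs list of [source_epoch()]s.
#' @param to_rate target sampling rate, Hz.
#' @return list of resampled [source_epoch()]s.
#' @export
resample_epochs <- function(epochs, to_rate) {
  lapply(epochs, function(ep) {
    if (ep$rate == to_rate) return(ep)
    g <- rate_gcd(to_rate, ep$rate)
    p <- to_rate / g
    q <- ep$rate / g
    data <- t(apply(ep$data, 1L, function(row)
      as.numeric(signal::resample(row, p, q))))
    rownames(data) <- rownames(ep$data)
    source_epoch(data, to_rate, subject = ep$subject,
                 interval = ep$interval, band = ep$band)
  })
}

rate_gcd <- function(a, b) {
  while (b > 1e-9) {
    tmp <- a %% b
    a <- b
    b <- tmp
  }
  a
}
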