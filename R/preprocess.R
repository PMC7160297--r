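#' Band-pass filter specification
#'
#' Zero-phase Butterworth-magnitude band-pass. The filter is applied in the
#' frequency domain as the squared magnitude response of an order-`order`
#' Butterworth band-pass prototype (the response a forward-backward IIR pass
#' would have), which is exactly zero-phase and so preserves ERP latencies.
#' Because the net amplitude response of a forward-backward pass is the
#' squared magnitude, low prototype orders sag near the band edges; the
#' default order 10 keeps the net passband ripple below 1 dB across
#' 2-18 Hz while attenuating 0.25 Hz drift and 40 Hz line-harmonic
#' activity by far more than 20 dB.
#'
#' @param band length-2 Hz interval, default `c(1, 20)`.
#' @param order Butterworth prototype order per pass.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(band = c(1, 20), order = 10L) {
  assert_that(length(band) == 2 && band[1] > 0 && band[1] < band[2],
              "`band` must be an increasing positive Hz interval")
  assert_count(order, "order")
  structure(list(band = as.numeric(band), order = as.integer(order)),
            class = "filter_spec")
}

# |H(f)|^2 of an order-n Butterworth band-pass (net gain of one
# forward-backward pass), evaluated at frequencies f (Hz).
butter_bp_gain <- function(f, band, order) {
  f0sq <- band[1] * band[2]
  bw <- band[2] - band[1]
  g <- numeric(length(f))
  nz <- f > 0
  w <- (f[nz]^2 - f0sq) / (f[nz] * bw)
  g[nz] <- 1 / (1 + w^(2 * order))
  g             # DC gain is exactly 0
}

#' Zero-phase band-pass filter an epoch set
#'
#' Applies the squared-magnitude Butterworth band-pass response in the
#' frequency domain with reflection padding (half the epoch length on each
#' side) to suppress circular edge effects.
#'
#' @param epochs an [epoch_set()].
#' @param spec a [filter_spec()].
#' @return the filtered [epoch_set()].
#' @export
bandpass <- function(epochs, spec = filter_spec()) {
  stopifnot(inherits(epochs, "epoch_set"))
  nyq <- epochs$sfreq / 2
  assert_that(spec$band[2] < nyq, "band must lie below the Nyquist frequency")
  d <- epochs$data
  n <- dim(d)[3]
  pad <- floor(n / 2)
  n_ext <- n + 2L * pad
  freqs <- epochs$sfreq * (0:(n_ext - 1)) / n_ext
  freqs <- pmin(freqs, epochs$sfreq - freqs)     # two-sided axis
  gain <- butter_bp_gain(freqs, spec$band, spec$order)
  left <- pad:1
  right <- n:(n - pad + 1L)
  for (i in seq_len(dim(d)[1])) {
    for (ch in seq_len(dim(d)[2])) {
      x <- d[i, ch, ]
      xe <- c(x[left], x, x[right])               # reflection padding
      y <- Re(stats::fft(stats::fft(xe) * gain, inverse = TRUE)) / n_ext
      d[i, ch, ] <- y[(pad + 1L):(pad + n)]
    }
  }
  epochs$data <- d
  epochs
}

#' Baseline specification
#'
#' @param window length-2 ms interval (closed), default `c(-200, 0)`.
#' @return an object of class `baseline_spec`.
#' @export
baseline_spec <- function(window = c(-200, 0)) {
  assert_that(length(window) == 2 && window[1] <= window[2],
              "`window` must be an increasing ms interval")
  structure(list(window = as.numeric(window)), class = "baseline_spec")
}

#' Subtract the pre-stimulus baseline mean from each epoch
#'
#' For every epoch and channel, the mean voltage over the baseline window is
#' subtracted from the whole waveform, eliminating any voltage offset.
#'
#' @param epochs an [epoch_set()].
#' @param spec a [baseline_spec()].
#' @return the corrected [epoch_set()].
#' @export
baseline_correct <- function(epochs, spec = baseline_spec()) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- which(epochs$time_ms >= spec$window[1] & epochs$time_ms <= spec$window[2])
  assert_that(length(idx) > 0, "baseline window is outside the epoch")
  d <- epochs$data
  base <- apply(d[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- d - array(base, dim = dim(d))    # broadcast over samples
  epochs
}
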