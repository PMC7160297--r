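#' Time-frequency decomposition parameters
#'
#' Parameters of the single-trial Morlet-wavelet event-related spectral
#' perturbation (ERSP): 22 logarithmically spaced frequencies spanning
#' 3-20 Hz, a wavelet cycle count rising linearly over the frequency-bin
#' index from 1 cycle at the lowest frequency to 10 at the highest, and 20
#' equal-width time bins covering `[0, 800)` ms after stimulus onset. Power
#' is expressed in dB re 1 uV^2 and floored.
#'
#' @param f_min,f_max frequency range, Hz.
#' @param n_freqs number of frequency bins.
#' @param cycles_min,cycles_max wavelet cycles at the lowest / highest bin.
#' @param t_window ms analysis window (half-open).
#' @param n_times number of time bins.
#' @param power_floor dB floor applied to all cells (keeps values finite).
#' @return an object of class `ersp_params`.
#' @export
ersp_params <- function(f_min = 3, f_max = 20, n_freqs = 22L,
                        cycles_min = 1, cycles_max = 10,
                        t_window = c(0, 800), n_times = 20L,
                        power_floor = -100) {
  assert_that(f_min > 0 && f_min < f_max, "`f_min` must be positive and < f_max")
  assert_count(n_freqs, "n_freqs", min = 2L)
  assert_that(cycles_min > 0 && cycles_min <= cycles_max,
              "cycle counts must be positive and non-decreasing")
  assert_count(n_times, "n_times")
  assert_that(length(t_window) == 2 && t_window[1] < t_window[2],
              "`t_window` must be an increasing ms interval")
  structure(list(f_min = f_min, f_max = f_max, n_freqs = as.integer(n_freqs),
                 cycles_min = cycles_min, cycles_max = cycles_max,
                 t_window = as.numeric(t_window), n_times = as.integer(n_times),
                 power_floor = power_floor),
            class = "ersp_params")
}

#' Logarithmically spaced analysis frequencies
#'
#' Geometric progression from `f_min` to `f_max` inclusive: consecutive
#' ratios are constant at `(f_max/f_min)^(1/(n_freqs-1))`.
#'
#' @param params an [ersp_params()].
#' @return numeric vector of length `n_freqs`, Hz.
#' @export
#' @examples
#' f <- log_spaced_freqs(ersp_params())
#' range(f); length(f)
log_spaced_freqs <- function(params = ersp_params()) {
  exp(seq(log(params$f_min), log(params$f_max), length.out = params$n_freqs))
}

#' Wavelet cycle counts per frequency bin
#'
#' Linear interpolation over the frequency-bin index from `cycles_min` at
#' bin 1 to `cycles_max` at the last bin (the `[c_min c_max]` convention of
#' standard time-frequency toolboxes).
#'
#' @param freqs frequency vector (only its length is used).
#' @param params an [ersp_params()].
#' @return numeric vector of cycle counts.
#' @export
cycles_for_freqs <- function(freqs, params = ersp_params()) {
  assert_that(length(freqs) >= 1, "`freqs` must be non-empty")
  n <- length(freqs)
  if (n == 1) return(params$cycles_min)
  params$cycles_min + (params$cycles_max - params$cycles_min) *
    (seq_len(n) - 1) / (n - 1)
}

# Complex Morlet wavelet at frequency f with the given cycle count,
# sampled at sfreq. Normalized to unit gain on a real sinusoid of
# amplitude 1 at its centre frequency (so power is in uV^2 for uV input).
morlet_wavelet <- function(f, cycles, sfreq) {
  sigma_t <- cycles / (2 * pi * f)
  half <- max(3L, ceiling(3.5 * sigma_t * sfreq))
  t <- (-half:half) / sfreq
  env <- exp(-t^2 / (2 * sigma_t^2))
  w <- env * exp(2i * pi * f * t)
  w * (2 / sum(env))
}

# FFT-based full convolution of each row of x (channels x samples) with
# complex kernel w, returning the "same"-aligned complex result.
convolve_rows_fft <- function(x, w) {
  n <- ncol(x)
  m <- length(w)
  nfft <- stats::nextn(n + m - 1L, 2)
  wf <- stats::fft(c(w, complex(real = rep(0, nfft - m))))
  half <- (m - 1L) %/% 2L
  out <- matrix(0i, nrow(x), n)
  for (ch in seq_len(nrow(x))) {
    xf <- stats::fft(c(x[ch, ], rep(0, nfft - n)))
    full <- stats::fft(xf * wf, inverse = TRUE) / nfft
    out[ch, ] <- full[(half + 1L):(half + n)]
  }
  out
}

#' Single-trial wavelet spectrogram stack
#'
#' Convolves one trial's 7-channel epoch with complex Morlet wavelets at
#' each analysis frequency, averages squared magnitude within each of the
#' `n_times` equal-width time bins spanning the analysis window, converts to
#' dB (`10*log10`), and floors at `power_floor`. The full `[-200, 800)` ms
#' epoch supports the convolution; where a wavelet overruns the epoch edge
#' the signal is treated as zero (linear convolution), which keeps edge
#' truncation leakage symmetric in frequency.
#'
#' @param epoch numeric matrix `[channels x samples]`, or an [epoch_set()]
#'   with a single trial.
#' @param params an [ersp_params()].
#' @param time_ms epoch time axis (defaults to the canonical axis).
#' @param direct use the brute-force time-domain convolution instead of the
#'   FFT path (the independent oracle; identical values expected).
#' @return an object of class `spectrogram_frame`: list with `power`
#'   (`[n_freqs x n_times x channels]`, dB), `freqs`, `time_centres`.
#' @export
single_trial_ersp <- function(epoch, params = ersp_params(),
                              time_ms = epoch_time_ms(), direct = FALSE) {
  if (inherits(epoch, "epoch_set")) {
    assert_that(dim(epoch$data)[1] == 1L, "epoch_set must contain one trial")
    time_ms <- epoch$time_ms
    epoch <- matrix(epoch$data[1, , ], nrow = dim(epoch$data)[2])
  }
  assert_that(is.matrix(epoch), "`epoch` must be a channels x samples matrix")
  sfreq <- 1000 / (time_ms[2] - time_ms[1])
  assert_that(time_ms[1] <= params$t_window[1] &&
                max(time_ms) >= params$t_window[2] - 1000 / sfreq,
              "epoch does not cover the analysis window")
  freqs <- log_spaced_freqs(params)
  cycles <- cycles_for_freqs(freqs, params)
  n_ch <- nrow(epoch)
  n <- ncol(epoch)

  # the full [-200, 800) epoch supports the convolution; beyond the epoch
  # the signal is taken as zero (linear convolution), which keeps edge
  # truncation leakage symmetric in frequency
  pad <- 0L
  xp <- epoch

  edges <- seq(params$t_window[1], params$t_window[2],
               length.out = params$n_times + 1L)
  bin_of <- findInterval(time_ms, edges, rightmost.closed = FALSE,
                         left.open = FALSE)
  in_win <- bin_of >= 1 & bin_of <= params$n_times &
    time_ms < params$t_window[2]
  win_pos <- which(in_win)
  groups <- lapply(seq_len(params$n_times),
                   function(b) win_pos[bin_of[win_pos] == b])
  assert_that(all(lengths(groups) > 0), "empty time bin; epoch too short")

  pw <- array(0, dim = c(params$n_freqs, params$n_times, n_ch))
  for (k in seq_along(freqs)) {
    w <- morlet_wavelet(freqs[k], cycles[k], sfreq)
    conv <- if (direct) convolve_rows_direct(xp, w) else convolve_rows_fft(xp, w)
    p <- Mod(conv[, (pad + 1L):(pad + n), drop = FALSE])^2
    for (ch in seq_len(n_ch)) {
      pw[k, , ch] <- vapply(groups, function(ii) mean(p[ch, ii]), 0)
    }
  }
  db <- 10 * log10(pmax(pw, 10^(params$power_floor / 10)))
  db <- pmax(db, params$power_floor)
  structure(list(power = db, freqs = freqs,
                 time_centres = (edges[-1] + edges[-length(edges)]) / 2),
            class = "spectrogram_frame")
}

# Brute-force time-domain convolution (sliding dot products built with
# `embed`, no FFT anywhere): the independent oracle for convolve_rows_fft,
# with identical "same" alignment.
convolve_rows_direct <- function(x, w) {
  n <- ncol(x)
  m <- length(w)
  half <- (m - 1L) %/% 2L
  out <- matrix(0i, nrow(x), n)
  wm <- cbind(Re(w), Im(w))
  for (ch in seq_len(nrow(x))) {
    xi <- c(rep(0, m - 1L), x[ch, ], rep(0, m - 1L))
    # row i of embed() holds xi[i+m-1], ..., xi[i]; its dot product with w
    # is the full linear convolution at lag i
    full <- embed(xi, m) %*% wm
    keep <- (half + 1L):(half + n)
    out[ch, ] <- complex(real = full[keep, 1], imaginary = full[keep, 2])
  }
  out
}

#' Compute spectrogram frames for a whole dataset
#'
#' Applies [single_trial_ersp()] to every trial of every subject, carrying
#' labels and subject ids through.
#'
#' @param epochs_list a list of [epoch_set()] objects (e.g.
#'   `simulate_eeg_dataset()$epochs`).
#' @param params an [ersp_params()].
#' @return an object of class `frame_set`: list with `frames` (array
#'   `[n_frames x n_freqs x n_times x n_channels]`), `subject_id` (character
#'   per frame), `group` (factor per frame), `freqs`, `time_centres`,
#'   `channels`.
#' @export
dataset_ersp <- function(epochs_list, params = ersp_params()) {
  assert_that(length(epochs_list) >= 1, "`epochs_list` must be non-empty")
  chans <- epochs_list[[1]]$channels
  for (es in epochs_list) {
    assert_that(identical(es$channels, chans),
                "channel order mismatch between epoch sets")
  }
  n_frames <- sum(vapply(epochs_list, function(e) dim(e$data)[1], 0L))
  fr <- array(0, dim = c(n_frames, params$n_freqs, params$n_times,
                         length(chans)))
  sid <- character(n_frames)
  grp <- character(n_frames)
  freqs <- NULL; tc <- NULL
  k <- 0L
  for (es in epochs_list) {
    for (i in seq_len(dim(es$data)[1])) {
      sf <- single_trial_ersp(matrix(es$data[i, , ], nrow = length(chans)),
                              params, es$time_ms)
      k <- k + 1L
      fr[k, , , ] <- sf$power
      sid[k] <- es$subject_id
      grp[k] <- as.character(es$group)
      if (is.null(freqs)) { freqs <- sf$freqs; tc <- sf$time_centres }
    }
  }
  structure(list(frames = fr, subject_id = sid,
                 group = factor(grp, levels = c("HC", "ADHD")),
                 freqs = freqs, time_centres = tc, channels = chans),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> %d frames [%d x %d x %d], %d subjects\n",
              dim(x$frames)[1], dim(x$frames)[2], dim(x$frames)[3],
              dim(x$frames)[4], length(unique(x$subject_id))))
  invisible(x)
}

# Subset a frame_set by frame index and/or channel names.
subset_frames <- function(fs, frames = NULL, channels = NULL) {
  idx <- frames %||% seq_len(dim(fs$frames)[1])
  chs <- channels %||% fs$channels
  ci <- match(chs, fs$channels)
  assert_that(!anyNA(ci), "unknown channel in subset")
  fs$frames <- fs$frames[idx, , , ci, drop = FALSE]
  fs$subject_id <- fs$subject_id[idx]
  fs$group <- fs$group[idx]
  fs$channels <- fs$channels[ci]
  fs
}
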