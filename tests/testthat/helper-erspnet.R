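# Shared fixtures, all generated in code at test time.

# Random spectrogram-like arrays with a linear class shift (separable).
toy_frames <- function(n_per_class, shape = c(22L, 20L, 7L), shift = 2,
                       seed = 1) {
  erspnet:::with_seed(seed, {
    n <- 2L * n_per_class
    x <- array(rnorm(n * prod(shape)), c(n, shape))
    x[seq_len(n_per_class), , , ] <- x[seq_len(n_per_class), , , ] + shift
    list(x = x,
         y = factor(rep(c("ADHD", "HC"), each = n_per_class),
                    levels = c("HC", "ADHD")))
  })
}

# Single sinusoidal epoch on the canonical grid.
sine_epoch <- function(freq, amp = 1, n_trials = 1, channels = 7) {
  t <- epoch_time_ms() / 1000
  d <- array(0, dim = c(n_trials, channels, length(t)))
  for (i in seq_len(n_trials)) {
    for (ch in seq_len(channels)) d[i, ch, ] <- amp * sin(2 * pi * freq * t)
  }
  epoch_set(d, subject_id = "S1", group = "HC")
}

# Band power (uV^2) of one epoch_set via the raw periodogram, averaged over
# trials and channels — an independent spectral oracle for the generator.
band_power <- function(es, band) {
  n <- dim(es$data)[3]
  freqs <- es$sfreq * (0:(n - 1)) / n
  sel <- freqs >= band[1] & freqs <= band[2]
  p <- 0
  for (i in seq_len(dim(es$data)[1])) {
    for (ch in seq_len(dim(es$data)[2])) {
      sp <- Mod(stats::fft(es$data[i, ch, ]))^2 / n^2
      p <- p + sum(sp[sel])
    }
  }
  p / (dim(es$data)[1] * dim(es$data)[2])
}

# One tiny end-to-end dataset shared by I/O and pipeline tests (built once).
.tiny_cache <- new.env(parent = emptyenv())
tiny_dataset <- function() {
  if (is.null(.tiny_cache$ds)) {
    cs <- cohort_spec(n_per_group = 2L, frames_per_subject = 6L, seed = 7L)
    es <- effect_spec(alpha_attenuation = -3, theta_boost = 3, seed = 8L)
    ds <- simulate_eeg_dataset(cs, es)
    ds$epochs <- lapply(ds$epochs, function(e) baseline_correct(bandpass(e)))
    .tiny_cache$ds <- ds
    .tiny_cache$frames <- dataset_ersp(ds$epochs)
  }
  list(ds = .tiny_cache$ds, frames = .tiny_cache$frames)
}
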