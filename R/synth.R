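#' Construct an epoch set
#'
#' Container for a subject's epoched multi-channel EEG: a
#' `[trials x channels x samples]` microvolt array on the fixed montage and
#' the canonical time axis (half-open epoch `[-200, 800)` ms sampled at
#' 500 Hz, i.e. 500 samples at the bin left edges -200, -198, ..., 798 ms).
#'
#' @param data 3-D numeric array `[n_trials x 7 x 500]` (or matching the
#'   supplied axes), microvolts.
#' @param time_ms numeric time axis in ms.
#' @param channels channel names (defaults to [eeg_channels()]).
#' @param sfreq sampling frequency, Hz.
#' @param subject_id subject identifier.
#' @param group optional group label carried for convenience.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, time_ms = epoch_time_ms(), channels = eeg_channels(),
                      sfreq = 500, subject_id = NA_character_, group = NA) {
  assert_that(length(dim(data)) == 3L, "`data` must be a 3-D array")
  assert_that(dim(data)[2] == length(channels),
              "channel dimension must match `channels`")
  assert_that(dim(data)[3] == length(time_ms),
              "sample dimension must match `time_ms`")
  structure(list(data = data, time_ms = time_ms, channels = channels,
                 sfreq = sfreq, subject_id = subject_id, group = group),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> subject %s: %d trials x %d channels x %d samples (%g Hz)\n",
              x$subject_id, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$sfreq))
  invisible(x)
}

#' Canonical epoch time axis
#'
#' @param sfreq sampling frequency (Hz).
#' @param t_start,t_end epoch span in ms, half-open `[t_start, t_end)`.
#' @return numeric vector of sample times (bin left edges), ms.
#' @export
epoch_time_ms <- function(sfreq = 500, t_start = -200, t_end = 800) {
  step <- 1000 / sfreq
  seq(t_start, t_end - step, by = step)
}

# Gaussian background noise with a 1/f^a amplitude spectrum, unit RMS.
one_over_f_noise <- function(n, exponent) {
  x <- stats::fft(rnorm(n))
  f <- c(1, seq_len(n - 1))                       # avoid the DC singularity
  f <- pmin(f, n - f + 1)                         # symmetric spectral index
  shape <- f^(-exponent / 2)
  shape[1] <- 0                                   # zero-mean
  y <- Re(stats::fft(x * shape, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

# Render one subject's epochs for the given event onsets.
# Signal model per trial and channel c:
#   gain_c * [ alpha + theta_burst + n100 ] + background_noise
# with group/subject effects applied as amplitude factors 10^(dB/20).
render_epochs <- function(subject, n_epochs, effects, seed,
                          event_locked = TRUE, resting = FALSE) {
  t_ms <- epoch_time_ms()
  t_s <- t_ms / 1000
  n_samp <- length(t_ms)
  n_ch <- 7L
  is_adhd <- identical(as.character(subject$group), "ADHD")

  subj_sd <- if (resting) effects$resting_subject_sd else effects$subject_sd
  subj_factor <- 10^((subject$effect_z * subj_sd) / 20)
  alpha_factor <- subj_factor *
    (if (is_adhd) 10^(effects$alpha_attenuation / 20) else 1)
  theta_factor <- subj_factor *
    (if (is_adhd) 10^(effects$theta_boost / 20) else 1)
  n100_factor <- if (is_adhd) effects$n100_gain else 1

  with_seed(seed, {
    # subject alpha frequency: idiosyncratic, inside the alpha band
    f_alpha <- min(max(rnorm(1, 10, 0.5), effects$alpha_band[1]),
                   effects$alpha_band[2])
    f_theta <- mean(effects$theta_band)
    sigma_theta_s <- (effects$theta_duration / 2.355) / 1000   # FWHM -> sd
    out <- array(0, dim = c(n_epochs, n_ch, n_samp))
    for (i in seq_len(n_epochs)) {
      alpha <- effects$alpha_amp * alpha_factor *
        cos(2 * pi * f_alpha * t_s + runif(1, 0, 2 * pi))
      if (event_locked) {
        env <- exp(-(t_s - effects$theta_latency / 1000)^2 /
                     (2 * sigma_theta_s^2))
        theta <- effects$theta_amp * theta_factor * env *
          cos(2 * pi * f_theta * t_s + runif(1, 0, 2 * pi))
        lat_jit <- rnorm(1, 0, 0.010)             # 10 ms latency jitter
        n100 <- -abs(effects$n100_amp) * n100_factor *
          exp(-(t_s - 0.100 - lat_jit)^2 / (2 * 0.030^2))
        sig <- alpha + theta + n100
      } else {
        sig <- alpha
      }
      for (ch in seq_len(n_ch)) {
        out[i, ch, ] <- effects$channel_gains[ch] * sig +
          effects$noise_rms * one_over_f_noise(n_samp, effects$noise_exponent)
      }
    }
    out
  })
}

#' Synthesize event-locked flanker-task epochs for one subject
#'
#' Renders one epoch per incongruent trial event: 1/f background noise plus
#' a sustained alpha oscillation (attenuated in ADHD), a transient theta
#' burst centred at `theta_latency` (boosted in ADHD), and an N100-like
#' negative deflection near 100 ms (gain `n100_gain` in ADHD), each scaled
#' by the per-channel gains. Deterministic given the effect seed and the
#' subject identity.
#'
#' @param subject one row of [generate_cohort()] (or an equivalent list with
#'   `subject_id`, `group`, `effect_z`).
#' @param events a trial-event `data.frame` from [generate_trial_sequence()];
#'   only incongruent trials are rendered.
#' @param effects an [effect_spec()].
#' @return an [epoch_set()] with one epoch per incongruent event.
#' @export
synthesize_epochs <- function(subject, events, effects = effect_spec()) {
  check_bands(effects)
  inc <- events[events$congruency == "incongruent", , drop = FALSE]
  assert_that(nrow(inc) >= 1, "no incongruent events to render")
  seed <- derive_seed(effects$seed, subject_stream(subject$subject_id))
  data <- render_epochs(subject, nrow(inc), effects, seed,
                        event_locked = TRUE, resting = FALSE)
  epoch_set(data, subject_id = as.character(subject$subject_id),
            group = as.character(subject$group))
}

#' Synthesize eyes-closed resting-state frames for one subject
#'
#' Resting frames carry only the tonic alpha group effect — no event-locked
#' theta burst and no N100 — and a larger between-subject alpha variability
#' (`resting_subject_sd`), reflecting how idiosyncratic eyes-closed alpha
#' dilutes group differences relative to task-locked activity.
#'
#' @param subject one cohort row.
#' @param n_frames number of resting frames to generate.
#' @param effects an [effect_spec()].
#' @return an [epoch_set()].
#' @export
synthesize_resting <- function(subject, n_frames, effects = effect_spec()) {
  check_bands(effects)
  assert_count(n_frames, "n_frames")
  seed <- derive_seed(effects$seed, subject_stream(subject$subject_id) + 7919L)
  data <- render_epochs(subject, n_frames, effects, seed,
                        event_locked = FALSE, resting = TRUE)
  epoch_set(data, subject_id = as.character(subject$subject_id),
            group = as.character(subject$group))
}

check_bands <- function(effects) {
  assert_that(inherits(effects, "effect_spec"), "`effects` must be an effect_spec")
  assert_that(effects$alpha_band[1] >= 1 && effects$alpha_band[2] <= 20 &&
                effects$theta_band[1] >= 1 && effects$theta_band[2] <= 20,
              "effect bands must lie inside the 1-20 Hz filter band")
}

# Stable small-integer stream index from a subject id.
subject_stream <- function(id) {
  sum(utf8ToInt(as.character(id)) * seq_along(utf8ToInt(as.character(id)))) %% 100000L
}

#' Simulate a complete epoched dataset for a cohort
#'
#' For each subject, generates `n_sessions` flanker sessions of
#' `140`-trial sequences (or proportionally fewer for reduced
#' `frames_per_subject`), pools the incongruent trials across sessions, and
#' truncates or tops up to exactly `frames_per_subject` epochs. In resting
#' mode the same number of frames is produced with no event-locked
#' structure.
#'
#' @param cohort_sp a [cohort_spec()].
#' @param effects an [effect_spec()].
#' @param mode `"task"` or `"resting"`.
#' @return a list with `subjects` (the cohort data.frame, with a
#'   reaction-time summary column in task mode) and `epochs` (a list of
#'   [epoch_set()] objects, one per subject).
#' @export
#' @examples
#' ds <- simulate_eeg_dataset(cohort_spec(n_per_group = 1,
#'                                        frames_per_subject = 4))
#' dim(ds$epochs[[1]]$data)
simulate_eeg_dataset <- function(cohort_sp = cohort_spec(),
                                 effects = effect_spec(),
                                 mode = c("task", "resting")) {
  mode <- match.arg(mode)
  subjects <- generate_cohort(cohort_sp)
  n_target <- cohort_sp$frames_per_subject
  # session length scaled so ~n_sessions sessions supply the target count
  trials_per_session <- max(3L, as.integer(ceiling(
    3 * n_target / cohort_sp$n_sessions)))
  epochs <- vector("list", nrow(subjects))
  subjects$mean_rt <- NA_real_
  for (i in seq_len(nrow(subjects))) {
    subj <- subjects[i, ]
    if (mode == "resting") {
      epochs[[i]] <- synthesize_resting(subj, n_target, effects)
      next
    }
    ev_list <- lapply(seq_len(cohort_sp$n_sessions), function(s) {
      generate_trial_sequence(
        trials_per_session,
        seed = derive_seed(cohort_sp$seed, 1000L * i + s))
    })
    ev <- do.call(rbind, ev_list)
    inc <- ev[ev$congruency == "incongruent", , drop = FALSE]
    while (nrow(inc) < n_target) {                 # top up (rare)
      extra <- generate_trial_sequence(
        trials_per_session,
        seed = derive_seed(cohort_sp$seed, 1000L * i + 900L + nrow(inc)))
      inc <- rbind(inc, extra[extra$congruency == "incongruent", ])
    }
    inc <- inc[seq_len(n_target), , drop = FALSE]
    rt <- generate_reaction_times(as.character(subj$group), n_target,
                                  cohort_sp,
                                  seed = derive_seed(cohort_sp$seed, 5000L + i))
    subjects$mean_rt[i] <- mean(rt)
    epochs[[i]] <- synthesize_epochs(subj, inc, effects)
  }
  list(subjects = subjects, epochs = epochs, mode = mode)
}
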