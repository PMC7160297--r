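#' Cohort specification for the synthetic flanker-task study
#'
#' Describes the simulated two-group study: per-group sample size, number of
#' analyzable incongruent frames per subject, number of experimental
#' sessions, the group age distributions, and mean reaction times. Defaults
#' reproduce the reference cohort: 20 ADHD / 20 healthy controls (HC), 140
#' frames per subject over 3 sessions, ages 43.85 (SD 14.78) years for ADHD
#' and 29.90 (SD 10.77) for HC, mean reaction times 368 / 321 ms.
#'
#' @param n_per_group subjects per group (default 20).
#' @param frames_per_subject incongruent frames kept per subject (default 140).
#' @param n_sessions experimental sessions pooled per subject (default 3).
#' @param age_mean_adhd,age_sd_adhd ADHD age distribution, years.
#' @param age_mean_hc,age_sd_hc HC age distribution, years.
#' @param rt_mean_adhd,rt_mean_hc group mean reaction times, ms.
#' @param rt_shape Gamma shape parameter for single-trial reaction times
#'   (mean/shape is the scale); 16 gives a realistic ~25% coefficient of
#'   variation.
#' @param seed integer seed driving all cohort-level randomness.
#' @return an object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n_per_group = 2, frames_per_subject = 10)
#' generate_cohort(spec)
cohort_spec <- function(n_per_group = 20L,
                        frames_per_subject = 140L,
                        n_sessions = 3L,
                        age_mean_adhd = 43.85, age_sd_adhd = 14.78,
                        age_mean_hc = 29.90, age_sd_hc = 10.77,
                        rt_mean_adhd = 368, rt_mean_hc = 321,
                        rt_shape = 16,
                        seed = 1L) {
  assert_count(n_per_group, "n_per_group")
  assert_count(frames_per_subject, "frames_per_subject")
  assert_count(n_sessions, "n_sessions")
  assert_positive(age_sd_adhd, "age_sd_adhd")
  assert_positive(age_sd_hc, "age_sd_hc")
  assert_positive(rt_mean_adhd, "rt_mean_adhd")
  assert_positive(rt_mean_hc, "rt_mean_hc")
  assert_positive(rt_shape, "rt_shape")
  structure(list(
    n_per_group = as.integer(n_per_group),
    frames_per_subject = as.integer(frames_per_subject),
    n_sessions = as.integer(n_sessions),
    age_mean_adhd = age_mean_adhd, age_sd_adhd = age_sd_adhd,
    age_mean_hc = age_mean_hc, age_sd_hc = age_sd_hc,
    rt_mean_adhd = rt_mean_adhd, rt_mean_hc = rt_mean_hc,
    rt_shape = rt_shape,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "cohort_spec")
}

#' Spectral effect specification for the synthetic EEG generator
#'
#' Encodes the class-discriminating structure injected into ADHD epochs
#' relative to HC: a tonic alpha-power attenuation across the whole epoch, a
#' transient delta-theta power boost near 100 ms, and a gain on the N100
#' deflection. Amplitude parameters are in microvolts; group effects are in
#' dB of power (an amplitude factor of `10^(dB/20)`).
#'
#' @param alpha_band Hz interval of the tonic alpha oscillation.
#' @param alpha_attenuation dB of ADHD-minus-HC alpha power (negative:
#'   ADHD alpha is reduced).
#' @param theta_band Hz interval of the event-locked delta-theta burst.
#' @param theta_boost dB of ADHD-minus-HC theta-burst power (positive).
#' @param theta_latency ms centre of the theta burst.
#' @param theta_duration ms full-width-half-maximum of the burst envelope.
#' @param n100_gain multiplier on the N100 deflection for ADHD subjects.
#' @param channel_gains length-7 multipliers applied to all signal
#'   components, in montage order; frontopolar channels default to a low
#'   gain (their signal quality is poor in practice).
#' @param noise_exponent slope of the 1/f^a background spectrum.
#' @param noise_rms microvolt RMS of the background noise.
#' @param alpha_amp,theta_amp,n100_amp HC component amplitudes, microvolts.
#' @param subject_sd dB SD of the between-subject random effect applied to
#'   the oscillatory amplitudes in task recordings.
#' @param resting_subject_sd dB SD of between-subject alpha variability in
#'   eyes-closed rest, where idiosyncratic alpha generators dominate; larger
#'   than `subject_sd` by design, which is what makes resting-state frames
#'   less separable than task frames.
#' @param seed integer seed for the epoch-level randomness.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(alpha_band = c(8, 12),
                        alpha_attenuation = -2,
                        theta_band = c(3, 7),
                        theta_boost = 2,
                        theta_latency = 100,
                        theta_duration = 100,
                        n100_gain = 1.3,
                        channel_gains = c(0.3, 0.3, 1, 1, 1, 1, 1),
                        noise_exponent = 1,
                        noise_rms = 4,
                        alpha_amp = 4,
                        theta_amp = 2.5,
                        n100_amp = 5,
                        subject_sd = 1,
                        resting_subject_sd = 3,
                        seed = 1L) {
  band_ok <- function(b) length(b) == 2 && b[1] < b[2] && b[1] >= 1 && b[2] <= 20
  assert_that(band_ok(alpha_band), "`alpha_band` must lie within [1, 20] Hz")
  assert_that(band_ok(theta_band), "`theta_band` must lie within [1, 20] Hz")
  assert_that(theta_latency >= -200 && theta_latency <= 800,
              "`theta_latency` must lie within the epoch window")
  assert_that(length(channel_gains) == 7L, "`channel_gains` must have length 7")
  assert_positive(theta_duration, "theta_duration")
  assert_that(subject_sd >= 0 && resting_subject_sd >= 0 && noise_rms >= 0,
              "SDs and noise RMS must be non-negative")
  structure(list(
    alpha_band = alpha_band, alpha_attenuation = alpha_attenuation,
    theta_band = theta_band, theta_boost = theta_boost,
    theta_latency = theta_latency, theta_duration = theta_duration,
    n100_gain = n100_gain,
    channel_gains = as.numeric(channel_gains),
    noise_exponent = noise_exponent, noise_rms = noise_rms,
    alpha_amp = alpha_amp, theta_amp = theta_amp, n100_amp = n100_amp,
    subject_sd = subject_sd, resting_subject_sd = resting_subject_sd,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "effect_spec")
}

# Effect spec with all group differences removed (null world). Between-
# subject variability is retained unless zero_subject_sd = TRUE.
#' Null effect specification (no group differences)
#' @param ... overrides passed to [effect_spec()].
#' @return an `effect_spec` with zero group effects.
#' @export
null_effect_spec <- function(...) {
  effect_spec(alpha_attenuation = 0, theta_boost = 0, n100_gain = 1, ...)
}

#' Generate a synthetic two-group cohort
#'
#' Draws `n_per_group` subjects per group with ages from the group-specific
#' normal distributions, truncated at 18 years (adult cohort), plus a
#' standard-normal per-subject effect offset that the epoch generator later
#' scales by its between-subject SD.
#'
#' @param spec a [cohort_spec()].
#' @return a `data.frame` with columns `subject_id`, `group` (factor with
#'   levels `HC`, `ADHD`), `age`, `effect_z`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_per_group
  with_seed(spec$seed, {
    draw_ages <- function(n, mean, sd) {
      ages <- numeric(0)
      while (length(ages) < n) {       # resample below the 18-year truncation
        a <- rnorm(2L * n, mean, sd)
        ages <- c(ages, a[a >= 18])
      }
      ages[seq_len(n)]
    }
    age_adhd <- draw_ages(n, spec$age_mean_adhd, spec$age_sd_adhd)
    age_hc <- draw_ages(n, spec$age_mean_hc, spec$age_sd_hc)
    data.frame(
      subject_id = c(sprintf("ADHD%02d", seq_len(n)),
                     sprintf("HC%02d", seq_len(n))),
      group = factor(rep(c("ADHD", "HC"), each = n), levels = c("HC", "ADHD")),
      age = c(age_adhd, age_hc),
      effect_z = rnorm(2L * n),
      stringsAsFactors = FALSE
    )
  })
}

# Flanker/target stimulus-duration staircase levels (ms), easiest to hardest.
flanker_levels <- function() {
  data.frame(flanker_ms = c(136, 114, 92, 70, 48),
             target_ms = c(62, 52, 42, 32, 22))
}

#' Generate a randomized flanker-task trial sequence
#'
#' Produces a fully random ordering of congruent and incongruent trials at
#' the requested congruent:incongruent ratio (2:1 by default), with
#' per-trial timing sampled from the task's stimulus grid: flanker-alone
#' duration from \{136, 114, 92, 70, 48\} ms paired with target durations
#' \{62, 52, 42, 32, 22\} ms (one difficulty level per sequence, emulating
#' the per-subject staircase), a 500 ms black screen, a 300 ms feedback
#' interval, and a fixation cross of 200, 300 or 400 ms.
#'
#' @param n_trials number of trials (default 140, one session).
#' @param ratio_congruent congruent trials per incongruent trial (default 2).
#'   The incongruent count is `round(n_trials / (ratio_congruent + 1))`.
#' @param seed integer seed.
#' @param level optional difficulty level 1..5; sampled if `NULL`.
#' @return a `data.frame` of trial events with strictly increasing onsets.
#' @export
#' @examples
#' ev <- generate_trial_sequence(140, seed = 1)
#' table(ev$congruency)
generate_trial_sequence <- function(n_trials = 140L, ratio_congruent = 2L,
                                    seed = NULL, level = NULL) {
  assert_count(n_trials, "n_trials")
  assert_count(ratio_congruent, "ratio_congruent")
  with_seed(seed, {
    n_inc <- max(1L, as.integer(round(n_trials / (ratio_congruent + 1))))
    n_inc <- min(n_inc, n_trials)
    congruency <- sample(rep(c("incongruent", "congruent"),
                             c(n_inc, n_trials - n_inc)))
    lv <- if (is.null(level)) sample.int(5L, 1L) else as.integer(level)
    assert_that(lv >= 1 && lv <= 5, "`level` must be in 1..5")
    grid <- flanker_levels()[lv, ]
    fixation_ms <- sample(c(200, 300, 400), n_trials, replace = TRUE)
    duration <- grid$flanker_ms + grid$target_ms + 500 + 300 + fixation_ms
    onset <- cumsum(c(0, duration[-n_trials]))
    data.frame(
      trial_index = seq_len(n_trials),
      congruency = factor(congruency, levels = c("congruent", "incongruent")),
      onset = onset,
      flanker_ms = grid$flanker_ms, target_ms = grid$target_ms,
      fixation_ms = fixation_ms,
      response_time = NA_real_, correct = NA,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate Gamma-distributed single-trial reaction times
#'
#' @param group `"ADHD"` or `"HC"`; selects the group mean.
#' @param n number of draws (0 gives an empty vector).
#' @param spec a [cohort_spec()] carrying the group means and Gamma shape.
#' @param seed integer seed.
#' @return numeric vector of reaction times in ms.
#' @export
generate_reaction_times <- function(group, n, spec = cohort_spec(),
                                    seed = NULL) {
  group <- match.arg(group, c("ADHD", "HC"))
  assert_that(is.numeric(n) && length(n) == 1L && n >= 0 && n == floor(n),
              "`n` must be a non-negative integer")
  if (n == 0) return(numeric(0))
  m <- if (group == "ADHD") spec$rt_mean_adhd else spec$rt_mean_hc
  with_seed(seed, rgamma(n, shape = spec$rt_shape, scale = m / spec$rt_shape))
}
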