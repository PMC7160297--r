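test_that("generate_cohort sizes, truncation and determinism", {
  co <- generate_cohort(cohort_spec())
  expect_equal(sum(co$group == "ADHD"), 20L)
  expect_equal(sum(co$group == "HC"), 20L)
  expect_true(all(co$age >= 18))

  co1 <- generate_cohort(cohort_spec(n_per_group = 1L))
  expect_equal(nrow(co1), 2L)
  expect_setequal(as.character(co1$group), c("ADHD", "HC"))

  a <- generate_cohort(cohort_spec(seed = 42L))
  b <- generate_cohort(cohort_spec(seed = 42L))
  expect_identical(a, b)

  expect_error(cohort_spec(n_per_group = 0), "n_per_group")
  expect_error(cohort_spec(age_sd_adhd = -1), "age_sd_adhd")
})

test_that("cohort ages match the stated (truncated) sampling distribution", {
  # Monte-Carlo check of the sampler against its own distribution: a normal
  # truncated at 18. Closed-form truncated-normal moments are the oracle.
  mu <- 43.85; s <- 14.78
  alpha <- (18 - mu) / s
  lam <- dnorm(alpha) / (1 - pnorm(alpha))
  m_trunc <- mu + s * lam
  v_trunc <- s^2 * (1 + alpha * lam - lam^2)
  co <- generate_cohort(cohort_spec(n_per_group = 5000L, seed = 9L))
  ages <- co$age[co$group == "ADHD"]
  se <- sqrt(v_trunc / length(ages))
  expect_lt(abs(mean(ages) - m_trunc), 3 * se)
})

test_that("trial sequences honour the 2:1 ratio and the timing grid", {
  ev <- generate_trial_sequence(140L, 2L, seed = 1L)
  expect_equal(sum(ev$congruency == "incongruent"), 47L)  # round(140/3)
  expect_equal(sum(ev$congruency == "congruent"), 93L)

  ev3 <- generate_trial_sequence(3L, 2L, seed = 1L)
  expect_equal(sum(ev3$congruency == "incongruent"), 1L)

  for (sd_ in 1:3) {
    ev <- generate_trial_sequence(60L, 2L, seed = sd_)
    expect_true(all(ev$fixation_ms %in% c(200, 300, 400)))
    expect_true(all(diff(ev$onset) > 0))
    dur <- ev$flanker_ms + ev$target_ms + 500 + 300 + ev$fixation_ms
    expect_true(all(dur >= 1070 & dur <= 1398))
    expect_true(all(cbind(ev$flanker_ms, ev$target_ms) %in%
                      unlist(erspnet:::flanker_levels())))
  }
  expect_identical(generate_trial_sequence(30L, seed = 5L),
                   generate_trial_sequence(30L, seed = 5L))
  expect_error(generate_trial_sequence(0L), "n_trials")
})

test_that("reaction times follow the stated Gamma law", {
  expect_identical(generate_reaction_times("HC", 0, seed = 1L), numeric(0))
  sp <- cohort_spec()
  rt <- generate_reaction_times("ADHD", 20000L, sp, seed = 3L)
  m <- sp$rt_mean_adhd
  expect_lt(abs(mean(rt) - m), 3 * (m / sqrt(sp$rt_shape)) / sqrt(20000))
  # Gamma moment identity: var = mean^2 / shape
  expect_lt(abs(var(rt) - m^2 / sp$rt_shape) / (m^2 / sp$rt_shape), 0.1)
  rt_hc <- generate_reaction_times("HC", 20000L, sp, seed = 3L)
  expect_lt(abs(mean(rt_hc) - sp$rt_mean_hc), 3)
  expect_error(generate_reaction_times("ADHD", -1, sp), "non-negative")
})

test_that("epoch synthesis: shapes, determinism, frame-count conservation", {
  co <- generate_cohort(cohort_spec(n_per_group = 1L, seed = 2L))
  ev <- generate_trial_sequence(30L, seed = 4L)
  es <- effect_spec(seed = 5L)
  ep <- synthesize_epochs(co[1, ], ev, es)
  expect_equal(dim(ep$data), c(sum(ev$congruency == "incongruent"), 7L, 500L))
  expect_equal(ep$time_ms[1], -200)
  expect_equal(ep$time_ms[500], 798)
  expect_identical(ep$data, synthesize_epochs(co[1, ], ev, es)$data)

  rest <- synthesize_resting(co[1, ], 5L, es)
  expect_equal(dim(rest$data), c(5L, 7L, 500L))

  for (np in c(2L, 3L)) {
    ds <- simulate_eeg_dataset(cohort_spec(n_per_group = np,
                                           frames_per_subject = 9L,
                                           seed = 6L),
                               effect_spec(seed = 7L))
    counts <- vapply(ds$epochs, function(e) dim(e$data)[1], 0L)
    expect_true(all(counts == 9L))
    expect_equal(length(ds$epochs), 2L * np)
  }
  expect_error(synthesize_epochs(co[1, ], ev,
                                 effect_spec(alpha_band = c(0.5, 12))),
               "1, 20")
})

test_that("alpha attenuation halves alpha band power (clean-signal oracle)", {
  # -3 dB on an isolated alpha component: ADHD/HC 8-12 Hz power ratio 0.5.
  es <- effect_spec(alpha_attenuation = -3, noise_rms = 0, subject_sd = 0,
                    theta_amp = 0, n100_amp = 0, seed = 11L)
  subA <- list(subject_id = "ADHD01", group = "ADHD", effect_z = 0)
  subH <- list(subject_id = "HC01", group = "HC", effect_z = 0)
  ev <- generate_trial_sequence(60L, seed = 12L)
  pA <- band_power(synthesize_epochs(subA, ev, es), c(8, 12))
  pH <- band_power(synthesize_epochs(subH, ev, es), c(8, 12))
  expect_lt(abs(pA / pH - 10^(-3 / 10)), 0.1 * 10^(-3 / 10))
})

test_that("null effects give exchangeable groups at the nominal test level", {
  # Subject-level two-sample t-test on alpha band power, zero effects and a
  # common age law: rejection rate compatible with alpha = 0.05.
  n_sim <- 150L
  rej <- 0L
  for (s in seq_len(n_sim)) {
    cs <- cohort_spec(n_per_group = 3L, frames_per_subject = 4L,
                      age_mean_hc = 43.85, age_sd_hc = 14.78, seed = 100L + s)
    ds <- simulate_eeg_dataset(cs, null_effect_spec(seed = 500L + s))
    bp <- vapply(ds$epochs, band_power, 0, band = c(8, 12))
    pv <- t.test(bp[ds$subjects$group == "ADHD"],
                 bp[ds$subjects$group == "HC"])$p.value
    rej <- rej + (pv < 0.05)
  }
  bounds <- qbinom(c(0.0025, 0.9975), n_sim, 0.05)
  expect_gte(rej, bounds[1])
  expect_lte(rej, bounds[2])
})
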