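test_that("frequency grid and cycle schedule follow the stated rules", {
  p <- ersp_params()
  f <- log_spaced_freqs(p)
  expect_length(f, 22L)
  expect_equal(f[1], 3)
  expect_equal(f[22], 20)
  ratios <- f[-1] / f[-22]
  expect_equal(ratios, rep((20 / 3)^(1 / 21), 21), tolerance = 1e-12)
  expect_equal(log_spaced_freqs(ersp_params(n_freqs = 2L)), c(3, 20))
  expect_error(ersp_params(n_freqs = 1L), "n_freqs")

  cyc <- cycles_for_freqs(f, p)
  expect_equal(cyc[1], 1)
  expect_equal(cyc[22], 10)
  expect_equal(cyc, 1 + 9 * (0:21) / 21, tolerance = 1e-12)
  expect_error(cycles_for_freqs(numeric(0)), "non-empty")
})

test_that("single-trial spectrograms have the right shape, floor and peak", {
  p <- ersp_params()
  zero <- matrix(0, 7, 500)
  sf0 <- single_trial_ersp(zero, p)
  expect_equal(dim(sf0$power), c(22L, 20L, 7L))
  expect_true(all(sf0$power == p$power_floor))

  # 1 uV 10 Hz sinusoid on channel 3 only: every time bin peaks at the
  # frequency bin closest to 10 Hz; silent channels stay at the floor
  es <- sine_epoch(10, amp = 1, channels = 7)
  es$data[1, -3, ] <- 0
  sf <- single_trial_ersp(es, p)
  f <- sf$freqs
  target_bin <- which.min(abs(f - 10))
  for (tb in seq_len(20)) {
    expect_equal(which.max(sf$power[, tb, 3]), target_bin)
  }
  expect_true(all(sf$power[, , -3] == p$power_floor))
  # unit-amplitude normalization: peak power near 0 dB re 1 uV^2
  expect_lt(abs(max(sf$power[target_bin, , 3])), 1.5)
})

test_that("dB scaling covariance and time-shift locality hold", {
  ds <- tiny_dataset()$ds
  ep <- matrix(ds$epochs[[1]]$data[1, , ], 7)
  p <- ersp_params(power_floor = -200)
  a <- single_trial_ersp(ep, p)$power
  b <- single_trial_ersp(5 * ep, p)$power
  expect_equal(b - a, array(20 * log10(5), dim(a)), tolerance = 1e-8)

  # a transient moved by 120 ms (3 bins) moves its dB maximum by 3 +/- 1 bins
  t <- epoch_time_ms() / 1000
  mk <- function(t0) {
    d <- matrix(0, 7, 500)
    for (ch in 1:7) {
      d[ch, ] <- cos(2 * pi * 10 * t) * exp(-(t - t0)^2 / (2 * 0.04^2))
    }
    d
  }
  pk <- function(t0) {
    pw <- single_trial_ersp(mk(t0), ersp_params())$power
    which.max(pw[which.min(abs(log_spaced_freqs(ersp_params()) - 10)), , 1])
  }
  shift_bins <- pk(0.42) - pk(0.30)
  expect_gte(shift_bins, 2L)
  expect_lte(shift_bins, 4L)
})

test_that("FFT path matches the direct time-domain convolution oracle", {
  set.seed(99)
  p <- ersp_params()
  for (i in 1:3) {
    ep <- matrix(rnorm(7 * 500), 7)
    a <- single_trial_ersp(ep, p)$power
    b <- single_trial_ersp(ep, p, direct = TRUE)$power
    expect_lt(max(abs(a - b)) / max(abs(a)), 1e-6)
  }
})

test_that("dataset_ersp counts frames and carries labels; generator effects
           appear with the injected sign", {
  td <- tiny_dataset()
  fs <- td$frames
  expect_equal(dim(fs$frames)[1], 4L * 6L)
  expect_equal(dim(fs$frames)[2:4], c(22L, 20L, 7L))
  expect_equal(length(fs$subject_id), 24L)
  expect_setequal(levels(fs$group), c("HC", "ADHD"))

  one <- dataset_ersp(list(td$ds$epochs[[1]]))
  expect_equal(dim(one$frames)[1], 6L)

  # theta boost > 0 in the generator -> positive mean ADHD-HC dB difference
  # in the 3-7 Hz x [50, 150] ms cells (tiny n, so only the sign is asserted)
  gd <- ersp_group_difference(fs)
  expect_gt(bandtime_summary(gd, c(3, 7), c(50, 150), fs$freqs,
                             fs$time_centres), 0)

  bad <- td$ds$epochs
  bad[[2]]$channels <- rev(bad[[2]]$channels)
  expect_error(dataset_ersp(bad), "channel order")
})
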