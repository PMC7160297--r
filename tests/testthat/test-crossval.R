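test_that("fold enumeration is exhaustive, deterministic and leakage-free", {
  mk <- function(na, nh) {
    data.frame(
      subject_id = c(sprintf("ADHD%02d", seq_len(na)),
                     sprintf("HC%02d", seq_len(nh))),
      group = factor(rep(c("ADHD", "HC"), c(na, nh)), levels = c("HC", "ADHD")))
  }
  expect_length(lpocv_folds(mk(1, 1)), 1L)
  expect_length(lpocv_folds(mk(2, 3)), 6L)
  expect_length(lpocv_folds(mk(3, 3)), 9L)
  expect_identical(lpocv_folds(mk(4, 4)), lpocv_folds(mk(4, 4)))
  for (f in lpocv_folds(mk(3, 4))) {
    expect_false(any(f$held_out %in% f$train_ids))
    expect_length(f$train_ids, 5L)
  }
  only_hc <- mk(2, 2)[3:4, ]
  expect_error(lpocv_folds(only_hc), "both classes")
})

test_that("subject scoring averages frames with the HC tie rule", {
  s <- score_subject(c(0.6, 0.7, 0.8))
  expect_equal(s$score, 0.7)
  expect_equal(s$class, "ADHD")
  expect_equal(score_subject(c(0.5, 0.5))$class, "HC")       # exact tie -> HC
  expect_equal(score_subject(rep(0.51, 140))$class, "ADHD")
  expect_error(score_subject(numeric(0)), "non-empty")
})

test_that("auc_wmw equals exhaustive pair counting", {
  expect_equal(auc_wmw(c(0.9, 0.8, 0.2, 0.1),
                       c("ADHD", "ADHD", "HC", "HC")), 1)
  expect_equal(auc_wmw(c(0.9, 0.4, 0.6, 0.1),
                       c("ADHD", "ADHD", "HC", "HC")), 0.75)
  expect_equal(auc_wmw(rep(0.5, 6), rep(c("ADHD", "HC"), 3)), 0.5)
  expect_error(auc_wmw(1:3, rep("HC", 3)), "empty")

  brute <- function(s, l) {
    pos <- s[l == "ADHD"]; neg <- s[l != "ADHD"]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(21)
  for (i in 1:60) {
    n <- sample(4:20, 1)
    l <- c("ADHD", "HC", sample(c("ADHD", "HC"), n - 2, replace = TRUE))
    s <- round(runif(n), sample(c(1, 2, 8), 1))   # coarse rounding forces ties
    expect_equal(auc_wmw(s, l), brute(s, l))
  }
})

test_that("propensity weighting behaves as inverse probability of group", {
  # uninformative covariate: everyone near 0.5 / weight near 2
  ip <- fit_propensity(rep(35, 20), rep(c("ADHD", "HC"), 10))
  expect_true(all(abs(ip$propensity - 0.5) < 1e-6))
  expect_true(all(abs(ip$weights - 2) < 1e-5))

  # ADHD older: the youngest ADHD subject carries the largest ADHD weight
  set.seed(31)
  ages <- c(rnorm(20, 46, 10), rnorm(20, 30, 10))
  labs <- rep(c("ADHD", "HC"), each = 20)
  ip2 <- fit_propensity(ages, labs)
  wa <- ip2$weights[1:20]
  expect_equal(which.max(wa), which.min(ages[1:20]))
  expect_true(all(ip2$weights > 0 & is.finite(ip2$weights)))
  expect_true(all(ip2$propensity >= 0.05 & ip2$propensity <= 0.95))

  # parameter recovery at n = 2000 from a known logit
  set.seed(32)
  a <- runif(2000, 18, 70)
  p_true <- plogis(-3 + 0.08 * a)
  y <- ifelse(runif(2000) < p_true, "ADHD", "HC")
  ip3 <- fit_propensity(a, y, clip = c(0.001, 0.999))
  expect_lt(sqrt(mean((ip3$propensity - p_true)^2)), 0.05)
})

test_that("compare_models matches the Welch formula and handles degeneracy", {
  x <- c(80, 82, 84, 86, 88)
  expect_equal(compare_models(x, x)$t, 0)
  expect_equal(compare_models(x, x)$p_value, 1)
  cm <- compare_models(x + 10, x)                 # constant shift separates
  expect_lt(cm$p_value, 0.05)

  set.seed(41)
  a <- rnorm(30, 88, 4); b <- rnorm(30, 80, 6)
  got <- compare_models(a, b)
  want <- t.test(a, b)
  expect_equal(got$t, unname(want$statistic), tolerance = 1e-9)
  expect_equal(got$p_value, want$p.value, tolerance = 1e-9)
  # identical constant vectors
  expect_equal(compare_models(rep(1, 4), rep(1, 4))$p_value, 1)
})

test_that("run_lpocv trains per fold without leakage and summarizes", {
  td <- tiny_dataset()
  res <- run_lpocv(td$frames, td$ds$subjects, "snn",
                   train_config(max_epochs = 6L, seed = 51L),
                   keep_models = TRUE)
  expect_equal(res$n_folds, 4L)                     # 2 x 2 cohort
  expect_true(res$accuracy >= 0 && res$accuracy <= 100)
  expect_true(res$pooled_auc >= 0 && res$pooled_auc <= 1)
  expect_length(res$models, 4L)
  for (f in res$folds) {
    expect_length(f$subject_scores, 2L)
    expect_true(all(f$subject_scores >= 0 & f$subject_scores <= 1))
    expect_false(any(f$held_out %in%
                       lpocv_folds(td$ds$subjects)[[f$fold_id]]$train_ids))
  }
  # channel ablation restricts the input stack
  res1 <- run_lpocv(td$frames, td$ds$subjects, "snn",
                    train_config(max_epochs = 2L, seed = 52L),
                    channel_subset = c("F3", "Fz", "F4"),
                    fold_subset = 1:2)
  expect_equal(res1$channels, c("F3", "Fz", "F4"))
  expect_equal(res1$n_folds, 2L)
  expect_error(run_lpocv(td$frames, td$ds$subjects, "svm"), "arg")
})
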