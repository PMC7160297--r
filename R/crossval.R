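#' Enumerate leave-pair-out cross-validation folds
#'
#' One fold per (ADHD, HC) subject pair — `n_ADHD x n_HC` folds in total,
#' enumerated deterministically over the sorted subject ids. Each fold
#' holds the pair out and trains on everyone else, so training sets stay
#' class-balanced by construction.
#'
#' @param subjects cohort `data.frame` with `subject_id` and `group`.
#' @return list of fold plans: `fold_id`, `held_out` (named pair),
#'   `train_ids`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(n_per_group = 2))
#' length(lpocv_folds(co))   # 4
lpocv_folds <- function(subjects) {
  adhd <- sort(as.character(subjects$subject_id[subjects$group == "ADHD"]))
  hc <- sort(as.character(subjects$subject_id[subjects$group == "HC"]))
  assert_that(length(adhd) > 0 && length(hc) > 0,
              "both classes must be present")
  folds <- vector("list", length(adhd) * length(hc))
  k <- 0L
  for (a in adhd) for (h in hc) {
    k <- k + 1L
    folds[[k]] <- list(fold_id = k, held_out = c(ADHD = a, HC = h),
                       train_ids = setdiff(c(adhd, hc), c(a, h)))
  }
  folds
}

#' Aggregate frame probabilities into a subject-level decision
#'
#' The subject score is the arithmetic mean of the frame-level ADHD
#' probabilities; the predicted class is ADHD iff the score exceeds 0.5
#' (a score of exactly 0.5 predicts HC, fixing the tie deterministically).
#'
#' @param frame_probs numeric vector of per-frame ADHD probabilities.
#' @return list with `score` and `class`.
#' @export
score_subject <- function(frame_probs) {
  assert_that(length(frame_probs) > 0 && all(is.finite(frame_probs)),
              "`frame_probs` must be non-empty and finite")
  s <- mean(frame_probs)
  list(score = s, class = if (s > 0.5) "ADHD" else "HC")
}

#' AUC via the Wilcoxon-Mann-Whitney statistic
#'
#' The probability that a randomly chosen positive (ADHD) score exceeds a
#' randomly chosen negative one, with ties counted half:
#' `AUC = (#concordant + 0.5 #tied) / (n_pos * n_neg)`, computed through
#' midranks.
#'
#' @param scores numeric scores.
#' @param labels parallel labels; `"ADHD"` (or `TRUE`/1) is positive.
#' @return AUC in `[0, 1]`.
#' @export
auc_wmw <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else as.character(labels) == "ADHD"
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  assert_that(n_pos > 0 && n_neg > 0,
              "AUC undefined: a class is empty")
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Inverse-probability age weights from a logistic propensity model
#'
#' Fits the propensity of ADHD given age with a single-covariate binomial
#' logit, clips the fitted propensities to `clip` (standard practice to
#' bound the weights under near-separation), and inverts: ADHD subjects
#' weigh `1/p`, HC subjects `1/(1-p)`. Younger ADHD subjects (rare when
#' ADHD is the older group) therefore receive the largest ADHD-side
#' weights.
#'
#' @param ages numeric ages.
#' @param labels parallel group labels (`"ADHD"` positive).
#' @param clip propensity clipping bounds.
#' @return object of class `ipw_weights`: `propensity`, `weights`,
#'   `coefficients`, `clipped` flag per subject.
#' @export
fit_propensity <- function(ages, labels, clip = c(0.05, 0.95)) {
  pos <- as.character(labels) == "ADHD"
  assert_that(sum(pos) > 0 && sum(!pos) > 0, "both classes required")
  fit <- suppressWarnings(stats::glm(pos ~ ages, family = stats::binomial()))
  if (!fit$converged || any(abs(stats::coef(fit)) > 50, na.rm = TRUE)) {
    warning("propensity model near-separated; weights are clipped")
  }
  p <- as.numeric(stats::predict(fit, type = "response"))
  clipped <- p < clip[1] | p > clip[2]
  p <- pmin(pmax(p, clip[1]), clip[2])
  w <- ifelse(pos, 1 / p, 1 / (1 - p))
  structure(list(propensity = p, weights = w,
                 coefficients = stats::coef(fit), clipped = clipped,
                 clip = clip),
            class = "ipw_weights")
}

build_arch <- function(architecture, input_shape, seed) {
  switch(architecture,
         cnn = build_cnn(cnn_config(input_shape = input_shape), seed = seed),
         snn = build_snn(snn_config(input_shape = input_shape), seed = seed),
         rnn = build_rnn(rnn_config(input_shape = input_shape), seed = seed),
         stop("unknown architecture: ", architecture))
}

#' Run leave-pair-out cross-validation
#'
#' For every fold (optionally a systematic subset, for reduced-budget
#' runs): trains a fresh network on all frames of the non-held-out
#' subjects — with inverse-probability age weights applied to the loss when
#' `ipw = TRUE` — and scores the two held-out subjects by frame-probability
#' averaging. Accuracy is the percentage of held-out subjects classified
#' correctly; AUC is the per-fold pair AUC (values 0 / 0.5 / 1) averaged
#' across folds, with the pooled AUC over all held-out subject scores also
#' reported. Dispersion is the across-fold SD.
#'
#' @param frames a `frame_set` covering every subject.
#' @param subjects the cohort `data.frame` (needs `subject_id`, `group`,
#'   `age`).
#' @param architecture `"cnn"`, `"snn"` or `"rnn"`.
#' @param config a [train_config()]; its seed drives all per-fold
#'   initialization, shuffling and dropout.
#' @param ipw apply inverse-probability age weighting (propensities are fit
#'   on the training subjects of each fold only).
#' @param channel_subset optional character vector of channels to restrict
#'   the input stack to (single-channel ablation).
#' @param fold_subset optional integer indices of folds to run.
#' @param keep_models retain each fold's trained model (needed for
#'   DeepDream over folds).
#' @return object of class `performance_summary` with fields `accuracy`,
#'   `accuracy_sd`, `auc`, `auc_sd`, `pooled_auc`, `n_folds`,
#'   `architecture`, and `$folds` (per-fold records).
#' @export
run_lpocv <- function(frames, subjects, architecture = c("cnn", "snn", "rnn"),
                      config = train_config(), ipw = FALSE,
                      channel_subset = NULL, fold_subset = NULL,
                      keep_models = FALSE) {
  architecture <- match.arg(architecture)
  stopifnot(inherits(frames, "frame_set"))
  if (!is.null(channel_subset)) {
    frames <- subset_frames(frames, channels = channel_subset)
  }
  plans <- lpocv_folds(subjects)
  if (!is.null(fold_subset)) plans <- plans[fold_subset]
  missing <- setdiff(as.character(subjects$subject_id), unique(frames$subject_id))
  assert_that(length(missing) == 0,
              paste("no frames for subject(s):", paste(missing, collapse = ", ")))
  input_shape <- dim(frames$frames)[2:4]
  sub_group <- setNames(as.character(subjects$group),
                        as.character(subjects$subject_id))
  sub_age <- setNames(subjects$age, as.character(subjects$subject_id))

  fold_results <- vector("list", length(plans))
  models <- if (keep_models) vector("list", length(plans)) else NULL
  for (j in seq_along(plans)) {
    plan <- plans[[j]]
    tr_idx <- which(frames$subject_id %in% plan$train_ids)
    te_idx <- which(frames$subject_id %in% plan$held_out)
    tr_frames <- subset_frames(frames, frames = tr_idx)
    weights <- NULL
    if (ipw) {
      ids <- plan$train_ids
      ip <- fit_propensity(sub_age[ids], sub_group[ids])
      w_sub <- setNames(ip$weights, ids)
      weights <- as.numeric(w_sub[tr_frames$subject_id])
      weights <- weights / mean(weights)       # keep effective LR comparable
    }
    fold_seed <- derive_seed(config$seed %||% 0L, plan$fold_id)
    model <- build_arch(architecture, input_shape, seed = fold_seed)
    cfg_j <- config
    cfg_j$seed <- derive_seed(fold_seed, 1L)
    model <- train(model, tr_frames, tr_frames$group,
                   sample_weights = weights, config = cfg_j)
    probs <- predict_frames(model, subset_frames(frames, frames = te_idx))
    te_sid <- frames$subject_id[te_idx]
    held <- unname(plan$held_out)
    scores <- vapply(held, function(id) {
      score_subject(probs[te_sid == id, "ADHD"])$score
    }, 0)
    preds <- ifelse(scores > 0.5, "ADHD", "HC")
    truth <- sub_group[held]
    fold_results[[j]] <- list(
      fold_id = plan$fold_id, held_out = plan$held_out,
      subject_scores = setNames(scores, held),
      subject_pred = setNames(preds, held),
      correct = unname(preds == truth),
      acc = 100 * mean(preds == truth),
      auc = auc_wmw(scores, truth))
    if (keep_models) models[[j]] <- model
  }
  accs <- vapply(fold_results, `[[`, 0, "acc")
  aucs <- vapply(fold_results, `[[`, 0, "auc")
  all_scores <- unlist(lapply(fold_results, `[[`, "subject_scores"))
  all_labels <- sub_group[unlist(lapply(fold_results,
                                        function(f) unname(f$held_out)))]
  structure(list(
    architecture = architecture,
    accuracy = mean(accs), accuracy_sd = stats::sd(accs),
    auc = 100 * mean(aucs), auc_sd = 100 * stats::sd(aucs),
    pooled_auc = auc_wmw(all_scores, all_labels),
    n_folds = length(fold_results),
    ipw = ipw, channels = frames$channels,
    folds = fold_results, models = models
  ), class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf(
    "<performance_summary> %s, %d folds%s: ACC %.1f +/- %.2f%%, AUC %.1f +/- %.2f%% (pooled %.3f)\n",
    toupper(x$architecture), x$n_folds, if (x$ipw) " (IPW)" else "",
    x$accuracy, x$accuracy_sd, x$auc, x$auc_sd, x$pooled_auc))
  invisible(x)
}

#' Compare two models' per-fold performance with a t-test
#'
#' Two-sample Welch t-test on the per-fold accuracy (or AUC) vectors.
#' Degenerate zero-variance inputs are handled explicitly: identical
#' constant vectors give `t = 0, p = 1`.
#'
#' @param acc_folds_a,acc_folds_b numeric per-fold performance vectors.
#' @return list with `t`, `p_value`, `df`, `mean_diff`.
#' @export
compare_models <- function(acc_folds_a, acc_folds_b) {
  na <- length(acc_folds_a)
  nb <- length(acc_folds_b)
  assert_that(na >= 2 && nb >= 2, "need at least two folds per model")
  va <- stats::var(acc_folds_a)
  vb <- stats::var(acc_folds_b)
  md <- mean(acc_folds_a) - mean(acc_folds_b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    t_stat <- if (md == 0) 0 else sign(md) * Inf
    return(list(t = t_stat, p_value = if (md == 0) 1 else 0,
                df = na + nb - 2, mean_diff = md))
  }
  t_stat <- md / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t_stat, p_value = 2 * stats::pt(-abs(t_stat), df), df = df,
       mean_diff = md)
}
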