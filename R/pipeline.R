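#' Assemble a full-run configuration
#'
#' Nested configuration binding every stage: cohort, effects, filtering,
#' time-frequency parameters, architecture and training, cross-validation
#' options and DeepDream settings. The global `seed` propagates
#' deterministically to every stage (each stage derives its own stream).
#'
#' @param cohort a [cohort_spec()].
#' @param effects an [effect_spec()].
#' @param filter a [filter_spec()].
#' @param baseline a [baseline_spec()].
#' @param ersp an [ersp_params()].
#' @param architecture `"cnn"`, `"snn"` or `"rnn"`.
#' @param training a [train_config()].
#' @param ipw apply inverse-probability age weighting.
#' @param channel_subset optional channel restriction.
#' @param fold_subset optional fold indices (reduced-budget runs).
#' @param dream a [dream_params()], or `NULL` to skip the dream stage.
#' @param mode `"task"` or `"resting"`.
#' @param seed global seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(), effects = effect_spec(),
                       filter = filter_spec(), baseline = baseline_spec(),
                       ersp = ersp_params(),
                       architecture = "cnn", training = train_config(),
                       ipw = FALSE, channel_subset = NULL, fold_subset = NULL,
                       dream = dream_params(), mode = "task", seed = 1L) {
  seed <- as.integer(seed)
  cohort$seed <- derive_seed(seed, 1L)
  effects$seed <- derive_seed(seed, 2L)
  training$seed <- derive_seed(seed, 3L)
  if (!is.null(dream)) dream$seed <- derive_seed(seed, 4L)
  structure(list(cohort = cohort, effects = effects, filter = filter,
                 baseline = baseline, ersp = ersp,
                 architecture = architecture, training = training,
                 ipw = ipw, channel_subset = channel_subset,
                 fold_subset = fold_subset, dream = dream,
                 mode = mode, seed = seed),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

log_stage <- function(stage, config, msg, verbose = TRUE) {
  if (verbose) {
    message(sprintf("[%s] seed=%d hash=%s %s",
                    stage, config$seed, substr(config_hash(config), 1, 8), msg))
  }
}

#' Run the complete pipeline
#'
#' simulate -> band-pass + baseline -> single-trial wavelet spectrograms ->
#' leave-pair-out train/evaluate -> DeepDream, writing a results JSON, the
#' subject table, spectrogram containers and a config snapshot sufficient
#' to reproduce the run bit-for-bit.
#'
#' @param config a [run_config()].
#' @param out_dir writable output directory.
#' @param verbose emit stage-tagged progress messages.
#' @return (invisibly) a list with `summary` (the `performance_summary`),
#'   `dream` (a `dream_map` or `NULL`), `frames`, `subjects`, and the
#'   output paths.
#' @export
run_all <- function(config, out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  assert_that(dir.exists(out_dir), "output directory is not writable")
  stage <- "simulate"
  result <- tryCatch({
    log_stage(stage, config, "generating cohort and epochs", verbose)
    ds <- simulate_eeg_dataset(config$cohort, config$effects, config$mode)

    stage <- "preprocess"
    log_stage(stage, config, "band-pass and baseline correction", verbose)
    ds$epochs <- lapply(ds$epochs, function(e) {
      baseline_correct(bandpass(e, config$filter), config$baseline)
    })

    stage <- "ersp"
    log_stage(stage, config, "wavelet spectrograms", verbose)
    frames <- dataset_ersp(ds$epochs, config$ersp)
    write_frames(frames, file.path(out_dir, "frames"))

    stage <- "evaluate"
    log_stage(stage, config, "LPOCV training and evaluation", verbose)
    summary <- run_lpocv(frames, ds$subjects, config$architecture,
                         config$training, ipw = config$ipw,
                         channel_subset = config$channel_subset,
                         fold_subset = config$fold_subset,
                         keep_models = !is.null(config$dream))

    dmap <- NULL
    if (!is.null(config$dream)) {
      stage <- "dream"
      log_stage(stage, config, "activation maximization", verbose)
      dmap <- dream_over_folds(summary$models, config$dream)
    }

    stage <- "write"
    utils::write.csv(ds$subjects, file.path(out_dir, "subjects.csv"),
                     row.names = FALSE)
    res <- list(
      config_hash = config_hash(config), seed = config$seed,
      architecture = summary$architecture, mode = config$mode,
      n_folds = summary$n_folds,
      accuracy = summary$accuracy, accuracy_sd = summary$accuracy_sd,
      auc = summary$auc, auc_sd = summary$auc_sd,
      pooled_auc = summary$pooled_auc,
      folds = lapply(summary$folds, function(f) {
        list(fold_id = f$fold_id, held_out = as.list(f$held_out),
             scores = as.list(f$subject_scores), acc = f$acc, auc = f$auc)
      }))
    if (!is.null(dmap)) {
      res$dream <- list(
        alpha_diff = bandtime_summary(dmap, c(8, 12), c(0, 800),
                                      freqs = frames$freqs,
                                      time_centres = frames$time_centres),
        theta_diff = bandtime_summary(dmap, c(3, 7), c(50, 150),
                                      freqs = frames$freqs,
                                      time_centres = frames$time_centres))
      utils::write.csv(dmap$difference,
                       file.path(out_dir, "dream_difference.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(res, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA)
    cfg_out <- config
    jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    list(summary = summary, dream = dmap, frames = frames,
         subjects = ds$subjects, out_dir = out_dir,
         results_path = file.path(out_dir, "results.json"))
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

#' Write small test datasets
#'
#' `tiny`: 2 subjects per group, 12 frames each (48 frames total);
#' `small`: 6 per group, 60 frames each. Both are generated
#' programmatically (deterministic at `seed`) and written as containers
#' readable by [read_epochs()] / [read_frames()].
#'
#' @param size `"tiny"` or `"small"`.
#' @param dir output directory.
#' @param seed integer seed.
#' @param format container format for [write_epochs()].
#' @return (invisibly) list with the dataset, frames and paths.
#' @export
make_fixtures <- function(size = c("tiny", "small"), dir = tempfile("fixtures"),
                          seed = 1L, format = "auto") {
  size <- match.arg(size)
  n <- if (size == "tiny") 2L else 6L
  fps <- if (size == "tiny") 12L else 60L
  cs <- cohort_spec(n_per_group = n, frames_per_subject = fps, seed = seed)
  es <- effect_spec(seed = derive_seed(seed, 2L))
  ds <- simulate_eeg_dataset(cs, es)
  write_epochs(ds, file.path(dir, "epochs"), format = format)
  frames <- dataset_ersp(lapply(ds$epochs, function(e) {
    baseline_correct(bandpass(e))
  }))
  write_frames(frames, file.path(dir, "frames"), format = format)
  invisible(list(dataset = ds, frames = frames, dir = dir))
}
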