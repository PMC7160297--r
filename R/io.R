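# Container I/O. The native container is a directory holding CSV/JSON
# (always available, text-only); an HDF5 single-file layout (datasets
# /epochs, /time_ms, /channels, ...) is used instead when the rhdf5
# binding is installed and format = "hdf5"/"auto".

have_hdf5 <- function() requireNamespace("rhdf5", quietly = TRUE)

resolve_format <- function(format) {
  format <- match.arg(format, c("auto", "hdf5", "csv"))
  if (format == "hdf5" && !have_hdf5()) {
    stop("format 'hdf5' requires the rhdf5 package", call. = FALSE)
  }
  if (format == "auto") format <- if (have_hdf5()) "hdf5" else "csv"
  format
}

#' Write an epoched dataset to a container
#'
#' HDF5 layout: `/epochs` (trials x channels x samples, pooled over
#' subjects), `/time_ms`, `/channels`, `/trial_subject`, with subject
#' metadata in a sibling `subjects.csv`. CSV layout: a directory with
#' `epochs.csv` (one row per trial x channel), `meta.json` and
#' `subjects.csv`.
#'
#' @param ds dataset from [simulate_eeg_dataset()] (fields `subjects`,
#'   `epochs`).
#' @param path output directory (created).
#' @param format `"auto"`, `"hdf5"` or `"csv"`.
#' @return the path, invisibly.
#' @export
write_epochs <- function(ds, path, format = "auto") {
  format <- resolve_format(format)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  subj <- ds$subjects
  utils::write.csv(subj[, c("subject_id", "group", "age")],
                   file.path(path, "subjects.csv"), row.names = FALSE)
  n_tr <- vapply(ds$epochs, function(e) dim(e$data)[1], 0L)
  all_dat <- array(0, dim = c(sum(n_tr), dim(ds$epochs[[1]]$data)[2:3]))
  trial_subject <- character(sum(n_tr))
  k <- 0L
  for (e in ds$epochs) {
    idx <- k + seq_len(dim(e$data)[1])
    all_dat[idx, , ] <- e$data
    trial_subject[idx] <- e$subject_id
    k <- k + dim(e$data)[1]
  }
  time_ms <- ds$epochs[[1]]$time_ms
  channels <- ds$epochs[[1]]$channels
  if (format == "hdf5") {
    h5 <- file.path(path, "epochs.h5")
    if (file.exists(h5)) unlink(h5)
    rhdf5::h5createFile(h5)
    rhdf5::h5write(all_dat, h5, "epochs")
    rhdf5::h5write(time_ms, h5, "time_ms")
    rhdf5::h5write(channels, h5, "channels")
    rhdf5::h5write(trial_subject, h5, "trial_subject")
    rhdf5::h5closeAll()
  } else {
    flat <- matrix(all_dat, nrow = dim(all_dat)[1] * dim(all_dat)[2])
    df <- data.frame(subject_id = rep(trial_subject, times = length(channels)),
                     channel = rep(channels, each = dim(all_dat)[1]),
                     flat, check.names = FALSE)
    utils::write.csv(df, file.path(path, "epochs.csv"), row.names = FALSE)
    jsonlite::write_json(list(n_trials = dim(all_dat)[1],
                              channels = channels, time_ms = time_ms,
                              mode = ds$mode %||% "task"),
                         file.path(path, "meta.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read an epoched dataset container
#'
#' @param path directory written by [write_epochs()].
#' @return a dataset list (`subjects`, `epochs`) mirroring
#'   [simulate_eeg_dataset()].
#' @export
read_epochs <- function(path) {
  subj <- utils::read.csv(file.path(path, "subjects.csv"),
                          stringsAsFactors = FALSE)
  subj$group <- factor(subj$group, levels = c("HC", "ADHD"))
  h5 <- file.path(path, "epochs.h5")
  if (file.exists(h5)) {
    assert_that(have_hdf5(), "container is HDF5 but rhdf5 is unavailable")
    all_dat <- rhdf5::h5read(h5, "epochs")
    time_ms <- as.numeric(rhdf5::h5read(h5, "time_ms"))
    channels <- as.character(rhdf5::h5read(h5, "channels"))
    trial_subject <- as.character(rhdf5::h5read(h5, "trial_subject"))
    rhdf5::h5closeAll()
  } else {
    meta <- jsonlite::read_json(file.path(path, "meta.json"),
                                simplifyVector = TRUE)
    df <- utils::read.csv(file.path(path, "epochs.csv"), check.names = FALSE,
                          stringsAsFactors = FALSE)
    channels <- meta$channels
    time_ms <- meta$time_ms
    n_tr <- meta$n_trials
    vals <- as.matrix(df[, -(1:2), drop = FALSE])
    all_dat <- array(as.numeric(vals), dim = c(n_tr, length(channels),
                                               length(time_ms)))
    trial_subject <- df$subject_id[seq_len(n_tr)]
  }
  epochs <- lapply(seq_len(nrow(subj)), function(i) {
    id <- subj$subject_id[i]
    sel <- which(trial_subject == id)
    epoch_set(all_dat[sel, , , drop = FALSE], time_ms, channels,
              subject_id = id, group = as.character(subj$group[i]))
  })
  list(subjects = subj, epochs = epochs)
}

#' Write a spectrogram frame set to a container
#'
#' HDF5 datasets `/frames` (n x freq x time x channel), `/labels`,
#' `/subject_ids`, `/freqs_hz`, `/time_ms`; or a CSV/JSON directory.
#'
#' @param fs a `frame_set`.
#' @param path output directory.
#' @param format `"auto"`, `"hdf5"` or `"csv"`.
#' @return the path, invisibly.
#' @export
write_frames <- function(fs, path, format = "auto") {
  format <- resolve_format(format)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (format == "hdf5") {
    h5 <- file.path(path, "frames.h5")
    if (file.exists(h5)) unlink(h5)
    rhdf5::h5createFile(h5)
    rhdf5::h5write(fs$frames, h5, "frames")
    rhdf5::h5write(as.character(fs$group), h5, "labels")
    rhdf5::h5write(fs$subject_id, h5, "subject_ids")
    rhdf5::h5write(fs$freqs, h5, "freqs_hz")
    rhdf5::h5write(fs$time_centres, h5, "time_ms")
    rhdf5::h5write(fs$channels, h5, "channels")
    rhdf5::h5closeAll()
  } else {
    n <- dim(fs$frames)[1]
    flat <- matrix(fs$frames, nrow = n)
    utils::write.csv(data.frame(subject_id = fs$subject_id,
                                label = as.character(fs$group),
                                flat, check.names = FALSE),
                     file.path(path, "frames.csv"), row.names = FALSE)
    jsonlite::write_json(list(dim = dim(fs$frames), freqs_hz = fs$freqs,
                              time_ms = fs$time_centres,
                              channels = fs$channels),
                         file.path(path, "meta.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a spectrogram frame container
#' @param path directory written by [write_frames()].
#' @return a `frame_set`.
#' @export
read_frames <- function(path) {
  h5 <- file.path(path, "frames.h5")
  if (file.exists(h5)) {
    assert_that(have_hdf5(), "container is HDF5 but rhdf5 is unavailable")
    fr <- rhdf5::h5read(h5, "frames")
    lab <- as.character(rhdf5::h5read(h5, "labels"))
    sid <- as.character(rhdf5::h5read(h5, "subject_ids"))
    freqs <- as.numeric(rhdf5::h5read(h5, "freqs_hz"))
    tc <- as.numeric(rhdf5::h5read(h5, "time_ms"))
    channels <- as.character(rhdf5::h5read(h5, "channels"))
    rhdf5::h5closeAll()
  } else {
    meta <- jsonlite::read_json(file.path(path, "meta.json"),
                                simplifyVector = TRUE)
    df <- utils::read.csv(file.path(path, "frames.csv"), check.names = FALSE,
                          stringsAsFactors = FALSE)
    fr <- array(as.numeric(as.matrix(df[, -(1:2), drop = FALSE])),
                dim = meta$dim)
    lab <- df$label
    sid <- df$subject_id
    freqs <- meta$freqs_hz
    tc <- meta$time_ms
    channels <- meta$channels
  }
  structure(list(frames = fr, subject_id = sid,
                 group = factor(lab, levels = c("HC", "ADHD")),
                 freqs = freqs, time_centres = tc, channels = channels),
            class = "frame_set")
}
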