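# Data model, native file format, epoch segmentation, preprocessing
# filters, and run configuration.

#' Labelled collection of fixed-length multi-channel epochs
#'
#' @param data `trials x channels x samples` numeric array.
#' @param fs Sampling rate in Hz.
#' @param channel_names Unique channel labels (10-20 montage names for
#'   recorded EEG).
#' @param labels Class label per trial (integers; `0` and `1` for the
#'   binary tasks).
#' @param task Free-text task description.
#' @return An `epoch_set`.
#' @export
epoch_set <- function(data, fs, channel_names = NULL, labels = NULL,
                      task = "") {
  if (!(is.array(data) && length(dim(data)) == 3))
    stop("'data' must be a trials x channels x samples array")
  if (!(is.numeric(fs) && length(fs) == 1 && fs > 0))
    stop("'fs' must be a positive sampling rate in Hz")
  nt <- dim(data)[1]; nc <- dim(data)[2]
  if (is.null(channel_names)) channel_names <- montage_1020(nc)
  if (length(channel_names) != nc) stop("one name per channel required")
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  if (is.null(labels)) labels <- rep(0L, nt)
  if (length(labels) != nt) stop("one label per trial required")
  structure(list(data = data, fs = fs,
                 channel_names = as.character(channel_names),
                 labels = as.integer(labels), task = as.character(task)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "Epoch set: %d trials x %d channels x %d samples at %g Hz\n",
    d[1], d[2], d[3], x$fs))
  cat(sprintf("  labels: %s\n",
              paste(sprintf("%s (n=%d)", names(table(x$labels)),
                            as.integer(table(x$labels))), collapse = ", ")))
  if (nzchar(x$task)) cat("  task:", x$task, "\n")
  invisible(x)
}

#' Segment a continuous resting recording into overlapping epochs
#'
#' Windows of `epoch_seconds` advance by `epoch_seconds - overlap_seconds`,
#' so consecutive epochs share exactly `overlap_seconds` of signal. With
#' the defaults, a 90-s recording yields 44 possible windows of which the
#' earliest `max_epochs = 40` are kept.
#'
#' @param x `channels x samples` numeric matrix (a vector is one channel).
#' @param fs Sampling rate in Hz.
#' @param epoch_seconds Window length in seconds (default 3).
#' @param overlap_seconds Overlap between consecutive windows (default 1).
#' @param max_epochs Cap on the number of windows, earliest first
#'   (default 40; `NULL` keeps all).
#' @param channel_names,label Passed to the resulting [epoch_set()]
#'   (label default 0 = resting).
#' @return An [epoch_set()] of resting epochs.
#' @export
segment_resting <- function(x, fs, epoch_seconds = 3, overlap_seconds = 1,
                            max_epochs = 40, channel_names = NULL,
                            label = 0L) {
  if (!is.matrix(x)) x <- matrix(as.numeric(x), nrow = 1)
  stopifnot(fs > 0, epoch_seconds > 0, overlap_seconds >= 0,
            overlap_seconds < epoch_seconds)
  len <- as.integer(round(epoch_seconds * fs))
  step <- as.integer(round((epoch_seconds - overlap_seconds) * fs))
  S <- ncol(x)
  if (S < len) stop("recording shorter than one epoch")
  starts <- seq.int(1L, S - len + 1L, by = step)
  if (!is.null(max_epochs) && length(starts) > max_epochs)
    starts <- starts[seq_len(max_epochs)]
  dat <- array(NA_real_, dim = c(length(starts), nrow(x), len))
  for (i in seq_along(starts))
    dat[i, , ] <- x[, starts[i] + 0:(len - 1L), drop = FALSE]
  epoch_set(dat, fs = fs, channel_names = channel_names,
            labels = rep(as.integer(label), length(starts)),
            task = "resting (segmented)")
}

#' Zero-phase band-pass filter
#'
#' Order-3 Butterworth band-pass applied forward and backward
#' (zero phase). The default 0.5-100 Hz band removes DC and drift while
#' keeping the EEG range.
#'
#' @param x Numeric vector or `channels x samples` matrix.
#' @param low,high Corner frequencies in Hz, `0 < low < high < fs / 2`.
#' @param fs Sampling rate in Hz.
#' @param order Butterworth order (default 3).
#' @return Filtered signal, same shape as the input.
#' @export
bandpass <- function(x, low = 0.5, high = 100, fs, order = 3) {
  if (!(low > 0 && high > low && high < fs / 2))
    stop("invalid corner frequencies: need 0 < low < high < fs/2")
  butter_bandpass(x, low, high, fs, order = order)
}

#' Write an epoch set to a directory
#'
#' Native storage: one delimited numeric matrix (`channels x samples`,
#' CSV, no header) per trial plus a single `metadata.json` sidecar holding
#' the sampling rate, channel names, labels and task.
#'
#' @param set An [epoch_set()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_epochset <- function(set, dir) {
  stopifnot(inherits(set, "epoch_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(set$data)
  meta <- list(fs = set$fs, channel_names = set$channel_names,
               labels = set$labels, task = set$task,
               n_trials = d[1], n_channels = d[2], n_samples = d[3])
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_len(d[1])) {
    data.table::fwrite(
      data.table::as.data.table(set$data[i, , , drop = TRUE]),
      file.path(dir, sprintf("trial_%03d.csv", i)), col.names = FALSE)
  }
  invisible(dir)
}

#' Read an epoch set written by [write_epochset()]
#'
#' @param dir Directory holding `metadata.json` and the per-trial CSV
#'   matrices.
#' @return An [epoch_set()]. Fails with the name of any missing metadata
#'   key.
#' @export
read_epochset <- function(dir) {
  mpath <- file.path(dir, "metadata.json")
  if (!file.exists(mpath)) stop("metadata sidecar not found: ", mpath)
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  for (key in c("fs", "channel_names", "labels", "n_trials", "n_channels",
                "n_samples")) {
    if (is.null(meta[[key]]))
      stop("metadata sidecar is missing required key '", key, "'")
  }
  dat <- array(NA_real_,
               dim = c(meta$n_trials, meta$n_channels, meta$n_samples))
  for (i in seq_len(meta$n_trials)) {
    f <- file.path(dir, sprintf("trial_%03d.csv", i))
    if (!file.exists(f)) stop("missing trial file: ", f)
    m <- as.matrix(data.table::fread(f, header = FALSE))
    if (!all(dim(m) == c(meta$n_channels, meta$n_samples)))
      stop(sprintf("trial %d has shape %d x %d, metadata says %d x %d",
                   i, nrow(m), ncol(m), meta$n_channels, meta$n_samples))
    dat[i, , ] <- m
  }
  epoch_set(dat, fs = meta$fs, channel_names = meta$channel_names,
            labels = meta$labels, task = meta$task %||% "")
}

#' Run configuration with the protocol defaults
#'
#' Central container for the tunable parameters, with the standard
#' defaults: delay `tau = 50` samples, saturation tolerance
#' `epsilon = 0.001`, embedding cap `M_max = 50`, Higuchi `kmax = 100`,
#' the [standard_bands()] set, a K-NN classifier, and all 30 channels.
#'
#' @param tau,epsilon,M_max GPFD parameters.
#' @param kmax HFD parameter.
#' @param bands Band set for band-power / CSP features.
#' @param spec A [classifier_spec()].
#' @param channel_policy `"all"` or `list(mode =, d =)`.
#' @param seed Master seed for anything stochastic downstream.
#' @return A `run_config` list; printing it shows every resolved value.
#' @export
run_config <- function(tau = 50, epsilon = 0.001, M_max = 50, kmax = 100,
                       bands = standard_bands(),
                       spec = classifier_spec(),
                       channel_policy = "all", seed = 1L) {
  structure(list(tau = tau, epsilon = epsilon, M_max = M_max, kmax = kmax,
                 bands = bands, spec = spec,
                 channel_policy = channel_policy, seed = seed),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  cat(sprintf("  tau = %d samples, epsilon = %g, M_max = %d, kmax = %d\n",
              x$tau, x$epsilon, x$M_max, x$kmax))
  cat(sprintf("  classifier: %s (K = %d, shrinkage = %g, standardize = %s)\n",
              x$spec$kind, x$spec$K, x$spec$shrinkage, x$spec$standardize))
  pol <- if (identical(x$channel_policy, "all")) "all"
         else sprintf("%s:%d", x$channel_policy$mode, x$channel_policy$d)
  cat(sprintf("  channels: %s, seed: %s\n", pol, format(x$seed)))
  cat(sprintf("  bands: %s\n",
              paste(vapply(x$bands, `[[`, character(1), "name"),
                    collapse = ", ")))
  invisible(x)
}
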