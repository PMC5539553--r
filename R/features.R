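# Baseline feature extractors: sub-band band power, autoregressive
# coefficients, and common spatial patterns (CSP).

#' Frequency band definition
#'
#' @param low,high Band edges in Hz, `0 < low < high`.
#' @param name Optional label (defaults to `"low-high Hz"`).
#' @return A `band_definition` list.
#' @export
band_def <- function(low, high, name = sprintf("%g-%g Hz", low, high)) {
  stop_if_not_scalar_pos(low, "low")
  stop_if_not_scalar_pos(high, "high")
  if (high <= low) stop("'high' must exceed 'low'")
  structure(list(low = low, high = high, name = name),
            class = "band_definition")
}

#' Standard sensorimotor-rhythm band set
#'
#' The five 4-Hz sub-bands spanning the mu and beta range (8-12, 12-16,
#' 16-20, 20-24, 24-28 Hz) used for band-power comparison, plus the broad
#' mu (8-13 Hz) and beta (13-30 Hz) bands used for CSP filtering.
#'
#' @return Named list of [band_def()] objects.
#' @export
standard_bands <- function() {
  list(bp1 = band_def(8, 12), bp2 = band_def(12, 16), bp3 = band_def(16, 20),
       bp4 = band_def(20, 24), bp5 = band_def(24, 28),
       mu = band_def(8, 13, "mu"), beta = band_def(13, 30, "beta"))
}

check_band <- function(band, fs) {
  if (!inherits(band, "band_definition")) stop("'band' must be a band_def()")
  if (band$high >= fs / 2)
    stop(sprintf("invalid band: %s exceeds the Nyquist frequency %g Hz",
                 band$name, fs / 2))
  invisible(band)
}

# Zero-phase order-3 Butterworth band-pass of a channels x samples matrix
# (or a vector). Filtering is always per epoch; the epoch is extended by
# reflection before filtering and trimmed afterwards, which suppresses the
# start-up transients of the forward-backward pass.
butter_bandpass <- function(x, low, high, fs, order = 3) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  one <- function(ch) {
    n <- length(ch)
    pad <- min(n - 1L, ceiling(3 * fs / low))
    ext <- c(2 * ch[1] - ch[(pad + 1):2],
             ch,
             2 * ch[n] - ch[(n - 1):(n - pad)])
    signal::filtfilt(bf, ext)[(pad + 1):(pad + n)]
  }
  if (is.matrix(x)) t(apply(x, 1, one)) else one(as.numeric(x))
}

#' Band power of each channel of an epoch
#'
#' Mean squared amplitude of the band-filtered signal, per channel. The
#' default estimator band-pass filters with a zero-phase order-3 Butterworth
#' (the same family used before CSP) and averages the squared samples; a
#' periodogram-integration alternative is available for cross-checking.
#'
#' @param epoch `channels x samples` numeric matrix (a vector is treated as
#'   one channel).
#' @param band A [band_def()].
#' @param fs Sampling rate in Hz.
#' @param method `"butterworth"` (default) or `"periodogram"`.
#' @param log Return log-power instead of linear power (default `FALSE`).
#' @return Numeric vector of per-channel powers (signal units squared).
#' @examples
#' t <- seq_len(1500) / 500
#' band_power(sin(2 * pi * 10 * t), band_def(8, 12), fs = 500)  # ~ 0.5
#' @export
band_power <- function(epoch, band, fs, method = c("butterworth",
                                                   "periodogram"),
                       log = FALSE) {
  method <- match.arg(method)
  check_band(band, fs)
  if (!is.matrix(epoch)) epoch <- matrix(as.numeric(epoch), nrow = 1)
  p <- if (method == "butterworth") {
    filt <- butter_bandpass(epoch, band$low, band$high, fs)
    if (!is.matrix(filt)) filt <- matrix(filt, nrow = 1)
    rowMeans(filt^2)
  } else {
    apply(epoch, 1, function(ch) {
      sp <- stats::spec.pgram(stats::ts(ch, frequency = fs), taper = 0,
                              detrend = FALSE, plot = FALSE)
      sel <- sp$freq >= band$low & sp$freq <= band$high
      # density integrates to var(x)/2 over [0, fs/2]; double for the
      # negative-frequency half
      2 * (fs / length(ch)) * sum(sp$spec[sel])
    })
  }
  if (log) log(p) else p
}

#' Autoregressive coefficients by ordinary least squares
#'
#' Fits `x(t) = a_1 x(t-1) + ... + a_d x(t-d) + e(t)` to the demeaned
#' signal by ordinary least squares on the lagged design matrix.
#'
#' @param x Numeric signal with `length(x) > 10 * order`.
#' @param order Model order `d` (positive integer; the study grid is 2-7).
#' @return Numeric vector of `d` coefficients, with attribute `degenerate`
#'   set to `TRUE` (and coefficients zero) when the design is rank
#'   deficient, e.g. for a constant signal.
#' @examples
#' x <- as.numeric(arima.sim(list(ar = 0.8), 1500))
#' ar_coefficients(x, 1)   # close to 0.8
#' @export
ar_coefficients <- function(x, order) {
  x <- as.numeric(x)
  if (!is_count(order, 1)) stop("'order' must be a positive integer")
  N <- length(x)
  if (N <= 10 * order)
    stop("signal too short: need length > 10 * order")
  x <- x - mean(x)
  y <- x[(order + 1):N]
  X <- vapply(seq_len(order), function(l) x[(order + 1 - l):(N - l)],
              numeric(N - order))
  qx <- qr(X)
  if (qx$rank < order) {
    co <- rep(0, order)
    attr(co, "degenerate") <- TRUE
    return(co)
  }
  co <- as.numeric(qr.coef(qx, y))
  attr(co, "degenerate") <- FALSE
  co
}

#' Concatenated per-channel AR feature vector
#'
#' @param epoch `channels x samples` matrix.
#' @param order AR order `d`; the result has `n_channels * d` entries,
#'   grouped channel by channel.
#' @return Numeric feature vector of length `n_channels * d`.
#' @export
ar_features <- function(epoch, order) {
  if (!is.matrix(epoch)) epoch <- matrix(as.numeric(epoch), nrow = 1)
  as.numeric(t(apply(epoch, 1, ar_coefficients, order = order)))
}

epochs_as_list <- function(epochs) {
  if (is.list(epochs)) return(epochs)
  if (inherits(epochs, "epoch_set"))
    return(lapply(seq_len(dim(epochs$data)[1]),
                  function(i) epochs$data[i, , , drop = TRUE]))
  if (is.array(epochs) && length(dim(epochs)) == 3)
    return(lapply(seq_len(dim(epochs)[1]),
                  function(i) epochs[i, , , drop = TRUE]))
  stop("expected a list of channel x sample matrices, a 3-d array, or an epoch_set")
}

trial_cov <- function(e) {
  C <- tcrossprod(e)
  C / sum(diag(C))
}

#' Fit a common-spatial-patterns model
#'
#' Band-pass filters every epoch (zero-phase order-3 Butterworth), averages
#' the trace-normalized per-trial spatial covariances within each class, and
#' solves the generalized eigenproblem of class A against the composite
#' covariance via whitening. Rows of the spatial transform `W` are ordered
#' by descending generalized eigenvalue, so the first rows maximize class-A
#' variance and the last rows maximize class-B variance.
#'
#' @param epochs_A,epochs_B Epoch collections for the two classes (lists of
#'   `channels x samples` matrices, or 3-d `trials x channels x samples`
#'   arrays). At least two channels and two epochs per class are required;
#'   the spatial covariance of a single channel cannot be decomposed.
#' @param band CSP filter band (default beta, 13-30 Hz).
#' @param fs Sampling rate in Hz.
#' @param p Filter pairs retained by [csp_features()] (default 1).
#' @param class_labels Labels of the two classes (for reporting).
#' @return A `csp_model` with the transform `W` (channels x channels),
#'   eigenvalues, `p`, `band`, `fs` and `class_labels`. When the composite
#'   covariance is rank deficient a small diagonal shrinkage is applied and
#'   recorded in the `shrinkage` field.
#' @export
csp_fit <- function(epochs_A, epochs_B, band = band_def(13, 30, "beta"),
                    fs, p = 1, class_labels = c("A", "B")) {
  ea <- epochs_as_list(epochs_A)
  eb <- epochs_as_list(epochs_B)
  if (length(ea) < 2 || length(eb) < 2)
    stop("need at least 2 epochs per class")
  nc <- nrow(ea[[1]])
  if (is.null(nc) || nc < 2)
    stop("at least two channels are required for CSP")
  check_band(band, fs)
  filt <- function(e) butter_bandpass(e, band$low, band$high, fs)
  CA <- Reduce(`+`, lapply(ea, function(e) trial_cov(filt(e)))) / length(ea)
  CB <- Reduce(`+`, lapply(eb, function(e) trial_cov(filt(e)))) / length(eb)
  Cc <- CA + CB
  ec <- eigen(Cc, symmetric = TRUE)
  shrinkage <- 0
  if (min(ec$values) < 1e-10 * max(ec$values)) {
    shrinkage <- 1e-6
    Cc <- (1 - shrinkage) * Cc + shrinkage * mean(diag(Cc)) * diag(nc)
    ec <- eigen(Cc, symmetric = TRUE)
    message("rank-deficient composite covariance: shrinkage applied")
  }
  P <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)   # whitening
  S <- P %*% CA %*% t(P)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)      # eigenvalues descending
  W <- t(es$vectors) %*% P
  structure(list(W = W, eigenvalues = es$values, p = as.integer(p),
                 band = band, fs = fs, class_labels = class_labels,
                 n_channels = nc, shrinkage = shrinkage),
            class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("CSP model: %d channels, band %s, p = %d\n", x$n_channels,
              x$band$name, x$p))
  cat("eigenvalues:", paste(sprintf("%.3f", x$eigenvalues), collapse = " "),
      "\n")
  invisible(x)
}

#' CSP log-power features of one epoch
#'
#' Projects the band-filtered epoch through the model's spatial transform
#' and returns normalized log variances of the first `p` and last `p`
#' projected rows: `log(var_i / sum(var_selected))`. The normalization makes
#' the features invariant to epoch-wide amplitude scaling.
#'
#' @param epoch `channels x samples` matrix matching the model's channels.
#' @param model A [csp_fit()] model.
#' @param p Filter pairs (default `model$p`); must satisfy
#'   `2 * p <= n_channels`.
#' @return Numeric vector of `2 p` features.
#' @export
csp_features <- function(epoch, model, p = model$p) {
  if (!inherits(model, "csp_model")) stop("'model' must come from csp_fit()")
  if (!is.matrix(epoch) || nrow(epoch) != model$n_channels)
    stop("epoch channel count does not match the CSP model")
  if (!is_count(p, 1) || 2 * p > model$n_channels)
    stop("invalid p: need 2 * p <= number of channels")
  z <- model$W %*% butter_bandpass(epoch, model$band$low, model$band$high,
                                   model$fs)
  nc <- model$n_channels
  sel <- c(seq_len(p), (nc - p + 1):nc)
  v <- apply(z[sel, , drop = FALSE], 1, stats::var)
  if (any(v <= 0)) stop("zero projected power: log-variance undefined")
  log(v / sum(v))
}
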