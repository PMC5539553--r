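# Fractal-dimension estimators: delay embedding, correlation integral /
# dimension, saturation-based GPFD, and the Higuchi method.

#' Delay-coordinate embedding of a scalar time series
#'
#' Reconstructs the phase space of a scalar signal `x` as a set of
#' M-dimensional vectors `y(i) = (x(i), x(i + tau), ..., x(i + (M-1) tau))`
#' for `i = 1, ..., N - (M-1) tau` (1-based indexing).
#'
#' @param x Numeric vector, the signal.
#' @param tau Time delay in samples (positive integer).
#' @param M Embedding dimension (integer >= 1). `M = 1` returns the samples
#'   themselves as 1-dimensional vectors.
#' @return An object of class `delay_embedding` with fields `vectors`
#'   (`Np x M` matrix), `tau`, `M` and `Np = N - (M-1) tau`.
#' @examples
#' emb <- delay_embed(sin(seq_len(200) / 10), tau = 5, M = 3)
#' dim(emb$vectors)
#' @export
delay_embed <- function(x, tau, M) {
  x <- as.numeric(x)
  if (!is_count(tau, 1)) stop("'tau' must be a positive integer")
  if (!is_count(M, 1)) stop("'M' must be an integer >= 1")
  N <- length(x)
  Np <- N - (M - 1L) * tau
  if (Np < 2L)
    stop(sprintf("epoch too short for (tau=%d, M=%d): need N >= %d, have %d",
                 tau, M, (M - 1L) * tau + 2L, N))
  idx <- outer(seq_len(Np), (seq_len(M) - 1L) * tau, `+`)
  structure(
    list(vectors = matrix(x[idx], nrow = Np, ncol = M),
         tau = as.integer(tau), M = as.integer(M), Np = as.integer(Np)),
    class = "delay_embedding")
}

#' @export
print.delay_embedding <- function(x, ...) {
  cat(sprintf("Delay embedding: %d vectors of dimension %d (tau = %d)\n",
              x$Np, x$M, x$tau))
  invisible(x)
}

as_embedding_matrix <- function(emb) {
  if (inherits(emb, "delay_embedding")) return(emb$vectors)
  if (is.matrix(emb)) return(emb)
  stop("expected a 'delay_embedding' or a numeric matrix of points")
}

#' Correlation integral at a single radius
#'
#' Fraction of unordered pairs of embedded vectors whose Euclidean distance
#' is strictly less than `r` (Heaviside convention `H(0) = 0`, so a pair at
#' distance exactly `r` is excluded). Normalized by the number of unordered
#' pairs `Np (Np - 1) / 2`, which keeps the value in `[0, 1]`.
#'
#' @param emb A `delay_embedding` (or a plain `Np x M` matrix of points).
#' @param r Radius, a positive scalar.
#' @return The correlation integral `C(r)`, a probability in `[0, 1]`.
#' @examples
#' emb <- delay_embed(c(0, 1, 2), tau = 1, M = 1)
#' correlation_integral(emb, 1.5)  # 2 of the 3 pairs are closer than 1.5
#' @export
correlation_integral <- function(emb, r) {
  stop_if_not_scalar_pos(r, "r")
  v <- as_embedding_matrix(emb)
  if (nrow(v) < 2L) stop("need at least 2 embedded vectors")
  d <- stats::dist(v)
  mean(d < r)
}

#' Radius grid specification for correlation-dimension fits
#'
#' The scaling region of `log C(r)` versus `log r` is delimited by
#' percentiles of the pairwise-distance distribution: `n_radii` log-spaced
#' radii between the `lo_q` and `hi_q` distance quantiles. The quantiles are
#' estimated on a deterministic systematic subsample of the embedded vectors
#' (`sample_points` evenly spaced vector indices, all pairs among them),
#' which makes the grid cheap for long signals and exact for short ones.
#'
#' @param n_radii Number of radii in the grid (default 24).
#' @param lo_q,hi_q Lower / upper distance quantiles bounding the grid
#'   (defaults 0.05 and 0.50; avoids the noise-dominated small-r tail and
#'   the saturated large-r plateau).
#' @param sample_points Number of evenly spaced vector indices used for the
#'   quantile estimate (default 64, i.e. at most 2016 sampled pairs).
#' @return A list with class `cd_radius_spec`.
#' @export
cd_radius_spec <- function(n_radii = 24, lo_q = 0.05, hi_q = 0.50,
                           sample_points = 64) {
  stopifnot(is_count(n_radii, 5), lo_q > 0, hi_q > lo_q, hi_q <= 1,
            is_count(sample_points, 4))
  structure(list(n_radii = as.integer(n_radii), lo_q = lo_q, hi_q = hi_q,
                 sample_points = as.integer(sample_points)),
            class = "cd_radius_spec")
}

# Radii for one embedding, from the systematic distance subsample.
# Returns a strictly increasing positive vector of length spec$n_radii.
cd_radii <- function(x, tau, M, spec) {
  N <- length(x)
  Np <- N - (M - 1L) * tau
  idx <- unique(round(seq(1L, Np, length.out = min(Np, spec$sample_points))))
  sub <- matrix(x[outer(idx, (seq_len(M) - 1L) * tau, `+`)],
                nrow = length(idx), ncol = M)
  d <- as.numeric(stats::dist(sub))
  if (!any(d > 0)) stop("zero-diameter attractor")
  lo <- stats::quantile(d, spec$lo_q, names = FALSE)
  hi <- stats::quantile(d, spec$hi_q, names = FALSE)
  if (lo <= 0) lo <- min(d[d > 0])
  if (hi <= lo) hi <- lo * (1 + 1e-6)
  exp(seq(log(lo), log(hi), length.out = spec$n_radii))
}

# Least-squares slope of log C on log r over radii with C > 0.
fit_scaling_region <- function(radii, values, min_points = 5) {
  ok <- values > 0
  if (sum(ok) < min_points)
    return(list(slope = NA_real_, r2 = NA_real_, fit_range = c(NA, NA)))
  lr <- log(radii[ok]); lc <- log(values[ok])
  if (stats::var(lc) == 0)   # flat curve: C(r) constant over the grid
    return(list(slope = 0, r2 = 1,
                fit_range = c(min(which(ok)), max(which(ok)))))
  fit <- stats::lm.fit(cbind(1, lr), lc)
  slope <- fit$coefficients[[2]]
  r2 <- 1 - sum(fit$residuals^2) / sum((lc - mean(lc))^2)
  list(slope = slope, r2 = r2, fit_range = c(min(which(ok)), max(which(ok))))
}

new_correlation_curve <- function(radii, values, fitinfo, tau, M) {
  structure(list(radii = radii, values = values,
                 fit_range = fitinfo$fit_range, slope = fitinfo$slope,
                 fit_r2 = fitinfo$r2, tau = tau, M = M),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf(
    "Correlation curve (M = %d, tau = %d): d_c = %.4f (R^2 = %.4f) over %d radii\n",
    x$M, x$tau, x$slope, x$fit_r2, length(x$radii)))
  invisible(x)
}

#' Correlation dimension at a fixed embedding dimension
#'
#' Estimates the Grassberger-Procaccia correlation dimension `d_c(M)`: the
#' slope of `log C(r)` versus `log r` over the scaling region, by linear
#' least squares. Radii come from [cd_radius_spec()] unless given explicitly.
#'
#' @param x Numeric signal, or an `Np x M` matrix of phase-space points (in
#'   which case `tau` and `M` are ignored for the embedding and the matrix
#'   columns are used directly).
#' @param tau Time delay in samples.
#' @param M Embedding dimension.
#' @param radius_spec A [cd_radius_spec()], or a numeric vector of explicit
#'   radii (positive, increasing).
#' @param max_ref Cap on the number of reference vectors: when the
#'   embedding holds more vectors than this, the correlation sum uses every
#'   k-th vector as reference point (paired against all later vectors), the
#'   standard device for long signals. `Inf` (the default here) enumerates
#'   all pairs exactly.
#' @return A `correlation_curve` with fields `radii`, `values` (each in
#'   `[0, 1]`, non-decreasing), `fit_range`, `slope` (= `d_c`) and `fit_r2`.
#' @examples
#' x <- seq(0, 1, length.out = 300)      # points on a line segment
#' correlation_dimension(x, tau = 1, M = 2)$slope  # close to 1
#' @export
correlation_dimension <- function(x, tau = 50, M = 2,
                                  radius_spec = cd_radius_spec(),
                                  max_ref = Inf) {
  if (is.matrix(x)) {
    v <- x
    if (is.numeric(radius_spec)) {
      radii <- radius_spec
    } else {
      d <- as.numeric(stats::dist(v[unique(round(seq(
        1L, nrow(v), length.out = min(nrow(v), radius_spec$sample_points)))),
        , drop = FALSE]))
      if (!any(d > 0)) stop("zero-diameter attractor")
      lo <- stats::quantile(d, radius_spec$lo_q, names = FALSE)
      hi <- stats::quantile(d, radius_spec$hi_q, names = FALSE)
      if (lo <= 0) lo <- min(d[d > 0])
      if (hi <= lo) hi <- lo * (1 + 1e-6)
      radii <- exp(seq(log(lo), log(hi), length.out = radius_spec$n_radii))
    }
    dd <- as.numeric(stats::dist(v))
    values <- vapply(radii, function(r) mean(dd < r), numeric(1))
    fitinfo <- fit_scaling_region(radii, values)
    return(new_correlation_curve(radii, values, fitinfo, NA_integer_,
                                 ncol(v)))
  }
  x <- as.numeric(x)
  if (is.numeric(radius_spec)) {
    radii <- radius_spec
    if (any(radii <= 0) || is.unsorted(radii)) stop("invalid radius grid")
  } else {
    radii <- cd_radii(x, tau, M, radius_spec)
  }
  emb <- delay_embed(x, tau, M)  # validates feasibility
  stride <- if (is.finite(max_ref)) max(1L, ceiling(emb$Np / max_ref)) else 1L
  values <- cpp_corr_curve(x, as.integer(tau), as.integer(M), radii^2,
                           as.integer(stride))
  fitinfo <- fit_scaling_region(radii, values)
  new_correlation_curve(radii, values, fitinfo, as.integer(tau),
                        as.integer(M))
}

#' Grassberger-Procaccia fractal dimension with saturation stopping
#'
#' Computes the correlation dimension `d_c(M)` for increasing embedding
#' dimensions, starting at `M = 2`, and stops at the first `M >= 3` with
#' `|d_c(M) - d_c(M-1)| < epsilon` (saturation). The fractal dimension is
#' the `d_c` value at stopping. If the cap `M_max` (or the largest feasible
#' `M` for the signal length) is reached without saturation the result is
#' returned with `saturated = FALSE` rather than an error; stochastic
#' signals such as white noise behave this way by design, since their
#' correlation dimension keeps growing with `M`.
#'
#' All `d_c(M)` values for one signal are obtained from a single pass over
#' vector pairs (the squared distance at `M + 1` extends the one at `M`), so
#' the cost is close to that of the largest embedding alone.
#'
#' @param x Numeric signal (non-constant).
#' @param tau Time delay in samples (default 50, i.e. 0.1 s at 500 Hz).
#' @param epsilon Saturation tolerance on successive `d_c` values
#'   (default 0.001).
#' @param M_max Cap on the embedding dimension (default 50; the signal
#'   length may impose a smaller feasible cap).
#' @param radius_spec Scaling-region specification, see [cd_radius_spec()].
#' @param max_ref Cap on the number of reference vectors in the correlation
#'   sums (default 300): longer embeddings pair every k-th vector against
#'   all later ones instead of enumerating every pair, cutting the cost by
#'   the subsampling factor with negligible effect on the fitted slope.
#'   Signals short enough to stay under the cap are computed exactly.
#' @return A `gpfd_result` with fields `fd`, `M_final`, `dc_trajectory`
#'   (data.frame of `M` and `dc` up to `M_final`), `saturated`, `epsilon`,
#'   `tau`, and `curve` (the `correlation_curve` at `M_final`).
#' @examples
#' fd <- gpfd(sin(2 * pi * 10 * seq_len(1500) / 500), tau = 12)
#' fd$fd       # near 1: a periodic orbit is one-dimensional
#' @export
gpfd <- function(x, tau = 50, epsilon = 0.001, M_max = 50,
                 radius_spec = cd_radius_spec(), max_ref = 300) {
  x <- as.numeric(x)
  if (!is_count(tau, 1)) stop("'tau' must be a positive integer")
  stop_if_not_scalar_pos(epsilon, "epsilon")
  if (!is_count(M_max, 2)) stop("'M_max' must be an integer >= 2")
  if (stats::sd(x) == 0) stop("constant signal: fractal dimension undefined")
  N <- length(x)
  M_feas <- min(M_max, (N - 2L) %/% tau + 1L)
  if (M_feas < 2L) stop(sprintf("epoch too short for (tau=%d, M=2)", tau))

  # The one-pass kernel computes every d_c(M) up to a cap; evaluate in
  # growing blocks so early saturation (the common case for deterministic
  # or strongly correlated signals) does not pay for the full cap.
  stop_scan <- function(dc, nM) {
    saturated <- FALSE
    M_final <- 2L
    for (k in 2:max(nM, 2)) {
      if (k > nM) break
      if (!is.finite(dc[k])) { M_final <- k; break }  # last finite M
      M_final <- k + 1L
      if (abs(dc[k] - dc[k - 1L]) < epsilon) { saturated <- TRUE; break }
    }
    list(saturated = saturated, M_final = M_final)
  }
  Np2 <- N - tau
  stride <- if (is.finite(max_ref)) max(1L, ceiling(Np2 / max_ref)) else 1L
  caps <- unique(pmin(c(8L, 16L, 32L, M_feas), M_feas))
  for (cap in caps) {
    nM <- cap - 1L
    radii <- vapply(2:cap, function(M) cd_radii(x, tau, M, radius_spec),
                    numeric(radius_spec$n_radii))
    Cmat <- cpp_corr_curves_all(x, as.integer(tau), as.integer(cap),
                                radii^2, as.integer(stride))
    fits <- lapply(seq_len(nM),
                   function(k) fit_scaling_region(radii[, k], Cmat[, k]))
    dc <- vapply(fits, `[[`, numeric(1), "slope")
    if (!is.finite(dc[1L]))
      stop("could not fit a scaling region at M = 2")
    sc <- stop_scan(dc, nM)
    if (sc$saturated || sc$M_final < cap || cap == M_feas) break
  }
  saturated <- sc$saturated
  M_final <- sc$M_final
  kf <- M_final - 1L
  structure(
    list(fd = dc[kf], M_final = M_final,
         dc_trajectory = data.frame(M = 2:M_final, dc = dc[seq_len(kf)]),
         saturated = saturated, epsilon = epsilon, tau = as.integer(tau),
         curve = new_correlation_curve(radii[, kf], Cmat[, kf], fits[[kf]],
                                       as.integer(tau), M_final)),
    class = "gpfd_result")
}

#' @export
print.gpfd_result <- function(x, ...) {
  cat(sprintf("GPFD: fd = %.4f at M = %d (tau = %d, epsilon = %g)%s\n",
              x$fd, x$M_final, x$tau, x$epsilon,
              if (x$saturated) "" else "  [not saturated]"))
  invisible(x)
}

#' Higuchi curve length for one subsampled series
#'
#' Length `L_m(k)` of the curve obtained by subsampling `y` from start index
#' `m` with step `k`:
#' `L_m(k) = (1/k) * (N-1) / (n k) * sum_{i=1}^{n} |y(m + i k) - y(m + (i-1) k)|`
#' with `n = int((N - m)/k)`. The `(N-1)/(n k)` factor normalizes for the
#' number of differences actually available.
#'
#' @param y Numeric signal of length `N`.
#' @param m Start index, `1 <= m <= k`.
#' @param k Time interval (positive integer, `k < N`).
#' @return The curve length `L_m(k)` (non-negative scalar).
#' @export
higuchi_curve_length <- function(y, m, k) {
  y <- as.numeric(y)
  N <- length(y)
  if (!is_count(k, 1) || k >= N) stop("interval exceeds signal")
  if (!is_count(m, 1) || m > k) stop("'m' must satisfy 1 <= m <= k")
  n <- (N - m) %/% k
  if (n < 1) stop("no differences available for (m, k)")
  s <- sum(abs(diff(y[m + (0:n) * k])))
  (1 / k) * ((N - 1) / (n * k)) * s
}

#' Higuchi fractal dimension
#'
#' The mean curve length `L(k)` over start indices `m = 1..k` is computed
#' for `k = 1..kmax`; the fractal dimension is the least-squares slope of
#' `log L(k)` against `log(1/k)`. For one-dimensional signals the value
#' ranges from 1 (deterministic, e.g. a smooth ramp) to 2 (uncorrelated
#' noise).
#'
#' @param y Numeric signal (non-constant).
#' @param kmax Maximum time interval (default 100; must satisfy
#'   `kmax < length(y) / 2`).
#' @return An `hfd_result` with fields `fd`, `k_values`, `lengths` (`L(k)`),
#'   `fit_r2` and `kmax`.
#' @examples
#' hfd(seq_len(1500))$fd          # exactly 1 for a noiseless ramp
#' @export
hfd <- function(y, kmax = 100) {
  y <- as.numeric(y)
  N <- length(y)
  if (!is_count(kmax, 2)) stop("'kmax' must be an integer >= 2")
  if (kmax >= N / 2) stop("'kmax' must be below half the signal length")
  if (stats::sd(y) == 0) stop("zero curve length, FD undefined")
  L <- cpp_higuchi_lengths(y, as.integer(kmax))
  k <- seq_len(kmax)
  ok <- is.finite(L) & L > 0
  if (sum(ok) < 2) stop("zero curve length, FD undefined")
  lx <- log(1 / k[ok]); ly <- log(L[ok])
  fit <- stats::lm.fit(cbind(1, lx), ly)
  r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)
  structure(list(fd = fit$coefficients[[2]], k_values = k, lengths = L,
                 fit_r2 = r2, kmax = as.integer(kmax)),
            class = "hfd_result")
}

#' @export
print.hfd_result <- function(x, ...) {
  cat(sprintf("HFD: fd = %.4f (kmax = %d, fit R^2 = %.4f)\n",
              x$fd, x$kmax, x$fit_r2))
  invisible(x)
}
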