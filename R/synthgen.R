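# Synthetic-data generator: reference signals of known fractal dimension
# and multi-channel two-class sessions with planted class structure.

#' Fractional Brownian motion by circulant embedding
#'
#' Exact-covariance fractional Gaussian noise via the Davies-Harte
#' circulant-embedding construction, cumulated to fractional Brownian
#' motion. The increments have the exact fGn autocovariance
#' `gamma(k) = 0.5 (|k+1|^2H - 2|k|^2H + |k-1|^2H)`.
#'
#' @param N Number of samples (the returned path has length `N`).
#' @param H Hurst exponent in `(0, 1)`; the Higuchi fractal dimension of
#'   the path is `2 - H`.
#' @param seed Optional seed; the caller's RNG stream is left untouched.
#' @return Numeric vector of length `N` (`B(1), ..., B(N)` with `B(0) = 0`
#'   dropped).
#' @examples
#' b <- gen_fbm(1500, H = 0.5, seed = 1)
#' @export
gen_fbm <- function(N, H, seed = NULL) {
  if (!is_count(N, 2)) stop("'N' must be an integer >= 2")
  if (!(is.numeric(H) && length(H) == 1 && H > 0 && H < 1))
    stop("'H' must lie strictly inside (0, 1)")
  g <- function(k) 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                            abs(k - 1)^(2 * H))
  m <- 2L * N
  row <- g(c(0:N, (N - 1):1))            # circulant first row, length 2N
  lam <- Re(stats::fft(row))
  lam[lam < 0 & lam > -1e-8] <- 0
  if (any(lam < 0)) stop("circulant embedding is not nonnegative definite")
  fgn <- with_seed(seed, {
    half <- m %/% 2
    w <- complex(length.out = m)
    w[1] <- sqrt(lam[1] / m) * stats::rnorm(1)
    w[half + 1] <- sqrt(lam[half + 1] / m) * stats::rnorm(1)
    u <- stats::rnorm(half - 1)
    v <- stats::rnorm(half - 1)
    k <- 2:half
    w[k] <- sqrt(lam[k] / (2 * m)) * complex(real = u, imaginary = v)
    w[m + 2 - k] <- Conj(w[k])
    Re(stats::fft(w))[seq_len(N)]
  })
  cumsum(fgn)
}

#' Reference signals of known fractal dimension
#'
#' A validation battery for the estimators: signals whose fractal (or
#' correlation) dimension is known analytically or well established.
#'
#' @param kind One of `"line"` (slope `a`, FD 1), `"sine"` (frequency
#'   `freq` Hz at `fs` Hz, FD 1), `"white_noise"` (FD 2 in the Higuchi
#'   sense), `"fbm"` (Hurst `H`, FD `2 - H`), `"lorenz"` (x-coordinate of
#'   the Lorenz system at the classical parameters, correlation dimension
#'   approximately 2.05).
#' @param N Number of samples.
#' @param params Named list of kind-specific parameters: `a` (line slope,
#'   default 1), `freq` and `fs` (sine, defaults 10 and 500), `H` (fbm,
#'   default 0.5), `dt` and `transient` (lorenz, defaults 0.01 and 10000
#'   discarded steps).
#' @param seed Optional seed for the stochastic kinds.
#' @return A `reference_signal` with `samples`, `kind`, `true_dimension`
#'   and `params`. `true_dimension` is only recorded for kinds with an
#'   analytic or established value.
#' @export
gen_reference <- function(kind = c("line", "sine", "white_noise", "fbm",
                                   "lorenz"),
                          N = 1500, params = list(), seed = NULL) {
  kind <- match.arg(kind)
  if (!is_count(N, 10)) stop("'N' must be an integer >= 10")
  p <- params
  out <- switch(kind,
    line = {
      a <- p$a %||% 1
      list(x = a * seq_len(N), d = 1)
    },
    sine = {
      freq <- p$freq %||% 10; fs <- p$fs %||% 500
      list(x = sin(2 * pi * freq * seq_len(N) / fs), d = 1)
    },
    white_noise = list(x = with_seed(seed, stats::rnorm(N)), d = 2),
    fbm = {
      H <- p$H %||% 0.5
      list(x = gen_fbm(N, H, seed = seed), d = 2 - H)
    },
    lorenz = {
      dt <- p$dt %||% 0.01
      transient <- p$transient %||% 10000L
      x <- lorenz_x(N, dt, transient)
      list(x = x, d = 2.05)
    })
  structure(list(kind = kind, samples = out$x, true_dimension = out$d,
                 params = p), class = "reference_signal")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# x-coordinate of the Lorenz system (sigma 10, rho 28, beta 8/3),
# integrated with fixed-step classical Runge-Kutta; transient discarded.
lorenz_x <- function(N, dt = 0.01, transient = 10000L) {
  deriv <- function(t, y, parms) {
    list(c(parms["sigma"] * (y[2] - y[1]),
           y[1] * (parms["rho"] - y[3]) - y[2],
           y[1] * y[2] - parms["beta"] * y[3]))
  }
  times <- seq(0, (N + transient) * dt, by = dt)
  sol <- deSolve::rk4(y = c(1, 1, 1), times = times, func = deriv,
                      parms = c(sigma = 10, rho = 28, beta = 8 / 3))
  sol[(transient + 1):(transient + N), 2]
}

#' Session specification for the synthetic generator
#'
#' Describes a two-class (resting vs. imagery) multi-channel session:
#' 30 channels of the 10-20 montage, 500 Hz, 3-s epochs, 40 epochs per
#' class by default. Class structure is planted on the informative channels
#' as a Hurst shift of the fractional-Brownian-motion backbone (imagery
#' epochs are rougher or smoother) and/or a band-limited sinusoidal
#' component with class-dependent amplitude.
#'
#' @param n_channels Number of channels (default 30).
#' @param fs Sampling rate in Hz (default 500).
#' @param epoch_seconds Epoch length in seconds (default 3).
#' @param epochs_per_class Epochs per class (default 40).
#' @param informative_channels Channel names or indices carrying the
#'   planted effect (default C3, CZ, C4).
#' @param hurst_shift Hurst increment on informative channels for the
#'   imagery class (default 0.2; set 0 for a no-effect session).
#' @param band_power_shift Optional `list(band = band_def(...), ratio)`:
#'   a sinusoid at the band center is added to every channel and its
#'   amplitude is multiplied by `sqrt(ratio)` on informative channels of
#'   imagery epochs.
#' @param baseline_hurst Baseline Hurst exponent `H0` (default 0.6;
#'   `H0 + hurst_shift` must stay inside `(0, 1)`).
#' @param noise_sd White measurement noise standard deviation relative to
#'   the unit-variance backbone (default 0.02; Higuchi estimates are
#'   sensitive to broadband noise, so this sets the signal-to-noise regime
#'   the planted complexity effect is detectable in).
#' @param seed Seed governing the whole session (reproducible bit for
#'   bit).
#' @return A `session_spec`.
#' @export
session_spec <- function(n_channels = 30, fs = 500, epoch_seconds = 3,
                         epochs_per_class = 40,
                         informative_channels = c("C3", "CZ", "C4"),
                         hurst_shift = 0.2, band_power_shift = NULL,
                         baseline_hurst = 0.6, noise_sd = 0.02,
                         seed = NULL) {
  stopifnot(is_count(n_channels, 1), fs > 0, epoch_seconds > 0,
            is_count(epochs_per_class, 2))
  ch <- montage_1020(n_channels)
  if (missing(informative_channels) &&
      !all(c("C3", "CZ", "C4") %in% ch)) {
    # small montages: plant the effect on the leading channels instead
    informative_channels <- seq_len(min(3L, n_channels))
  }
  info <- if (is.character(informative_channels))
    match(toupper(informative_channels), ch)
  else as.integer(informative_channels)
  if (anyNA(info) || any(info < 1 | info > n_channels))
    stop("informative_channels must be a subset of the montage")
  H0 <- baseline_hurst
  if (!(H0 > 0 && H0 < 1 && H0 + hurst_shift > 0 && H0 + hurst_shift < 1))
    stop("baseline_hurst and baseline_hurst + hurst_shift must lie in (0, 1)")
  if (!is.null(band_power_shift)) {
    stopifnot(inherits(band_power_shift$band, "band_definition"),
              band_power_shift$ratio > 0)
  }
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 epoch_seconds = epoch_seconds,
                 epochs_per_class = as.integer(epochs_per_class),
                 informative_channels = info, hurst_shift = hurst_shift,
                 band_power_shift = band_power_shift,
                 baseline_hurst = H0, noise_sd = noise_sd, seed = seed,
                 channel_names = ch),
            class = "session_spec")
}

#' Standard 10-20 montage labels
#'
#' The 30-channel analysis montage (reference and ground electrodes
#' excluded).
#'
#' @param n Number of leading channels to return (default 30).
#' @return Character vector of channel labels.
#' @export
montage_1020 <- function(n = 30) {
  ch <- c("FP1", "FP2", "F7", "F3", "FZ", "F4", "F8",
          "FT7", "FC3", "FCZ", "FC4", "FT8",
          "T3", "C3", "CZ", "C4", "T4",
          "TP7", "CP3", "CPZ", "CP4", "TP8",
          "T5", "P3", "PZ", "P4", "T6",
          "O1", "OZ", "O2")
  if (n <= length(ch)) ch[seq_len(n)]
  else c(ch, paste0("X", seq_len(n - length(ch))))
}

#' Generate a synthetic two-class session
#'
#' Every epoch of every channel is a unit-variance fractional-Brownian-
#' motion backbone plus white measurement noise; on the informative
#' channels the imagery class uses Hurst `H0 + hurst_shift` (a complexity
#' shift, which is exactly what fractal-dimension features respond to) and,
#' when configured, a stronger band-limited sinusoidal component. Labels
#' are balanced (class 0 = resting, class 1 = imagery) and the whole
#' session is reproducible from the spec seed alone.
#'
#' @param spec A [session_spec()].
#' @return An [epoch_set()] of dimension
#'   `2 * epochs_per_class x n_channels x fs * epoch_seconds`.
#' @examples
#' ses <- gen_session(session_spec(n_channels = 4, epochs_per_class = 3,
#'                                 seed = 1))
#' dim(ses$data)
#' @export
gen_session <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  ns <- as.integer(round(spec$fs * spec$epoch_seconds))
  nt <- 2L * spec$epochs_per_class
  nc <- spec$n_channels
  labels <- rep(c(0L, 1L), each = spec$epochs_per_class)
  seeds <- derive_seeds(spec$seed %||% stats::runif(1, 1, 2^30), nt * nc)
  dat <- array(NA_real_, dim = c(nt, nc, ns))
  bps <- spec$band_power_shift
  f0 <- if (!is.null(bps)) (bps$band$low + bps$band$high) / 2 else NULL
  for (t in seq_len(nt)) {
    for (c_ in seq_len(nc)) {
      inform <- c_ %in% spec$informative_channels
      H <- spec$baseline_hurst +
        if (inform && labels[t] == 1L) spec$hurst_shift else 0
      sd_i <- seeds[(t - 1L) * nc + c_]
      x <- with_seed(sd_i, {
        b <- gen_fbm(ns, H)
        b <- (b - mean(b)) / stats::sd(b)
        if (!is.null(bps)) {
          amp <- 0.5 * if (inform && labels[t] == 1L) sqrt(bps$ratio) else 1
          b <- b + amp * sin(2 * pi * f0 * seq_len(ns) / spec$fs +
                               stats::runif(1, 0, 2 * pi))
        }
        b + spec$noise_sd * stats::rnorm(ns)
      })
      dat[t, c_, ] <- x
    }
  }
  epoch_set(dat, fs = spec$fs, channel_names = spec$channel_names,
            labels = labels, task = "imagery-vs-resting (synthetic)")
}

#' Recording-session duration arithmetic
#'
#' Duration of a cue-based motor-imagery collection session: each trial is
#' a ready-to-start period plus an imagery period, repeated over several
#' runs with breaks in between.
#'
#' @param trial_seconds Seconds per trial (default 8: 5-s ready + 3-s
#'   imagery).
#' @param trials_per_run Trials per run (default 40).
#' @param runs Number of runs (default 3).
#' @param break_seconds Seconds per inter-run break (default 120).
#' @param n_breaks Number of breaks (default `runs - 1`).
#' @return Total session duration in seconds (1200 s = 20 min with the
#'   defaults).
#' @export
session_duration <- function(trial_seconds = 8, trials_per_run = 40,
                             runs = 3, break_seconds = 120,
                             n_breaks = runs - 1) {
  trial_seconds * trials_per_run * runs + break_seconds * n_breaks
}
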