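#' Parameters of the synthetic four-lobe pulse model
#'
#' The continuous beat is a sum of four Gaussian lobes (systolic, reflected,
#' mid-late systolic "curvature", diastolic) multiplied by a smooth
#' exponential decay that switches on past the diastolic lobe:
#' \deqn{f(t) = \left[\sum_k A_k e^{-(t-\mu_k)^2/2\sigma_k^2}\right]
#'       e^{-\lambda\, s(t-\mu_4)}}
#' where \eqn{s(u) = \log(1 + e^{\kappa u})/\kappa} is a softplus ramp.
#' The model produces every fiducial of interest (foot, systolic peak,
#' dicrotic notch, diastolic peak, alternating second-derivative extrema)
#' with a continuous, infinitely differentiable functional form, so analytic
#' truths can be computed by adaptive quadrature and high-resolution
#' optimization on the continuous function rather than on a sample grid.
#'
#' @param amplitudes,centers,widths numeric length-4: Gaussian component
#'   amplitude (arbitrary units), center (s) and SD width (s). Centers must
#'   be strictly increasing, widths positive.
#' @param decay_rate diastolic exponential decay rate (1/s).
#' @param period beat duration (s).
#' @param morph_c multiplier on the third (mid-late systolic) component
#'   amplitude: the curvature morph of the c-wave.
#' @return A `beat_params` list.
#' @export
beat_params <- function(amplitudes = c(1.00, 0.42, 0.18, 0.24),
                        centers    = c(0.125, 0.220, 0.310, 0.445),
                        widths     = c(0.042, 0.060, 0.042, 0.075),
                        decay_rate = 3.0,
                        period     = 0.80,
                        morph_c    = 1.0) {
  stopifnot(length(amplitudes) == 4, length(centers) == 4, length(widths) == 4)
  if (any(diff(centers) <= 0)) stop("component centers must be strictly increasing")
  if (any(widths <= 0)) stop("component widths must be positive")
  if (period <= centers[4]) stop("period must exceed the diastolic center")
  structure(list(amplitudes = amplitudes, centers = centers, widths = widths,
                 decay_rate = decay_rate, period = period, morph_c = morph_c),
            class = "beat_params")
}

#' Continuous beat function for a parameter set
#'
#' @param params a `beat_params`.
#' @return A vectorized function of time (s) returning raw (pre-normalization)
#'   amplitude.
#' @export
beat_function <- function(params) {
  A <- params$amplitudes
  A[3] <- A[3] * params$morph_c
  mu <- params$centers; sg <- params$widths
  lam <- params$decay_rate; kap <- 60
  function(t) {
    g <- A[1] * exp(-(t - mu[1])^2 / (2 * sg[1]^2)) +
         A[2] * exp(-(t - mu[2])^2 / (2 * sg[2]^2)) +
         A[3] * exp(-(t - mu[3])^2 / (2 * sg[3]^2)) +
         A[4] * exp(-(t - mu[4])^2 / (2 * sg[4]^2))
    u <- kap * (t - mu[4])
    soft <- ifelse(u > 30, u, log1p(exp(pmin(u, 30)))) / kap
    g * exp(-lam * soft)
  }
}

# numerical derivatives of a continuous function (five-point central
# differences, step 1e-4 s: truncation error << the 2-sample tolerances the
# truth record is used with)
.fd1 <- function(f, t, h = 1e-4)
  (-f(t + 2 * h) + 8 * f(t + h) - 8 * f(t - h) + f(t - 2 * h)) / (12 * h)
.fd2 <- function(f, t, h = 1e-4)
  (-f(t + 2 * h) + 16 * f(t + h) - 30 * f(t) + 16 * f(t - h) - f(t - 2 * h)) /
  (12 * h^2)

# locate local extrema of g on [lo, hi] by dense scan + golden refinement
.local_extrema <- function(g, lo, hi, n_grid = 4000) {
  tt <- seq(lo, hi, length.out = n_grid)
  y <- g(tt)
  out <- list()
  for (i in 2:(n_grid - 1)) {
    if (y[i] > y[i - 1] && y[i] >= y[i + 1]) {
      o <- stats::optimize(g, c(tt[i - 1], tt[i + 1]), maximum = TRUE,
                           tol = 1e-9)
      out[[length(out) + 1]] <- c(t = o$maximum, value = o$objective, type = 1)
    } else if (y[i] < y[i - 1] && y[i] <= y[i + 1]) {
      o <- stats::optimize(g, c(tt[i - 1], tt[i + 1]), tol = 1e-9)
      out[[length(out) + 1]] <- c(t = o$minimum, value = o$objective, type = -1)
    }
  }
  if (!length(out)) return(data.frame(t = numeric(0), value = numeric(0),
                                      type = numeric(0)))
  as.data.frame(do.call(rbind, out))
}

#' Generate one synthetic beat with its ground-truth record
#'
#' Evaluates the continuous four-lobe model on a uniform grid and computes
#' truth on the continuous function: fiducial times by high-resolution
#' optimization, areas of the normalized contour by adaptive quadrature.
#'
#' @param params a `beat_params`.
#' @param sampling_rate samples per second (default 250 Hz).
#' @return list with `pulse` (a normalized `pulse_wave`), `raw` (raw grid
#'   samples) and `truth`: `t_sys`, `t_notch`, `t_dia`, `t_a`..`t_e`,
#'   `d2_a`..`d2_e` (second derivative of the *normalized* continuous beat),
#'   `A1`, `A2` (quadrature areas of the normalized beat), `f_min`, `f_max`.
#' @export
generate_beat <- function(params, sampling_rate = 250) {
  stopifnot(inherits(params, "beat_params"), sampling_rate > 0)
  f <- beat_function(params)
  T <- params$period
  tt <- seq(0, T, by = 1 / sampling_rate)
  raw <- f(tt)

  # continuous min / max for normalization truth
  grid <- seq(0, T, length.out = 8000)
  fg <- f(grid)
  i_max <- which.max(fg)
  o <- stats::optimize(f, c(grid[max(1, i_max - 1)], grid[min(8000, i_max + 1)]),
                       maximum = TRUE, tol = 1e-10)
  f_max <- o$objective; t_sys <- o$maximum
  f_min <- min(f(0), f(T), min(fg))
  fn <- function(t) (f(t) - f_min) / (f_max - f_min)   # normalized continuous beat

  # dicrotic notch: earliest local minimum of f between systolic peak and end
  mins <- .local_extrema(f, t_sys, T)
  mins <- mins[mins$type < 0 & mins$t < params$centers[4] + 2 * params$widths[4], ]
  maxs <- .local_extrema(f, t_sys + 1e-3, T)
  maxs <- maxs[maxs$type > 0, ]
  t_notch <- if (nrow(mins)) mins$t[1] else NA_real_
  t_dia <- if (nrow(maxs)) maxs$t[which.max(maxs$value)] else NA_real_
  if (!is.na(t_notch) && !is.na(t_dia) && t_dia < t_notch) t_dia <- NA_real_

  # a-e: alternating extrema of the second derivative of the normalized beat
  d2n <- function(t) .fd2(fn, t)
  ex <- .local_extrema(d2n, 0.005, min(if (is.na(t_notch)) T else 1.2 * t_notch,
                                       T - 0.005), n_grid = 6000)
  abcde <- rep(NA_real_, 5); abcde_amp <- rep(NA_real_, 5)
  # a = first max; then alternate min/max
  want <- c(1, -1, 1, -1, 1)
  j <- 1
  for (i in seq_len(nrow(ex))) {
    if (j > 5) break
    if (ex$type[i] == want[j]) {
      abcde[j] <- ex$t[i]; abcde_amp[j] <- ex$value[i]; j <- j + 1
    }
  }

  # areas of the normalized beat by adaptive quadrature
  A1 <- A2 <- NA_real_
  if (!is.na(t_notch)) {
    A1 <- stats::integrate(fn, 0, t_notch, rel.tol = 1e-9,
                           subdivisions = 500)$value
    A2 <- stats::integrate(fn, t_notch, T, rel.tol = 1e-9,
                           subdivisions = 500)$value
  }

  truth <- list(t_sys = t_sys, t_notch = t_notch, t_dia = t_dia,
                t_a = abcde[1], t_b = abcde[2], t_c = abcde[3],
                t_d = abcde[4], t_e = abcde[5],
                d2_a = abcde_amp[1], d2_b = abcde_amp[2], d2_c = abcde_amp[3],
                d2_d = abcde_amp[4], d2_e = abcde_amp[5],
                A1 = A1, A2 = A2, f_min = f_min, f_max = f_max,
                period = T)
  list(pulse = normalize_pulse(raw, 1 / sampling_rate), raw = raw,
       truth = truth, params = params, sampling_rate = sampling_rate)
}

#' Generate a multi-beat PPG train with noise and period jitter
#'
#' Concatenates jittered repeats of the continuous beat (each beat's period
#' scaled by an independent lognormal jitter) and adds white Gaussian noise.
#' Ground-truth foot sample indices are recorded for segmentation oracles.
#'
#' @param params a `beat_params`.
#' @param n_beats number of beats (>= 3).
#' @param sampling_rate Hz.
#' @param noise_sd additive Gaussian noise SD, in raw amplitude units.
#' @param period_jitter_sd SD of the relative period jitter (e.g. 0.02).
#' @param seed integer seed (mandatory: trains are reproducible).
#' @return list with `samples`, `sampling_rate`, `foot_idx` (true foot
#'   sample indices, 1-based), `beat_periods` (s) and `seed`.
#' @export
generate_beat_train <- function(params, n_beats = 15, sampling_rate = 250,
                                noise_sd = 0, period_jitter_sd = 0, seed = 1) {
  stopifnot(inherits(params, "beat_params"))
  if (n_beats < 3) stop("need at least 3 beats")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  set.seed(seed)
  jit <- exp(stats::rnorm(n_beats, 0, period_jitter_sd))
  periods <- params$period * jit
  dt <- 1 / sampling_rate
  samples <- numeric(0); foot_idx <- integer(0)
  for (k in seq_len(n_beats)) {
    pk <- params; pk$period <- periods[k]
    # stretch the time axis of the canonical beat to the jittered period
    f <- beat_function(params)
    nk <- round(periods[k] * sampling_rate)
    tk <- seq(0, length.out = nk, by = dt) * (params$period / periods[k])
    foot_idx <- c(foot_idx, length(samples) + 1L)
    samples <- c(samples, f(tk))
  }
  if (noise_sd > 0) samples <- samples + stats::rnorm(length(samples), 0, noise_sd)
  list(samples = samples, sampling_rate = sampling_rate, foot_idx = foot_idx,
       beat_periods = periods, seed = seed)
}
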