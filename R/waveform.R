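#' Pulse wave container
#'
#' A `pulse_wave` holds one amplitude-normalized, ensemble-averaged PPG beat:
#' samples scaled to `[0, 1]`, a sampling interval `dt` in seconds, and the
#' beat period `period_T = (n - 1) * dt`.
#'
#' @param samples numeric vector of amplitudes, min 0 and max 1.
#' @param dt sampling interval in seconds.
#' @return An object of class `pulse_wave`.
#' @export
pulse_wave <- function(samples, dt) {
  stopifnot(is.numeric(samples), length(samples) >= 4, is.finite(dt), dt > 0)
  if (abs(min(samples)) > 1e-9 || abs(max(samples) - 1) > 1e-9)
    stop("pulse_wave samples must be normalized to [0, 1]; use normalize_pulse()")
  structure(list(samples = as.numeric(samples), dt = dt,
                 period_T = (length(samples) - 1) * dt),
            class = "pulse_wave")
}

#' @export
print.pulse_wave <- function(x, ...) {
  cat(sprintf("<pulse_wave> %d samples, dt = %.4g s, T = %.4g s\n",
              length(x$samples), x$dt, x$period_T))
  invisible(x)
}

#' Time axis of a pulse wave (seconds, foot at 0)
#' @param pulse a `pulse_wave`.
#' @return numeric vector of sample times.
#' @export
pulse_time <- function(pulse) (seq_along(pulse$samples) - 1) * pulse$dt

#' Min-max normalize a beat to the unit interval
#'
#' Scales amplitudes so that the minimum maps to 0 and the maximum to 1,
#' with the time axis in seconds and the beat foot at t = 0. Idempotent.
#'
#' @param beat numeric amplitude sequence (arbitrary units).
#' @param dt sampling interval in seconds.
#' @return A `pulse_wave`.
#' @export
normalize_pulse <- function(beat, dt) {
  stopifnot(is.numeric(beat), length(beat) >= 4)
  rng <- range(beat)
  if (diff(rng) <= 0) stop("cannot normalize a constant beat (zero amplitude range)")
  pulse_wave((beat - rng[1]) / diff(rng), dt)
}

#' Segment a PPG recording into foot-to-foot beats
#'
#' Beat onsets are located as the local minimum of the signal inside a
#' 250 ms window preceding each maximum-upslope point (local maximum of the
#' first derivative exceeding `upslope_frac` of the global derivative
#' maximum, with a 300 ms refractory period). Beats shorter than 0.3 s or
#' longer than 2 s are discarded.
#'
#' @param samples raw signal samples (arbitrary units).
#' @param sampling_rate samples per second (Hz).
#' @param upslope_frac fraction of the maximum upslope a derivative peak
#'   must reach to count as a beat upstroke.
#' @param foot_window_s length of the pre-upstroke search window for the
#'   beat foot, in seconds.
#' @return A list with `beats` (list of numeric vectors, foot-to-foot) and
#'   `foot_idx` (1-based sample indices of each detected foot).
#' @export
segment_beats <- function(samples, sampling_rate, upslope_frac = 0.4,
                          foot_window_s = 0.25) {
  stopifnot(is.numeric(samples), sampling_rate > 0)
  n <- length(samples)
  if (n < 2 * sampling_rate)
    stop("signal too short for segmentation (need at least 2 s)")
  dt <- 1 / sampling_rate
  # smooth before differentiation and foot search to suppress sample noise
  win <- as.integer(max(5, round(0.04 * sampling_rate)))
  if (win %% 2L == 0L) win <- win + 1L
  sm <- sgolay_deriv(samples, dt, window = win, poly_order = 3, deriv = 0)
  d1 <- sgolay_deriv(samples, dt, window = win, poly_order = 3, deriv = 1)
  thr <- upslope_frac * max(d1)
  if (!is.finite(thr) || thr <= 0) stop("insufficient beats: no rising edges found")
  refract <- max(1L, round(0.3 * sampling_rate))
  # local maxima of d1 above threshold, earliest sample on ties
  is_peak <- d1 >= thr &
    d1 > c(-Inf, d1[-n]) &
    d1 >= c(d1[-1], -Inf)
  peaks <- which(is_peak)
  keep <- integer(0)
  last <- -Inf
  for (p in peaks) {
    if (p - last >= refract) { keep <- c(keep, p); last <- p }
  }
  fw <- as.integer(max(1, round(foot_window_s * sampling_rate)))
  feet <- vapply(keep, function(p) {
    lo <- max(1L, as.integer(p) - fw)
    seg <- sm[lo:p]
    m <- length(seg)
    # last local minimum of the smoothed signal before the upslope; on a
    # monotone-decaying tail (no interior minimum) fall back to the last
    # sample attaining the window minimum
    cand <- NA_integer_
    if (m >= 3) {
      interior <- 2:(m - 1)
      is_min <- seg[interior] < seg[interior - 1] &
        seg[interior] <= seg[interior + 1]
      if (any(is_min)) cand <- lo + interior[max(which(is_min))] - 1L
    }
    if (is.na(cand)) cand <- lo + max(which(seg == min(seg))) - 1L
    # refine on the raw samples around the smoothed candidate (recovers the
    # exact junction minimum when the signal is clean)
    h <- (win - 1L) %/% 2L
    rlo <- max(lo, cand - h); rhi <- min(p, cand + h)
    rlo + max(which(samples[rlo:rhi] == min(samples[rlo:rhi]))) - 1L
  }, integer(1))
  feet <- unique(feet)
  if (length(feet) < 4) stop("insufficient beats")
  beats <- list(); foot_idx <- integer(0)
  for (i in seq_len(length(feet) - 1)) {
    len_s <- (feet[i + 1] - feet[i]) * dt
    if (len_s < 0.3 || len_s > 2.0) next
    beats[[length(beats) + 1]] <- samples[feet[i]:feet[i + 1]]
    foot_idx <- c(foot_idx, feet[i])
  }
  if (length(beats) < 3) stop("insufficient beats")
  list(beats = beats, foot_idx = foot_idx, dt = dt)
}

#' Ensemble-average segmented beats into one representative pulse
#'
#' Beats are linearly resampled to the median beat length, averaged
#' pointwise, and min-max normalized. Only beats falling within the first
#' `window_s` seconds of cumulative duration are used (the field-standard
#' 10-15 s averaging window).
#'
#' @param beats list of numeric beat vectors (foot-to-foot).
#' @param dt sampling interval in seconds.
#' @param window_s averaging window in seconds (default 15).
#' @return A `pulse_wave` whose `period_T` is the median beat duration.
#' @export
ensemble_average <- function(beats, dt, window_s = 15) {
  if (length(beats) == 0) stop("empty beat list")
  durs <- vapply(beats, function(b) (length(b) - 1) * dt, numeric(1))
  cum <- cumsum(durs)
  use <- which(cum <= window_s)
  if (length(use) < 3) use <- seq_len(min(length(beats), 3))
  if (length(use) < 3) stop("need at least 3 beats to ensemble average")
  beats <- beats[use]
  lens <- vapply(beats, length, integer(1))
  m <- round(stats::median(lens))
  aligned <- vapply(beats, function(b) {
    stats::approx(seq(0, 1, length.out = length(b)), b,
                  xout = seq(0, 1, length.out = m))$y
  }, numeric(m))
  avg <- rowMeans(aligned)
  pw <- normalize_pulse(avg, dt)
  pw$period_T <- stats::median(durs[seq_along(beats)])
  pw
}

#' Savitzky-Golay smoothed derivative
#'
#' Local least-squares polynomial fit in a sliding window; the derivative of
#' the fitted polynomial is evaluated at each sample. Interior samples use
#' the centered window (a single convolution); edge samples reuse the first
#' or last full window with the polynomial evaluated off-center, so the
#' output has the same length as the input.
#'
#' @param x numeric signal.
#' @param dt sampling interval (s).
#' @param window odd window length in samples.
#' @param poly_order polynomial order (must be < window).
#' @param deriv derivative order (0 = smoothing).
#' @return numeric vector, same length as `x`, in units of `x` per s^deriv.
#' @keywords internal
sgolay_deriv <- function(x, dt, window, poly_order = 4, deriv = 1) {
  n <- length(x)
  if (window %% 2 == 0) window <- window + 1
  if (window <= poly_order) stop("window must exceed poly_order")
  if (window > n) stop("smoothing window larger than the signal")
  h <- (window - 1L) %/% 2L
  # basis in sample units for conditioning; rescale by dt^deriv at the end
  s <- -h:h
  X <- outer(s, 0:poly_order, `^`)
  P <- solve(crossprod(X), t(X))          # (poly_order+1) x window
  dfac <- function(k, d) if (k < d) 0 else factorial(k) / factorial(k - d)
  # derivative of the local fit at offset j samples from the window center
  eval_row <- function(j) {
    w <- vapply(0:poly_order, function(k)
      dfac(k, deriv) * j^(max(k - deriv, 0)), numeric(1))
    as.numeric(w %*% P)
  }
  out <- numeric(n)
  ctr <- eval_row(0)
  # interior via filter (convolution with reversed kernel)
  interior <- stats::filter(x, rev(ctr), sides = 2)
  out[(h + 1):(n - h)] <- interior[(h + 1):(n - h)]
  # edges: fit on the first/last window, evaluate off-center
  for (i in 1:h) {
    out[i] <- sum(eval_row(i - 1 - h) * x[1:window])
    j <- n - h + i
    out[j] <- sum(eval_row(i) * x[(n - window + 1):n])
  }
  out / dt^deriv
}

#' First and second derivatives of a pulse wave
#'
#' Smoothed polynomial-filter (Savitzky-Golay) derivatives. The second
#' derivative is obtained directly from the local polynomial fit, so it is
#' consistent with the first derivative under the same smoothing.
#'
#' @param pulse a `pulse_wave`.
#' @param smoothing_window_s filter window in seconds (default 0.05).
#' @param poly_order local polynomial order (default 4: order 3 biases the
#'   positions of second-derivative landmarks by several milliseconds).
#' @return An object of class `derivative_pair` with elements `d1` (1/s),
#'   `d2` (1/s^2) and `dt`.
#' @export
derivatives <- function(pulse, smoothing_window_s = 0.05, poly_order = 4) {
  stopifnot(inherits(pulse, "pulse_wave"))
  w <- round(smoothing_window_s / pulse$dt)
  if (w %% 2 == 0) w <- w + 1
  w <- max(w, poly_order + 2)
  if (w > length(pulse$samples)) stop("smoothing window larger than the beat")
  structure(list(
    d1 = sgolay_deriv(pulse$samples, pulse$dt, w, poly_order, 1),
    d2 = sgolay_deriv(pulse$samples, pulse$dt, w, poly_order, 2),
    dt = pulse$dt
  ), class = "derivative_pair")
}

#' Read waveform CSV (long format)
#'
#' Expects a header with columns `amplitude` and optionally `t_seconds` and
#' `participant_id`. Returns a named list of numeric sample vectors, one per
#' participant (a single unnamed entry when no id column is present).
#'
#' @param path CSV file path.
#' @return named list of numeric vectors, with attribute `sampling_rate`
#'   when `t_seconds` is present.
#' @export
read_waveforms <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"amplitude" %in% names(df)) stop("waveform CSV needs an 'amplitude' column")
  split_col <- if ("participant_id" %in% names(df)) df$participant_id else
    rep("1", nrow(df))
  out <- lapply(split(df, split_col), function(d) as.numeric(d$amplitude))
  if ("t_seconds" %in% names(df)) {
    first <- split(df, split_col)[[1]]
    dtv <- diff(as.numeric(first$t_seconds))
    attr(out, "sampling_rate") <- 1 / stats::median(dtv)
  }
  out
}
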