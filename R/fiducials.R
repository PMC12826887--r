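# Fiducial-point detection on a normalized beat and its derivatives.
#
# All searches operate on the sample grid; ties resolve to the earliest
# sample. Missing landmarks are flagged rather than imputed, and indices
# that depend on a missing landmark become NA downstream.

# local extrema indices of y within index window [lo, hi]; type +1 max, -1 min
.grid_extrema <- function(y, lo, hi) {
  lo <- max(lo, 2L); hi <- min(hi, length(y) - 1L)
  if (hi < lo) return(data.frame(idx = integer(0), type = integer(0)))
  idx <- lo:hi
  left <- y[idx] - y[idx - 1L]
  right <- y[idx + 1L] - y[idx]
  is_max <- left > 0 & right <= 0
  is_min <- left < 0 & right >= 0
  data.frame(idx = c(idx[is_max], idx[is_min]),
             type = c(rep(1L, sum(is_max)), rep(-1L, sum(is_min))))[
               order(c(idx[is_max], idx[is_min])), , drop = FALSE]
}

#' Detect the systolic peak
#'
#' Global maximum of the normalized beat; earliest sample on ties.
#'
#' @param pulse a `pulse_wave`.
#' @return list `(t_sys, amp_sys, idx)`.
#' @export
detect_systolic_peak <- function(pulse) {
  i <- which.max(pulse$samples)          # which.max takes the earliest tie
  list(t_sys = (i - 1) * pulse$dt, amp_sys = pulse$samples[i], idx = i)
}

#' Detect the maximum-upslope point (ms)
#'
#' Maximum of the first derivative over the rising phase `[0, t_sys]`.
#'
#' @param deriv a `derivative_pair`.
#' @param t_sys systolic-peak time (s) bounding the search.
#' @return list `(t_ms, amp_ms, idx)`.
#' @export
detect_ms <- function(deriv, t_sys) {
  hi <- max(2L, floor(t_sys / deriv$dt) + 1L)
  if (hi < 2) stop("empty search window for ms")
  seg <- deriv$d1[1:hi]
  i <- which.max(seg)
  list(t_ms = (i - 1) * deriv$dt, amp_ms = seg[i], idx = i)
}

#' Detect the a-e waves of the second derivative
#'
#' a = first maximum of d2 after the foot; b = first minimum after a;
#' c = next maximum after b; d = next minimum after c; e = next maximum
#' after d. The scan is bounded above by `1.2 * t_notch_estimate` (or the
#' beat end when no estimate is available). A wave that does not exist
#' (monotone d2 segment) is flagged missing, not imputed.
#'
#' @param deriv a `derivative_pair`.
#' @param t_sys systolic peak time (s).
#' @param t_notch_estimate rough notch time (s) bounding the e-wave search,
#'   or `NA`.
#' @return data.frame with columns `wave` (a..e), `t`, `amp`, `missing`.
#' @export
detect_abcde <- function(deriv, t_sys, t_notch_estimate = NA) {
  n <- length(deriv$d2)
  t_hi <- if (is.na(t_notch_estimate)) (n - 1) * deriv$dt else
    min(1.2 * t_notch_estimate, (n - 1) * deriv$dt)
  hi <- min(n - 1L, floor(t_hi / deriv$dt) + 1L)
  ex <- .grid_extrema(deriv$d2, 2L, hi)
  want <- c(1L, -1L, 1L, -1L, 1L)
  t <- amp <- rep(NA_real_, 5); idx <- rep(NA_integer_, 5)
  j <- 1L
  for (i in seq_len(nrow(ex))) {
    if (j > 5L) break
    if (ex$type[i] == want[j]) {
      idx[j] <- ex$idx[i]
      t[j] <- (ex$idx[i] - 1) * deriv$dt
      amp[j] <- deriv$d2[ex$idx[i]]
      j <- j + 1L
    }
  }
  data.frame(wave = c("a", "b", "c", "d", "e"), t = t, amp = amp, idx = idx,
             missing = is.na(t), stringsAsFactors = FALSE)
}

#' Detect the dicrotic notch
#'
#' Earliest local minimum of the waveform between the systolic peak and the
#' beat end; when no local minimum exists (notchless, older-physiology
#' contours) the e-wave time of the second derivative is used and flagged
#' as a fallback.
#'
#' @param pulse a `pulse_wave`.
#' @param deriv a `derivative_pair`.
#' @param t_sys systolic peak time (s).
#' @param t_e e-wave time (s) or `NA`, used as the fallback.
#' @param smoothed optional smoothed copy of the samples used for the
#'   extremum scan (suppresses residual-noise ripples); amplitudes are
#'   always read off the raw samples.
#' @return list `(t_notch, amp_notch, idx, fallback)`.
#' @export
detect_dicrotic_notch <- function(pulse, deriv, t_sys, t_e = NA,
                                  smoothed = NULL) {
  y <- if (is.null(smoothed)) pulse$samples else smoothed
  n <- length(pulse$samples)
  lo <- floor(t_sys / pulse$dt) + 2L
  ex <- .grid_extrema(y, lo, n - 1L)
  mins <- ex$idx[ex$type < 0]
  if (length(mins)) {
    i <- mins[1]
    return(list(t_notch = (i - 1) * pulse$dt, amp_notch = pulse$samples[i],
                idx = i, fallback = FALSE))
  }
  if (!is.na(t_e)) {
    i <- round(t_e / pulse$dt) + 1L
    return(list(t_notch = t_e, amp_notch = pulse$samples[i], idx = i,
                fallback = TRUE))
  }
  stop("notch undetectable")
}

#' Detect the diastolic peak
#'
#' Largest local maximum of the waveform in `(t_notch, t_end)`; when the
#' diastole decays monotonically the first inflection (zero crossing of the
#' second derivative) in the window is returned and flagged.
#'
#' @param pulse a `pulse_wave`.
#' @param deriv a `derivative_pair`.
#' @param t_notch notch time (s).
#' @param smoothed optional smoothed samples for the extremum scan.
#' @return list `(t_dia, amp_dia, idx, fallback)`.
#' @export
detect_diastolic_peak <- function(pulse, deriv, t_notch, smoothed = NULL) {
  y <- if (is.null(smoothed)) pulse$samples else smoothed
  n <- length(pulse$samples)
  lo <- floor(t_notch / pulse$dt) + 2L
  if (lo >= n) stop("empty diastolic search window")
  ex <- .grid_extrema(y, lo, n - 1L)
  maxs <- ex$idx[ex$type > 0]
  if (length(maxs)) {
    i <- maxs[which.max(y[maxs])]
    return(list(t_dia = (i - 1) * pulse$dt, amp_dia = pulse$samples[i],
                idx = i, fallback = FALSE))
  }
  d2 <- deriv$d2[lo:(n - 1L)]
  cross <- which(d2[-length(d2)] > 0 & d2[-1] <= 0 |
                 d2[-length(d2)] < 0 & d2[-1] >= 0)
  # no strict zero crossing (e.g. a purely convex decay): flattest-
  # curvature point as the inflection surrogate
  i <- if (length(cross)) lo + cross[1] - 1L else
    lo + which.min(abs(d2)) - 1L
  list(t_dia = (i - 1) * pulse$dt, amp_dia = pulse$samples[i], idx = i,
       fallback = TRUE)
}

#' Detect the full fiducial set of a beat
#'
#' Runs all individual detectors in dependency order and assembles a
#' `fiducial_set`: foot (t = 0), systolic peak, maximum upslope, a-e waves
#' of the second derivative, dicrotic notch (with e-wave fallback),
#' diastolic peak (with inflection fallback) and pulse end (t = period).
#'
#' @param pulse a `pulse_wave`.
#' @param deriv optional precomputed `derivative_pair`.
#' @param ... passed to [derivatives()] when `deriv` is missing.
#' @return An object of class `fiducial_set`: named list of times (s),
#'   amplitudes, and logical flags `notch_fallback`, `dia_fallback`,
#'   `missing` (named vector over a-e).
#' @export
detect_fiducials <- function(pulse, deriv = NULL, ...) {
  stopifnot(inherits(pulse, "pulse_wave"))
  if (is.null(deriv)) deriv <- derivatives(pulse, ...)
  # notch/diastolic scans run on a smoothed copy (same filter as the
  # derivatives) so residual noise ripples do not spawn spurious extrema
  w <- max(5L, as.integer(round(0.05 / pulse$dt)))
  if (w %% 2L == 0L) w <- w + 1L
  sm <- if (w < length(pulse$samples))
    sgolay_deriv(pulse$samples, pulse$dt, w, 4, 0) else pulse$samples
  sys <- detect_systolic_peak(pulse)
  ms <- detect_ms(deriv, sys$t_sys)
  # first pass without a notch bound to get an e-wave estimate
  ab0 <- detect_abcde(deriv, sys$t_sys, NA)
  notch <- detect_dicrotic_notch(pulse, deriv, sys$t_sys,
                                 t_e = ab0$t[ab0$wave == "e"],
                                 smoothed = sm)
  ab <- detect_abcde(deriv, sys$t_sys, notch$t_notch)
  dia <- detect_diastolic_peak(pulse, deriv, notch$t_notch, smoothed = sm)
  fs <- list(
    t_foot = 0, t_sys = sys$t_sys, amp_sys = sys$amp_sys,
    t_ms = ms$t_ms, amp_ms = ms$amp_ms,
    t_notch = notch$t_notch, amp_notch = notch$amp_notch,
    t_dia = dia$t_dia, amp_dia = dia$amp_dia,
    t_end = pulse$period_T,
    t_a = ab$t[1], t_b = ab$t[2], t_c = ab$t[3], t_d = ab$t[4], t_e = ab$t[5],
    amp_a = ab$amp[1], amp_b = ab$amp[2], amp_c = ab$amp[3],
    amp_d = ab$amp[4], amp_e = ab$amp[5],
    notch_fallback = notch$fallback, dia_fallback = dia$fallback,
    missing = stats::setNames(ab$missing, ab$wave)
  )
  class(fs) <- "fiducial_set"
  fs
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat("<fiducial_set>\n")
  tm <- c(foot = x$t_foot, a = x$t_a, b = x$t_b, sys = x$t_sys, c = x$t_c,
          d = x$t_d, e = x$t_e, notch = x$t_notch, dia = x$t_dia,
          end = x$t_end)
  print(round(tm, 4))
  if (x$notch_fallback) cat("  notch: e-wave fallback\n")
  if (x$dia_fallback) cat("  diastolic peak: inflection fallback\n")
  if (any(x$missing)) cat("  missing waves:",
                          paste(names(x$missing)[x$missing], collapse = ", "),
                          "\n")
  invisible(x)
}

#' Export a fiducial table for a batch of beats
#'
#' @param fiducial_list list of `fiducial_set` objects (possibly named by
#'   participant id).
#' @return data.frame, one row per beat, with times, amplitudes and flags.
#' @export
fiducial_table <- function(fiducial_list) {
  rows <- lapply(fiducial_list, function(fs) {
    data.frame(t_foot = fs$t_foot, t_sys = fs$t_sys, amp_sys = fs$amp_sys,
               t_ms = fs$t_ms, amp_ms = fs$amp_ms, t_notch = fs$t_notch,
               amp_notch = fs$amp_notch, t_dia = fs$t_dia,
               amp_dia = fs$amp_dia, t_end = fs$t_end,
               t_a = fs$t_a, t_b = fs$t_b, t_c = fs$t_c, t_d = fs$t_d,
               t_e = fs$t_e, amp_a = fs$amp_a, amp_b = fs$amp_b,
               amp_c = fs$amp_c, amp_d = fs$amp_d, amp_e = fs$amp_e,
               notch_fallback = fs$notch_fallback,
               dia_fallback = fs$dia_fallback,
               n_missing_waves = sum(fs$missing))
  })
  out <- do.call(rbind, rows)
  if (!is.null(names(fiducial_list)))
    out <- cbind(participant_id = names(fiducial_list), out)
  rownames(out) <- NULL
  out
}
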