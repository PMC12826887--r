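# The 20 morphological indices computed from a normalized beat and its
# fiducial set. Undefined quantities (missing upstream landmark, degenerate
# window) propagate as NA; batch extraction never aborts.

#' Names of the 20 emitted indices
#'
#' Heart rate and the stiffness index SI are deliberately absent: period is
#' used in preference to heart rate, and SI's ingredient (the time between
#' the two peaks, DT) is emitted instead of SI itself.
#' @return character vector of length 20.
#' @export
index_names <- function() c(
  "T", "DT", "CT", "t_systole", "t_bc", "t_bd", "dia_amp",
  "A1", "A2", "ms", "a", "b", "c", "d", "e",
  "AGI_mod", "slope_bc", "slope_bd", "IPAD", "k")

#' Systolic and diastolic areas
#'
#' Trapezoidal integrals of the normalized waveform from foot to dicrotic
#' notch (A1) and from notch to pulse end (A2), in seconds (area of a
#' unit-normalized amplitude over time).
#'
#' @param pulse a `pulse_wave`.
#' @param fp a `fiducial_set`.
#' @return list `(A1, A2)`; both `NA` when the notch is undefined.
#' @export
compute_areas <- function(pulse, fp) {
  if (is.na(fp$t_notch)) return(list(A1 = NA_real_, A2 = NA_real_))
  y <- pulse$samples; dt <- pulse$dt
  i_notch <- round(fp$t_notch / dt) + 1L
  trap <- function(v) if (length(v) < 2) 0 else
    dt * (sum(v) - (v[1] + v[length(v)]) / 2)
  list(A1 = trap(y[1:i_notch]), A2 = trap(y[i_notch:length(y)]))
}

#' Timing indices
#'
#' `T` is the beat period, `CT` the foot-to-systolic-peak time, `t_systole`
#' the foot-to-notch time, `DT` the systolic-to-diastolic peak separation,
#' and `t_bc`, `t_bd` the spacings of the second-derivative b/c and b/d
#' waves.
#'
#' @param fp a `fiducial_set`.
#' @return named list of the six timing indices (s), NA where a needed
#'   fiducial is missing.
#' @export
compute_timing <- function(fp) {
  list(T = fp$t_end,
       DT = fp$t_dia - fp$t_sys,
       CT = fp$t_sys,
       t_systole = fp$t_notch,
       t_bc = fp$t_c - fp$t_b,
       t_bd = fp$t_d - fp$t_b)
}

#' Second-derivative composite indices
#'
#' `AGI_mod = (b - c - d)/a` (modified aging index);
#' `slope_bc = (c - b) / ((t_c - t_b) * a)` and analogously `slope_bd`,
#' i.e. the slope of the chord between the named second-derivative waves,
#' normalized by the a-wave amplitude.
#'
#' @param fp a `fiducial_set`.
#' @return named list `(a, b, c, d, e, AGI_mod, slope_bc, slope_bd, d_over_a)`.
#' @export
compute_sdppg_indices <- function(fp) {
  a <- fp$amp_a; b <- fp$amp_b; cc <- fp$amp_c; d <- fp$amp_d; e <- fp$amp_e
  bad_a <- is.na(a) || a == 0
  agi <- if (bad_a || anyNA(c(b, cc, d))) NA_real_ else (b - cc - d) / a
  sbc <- if (bad_a || anyNA(c(b, cc)) || is.na(fp$t_c) || fp$t_c == fp$t_b)
    NA_real_ else (cc - b) / ((fp$t_c - fp$t_b) * a)
  sbd <- if (bad_a || anyNA(c(b, d)) || is.na(fp$t_d) || fp$t_d == fp$t_b)
    NA_real_ else (d - b) / ((fp$t_d - fp$t_b) * a)
  doa <- if (bad_a || is.na(d)) NA_real_ else d / a
  list(a = a, b = b, c = cc, d = d, e = e,
       AGI_mod = agi, slope_bc = sbc, slope_bd = sbd, d_over_a = doa)
}

#' IPAD index
#'
#' Ratio of diastolic to systolic area plus the d-to-a amplitude ratio:
#' `IPAD = A2/A1 + d/a`.
#'
#' @param A1,A2 areas (s).
#' @param amp_a,amp_d second-derivative wave amplitudes (1/s^2).
#' @return numeric scalar or `NA` when `A1 = 0` or `a = 0` or inputs missing.
#' @export
compute_ipad <- function(A1, A2, amp_a, amp_d) {
  if (anyNA(c(A1, A2, amp_a, amp_d)) || A1 <= 0 || amp_a == 0) return(NA_real_)
  A2 / A1 + amp_d / amp_a
}

#' Diastolic stiffness decay constant k
#'
#' Default strategy: least-squares fit of `x(t) = A * exp(-k (t - t_dia)) + C`
#' over the diastolic tail `[t_dia, t_end]`; `k` (1/s) is the decay rate.
#' By default the offset `C` is estimated jointly (`"exp_decay_free"`): an
#' exact exponential tail is then recovered exactly. The alternative
#' `"exp_decay"` strategy pins `C` at the end-of-beat amplitude `x(t_end)`,
#' which is simpler but biased upward whenever the tail has not reached its
#' asymptote by the pulse end. For a near-flat tail (amplitude range below
#' `flat_tol`) `k = 0`. The strategy is configurable so alternative
#' stiffness definitions can be swapped in.
#'
#' @param pulse a `pulse_wave`.
#' @param fp a `fiducial_set`.
#' @param strategy `"exp_decay_free"` (default, offset estimated) or
#'   `"exp_decay"` (offset fixed at `x(t_end)`).
#' @param flat_tol amplitude range below which the tail counts as flat.
#' @return decay rate k (1/s) or `NA` when the window has < 5 samples.
#' @export
compute_stiffness_k <- function(pulse, fp, strategy = c("exp_decay_free",
                                                        "exp_decay"),
                                flat_tol = 1e-6) {
  strategy <- match.arg(strategy)
  if (is.na(fp$t_dia)) return(NA_real_)
  dt <- pulse$dt
  i0 <- round(fp$t_dia / dt) + 1L
  y <- pulse$samples[i0:length(pulse$samples)]
  if (length(y) < 5) return(NA_real_)
  if (diff(range(y)) < flat_tol) return(0)
  tau <- (seq_along(y) - 1) * dt
  if (strategy == "exp_decay") {
    z <- y - y[length(y)]
    # profile A for fixed k, optimize k on [0, 60] 1/s
    sse <- function(k) {
      e <- exp(-k * tau)
      A <- sum(z * e) / sum(e * e)
      v <- sum((z - A * e)^2)
      if (is.finite(v)) v else .Machine$double.xmax
    }
    stats::optimize(sse, c(0, 60), tol = 1e-8)$minimum
  } else {
    # free offset: profile A and C jointly (linear for fixed k)
    sse <- function(k) {
      e <- exp(-k * tau)
      X <- cbind(e, 1)
      co <- qr.coef(qr(X), y)
      v <- sum((y - X %*% co)^2)
      if (is.finite(v)) v else .Machine$double.xmax
    }
    stats::optimize(sse, c(0, 60), tol = 1e-8)$minimum
  }
}

#' Extract all 20 indices from one beat
#'
#' Runs derivatives, fiducial detection and every index computation; flags
#' propagate (fallback-derived notch/diastolic peak mark the dependent
#' indices) and a failure yields NA for the affected indices rather than an
#' error.
#'
#' @param pulse a `pulse_wave`.
#' @param smoothing_window_s,poly_order forwarded to [derivatives()].
#' @param k_strategy forwarded to [compute_stiffness_k()].
#' @return one-row data.frame: the 20 index columns of [index_names()] plus
#'   `notch_fallback`, `dia_fallback`, `n_missing_waves`.
#' @export
extract_all <- function(pulse, smoothing_window_s = 0.05, poly_order = 4,
                        k_strategy = "exp_decay_free") {
  empty <- as.data.frame(as.list(stats::setNames(rep(NA_real_, 20),
                                                 index_names())),
                         check.names = FALSE)
  empty$notch_fallback <- NA; empty$dia_fallback <- NA
  empty$n_missing_waves <- NA_integer_
  fs <- tryCatch({
    dv <- derivatives(pulse, smoothing_window_s, poly_order)
    list(fp = detect_fiducials(pulse, dv), dv = dv)
  }, error = function(e) NULL)
  if (is.null(fs)) return(empty)
  fp <- fs$fp; dv <- fs$dv
  tm <- compute_timing(fp)
  ar <- compute_areas(pulse, fp)
  sd2 <- compute_sdppg_indices(fp)
  out <- data.frame(
    T = tm$T, DT = tm$DT, CT = tm$CT, t_systole = tm$t_systole,
    t_bc = tm$t_bc, t_bd = tm$t_bd, dia_amp = fp$amp_dia,
    A1 = ar$A1, A2 = ar$A2, ms = fp$amp_ms,
    a = sd2$a, b = sd2$b, c = sd2$c, d = sd2$d, e = sd2$e,
    AGI_mod = sd2$AGI_mod, slope_bc = sd2$slope_bc, slope_bd = sd2$slope_bd,
    IPAD = compute_ipad(ar$A1, ar$A2, fp$amp_a, fp$amp_d),
    k = tryCatch(compute_stiffness_k(pulse, fp, k_strategy),
                 error = function(e) NA_real_),
    notch_fallback = fp$notch_fallback, dia_fallback = fp$dia_fallback,
    n_missing_waves = sum(fp$missing),
    check.names = FALSE)
  out
}

#' Extract indices for a batch of beats
#'
#' @param pulses list of `pulse_wave` objects (optionally named).
#' @param ... forwarded to [extract_all()].
#' @return data.frame with one row per beat; degenerate beats yield NA rows
#'   with flags, never an aborted batch.
#' @export
extract_batch <- function(pulses, ...) {
  rows <- lapply(pulses, function(p)
    tryCatch(extract_all(p, ...), error = function(e) extract_all(NULL)))
  out <- do.call(rbind, rows)
  if (!is.null(names(pulses))) out <- cbind(participant_id = names(pulses), out)
  rownames(out) <- NULL
  out
}
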