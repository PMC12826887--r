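# Harrell's concordance over usable pairs, authored in-package so it can be
# dual-checked against an exhaustive pair-enumeration oracle in the tests.

#' Harrell's concordance index
#'
#' A pair is usable when its member with the strictly shorter observed time
#' has an event (pairs with tied observed times are not usable). The pair
#' is concordant when that member also has the higher risk score; tied risk
#' scores count 1/2. Equals Somers' Dxy / 2 + 0.5 for the (risk, time)
#' ordering. Higher risk must mean higher hazard (shorter survival).
#'
#' @param time observed times.
#' @param event 0/1 event indicators.
#' @param risk risk scores (e.g. Cox linear predictor).
#' @return list `(c, n_pairs, concordant, tied_risk)`.
#' @export
concordance_index <- function(time, event, risk) {
  n <- length(time)
  stopifnot(length(event) == n, length(risk) == n,
            all(event %in% c(0, 1)))
  idx_ev <- which(event == 1)
  conc <- 0; ties <- 0; usable <- 0
  for (i in idx_ev) {
    later <- time > time[i]          # strictly later observed time
    m <- sum(later)
    if (!m) next
    usable <- usable + m
    conc <- conc + sum(risk[i] > risk[later])
    ties <- ties + sum(risk[i] == risk[later])
  }
  if (usable == 0) stop("no usable pairs")
  list(c = (conc + 0.5 * ties) / usable, n_pairs = usable,
       concordant = conc, tied_risk = ties)
}

#' Bootstrap percentile CI for the concordance index
#'
#' Participant-level resampling with replacement; resamples with no usable
#' pairs are redrawn (and counted). `B = 1` degenerates to a point and
#' warns.
#'
#' @param time,event,risk as in [concordance_index()].
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param conf_level CI level.
#' @return list `(c, ci, B, n_redrawn, boot)` where `boot` is the vector of
#'   replicate values.
#' @export
bootstrap_c_ci <- function(time, event, risk, B = 1000, seed = 1,
                           conf_level = 0.95) {
  point <- concordance_index(time, event, risk)$c
  if (B == 1) warning("B = 1: interval collapses to a point")
  set.seed(seed)
  n <- length(time)
  boot <- numeric(B); redrawn <- 0
  for (b in seq_len(B)) {
    repeat {
      id <- sample.int(n, n, replace = TRUE)
      v <- tryCatch(concordance_index(time[id], event[id], risk[id])$c,
                    error = function(e) NA_real_)
      if (!is.na(v)) break
      redrawn <- redrawn + 1
    }
    boot[b] <- v
  }
  a <- (1 - conf_level) / 2
  list(c = point, ci = unname(stats::quantile(boot, c(a, 1 - a))), B = B,
       n_redrawn = redrawn, boot = boot)
}

#' Paired bootstrap Z-test for a change in concordance
#'
#' Computes \eqn{\Delta C = C_B - C_A} on identical rows, the percentile CI
#' of the paired bootstrap distribution, and a two-sided p-value from
#' \eqn{Z = \Delta C / \mathrm{SE}_{boot}}. Identical risk scores short-
#' circuit to \eqn{\Delta C = 0, p = 1}. Invariant under strictly monotone
#' transforms of either score.
#'
#' @param time,event observed data.
#' @param risk_a,risk_b risk scores of the two models on the same rows.
#' @param B bootstrap replicates.
#' @param seed integer seed.
#' @param conf_level CI level.
#' @return list `(delta_c, ci, p, z, se, c_a, c_b)`.
#' @export
delta_c_test <- function(time, event, risk_a, risk_b, B = 1000, seed = 1,
                         conf_level = 0.95) {
  c_a <- concordance_index(time, event, risk_a)$c
  c_b <- concordance_index(time, event, risk_b)$c
  dc <- c_b - c_a
  if (identical(rank(risk_a), rank(risk_b)))
    return(list(delta_c = 0, ci = c(0, 0), p = 1, z = 0, se = 0,
                c_a = c_a, c_b = c_b))
  set.seed(seed)
  n <- length(time)
  boot <- numeric(B)
  for (b in seq_len(B)) {
    repeat {
      id <- sample.int(n, n, replace = TRUE)
      v <- tryCatch(
        concordance_index(time[id], event[id], risk_b[id])$c -
          concordance_index(time[id], event[id], risk_a[id])$c,
        error = function(e) NA_real_)
      if (!is.na(v)) break
    }
    boot[b] <- v
  }
  se <- stats::sd(boot)
  z <- if (se > 0) dc / se else 0
  a <- (1 - conf_level) / 2
  list(delta_c = dc, ci = unname(stats::quantile(boot, c(a, 1 - a))),
       p = if (se > 0) 2 * stats::pnorm(-abs(z)) else 1,
       z = z, se = se, c_a = c_a, c_b = c_b)
}
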