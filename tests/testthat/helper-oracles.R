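# Independent oracles used across the suite. Deliberately naive: exhaustive
# enumeration and brute-force finite differences, never sharing code with
# the implementation they check.

# Harrell's C by exhaustive enumeration over all ordered pairs: a pair is
# usable when the strictly shorter observed time has an event; concordant
# when that member has the higher risk; tied risks count half.
oracle_concordance <- function(time, event, risk) {
  n <- length(time)
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (time[i] < time[j] && event[i] == 1) {
        den <- den + 1
        if (risk[i] > risk[j]) num <- num + 1
        else if (risk[i] == risk[j]) num <- num + 0.5
      }
    }
  }
  if (den == 0) stop("no usable pairs")
  num / den
}

# Somers' Dxy of (-risk, time) by enumeration, defined on fully uncensored
# data: (concordant - discordant) / comparable pairs over strictly
# different times.
oracle_somers_dxy <- function(time, risk) {
  n <- length(time); conc <- 0; disc <- 0; comp <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) next
      comp <- comp + 1
      s <- sign(time[j] - time[i]) * sign((-risk[j]) - (-risk[i]))
      if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
    }
  }
  (conc - disc) / comp
}

# dense-grid argmax of a continuous function at 10x the sampling resolution
oracle_argmax <- function(f, lo, hi, sampling_rate) {
  tt <- seq(lo, hi, by = 1 / (10 * sampling_rate))
  tt[which.max(f(tt))]
}

# random canonical-family beat parameters (moderate perturbations that keep
# all fiducials present)
random_beat_params <- function() {
  beat_params(
    amplitudes = c(1, 0.42, 0.18, 0.24) * stats::runif(4, 0.9, 1.1),
    centers    = c(0.125, 0.220, 0.310, 0.445) * stats::runif(1, 0.9, 1.1),
    widths     = c(0.042, 0.060, 0.042, 0.075) * stats::runif(4, 0.95, 1.05),
    decay_rate = stats::runif(1, 2, 5),
    period     = stats::runif(1, 0.67, 0.95))
}

# time-varying-coefficient survival generator for the Schoenfeld power
# check: hazard h(t|x) = h0 exp(beta0 * t * x), exponential baseline,
# inverse transform; infinite cumulative hazard -> administrative censoring.
simulate_tvc <- function(n, beta0, h0 = 0.05, horizon = 10, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  u <- stats::runif(n)
  arg <- 1 - beta0 * x * log(u) / h0
  t_ev <- ifelse(arg > 0, log(pmax(arg, 1e-12)) / (beta0 * x), Inf)
  t_ev[abs(beta0 * x) < 1e-10] <- (-log(u) / h0)[abs(beta0 * x) < 1e-10]
  time <- pmin(t_ev, horizon)
  data.frame(x = x, time = time, event = as.integer(t_ev <= horizon))
}
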