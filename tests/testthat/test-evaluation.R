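test_that("concordance: perfect, all-tied, hand-worked and oracle cases", {
  # risks exactly anti-ordered with event times, all events
  time <- c(1, 2, 3, 4, 5); event <- rep(1, 5); risk <- 5:1
  expect_equal(concordance_index(time, event, risk)$c, 1)
  # constant risks: every usable pair tied
  expect_equal(concordance_index(time, event, rep(2, 5))$c, 0.5)

  # 6 subjects, mixed censoring, hand-chosen risks
  time <- c(2, 4, 4, 6, 7, 9)
  event <- c(1, 0, 1, 1, 0, 0)
  risk <- c(3.0, 1.0, 2.5, 2.5, 0.5, 1.5)
  got <- concordance_index(time, event, risk)
  expect_equal(got$c, oracle_concordance(time, event, risk))

  expect_error(concordance_index(c(1, 2), c(0, 0), c(1, 2)), "usable")
})

test_that("concordance equals the exhaustive oracle on random instances", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    time <- sample.int(15, n, replace = TRUE)      # induces time ties
    event <- rbinom(n, 1, 0.6)
    risk <- sample(seq(0, 2, by = 0.25), n, replace = TRUE)  # risk ties
    if (sum(event) == 0) next
    a <- tryCatch(concordance_index(time, event, risk)$c,
                  error = function(e) NA)
    b <- tryCatch(oracle_concordance(time, event, risk),
                  error = function(e) NA)
    expect_equal(a, b)
  }
})

test_that("concordance symmetries and the Somers' Dxy identity", {
  set.seed(13)
  for (i in 1:10) {
    n <- 40
    time <- rexp(n); event <- rbinom(n, 1, 0.7); risk <- rnorm(n)
    if (sum(event) == 0) next
    c1 <- concordance_index(time, event, risk)$c
    c2 <- concordance_index(time, event, -risk)$c
    expect_equal(c1 + c2, 1)
    # uncensored subset: C = Dxy/2 + 0.5
    ev <- event == 1
    if (sum(ev) > 5) {
      dxy <- oracle_somers_dxy(time[ev], risk[ev])
      expect_equal(concordance_index(time[ev], rep(1, sum(ev)), risk[ev])$c,
                   dxy / 2 + 0.5)
    }
  }
})

test_that("bootstrap CI: determinism, degenerate B, null coverage", {
  set.seed(17)
  n <- 300
  time <- rexp(n, 0.1); event <- rbinom(n, 1, 0.3); risk <- rnorm(n)
  a <- bootstrap_c_ci(time, event, risk, B = 100, seed = 5)
  b <- bootstrap_c_ci(time, event, risk, B = 100, seed = 5)
  expect_identical(a$ci, b$ci)
  expect_true(a$ci[1] <= a$c && a$c <= a$ci[2])
  expect_warning(bootstrap_c_ci(time, event, risk, B = 1, seed = 1),
                 "point")

  cover <- vapply(1:60, function(s) {
    set.seed(1000 + s)
    tm <- rexp(n, 0.1); ev <- rbinom(n, 1, 0.3); rk <- rnorm(n)
    ci <- bootstrap_c_ci(tm, ev, rk, B = 150, seed = s)$ci
    ci[1] <= 0.5 && 0.5 <= ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.85)
})

test_that("delta-C test: self-comparison, monotone invariance, power", {
  set.seed(19)
  n <- 500
  time <- rexp(n, 0.1); event <- rbinom(n, 1, 0.4)
  risk <- rnorm(n)
  d0 <- delta_c_test(time, event, risk, risk, B = 50, seed = 1)
  expect_identical(d0$delta_c, 0)
  expect_identical(d0$p, 1)

  # invariant under strictly monotone transforms of either score
  risk_b <- rnorm(n)
  d1 <- delta_c_test(time, event, risk, risk_b, B = 100, seed = 2)
  d2 <- delta_c_test(time, event, exp(risk), risk_b, B = 100, seed = 2)
  d3 <- delta_c_test(time, event, risk, 3 * risk_b - 7, B = 100, seed = 2)
  expect_equal(d1$delta_c, d2$delta_c)
  expect_equal(d1$p, d2$p)
  expect_equal(d1$delta_c, d3$delta_c)

  # signal beyond covariates is detected
  rej <- vapply(1:5, function(s) {
    co <- simulate_cohort(cohort_spec(n = 10000,
                                      beta = c(t_systole = log(1.43),
                                               A1 = log(0.79),
                                               c = log(0.80))), seed = s)
    sp <- split_cohort(nrow(co), s)
    test <- co[sp$test, ]
    lp_a <- ppgrisk:::.lp_on_test(co, crf_names(), sp$train, sp$test)
    lp_b <- ppgrisk:::.lp_on_test(co, c(crf_names(), c("t_systole", "A1",
                                                       "c")),
                                  sp$train, sp$test)
    d <- delta_c_test(test$time, test$event, lp_a, lp_b, B = 150, seed = s)
    d$delta_c > 0 && d$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)
})

test_that("model ladder: shape, null additions, full-signal trend", {
  co_null <- simulate_cohort(cohort_spec(n = 4000,
                                         beta_crf = c(age = 0.6, sex = 0,
                                                      ethnicity = 0, bmi = 0,
                                                      smoking = 0,
                                                      diabetes = 0,
                                                      tchdl = 0, sbp = 0,
                                                      bp_med = 0)), seed = 21)
  lad <- model_ladder(co_null, B = 100, seed = 21)
  expect_equal(nrow(lad), 10)
  expect_equal(lad$model, 1:10)
  expect_true(all(abs(lad$delta_c[-1]) < 0.03))

  co_full <- simulate_cohort(cohort_spec(n = 6000,
                                         beta = c(t_systole = log(1.43),
                                                  A1 = log(0.79),
                                                  c = log(0.80))), seed = 22)
  lad2 <- model_ladder(co_full, B = 100, seed = 22)
  expect_gt(lad2$c[10], lad2$c[1])
  expect_true(all(diff(lad2$c) > -0.03))
  expect_gt(lad2$delta_c[10], 0)

  co_miss <- co_full[, setdiff(names(co_full), "sbp")]
  expect_error(model_ladder(co_miss, B = 10, seed = 1), "sbp")
})

test_that("age-stratified evaluation partitions and detects gradients", {
  # stronger index effect below 50: splice two generated cohorts
  beta_strong <- c(t_systole = log(1.8), A1 = log(0.6), c = log(0.6))
  young <- simulate_cohort(cohort_spec(n = 30000, beta = beta_strong),
                           seed = 31)
  young <- young[young$age < 50, ]
  old <- simulate_cohort(cohort_spec(n = 30000), seed = 32)
  old <- old[old$age >= 50, ]
  co <- rbind(young, old)
  strat <- age_stratified_eval(co, B = 100, seed = 31)
  expect_equal(nrow(strat), 3)
  expect_equal(sum(strat$n), nrow(co))      # strata partition the cohort
  expect_false(any(strat$flagged))
  expect_gt(strat$delta_c[1], strat$delta_c[3])

  # empty stratum flagged, not fatal
  strat2 <- age_stratified_eval(co[co$age >= 50, ], B = 50, seed = 1)
  expect_true(strat2$flagged[1])
})
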