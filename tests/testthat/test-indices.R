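test_that("areas: rectangle and triangle geometry, conservation", {
  dt <- 0.001
  # rectangle: amplitude 1 on [0, 0.3], zero to 1.0 s, notch at 0.3 s
  n1 <- 301; n0 <- 700
  pw <- pulse_wave(c(rep(1, n1), rep(0, n0)), dt)
  ar <- compute_areas(pw, list(t_notch = 0.3))
  expect_equal(ar$A1, 0.3, tolerance = 1e-12)
  expect_lt(ar$A2, dt)                       # one boundary trapezoid only

  # unit triangle over [0, 1], apex (notch) at 0.5
  tt <- seq(0, 1, by = dt)
  tri <- 1 - abs(tt - 0.5) * 2
  pwt <- pulse_wave(tri - min(tri), dt)     # min already 0
  art <- compute_areas(pwt, list(t_notch = 0.5))
  expect_equal(art$A1, 0.25, tolerance = 1e-10)
  expect_equal(art$A2, 0.25, tolerance = 1e-10)

  # A1 + A2 equals the whole-beat trapezoid integral exactly
  g <- generate_beat(beat_params(), 500)
  fp <- detect_fiducials(g$pulse)
  a <- compute_areas(g$pulse, fp)
  y <- g$pulse$samples
  whole <- g$pulse$dt * (sum(y) - (y[1] + y[length(y)]) / 2)
  expect_equal(a$A1 + a$A2, whole, tolerance = 1e-12)

  expect_true(is.na(compute_areas(g$pulse, list(t_notch = NA))$A1))
})

test_that("areas match the quadrature oracle on generator beats", {
  g <- generate_beat(beat_params(), 1000)
  fp <- detect_fiducials(g$pulse)
  ar <- compute_areas(g$pulse, fp)
  expect_lt(abs(ar$A1 - g$truth$A1), 1e-4)
  expect_lt(abs(ar$A2 - g$truth$A2), 1e-4)
})

test_that("timing indices: direct differences, dilation, generator truth", {
  fp <- list(t_end = 0.8, t_sys = 0.15, t_dia = 0.45, t_notch = 0.33,
             t_b = 0.10, t_c = 0.18, t_d = 0.26)
  tm <- compute_timing(fp)
  expect_equal(tm$DT, 0.30)
  expect_equal(tm$CT, 0.15)
  expect_equal(tm$t_systole, 0.33)
  expect_equal(tm$t_bc, 0.08)
  expect_equal(tm$t_bd, 0.16)

  fp2 <- lapply(fp, `*`, 1.2)
  tm2 <- compute_timing(fp2)
  for (nm in names(tm)) expect_equal(tm2[[nm]], 1.2 * tm[[nm]])

  for (bpm in c(50, 70, 90)) {
    per <- 60 / bpm
    g <- generate_beat(beat_params(period = per), 250)
    tm <- compute_timing(detect_fiducials(g$pulse))
    expect_lte(abs(tm$T - per), 1 / 250)
  }
})

test_that("second-derivative composites follow their formulas", {
  fp <- list(amp_a = 2, amp_b = -1, amp_c = 0.5, amp_d = -0.4, amp_e = 0.1,
             t_b = 0.10, t_c = 0.18, t_d = 0.26)
  s <- compute_sdppg_indices(fp)
  expect_equal(s$AGI_mod, (-1 - 0.5 - (-0.4)) / 2)
  expect_equal(s$slope_bc, (0.5 - (-1)) / ((0.18 - 0.10) * 2))
  expect_equal(s$slope_bd, (-0.4 - (-1)) / ((0.26 - 0.10) * 2))
  expect_equal(s$d_over_a, -0.2)

  fp$amp_c <- fp$amp_b                       # equal amplitudes: zero slope
  expect_equal(compute_sdppg_indices(fp)$slope_bc, 0)

  fp$amp_a <- 0                              # degenerate a-wave
  expect_true(is.na(compute_sdppg_indices(fp)$AGI_mod))
})

test_that("IPAD is the area ratio plus amplitude ratio", {
  expect_equal(compute_ipad(1, 0.4, 1, -0.2), 0.2)
  expect_equal(compute_ipad(0.5, 0, 2, 0), 0)
  expect_true(is.na(compute_ipad(0, 0.1, 1, 0.1)))

  # the formula is exact on oracle inputs ...
  g <- generate_beat(beat_params(), 1000)
  tr <- g$truth
  expect_identical(compute_ipad(tr$A1, tr$A2, tr$d2_a, tr$d2_d),
                   tr$A2 / tr$A1 + tr$d2_d / tr$d2_a)
  # ... and the pipeline composition tracks the oracle composition to the
  # accuracy limit set by derivative smoothing (see methods vignette)
  fp <- detect_fiducials(g$pulse)
  ar <- compute_areas(g$pulse, fp)
  got <- compute_ipad(ar$A1, ar$A2, fp$amp_a, fp$amp_d)
  oracle <- tr$A2 / tr$A1 + tr$d2_d / tr$d2_a
  expect_lt(abs(got - oracle), 5e-3)
})

test_that("stiffness k: exact recovery, flat tail, decay ordering", {
  dt <- 1 / 500
  rise <- seq(0, 0.5, length.out = 100)[-100]
  tail_t <- seq(0, 1, by = dt)
  beat <- c(rise, 0.5 * exp(-3 * tail_t))
  pw <- normalize_pulse(beat, dt)
  k <- compute_stiffness_k(pw, list(t_dia = length(rise) * dt))
  expect_equal(k, 3, tolerance = 0.01)

  flat <- normalize_pulse(c(seq(0, 1, length.out = 50), rep(0.2, 100)), dt)
  expect_equal(compute_stiffness_k(flat, list(t_dia = 60 * dt)), 0)

  ks <- vapply(c(2, 4, 6), function(lam) {
    g <- generate_beat(beat_params(decay_rate = lam), 250)
    compute_stiffness_k(g$pulse, detect_fiducials(g$pulse))
  }, numeric(1))
  expect_true(all(diff(ks) > 0))
})

test_that("extract_all emits the 20 indices with flag propagation", {
  g <- generate_beat(beat_params(), 250)
  iv <- extract_all(g$pulse)
  expect_true(all(index_names() %in% names(iv)))
  expect_false(anyNA(iv[, index_names()]))
  expect_false(iv$notch_fallback)
  expect_true(iv$t_bc > 0)
  expect_true(iv$t_bd > iv$t_bc)
  expect_true(iv$DT > 0)

  # notchless (merged-diastole) beat: fallback-derived A1/A2/t_systole
  # flagged
  g0 <- generate_beat(beat_params(centers = c(0.125, 0.220, 0.310, 0.40),
                                  widths = c(0.042, 0.060, 0.042, 0.10)),
                      250)
  iv0 <- extract_all(g0$pulse)
  expect_true(iv0$notch_fallback)
  expect_true(iv0$dia_fallback)

  # batch of 30 with 3 degenerate inputs: 30 rows, 3 NA-flagged
  pulses <- c(lapply(1:27, function(i) {
    set.seed(i); generate_beat(random_beat_params(), 250)$pulse
  }), lapply(1:3, function(i) pulse_wave(c(0, 1, 0, 1, 0, 1), 0.01)))
  batch <- extract_batch(pulses)
  expect_equal(nrow(batch), 30)
  expect_gte(sum(is.na(batch$t_systole) | batch$n_missing_waves > 0 |
                   batch$notch_fallback), 3)
})

test_that("heart rate and stiffness index SI are never emitted", {
  expect_false(any(c("HR", "heart_rate", "SI", "stiffness_index") %in%
                     index_names()))
  expect_length(index_names(), 20)
})

test_that("indices are invariant to raw amplitude scaling", {
  set.seed(42)
  for (i in 1:10) {
    p <- random_beat_params()
    f <- beat_function(p)
    tt <- seq(0, p$period, by = 1 / 250)
    raw <- f(tt)
    al <- runif(1, 0.2, 8)
    iv1 <- extract_all(normalize_pulse(raw, 1 / 250))
    iv2 <- extract_all(normalize_pulse(al * raw, 1 / 250))
    for (nm in index_names())
      expect_equal(iv2[[nm]], iv1[[nm]], tolerance = 1e-7)
  }
})

test_that("indices transform covariantly under time dilation", {
  # dilating the world (dt and the smoothing window) by gamma multiplies
  # the timing indices and areas by gamma, divides ms, slopes and k by
  # gamma, divides a-e by gamma^2, and fixes the unitless composites.
  pow <- c(T = 1, DT = 1, CT = 1, t_systole = 1, t_bc = 1, t_bd = 1,
           dia_amp = 0, A1 = 1, A2 = 1, ms = -1, a = -2, b = -2, c = -2,
           d = -2, e = -2, AGI_mod = 0, slope_bc = -1, slope_bd = -1,
           IPAD = 0, k = -1)
  set.seed(7)
  for (i in 1:5) {
    p <- random_beat_params()
    f <- beat_function(p)
    raw <- f(seq(0, p$period, by = 1 / 250))
    gam <- runif(1, 0.7, 1.4)
    iv1 <- extract_all(normalize_pulse(raw, 1 / 250))
    iv2 <- extract_all(normalize_pulse(raw, gam / 250),
                       smoothing_window_s = 0.05 * gam)
    for (nm in index_names())
      expect_equal(iv2[[nm]], iv1[[nm]] * gam^pow[[nm]], tolerance = 1e-5)
  }
})
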