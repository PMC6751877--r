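make_traj <- function(f, duration = 96, dt = 0.05) {
  t <- seq(0, duration, by = dt)
  tibble::tibble(time = t, y = f(t))
}

test_that("spectral normalisation reports sine amplitudes", {
  tr <- make_traj(function(t) 150 + 300 * sin(2 * pi * t / 12))
  sp <- signal_spectrum(tr, "y", ideal_period = 12)
  expect_equal(leading_magnitude(sp), 300, tolerance = 1 / 300)
  expect_equal(sp$harmonics$mag[1], 300, tolerance = 1 / 300)
  expect_lt(max(sp$harmonics$mag[-1]), 1)

  flat <- make_traj(function(t) rep(42, length(t)))
  expect_equal(max(signal_spectrum(flat, "y", 12)$mags), 0, tolerance = 1e-9)
})

test_that("two-tone harmonics match a brute-force DFT", {
  f <- function(t) 300 * sin(2 * pi * t / 12) + 50 * sin(2 * pi * t / 6)
  tr <- make_traj(f)
  sp <- signal_spectrum(tr, "y", ideal_period = 12)
  expect_equal(sp$harmonics$mag[1:2], c(300, 50), tolerance = 1e-2)
  # independent oracle: direct projection onto the extracted bin frequencies
  expect_equal(sp$harmonics$mag[1],
               dft_amplitude(tr$y, tr$time, sp$harmonics$freq[1]),
               tolerance = 1e-6)
  expect_equal(sp$harmonics$mag[2],
               dft_amplitude(tr$y, tr$time, sp$harmonics$freq[2]),
               tolerance = 1e-6)
})

test_that("spectrum refuses windows under two ideal periods", {
  tr <- make_traj(function(t) sin(t), duration = 20)
  expect_error(signal_spectrum(tr, "y", ideal_period = 12),
               "insufficient duration")
})

test_that("harmonic MSE: identity, boundary and non-negativity", {
  tr <- make_traj(function(t) 300 * sin(2 * pi * t / 12))
  sp <- signal_spectrum(tr, "y", 12)
  same <- harmonic_mse(sp, sp, tol = 10)
  expect_equal(same$value, 0)
  expect_true(same$viable)

  # every harmonic off by exactly 10 nM at tol 10 sits on the boundary
  off <- sp
  off$harmonics$mag <- sp$harmonics$mag + 10
  cv <- harmonic_mse(off, sp, tol = 10)
  expect_equal(cv$value, 10 * 10^2)
  expect_true(cv$viable)
  cv2 <- harmonic_mse(off, sp, tol = 9.99)
  expect_false(cv2$viable)
  expect_gte(cv$value, 0)

  bad <- sp
  bad$harmonics <- bad$harmonics[1:5, ]
  expect_error(harmonic_mse(bad, sp), "harmonic counts")
})

test_that("harmonic cost is invariant to signal phase", {
  base <- make_traj(function(t) 250 * sin(2 * pi * t / 12))
  ideal <- ideal_harmonics(300, 12, base)
  costs <- vapply(c(0, 1.7, 3, 7.2), function(ph) {
    tr <- make_traj(function(t) 250 * sin(2 * pi * (t + ph) / 12))
    harmonic_mse(signal_spectrum(tr, "y", 12), ideal, tol = 10)$value
  }, numeric(1))
  expect_lt(max(abs(costs - costs[1])) / costs[1], 0.01)
})

test_that("ideal spectra report the study amplitudes", {
  grid <- seq(0, 96, by = 0.05)
  for (case in list(c(300, 12), c(50, 48), c(200, 12))) {
    sp <- ideal_harmonics(case[1], case[2], grid)
    expect_equal(sp$harmonics$mag[1], case[1], tolerance = 0.01)
    expect_equal(leading_magnitude(sp), case[1], tolerance = 0.01)
  }
})

test_that("peak cost telescopes and handles degenerate spectra", {
  # synthetic spectrum with three isolated peaks at known heights
  mags <- rep(0.05, 60)
  mags[c(10, 20, 30)] <- c(10, 4, 1)
  spec <- structure(list(freqs = seq_along(mags) / 100, mags = mags,
                         harmonic_idx = c(2L, 4L, 6L, 8L, 10L)),
                    class = "harmonic_spectrum")
  cv <- peak_prominence_cost(spec, E0 = 0)
  # oracle: direct summation of the defining formula
  sig <- c(sd(mags[9:11]), sd(mags[19:21]), sd(mags[29:31]))
  g <- c(10, 4, 1)
  direct <- -mean(sig) - sum(g[-length(g)] - g[-1])
  expect_equal(cv$value, direct)
  expect_equal(cv$value, -mean(sig) - (g[1] - g[length(g)])) # telescoped
  expect_equal(cv$diagnostics$P, 3L)

  # single peak: the telescoping sum is empty
  m1 <- rep(0, 30)
  m1[10] <- 6
  spec1 <- structure(list(freqs = seq_along(m1) / 100, mags = m1,
                          harmonic_idx = c(2L, 4L)),
                     class = "harmonic_spectrum")
  cv1 <- peak_prominence_cost(spec1, E0 = 0)
  expect_equal(cv1$value, -sd(c(0, 6, 0)))

  flat <- structure(list(freqs = seq_len(30) / 100, mags = rep(1, 30),
                         harmonic_idx = c(2L, 4L)),
                    class = "harmonic_spectrum")
  cv0 <- peak_prominence_cost(flat, E0 = -1)
  expect_equal(cv0$value, 0)
  expect_false(cv0$viable)
})

test_that("peak-cost amplitude window gates viability", {
  tr <- make_traj(function(t) {
    300 * sin(2 * pi * t / 12) + 40 * sin(2 * pi * t / 6)
  })
  sp <- signal_spectrum(tr, "y", 12)
  in_win <- peak_prominence_cost(sp, E0 = -100, amplitude_window = c(200, 400))
  out_win <- peak_prominence_cost(sp, E0 = -100, amplitude_window = c(350, 400))
  expect_true(in_win$viable)
  expect_false(out_win$viable)
  expect_equal(in_win$value, out_win$value)
})

test_that("time-domain switching cost measures RMS deviation exactly", {
  t <- seq(0, 48, by = 0.1)
  tr1 <- tibble::tibble(time = t, X = rep(0, length(t)), Y = rep(400, length(t)))
  tr2 <- tibble::tibble(time = t, X = rep(400, length(t)), Y = rep(0, length(t)))
  targets <- list(c(X = 0, Y = 400), c(X = 400, Y = 0))
  cv <- time_mse(list(tr1, tr2), targets, tol = 4)
  expect_equal(cv$value, 0)
  expect_true(cv$viable)

  # constant 4 nM offset on one species: RMS pools to 4/sqrt(2) per
  # scenario-species pair but the per-scenario RMS is sqrt(16/2)
  tr1b <- tr1
  tr1b$X <- tr1$X + 4
  cvb <- time_mse(list(tr1b, tr2), targets, tol = 4)
  expect_equal(cvb$diagnostics$rms[1], sqrt(16 / 2))
  expect_true(cvb$viable)
  tr1c <- tr1
  tr1c$X <- tr1$X + 4
  tr1c$Y <- tr1$Y - 4
  cvc <- time_mse(list(tr1c, tr2), targets, tol = 4)
  expect_equal(cvc$diagnostics$rms[1], 4) # boundary-viable
  expect_true(cvc$viable)
  cvd <- time_mse(list(tr1c, tr2), targets, tol = 3.99)
  expect_false(cvd$viable)
})

test_that("printed case-study points satisfy their target costs", {
  mod <- grn_model("repressilator")
  expect_true(evaluate_cost(mod, theta_fig3,
                            preset_cost("repressilator_loose"))$viable)
  ac <- grn_model("acdc")
  expect_true(evaluate_cost(ac, theta_acdc_bistable,
                            preset_cost("acdc_bistable"))$viable)
  expect_true(evaluate_cost(ac, theta_acdc_osc,
                            preset_cost("acdc_oscillatory"))$viable)
  ff <- grn_model("dflipflop", omega1 = 1, omega2 = 1)
  expect_true(evaluate_cost(ff, theta_flipflop,
                            preset_cost("flipflop_counter"))$viable)

  # a dead flip-flop must not pass by harmonic-average dilution
  dead <- c(alpha1 = 0.1, alpha2 = 0.1, alpha3 = 0.1, alpha4 = 0.1,
            delta1 = 1, delta2 = 1, Kd = 100, n = 2)
  expect_false(evaluate_cost(ff, dead, preset_cost("flipflop_counter"))$viable)
})

test_that("leading-harmonic amplitude recovers sine amplitudes within 1%", {
  for (A in c(50, 200, 300)) {
    tr <- make_traj(function(t) A * sin(2 * pi * t / 12))
    m <- measure_oscillation(tr, "y", discard_fraction = 0)
    expect_equal(m$amplitude, A, tolerance = 0.01)
    expect_equal(m$period, 12, tolerance = 0.01)
  }
})
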