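test_that("QSSA projection yields one production and one loss per species", {
  mod <- grn_model("repressilator")
  net <- project_qssa(mod, theta_fig3)
  expect_equal(ncol(net$stoich), 12)
  expect_equal(sum(net$stoich == 1), 6)
  expect_equal(sum(net$stoich == -1), 6)

  # at Z = 0 the mX production propensity is alpha + alpha0
  a <- net$propensity(c(mX = 0, mY = 0, mZ = 0, X = 0, Y = 0, Z = 0), 0)
  expect_equal(a[1], 49.61 + 1.43)
  ff <- grn_model("dflipflop")
  expect_equal(ncol(project_qssa(ff, theta_flipflop)$stoich), 8)
})

test_that("a pure death process follows its exponential mean", {
  delta <- 0.5
  net <- reaction_network("A", matrix(-1, 1, 1),
                          function(x, t) delta * x)
  set.seed(40)
  X0 <- 30
  finals <- vapply(1:1000, function(i) {
    tr <- ssa_run(net, c(A = X0), duration = 2, dt_out = 1)
    tail(tr$A, 1)
  }, numeric(1))
  want <- X0 * exp(-delta * 2)
  se <- sqrt(X0 * exp(-delta * 2) * (1 - exp(-delta * 2)) / 1000)
  expect_lt(abs(mean(finals) - want), 4 * se)
})

test_that("waiting times of a constant-propensity network are exponential", {
  # birth-only process: inter-event times are iid Exp(rate)
  rate <- 7
  net <- reaction_network("A", matrix(1, 1, 1), function(x, t) rate)
  set.seed(41)
  tr <- ssa_run(net, c(A = 0), duration = 300, dt_out = 0.01)
  # counts on a fine grid: reconstruct event times from increments
  inc <- diff(tr$A)
  expect_true(all(inc >= 0))
  n_events <- sum(inc)
  expect_equal(n_events / 300, rate, tolerance = 0.05)
  # Poisson event counts in unit-time windows: mean = variance = rate
  counts <- vapply(split(inc, ceiling(seq_along(inc) / 100)), sum, numeric(1))
  expect_equal(mean(counts), rate, tolerance = 0.1)
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.25)
})

test_that("exact exponential waiting times in the R reference loop", {
  rate <- 3
  net <- reaction_network("A", matrix(1, 1, 1), function(x, t) rate)
  set.seed(42)
  # record true event times by running with a very fine grid
  tr <- ssa_run(net, c(A = 0), duration = 200, dt_out = 0.001)
  ev <- tr$time[c(FALSE, diff(tr$A) > 0)]
  waits <- diff(ev)
  ks <- suppressWarnings(stats::ks.test(waits, "pexp", rate))
  expect_gt(ks$p.value, 0.01)
})

test_that("the SSA ensemble mean approaches the ODE in the scaling limit", {
  mod <- grn_model("repressilator")
  net <- project_qssa(mod, theta_fig3)
  ode <- simulate_grn(mod, theta_fig3, duration = 6, dt_out = 0.1)
  err <- vapply(c(1, 10, 100), function(sc) {
    n_runs <- c(`1` = 40, `10` = 12, `100` = 4)[[as.character(sc)]]
    set.seed(43)
    runs <- simulate_ensemble(net, round(mod$y0 * sc), 6,
                              n_runs = n_runs, dt_out = 0.1, scale = sc)
    mx <- rowMeans(vapply(runs, function(tr) tr$X / sc,
                          numeric(nrow(ode))))
    sqrt(mean((mx - ode$X)^2)) / diff(range(ode$X))
  }, numeric(1))
  expect_lt(err[3], 0.1) # mean-field limit
  expect_lt(err[3], err[1]) # error shrinks with copy number
})

test_that("ensemble summaries are exact on ideal signals", {
  t <- seq(0, 96, by = 0.05)
  mk <- function(ph) {
    structure(tibble::tibble(time = t,
                             X = 150 + 100 * sin(2 * pi * (t + ph) / 12)),
              class = c("grn_trajectory", "tbl_df", "tbl", "data.frame"))
  }
  runs <- lapply(c(0, 3, 6), mk)
  s <- summarize_ensemble(runs, "oscillatory", species = "X",
                          min_prom_frac = 0.1)
  expect_equal(s$summary$mean_amplitude, 100, tolerance = 0.01)
  expect_equal(s$summary$mean_period, 12, tolerance = 0.01)
  expect_equal(s$summary$n_excluded, 0)
  # order invariance
  s2 <- summarize_ensemble(rev(runs), "oscillatory", species = "X",
                           min_prom_frac = 0.1)
  expect_equal(s2$summary, s$summary)

  bist <- lapply(1:3, function(i) {
    structure(tibble::tibble(time = t, X = rep(0, length(t)),
                             Y = rep(400, length(t))),
              class = c("grn_trajectory", "tbl_df", "tbl", "data.frame"))
  })
  sb <- summarize_ensemble(bist, "bistable", species_high = "Y",
                           species_low = "X")
  expect_equal(sb$summary$mean_distance, 400)
})

test_that("stochastic repressilator runs keep oscillating at viable points", {
  mod <- grn_model("repressilator")
  net <- project_qssa(mod, theta_fig3)
  set.seed(44)
  runs <- simulate_ensemble(net, mod$y0, 48, n_runs = 5, dt_out = 0.1)
  s <- summarize_ensemble(runs, "oscillatory", species = "X")
  expect_equal(s$summary$n_excluded, 0)
  expect_equal(s$summary$mean_period, 11.2, tolerance = 0.15)
  det <- measure_oscillation(simulate_grn(mod, theta_fig3), "X")
  # intrinsic noise inflates amplitudes relative to the deterministic run
  expect_gt(s$summary$mean_amplitude, 0.8 * det$amplitude)
})
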