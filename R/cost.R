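#' Specify a viability cost
#'
#' A cost specification pairs a scalar cost function E(theta) with the
#' threshold rule that turns it into the binary viability predicate
#' E(theta) < E0. Three kinds are supported:
#'
#' * `"harmonic_mse"` — sum of squared differences between the first
#'   `n_harmonics` harmonics of the readout and of an ideal sine
#'   (`ideal_amplitude`, `ideal_period`). Viability is expressed as an
#'   average per-harmonic budget: viable when the mean absolute harmonic
#'   deviation `mean(|h_obs - h_ideal|)` is at most `tol` nM (the reading
#'   under which the printed repressilator case-study point sits exactly
#'   on its 10 nM budget), or `E < E0` when an absolute threshold is given
#'   instead. Phase-invariant by construction.
#' * `"peak_prominence"` — a loose oscillation score on the magnitude
#'   spectrum: minus the mean 3-bin standard deviation around each spectral
#'   peak, minus the total drop from the first to the last peak
#'   (frequency-ordered). Sharp, high, isolated peaks give large negative
#'   values. Viable when the value falls below `E0` and the leading
#'   harmonic lies inside `amplitude_window`.
#' * `"time_mse"` — mean squared deviation, in the time domain, from
#'   scenario-specific target levels (bistable switching: the initially
#'   high species must settle at `high_level`, the low one at `low_level`,
#'   under both the reference and the mirrored initial condition). Viable
#'   when the RMS deviation over the evaluation window is at most `tol` nM
#'   in every scenario.
#'
#' @param kind cost kind, see above.
#' @param ideal_amplitude,ideal_period ideal signal, nM and h.
#' @param n_harmonics harmonics compared (`harmonic_mse`) or used to bound
#'   the peak-search band (`peak_prominence`).
#' @param tol per-harmonic (or time-domain RMS) budget in nM. Exactly one
#'   of `tol` and `E0` must be given for `harmonic_mse` / `time_mse`.
#' @param E0 absolute cost threshold.
#' @param amplitude_window length-2 numeric, admissible leading-harmonic
#'   magnitude range in nM (`peak_prominence` only).
#' @param readout species the cost is evaluated on; defaults to the
#'   model's designated readout at evaluation time.
#' @param discard_fraction initial fraction of the evaluation window
#'   dropped before the spectral transform (0 keeps the full window).
#' @param window_fraction final fraction of the window scored by
#'   `time_mse`; the default 0.5 excludes the approach transient, which for
#'   realistic switching trajectories alone exceeds a few-nM RMS budget.
#' @param high_level,low_level bistable target levels in nM.
#' @param label optional tag attached to viable points (e.g. "bistable").
#' @return A `cost_spec` object.
#' @export
cost_spec <- function(kind = c("harmonic_mse", "peak_prominence", "time_mse"),
                      ideal_amplitude = NULL, ideal_period = NULL,
                      n_harmonics = 10, tol = NULL, E0 = NULL,
                      amplitude_window = NULL, readout = NULL,
                      discard_fraction = 0, window_fraction = 0.5,
                      high_level = 400, low_level = 0, label = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("harmonic_mse", "time_mse") &&
      (is.null(tol) + is.null(E0)) != 1) {
    abort("give exactly one of `tol` and `E0`")
  }
  if (kind == "harmonic_mse" &&
      (is.null(ideal_amplitude) || is.null(ideal_period))) {
    abort("harmonic_mse needs ideal_amplitude and ideal_period")
  }
  if (kind == "peak_prominence" && is.null(E0)) {
    abort("peak_prominence needs E0")
  }
  if (!is.null(amplitude_window)) {
    if (kind != "peak_prominence") {
      abort("amplitude_window is only meaningful for peak_prominence")
    }
    stopifnot(length(amplitude_window) == 2)
  }
  structure(list(kind = kind, ideal_amplitude = ideal_amplitude,
                 ideal_period = ideal_period, n_harmonics = n_harmonics,
                 tol = tol, E0 = E0, amplitude_window = amplitude_window,
                 readout = readout, discard_fraction = discard_fraction,
                 window_fraction = window_fraction,
                 high_level = high_level, low_level = low_level,
                 label = label %||% kind),
            class = "cost_spec")
}

#' @export
print.cost_spec <- function(x, ...) {
  thr <- if (!is.null(x$tol)) paste0("tol ", x$tol, " nM") else paste0("E0 ", x$E0)
  cat("<cost_spec> ", x$kind, " (", x$label, "), ", thr, "\n", sep = "")
  invisible(x)
}

cost_value <- function(value, viable, diagnostics = list()) {
  structure(list(value = value, viable = isTRUE(viable),
                 diagnostics = diagnostics), class = "cost_value")
}

#' @export
print.cost_value <- function(x, ...) {
  cat("<cost_value>", format(x$value, digits = 5),
      if (x$viable) "(viable)" else "(not viable)", "\n")
  invisible(x)
}

#' Study cost functions used with the built-in circuits
#'
#' Ready-made [cost_spec()]s: `"repressilator_sine"` (harmonics within
#' 10 nM of a 300 nM / 12 h sine), `"repressilator_loose"` (spectral peak
#' cost below -200 with the leading harmonic between 200 and 400 nM),
#' `"acdc_oscillatory"` (15 nM per-harmonic budget, 200 nM / 12 h ideal),
#' `"acdc_bistable"` (time-domain RMS within 4 nM of the 0 / 400 nM levels
#' under both initial-condition scenarios), and `"flipflop_counter"`
#' (10 nM per-harmonic budget, 50 nM / 48 h ideal on the slave output q).
#'
#' @param name preset name.
#' @return A `cost_spec`.
#' @export
preset_cost <- function(name = c("repressilator_sine", "repressilator_loose",
                                 "acdc_oscillatory", "acdc_bistable",
                                 "flipflop_counter")) {
  switch(match.arg(name),
    repressilator_sine = cost_spec("harmonic_mse", 300, 12, tol = 10,
                                   readout = "X", label = "oscillatory"),
    repressilator_loose = cost_spec("peak_prominence", ideal_period = 12,
                                    E0 = -200,
                                    amplitude_window = c(200, 400),
                                    readout = "X", label = "oscillatory"),
    acdc_oscillatory = cost_spec("harmonic_mse", 200, 12, tol = 15,
                                 readout = "X", label = "oscillatory"),
    acdc_bistable = cost_spec("time_mse", tol = 4, readout = "X",
                              label = "bistable"),
    flipflop_counter = cost_spec("harmonic_mse", 50, 48, tol = 10,
                                 readout = "q", label = "counter"))
}

#' Harmonic mean-squared-error cost
#'
#' `E = sum_i (h_obs_i - h_ideal_i)^2` over the extracted harmonics.
#'
#' @param obs,ideal `harmonic_spectrum` objects on the same grid with equal
#'   harmonic counts.
#' @param tol per-harmonic viability budget (nM): viable iff
#'   `mean(|h_obs - h_ideal|) <= tol`.
#' @param E0 absolute threshold used instead of `tol` when given.
#' @return A `cost_value`; diagnostics carry the leading magnitude.
#' @export
harmonic_mse <- function(obs, ideal, tol = NULL, E0 = NULL) {
  ho <- obs$harmonics$mag
  hi <- ideal$harmonics$mag
  if (length(ho) != length(hi)) abort("harmonic counts differ")
  value <- sum((ho - hi)^2)
  mad <- mean(abs(ho - hi))
  # the target rhythm must actually be present: its fundamental dominates
  # the comb and carries at least half the ideal amplitude. For large
  # ideals the deviation budget already implies this; for small ones
  # (e.g. a 50 nM ideal under a 10 nM x 10-harmonic budget) averaging
  # would otherwise let a flat or wrong-period response through.
  fund_ok <- ho[1] >= max(ho[-1]) && ho[1] >= hi[1] / 2
  viable <- fund_ok && if (!is.null(tol)) mad <= tol else value < E0
  cost_value(value, viable,
             list(leading = leading_magnitude(obs),
                  mean_abs_dev = mad, fundamental = ho[1],
                  rms_per_harmonic = sqrt(value / length(ho))))
}

# strict local maxima with a prominence floor; returns indices
find_spectral_peaks <- function(m, min_prom_frac = 0.01) {
  n <- length(m)
  if (n < 3) return(integer())
  cand <- which(m[2:(n - 1)] > m[1:(n - 2)] & m[2:(n - 1)] > m[3:n]) + 1
  floor_prom <- min_prom_frac * max(m)
  keep <- vapply(cand, function(i) {
    left <- m[1:(i - 1)]
    hil <- which(left > m[i])
    lbase <- min(left[seq(if (length(hil)) max(hil) else 1, i - 1)])
    right <- m[(i + 1):n]
    hir <- which(right > m[i])
    rbase <- min(right[seq_len(if (length(hir)) min(hir) else length(right))])
    (m[i] - max(lbase, rbase)) >= floor_prom
  }, logical(1))
  cand[keep]
}

#' Spectral peak-prominence cost
#'
#' The loose oscillation score: with peaks `g_1..g_P` (frequency-ordered
#' strict local maxima of the magnitude spectrum, within the first
#' `50 * fundamental` band, prominence at least 1% of the spectrum
#' maximum) and `s_i` the standard deviation of the 3-bin window centred
#' on peak i,
#' `E = -mean(s) - sum_{i=2..P} (g_{i-1} - g_i) = -mean(s) - (g_1 - g_P)`.
#' One sharp dominant peak therefore scores strongly negative, while flat
#' or noisy spectra score near 0. No peaks yields 0 and non-viability.
#'
#' @param spec a `harmonic_spectrum` ([signal_spectrum()]).
#' @param E0 viability threshold: viable iff `E < E0`.
#' @param amplitude_window optional admissible range for the leading
#'   magnitude (the amplitude estimate).
#' @param min_prom_frac prominence floor relative to the spectrum maximum.
#' @return A `cost_value`; diagnostics carry the peak count `P`, the mean
#'   window deviation and the leading magnitude.
#' @export
peak_prominence_cost <- function(spec, E0, amplitude_window = NULL,
                                 min_prom_frac = 0.01) {
  max_bin <- min(length(spec$mags), 50L * spec$harmonic_idx[1])
  m <- spec$mags[seq_len(max_bin)]
  pk <- find_spectral_peaks(m, min_prom_frac)
  if (!length(pk)) {
    return(cost_value(0, FALSE, list(P = 0L, mean_sigma = NA_real_,
                                     leading = leading_magnitude(spec))))
  }
  sig <- vapply(pk, function(i) {
    sd(m[max(1, i - 1):min(length(m), i + 1)])
  }, numeric(1))
  g <- m[pk]
  value <- -mean(sig) - (g[1] - g[length(g)])
  lead <- leading_magnitude(spec)
  amp_ok <- is.null(amplitude_window) ||
    (lead >= amplitude_window[1] && lead <= amplitude_window[2])
  cost_value(value, value < E0 && amp_ok,
             list(P = length(pk), mean_sigma = mean(sig), leading = lead))
}

#' Time-domain switching cost
#'
#' Mean squared deviation of the readout species from their scenario
#' target levels, over the final `window_fraction` of each trajectory.
#'
#' @param trajs list of trajectories, one per initial-condition scenario.
#' @param targets list (same length) of named numeric vectors
#'   `c(species = target_level_nM, ...)`.
#' @param tol viability RMS budget in nM, enforced per scenario.
#' @param window_fraction final fraction of the window scored.
#' @return A `cost_value` whose value is the pooled mean squared
#'   deviation; diagnostics carry the per-scenario RMS.
#' @export
time_mse <- function(trajs, targets, tol, window_fraction = 0.5) {
  stopifnot(length(trajs) == length(targets))
  rms <- purrr::map2_dbl(trajs, targets, function(tr, tg) {
    sel <- tr$time >= (1 - window_fraction) * max(tr$time)
    dev2 <- purrr::imap(tg, function(lvl, sp) (tr[[sp]][sel] - lvl)^2)
    sqrt(mean(unlist(dev2)))
  })
  cost_value(mean(rms^2), all(rms <= tol), list(rms = rms))
}

#' Evaluate a cost for one candidate
#'
#' Runs the simulations the cost needs (one trajectory; two for the
#' bistable scenarios) and applies the cost. A failed integration marks
#' the candidate non-viable with infinite cost rather than raising.
#'
#' @param model a [grn_model()].
#' @param theta named numeric vector of free parameters.
#' @param cost a [cost_spec()].
#' @param dt_out,duration simulation control (defaults: 0.05 h and the
#'   model horizon).
#' @return A `cost_value`.
#' @export
evaluate_cost <- function(model, theta, cost, dt_out = 0.05, duration = NULL) {
  traj <- simulate_grn(model, theta, duration = duration, dt_out = dt_out)
  if (!traj_ok(traj)) return(cost_value(Inf, FALSE, list(sim_failed = TRUE)))
  cost_on_traj(model, theta, cost, traj, dt_out = dt_out, duration = duration)
}

cost_on_traj <- function(model, theta, cost, traj, dt_out = 0.05,
                         duration = NULL) {
  readout <- cost$readout %||% model$readout
  if (cost$kind == "harmonic_mse") {
    obs <- signal_spectrum(traj, readout, cost$ideal_period,
                           cost$n_harmonics, cost$discard_fraction)
    ideal <- ideal_harmonics(cost$ideal_amplitude, cost$ideal_period,
                             traj, cost$n_harmonics, cost$discard_fraction)
    harmonic_mse(obs, ideal, tol = cost$tol, E0 = cost$E0)
  } else if (cost$kind == "peak_prominence") {
    obs <- signal_spectrum(traj, readout, cost$ideal_period,
                           cost$n_harmonics, cost$discard_fraction)
    peak_prominence_cost(obs, cost$E0, cost$amplitude_window)
  } else {
    if (is.null(model$y0_mirror)) {
      abort("time_mse needs a model with a mirrored initial-condition scenario")
    }
    traj2 <- simulate_grn(model, theta, y0 = model$y0_mirror,
                          duration = duration, dt_out = dt_out)
    if (!traj_ok(traj2)) return(cost_value(Inf, FALSE, list(sim_failed = TRUE)))
    lo <- cost$low_level; hi <- cost$high_level
    time_mse(list(traj, traj2),
             list(c(X = lo, Y = hi), c(X = hi, Y = lo)),
             tol = cost$tol, window_fraction = cost$window_fraction)
  }
}

#' Build a batch candidate evaluator
#'
#' Returns a closure mapping a matrix of candidates (rows) to a tibble
#' with one row per candidate: `cost` (value of the first satisfied cost,
#' or of the first cost when none is satisfied), `viable` (satisfies at
#' least one cost) and `tag` (label of the first satisfied cost). Each
#' candidate is simulated once per distinct initial-condition scenario and
#' the trajectories are shared across costs.
#'
#' @param model a [grn_model()].
#' @param costs a [cost_spec()] or (possibly named) list of them.
#' @param dt_out output step used during search (coarser than the default
#'   simulation step; the 10th harmonic of every study cost stays far
#'   below the Nyquist frequency).
#' @param duration evaluation horizon (default: model horizon).
#' @return A function `(points) -> tibble(cost, viable, tag)`.
#' @export
candidate_evaluator <- function(model, costs, dt_out = 0.1, duration = NULL) {
  if (inherits(costs, "cost_spec")) costs <- list(costs)
  labels <- vapply(costs, function(cs) cs$label, character(1))
  force(model); force(dt_out); force(duration)

  function(points) {
    points <- as_param_matrix(points, model$space)
    out <- purrr::map_dfr(seq_len(nrow(points)), function(i) {
      theta <- points[i, ]
      traj <- simulate_grn(model, theta, duration = duration, dt_out = dt_out)
      if (!traj_ok(traj)) {
        return(tibble(cost = Inf, viable = FALSE, tag = NA_character_))
      }
      vals <- purrr::map(costs, function(cs) {
        tryCatch(cost_on_traj(model, theta, cs, traj,
                              dt_out = dt_out, duration = duration),
                 error = function(e) cost_value(Inf, FALSE))
      })
      ok <- vapply(vals, `[[`, logical(1), "viable")
      first <- if (any(ok)) which(ok)[1] else 1L
      tibble(cost = vals[[first]]$value, viable = any(ok),
             tag = if (any(ok)) labels[first] else NA_character_)
    })
    out
  }
}
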