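#' Reaction network for stochastic simulation
#'
#' A set of species with integer copy-number state and reactions given by
#' a stoichiometry matrix plus a propensity function. With the reaction
#' volume factor fixed at 1 /nM, one molecule corresponds to 1 nM, so
#' deterministic rate laws translate directly into propensities.
#'
#' @param species character vector of species names.
#' @param stoich integer matrix, species x reactions: state change per
#'   firing.
#' @param propensity `function(x, t)` returning the non-negative reaction
#'   rates at copy-number state `x` and time `t`.
#' @param kernel internal id of a compiled kernel (built-in circuits), or
#'   `NULL` for the plain-R simulator.
#' @param parms parameter vector forwarded to the compiled kernel.
#' @return A `reaction_network`.
#' @export
reaction_network <- function(species, stoich, propensity, kernel = NULL,
                             parms = NULL) {
  stoich <- as.matrix(stoich)
  stopifnot(nrow(stoich) == length(species), is.function(propensity))
  structure(list(species = species, stoich = stoich,
                 propensity = propensity, kernel = kernel, parms = parms),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network>", length(x$species), "species,",
      ncol(x$stoich), "reactions",
      if (!is.null(x$kernel)) "(compiled kernel)" else "", "\n")
  invisible(x)
}

#' Project a deterministic circuit onto its stochastic equivalent
#'
#' Direct QSSA projection: one production and one degradation channel per
#' species, whose propensities are the deterministic production and
#' degradation terms evaluated at the current copy numbers (Hill and
#' Michaelis-Menten factors included). The flip-flop clock stays a
#' deterministic square wave entering the propensities as a time-varying
#' input.
#'
#' @param model a [grn_model()].
#' @param theta named free-parameter vector.
#' @return A `reaction_network` with a compiled kernel attached.
#' @export
project_qssa <- function(model, theta) {
  ns <- length(model$species)
  stoich <- cbind(diag(ns), -diag(ns))
  parms <- unname(c_parms(model, theta))
  mod <- model
  propensity <- function(x, t) {
    state <- setNames(pmax(x, 0), mod$species)
    d <- rhs(mod, state, t, theta)
    # split the net rate into its production and degradation parts
    deg <- degradation_rates(mod, state, t, theta)
    prod <- d + deg
    c(pmax(prod, 0), pmax(deg, 0))
  }
  reaction_network(model$species, stoich, propensity,
                   kernel = model$kernel, parms = parms)
}

# per-species first-order loss rates (always non-negative)
degradation_rates <- function(model, state, t, theta) {
  p <- c_parms(model, theta)
  if (model$id %in% c("repressilator", "acdc")) {
    unname(c(rep(p[["delta_m"]], 3) * state[1:3],
             rep(p[["delta_p"]], 3) * state[4:6]))
  } else {
    P <- sum(state)
    f1 <- if (p[["omega2"]] == 0) {
      p[["delta1"]] * p[["E_prot"]] / (p[["K_M"]] + P) + p[["delta_dil"]]
    } else p[["delta1"]]
    f2 <- if (p[["omega2"]] == 0) {
      p[["delta2"]] * p[["E_prot"]] / (p[["K_M"]] + P) + p[["delta_dil"]]
    } else p[["delta2"]]
    unname(c(f1 * state[1:2], f2 * state[3:4]))
  }
}

#' Gillespie stochastic simulation
#'
#' Exact direct-method simulation of a [reaction_network()]: exponential
#' waiting times at the total propensity, categorical reaction choice.
#' Built-in circuits run in a compiled kernel (the flip-flop truncates
#' waiting times at clock edges, which keeps the method exact for its
#' piecewise-constant propensities); arbitrary networks run in R and
#' assume time-invariant propensities between events.
#'
#' @param net a [reaction_network()].
#' @param y0 non-negative integer initial copy numbers.
#' @param duration simulated time span (h).
#' @param dt_out output grid step (h); the piecewise-constant state is
#'   sampled onto this grid.
#' @param scale copy-number scale factor Omega: propensities become
#'   `Omega * a(x / Omega)`, for probing the mean-field limit.
#' @return A trajectory tibble (`time` plus one column per species) of
#'   class `grn_trajectory`; counts equal concentrations in nM at
#'   `scale = 1`.
#' @export
ssa_run <- function(net, y0, duration, dt_out = 0.05, scale = 1) {
  stopifnot(all(y0 >= 0), duration > 0)
  if (!is.null(names(y0))) y0 <- y0[net$species]
  y0 <- round(y0)
  times <- seq(0, duration, by = dt_out)

  if (!is.null(net$kernel)) {
    m <- .Call("viaspace_ssa_run", as.integer(net$kernel),
               as.double(net$parms), as.double(y0), as.double(times),
               as.double(scale), PACKAGE = "viaspace")
  } else {
    m <- ssa_r_loop(net, y0, times, scale)
  }
  colnames(m) <- net$species
  traj <- as_tibble(as.data.frame(cbind(time = times, m)))
  structure(traj, class = c("grn_trajectory", class(traj)),
            ok = TRUE, clipped = 0L)
}

# plain-R direct method; propensities re-evaluated after every event
ssa_r_loop <- function(net, y0, times, scale = 1) {
  x <- as.numeric(y0)
  nt <- length(times)
  out <- matrix(NA_real_, nt, length(x))
  t <- times[1]
  iout <- 1L
  tend <- times[nt]
  repeat {
    a <- scale * net$propensity(x / scale, t)
    a[!is.finite(a) | a < 0] <- 0
    a0 <- sum(a)
    tnext <- if (a0 <= 0) Inf else t + stats::rexp(1, a0)
    while (iout <= nt && times[iout] < tnext) {
      out[iout, ] <- x
      iout <- iout + 1L
    }
    if (iout > nt || tnext > tend) break
    t <- tnext
    r <- sample.int(length(a), 1, prob = a)
    x <- pmax(x + net$stoich[, r], 0)
  }
  while (iout <= nt) {
    out[iout, ] <- x
    iout <- iout + 1L
  }
  out
}

#' Ensemble of stochastic runs
#'
#' @param net a [reaction_network()].
#' @param y0,duration,dt_out,scale as in [ssa_run()].
#' @param n_runs number of independent runs.
#' @return List of trajectories.
#' @export
simulate_ensemble <- function(net, y0, duration, n_runs = 100,
                              dt_out = 0.05, scale = 1) {
  lapply(seq_len(n_runs), function(i) ssa_run(net, y0, duration, dt_out, scale))
}

#' Summarise a stochastic ensemble
#'
#' Oscillatory mode: cycles are detected with a hysteresis rule — an
#' up-crossing of the mid-level band (half-width `min_prom_frac` of the
#' signal range) opens a new cycle, the maximum within a cycle is its
#' peak and the minimum between consecutive peaks its trough — which is
#' exact on clean periodic signals and robust to shot noise. Each run
#' contributes its mean inter-peak interval (period) and half its mean
#' peak-to-trough excursion (amplitude); runs without at least two
#' detected cycles are excluded from the period average and counted.
#' Bistable mode: each run contributes the distance between the mean
#' levels of the high and low species over the final third of the run.
#'
#' @param runs list of trajectories (e.g. [simulate_ensemble()]).
#' @param mode `"oscillatory"` or `"bistable"`.
#' @param species readout species (oscillatory mode).
#' @param species_high,species_low readouts for the bistable distance.
#' @param min_prom_frac peak prominence floor, as a fraction of the
#'   per-run signal range.
#' @return List with `summary` (one-row tibble: `n_runs`,
#'   `mean_amplitude`, `mean_period` or `mean_distance`, `n_excluded`)
#'   and `per_run` (one row per contributing run).
#' @export
summarize_ensemble <- function(runs, mode = c("oscillatory", "bistable"),
                               species = NULL, species_high = NULL,
                               species_low = NULL, min_prom_frac = 0.2) {
  mode <- match.arg(mode)
  stopifnot(length(runs) >= 1)
  if (mode == "oscillatory") {
    species <- species %||% traj_species(runs[[1]])[1]
    per <- purrr::map_dfr(seq_along(runs), function(i) {
      tr <- runs[[i]]
      cyc <- find_cycles(tr$time, tr[[species]], min_prom_frac)
      if (length(cyc$peaks) < 2) {
        return(tibble(run = i, amplitude = NA_real_, period = NA_real_))
      }
      tibble(run = i,
             amplitude = (mean(cyc$peak_vals) - mean(cyc$trough_vals)) / 2,
             period = mean(diff(tr$time[cyc$peaks])))
    })
    ok <- !is.na(per$period)
    list(summary = tibble(n_runs = length(runs),
                          mean_amplitude = mean(per$amplitude[ok]),
                          mean_period = mean(per$period[ok]),
                          n_excluded = sum(!ok)),
         per_run = per)
  } else {
    stopifnot(!is.null(species_high), !is.null(species_low))
    per <- purrr::map_dfr(seq_along(runs), function(i) {
      tr <- runs[[i]]
      sel <- tr$time >= 2 / 3 * max(tr$time)
      tibble(run = i,
             distance = abs(mean(tr[[species_high]][sel]) -
                              mean(tr[[species_low]][sel])))
    })
    list(summary = tibble(n_runs = length(runs),
                          mean_distance = mean(per$distance),
                          n_excluded = 0L),
         per_run = per)
  }
}

# hysteresis cycle detector: an up-crossing of the band around the
# mid-level opens a cycle; one peak (max) per cycle, one trough (min)
# between consecutive peaks
find_cycles <- function(t, y, min_prom_frac = 0.2) {
  rng <- range(y)
  if (diff(rng) == 0) return(list(peaks = integer(), troughs = integer()))
  mid <- mean(rng)
  h <- min_prom_frac * diff(rng) / 2
  state <- 0L
  ups <- integer()
  for (i in seq_along(y)) {
    if (y[i] > mid + h) {
      if (state <= 0L) ups <- c(ups, i)
      state <- 1L
    } else if (y[i] < mid - h) {
      state <- -1L
    }
  }
  if (length(ups) < 2) return(list(peaks = integer(), troughs = integer()))
  seg <- cbind(ups, c(ups[-1] - 1L, length(y)))
  peaks <- apply(seg, 1, function(s) s[1] - 1L + which.max(y[s[1]:s[2]]))
  troughs <- vapply(seq_len(length(peaks) - 1), function(j) {
    a <- peaks[j]
    b <- peaks[j + 1]
    a - 1L + which.min(y[a:b])
  }, integer(1))
  list(peaks = peaks, troughs = troughs,
       peak_vals = y[peaks], trough_vals = y[troughs])
}
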