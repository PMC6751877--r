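#' Deterministic simulation of a circuit
#'
#' Integrates the model ODEs with a stiff-capable adaptive solver (lsoda,
#' compiled right-hand side) and samples the solution on a uniform output
#' grid. Hill nonlinearities with cooperativity up to 5 make parts of the
#' feasible box stiff, hence the conservative default tolerances.
#'
#' Tiny negative solver excursions are clipped to 0 on output (the number of
#' clipped values is kept in the `clipped` attribute). A solver failure does
#' not raise an error: the returned trajectory carries `ok = FALSE`, so that
#' a search over thousands of candidates can mark the point non-viable and
#' move on.
#'
#' @param model a [grn_model()].
#' @param theta named numeric vector (or 1-row data frame) of free
#'   parameters.
#' @param y0 initial concentrations (nM); defaults to the model's reference
#'   initial state (repressilator: X = 150 nM, everything else 0; AC-DC:
#'   X = 37, Y = Z = 280 nM; flip-flop: all 0).
#' @param duration simulation length in h; defaults to the model's
#'   evaluation horizon (48 h, or 4 clock periods for the flip-flop).
#' @param dt_out output step in h.
#' @param rtol,atol relative / absolute solver tolerances (atol in nM).
#' @return A tibble of class `grn_trajectory` with column `time` (h) and one
#'   column per species (nM). Attributes: `model_id`, `theta`, `ok`,
#'   `clipped`.
#' @examples
#' mod <- grn_model("repressilator")
#' th <- c(alpha = 49.61, alpha0 = 1.43, n = 4.4, beta = 21.83,
#'         delta_m = 1.72, delta_p = 0.78, Kd = 123.12)
#' traj <- simulate_grn(mod, th)
#' measure_oscillation(traj, "X")
#' @export
simulate_grn <- function(model, theta, y0 = NULL, duration = NULL,
                         dt_out = 0.05, rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(model, "grn_model"))
  duration <- duration %||% model$horizon
  if (duration <= 0) abort("duration must be positive")
  y0 <- y0 %||% model$y0
  if (!is.null(names(y0))) y0 <- y0[model$species]
  if (length(y0) != length(model$species) || any(y0 < 0)) {
    abort("y0 must be non-negative and match the model's species")
  }
  parms <- unname(c_parms(model, theta))
  times <- seq(0, duration, by = dt_out)
  out <- try(deSolve::ode(
    y = unname(y0), times = times, parms = parms,
    func = model$deriv, initfunc = model$initfn, dllname = "viaspace",
    method = "lsoda", rtol = rtol, atol = atol, maxsteps = 10000), silent = TRUE)

  ok <- !inherits(out, "try-error") && nrow(out) == length(times) &&
    all(is.finite(out[, -1]))
  if (inherits(out, "try-error") || nrow(out) < 2) {
    m <- matrix(NA_real_, length(times), length(model$species))
    out <- cbind(times, m)
    ok <- FALSE
  } else if (nrow(out) < length(times)) {
    pad <- matrix(NA_real_, length(times) - nrow(out), ncol(out))
    out <- rbind(unclass(out), pad)
  }
  y <- out[, -1, drop = FALSE]
  clipped <- sum(y < 0, na.rm = TRUE)
  y[y < 0] <- 0
  colnames(y) <- model$species
  traj <- as_tibble(as.data.frame(cbind(time = times, y)))
  structure(traj, class = c("grn_trajectory", class(traj)),
            model_id = model$id, theta = as_param_matrix(theta, model$space)[1, ],
            ok = ok, clipped = clipped)
}

traj_ok <- function(traj) isTRUE(attr(traj, "ok"))

traj_dt <- function(traj) {
  t <- traj$time
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-8) abort("trajectory is not uniformly sampled")
  dt[1]
}

traj_species <- function(traj) setdiff(names(traj), "time")

#' Write / read a trajectory as CSV
#'
#' Plain CSV with a one-line unit comment header (`# time: h, species: nM`).
#'
#' @param traj a trajectory from [simulate_grn()] or [ssa_run()].
#' @param path file path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a tibble.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# time: h, species concentrations: nM", con)
  write.csv(as.data.frame(traj), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  as_tibble(read.csv(path, comment.char = "#"))
}

#' @method autoplot grn_trajectory
#' @export
autoplot.grn_trajectory <- function(object, species = NULL, ...) {
  species <- species %||% traj_species(object)
  long <- tidyr::pivot_longer(object, dplyr::all_of(species),
                              names_to = "species", values_to = "conc")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$conc,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [h]", y = "concentration [nM]") +
    ggplot2::theme_minimal()
}
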