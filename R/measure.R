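#' Harmonic spectrum of a trajectory readout
#'
#' Discrete Fourier magnitudes of one species, normalised so that a pure
#' sine of amplitude A reports a leading magnitude of A (nM). The mean
#' (zero-frequency) component is excluded. Harmonics are read at the
#' frequency bins nearest integer multiples of `1/ideal_period`, so a
#' sensible evaluation window is an integer number of ideal periods.
#'
#' @param traj a uniformly sampled trajectory ([simulate_grn()]), or a
#'   data frame with a `time` column.
#' @param species readout species name.
#' @param ideal_period target period in h; fixes the harmonic comb.
#' @param n_harmonics number of harmonics to extract.
#' @param discard_fraction fraction of the window dropped from the start
#'   before the transform (transient removal; 0 disables).
#' @return An object of class `harmonic_spectrum`: a list with the full
#'   one-sided `freqs` (1/h) and `mags` (nM), the harmonic positions
#'   `harmonic_idx`, the extracted `harmonics` tibble and
#'   `fundamental_index` (index, among all bins, of the largest magnitude).
#' @export
signal_spectrum <- function(traj, species, ideal_period, n_harmonics = 10,
                            discard_fraction = 0) {
  dt <- traj_dt(traj)
  y <- traj[[species]]
  if (discard_fraction > 0) {
    y <- y[traj$time >= discard_fraction * max(traj$time)]
  }
  if (length(y) * dt < 2 * ideal_period) abort("insufficient duration")
  sp <- raw_spectrum(y, dt)
  idx <- vapply(seq_len(n_harmonics),
                function(i) which.min(abs(sp$freqs - i / ideal_period)),
                integer(1))
  structure(
    list(freqs = sp$freqs, mags = sp$mags,
         harmonic_idx = idx,
         harmonics = tibble(harmonic = seq_len(n_harmonics),
                            freq = sp$freqs[idx], mag = sp$mags[idx]),
         fundamental_index = which.max(sp$mags)),
    class = "harmonic_spectrum")
}

# one-sided magnitude spectrum without the DC bin; amplitude normalisation
raw_spectrum <- function(y, dt) {
  y <- y - mean(y)
  n <- length(y)
  half <- seq(2, n %/% 2)
  list(freqs = (half - 1) / (n * dt), mags = Mod(fft(y))[half] * 2 / n)
}

#' @export
print.harmonic_spectrum <- function(x, ...) {
  cat("<harmonic_spectrum> leading", round(leading_magnitude(x), 2),
      "nM at period", round(1 / x$freqs[x$fundamental_index], 3), "h\n")
  print(x$harmonics)
  invisible(x)
}

leading_magnitude <- function(spec) max(spec$mags)

#' Spectrum of the ideal oscillatory signal
#'
#' The ideal signal is `A * sin(2*pi*t/T)` sampled on the same time grid as
#' the observed trajectory, so that finite-window and discretisation biases
#' affect observed and ideal harmonics alike and cancel in the cost.
#'
#' @param amplitude A in nM.
#' @param period T in h.
#' @param grid time grid: a numeric vector of times or a trajectory to copy
#'   the grid from.
#' @param n_harmonics,discard_fraction as in [signal_spectrum()].
#' @return A `harmonic_spectrum`.
#' @export
ideal_harmonics <- function(amplitude, period, grid, n_harmonics = 10,
                            discard_fraction = 0) {
  stopifnot(amplitude > 0, period > 0)
  if (is.data.frame(grid)) grid <- grid$time
  traj <- tibble(time = grid, y = amplitude * sin(2 * pi * grid / period))
  signal_spectrum(traj, "y", period, n_harmonics, discard_fraction)
}

#' Amplitude and period of an oscillatory readout
#'
#' Spectral measurement over the post-transient window: the oscillation
#' amplitude is the magnitude of the leading (largest) spectral component
#' and the period is the inverse of its frequency. This is the same
#' convention the harmonic cost functions use, and it is robust to the
#' non-sinusoidal, spiky waveforms relaxation-type gene oscillators
#' produce (where half the peak-to-trough excursion overestimates the
#' dominant component).
#'
#' @param traj a trajectory.
#' @param species one or more readout species.
#' @param discard_fraction initial fraction of the window dropped as
#'   transient before measuring.
#' @return A tibble with one row per species: `amplitude` (nM), `period`
#'   (h) and `oscillating` (TRUE when the leading component rises above
#'   both 1 nM and 2% of the signal range — a floor that separates decaying
#'   or flat responses from sustained rhythms).
#' @export
measure_oscillation <- function(traj, species = NULL, discard_fraction = 0.25) {
  species <- species %||% traj_species(traj)
  dt <- traj_dt(traj)
  purrr::map_dfr(species, function(sp) {
    y <- traj[[sp]][traj$time >= discard_fraction * max(traj$time)]
    s <- raw_spectrum(y, dt)
    i <- which.max(s$mags)
    tibble(species = sp, amplitude = s$mags[i], period = 1 / s$freqs[i],
           oscillating = s$mags[i] > pmax(1, 0.02 * diff(range(y))))
  })
}

#' Late-time steady level of a readout
#'
#' Mean concentration over the final fraction of the trajectory, with the
#' spread over the same window reported as a stationarity diagnostic.
#'
#' @param traj a trajectory.
#' @param species one or more species.
#' @param tail_fraction final fraction of the window to average over.
#' @return A tibble with `level` (nM) and `spread` (sd over the window, nM).
#' @export
steady_state_level <- function(traj, species = NULL, tail_fraction = 0.25) {
  species <- species %||% traj_species(traj)
  sel <- traj$time >= (1 - tail_fraction) * max(traj$time)
  purrr::map_dfr(species, function(sp) {
    tibble(species = sp, level = mean(traj[[sp]][sel]),
           spread = sd(traj[[sp]][sel]))
  })
}
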