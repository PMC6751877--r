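#' Define a gene-circuit model
#'
#' Three benchmark circuits are built in:
#'
#' * `"repressilator"` — three repressors in a negative-feedback ring
#'   (6 species: mRNAs `mX`, `mY`, `mZ` and proteins `X`, `Y`, `Z`).
#' * `"acdc"` — the AC-DC circuit, a repressilator sharing two edges with a
#'   toggle switch; capable of oscillations ("AC") and bistability ("DC").
#'   Same 6 species. The signalling molecule is not modelled.
#' * `"dflipflop"` — an edge-triggered master-slave D flip-flop driven by a
#'   square-wave clock (4 species: `a`, `a_c`, `q`, `q_c`). Two binary
#'   structure flags select the functional forms: `omega1` chooses
#'   competitive (0) or independent (1) binding of the input and clock at
#'   the master promoters, `omega2` chooses Michaelian (0, protease-shared
#'   with dilution) or linear (1) protein degradation. In counter mode the
#'   input `d` is wired to `q_c`, so a viable flip-flop halves the clock
#'   frequency.
#'
#' Each model carries its feasible [parameter_space()] with field-typical
#' prokaryote/eukaryote rate ranges: transcription and translation
#' 1e-2–50 /h, protein production 0.1–50 /h, protein degradation
#' 1e-3–50 /h, mRNA degradation 0.1–100 /h, dissociation and Michaelis
#' constants 1e-2–250 nM, protease concentration 10–1000 nM, Hill
#' coefficient 1–5; the dilution rate is fixed at 0.6 /h and the reaction
#' volume factor at 1 /nM.
#'
#' @param id one of `"repressilator"`, `"acdc"`, `"dflipflop"`.
#' @param omega1,omega2 flip-flop structure flags (0 or 1); ignored for the
#'   other circuits.
#' @param clk_period,clk_amplitude,clk_duty square-wave clock driving the
#'   flip-flop: period in h, amplitude in nM, duty as a fraction of the
#'   period spent high. The clock is high at phase 0.
#' @param d_mode `"counter"` wires the flip-flop input `d` to `q_c`
#'   (1-bit counter); `"constant"` holds it at `d_value` nM.
#' @param d_value constant input level, used when `d_mode = "constant"`.
#' @return An object of class `grn_model`: a list with the species names,
#'   free-parameter space, fixed constants, default initial conditions,
#'   default evaluation horizon and the designated readout species.
#' @examples
#' mod <- grn_model("repressilator")
#' mod$space
#' @export
grn_model <- function(id = c("repressilator", "acdc", "dflipflop"),
                      omega1 = 1, omega2 = 1,
                      clk_period = 24, clk_amplitude = 100, clk_duty = 0.5,
                      d_mode = c("counter", "constant"), d_value = 0) {
  id <- match.arg(id)
  d_mode <- match.arg(d_mode)
  if (!omega1 %in% c(0, 1) || !omega2 %in% c(0, 1)) {
    abort("omega1 and omega2 must be 0 or 1")
  }

  if (id == "repressilator") {
    space <- parameter_space(
      c("alpha", "alpha0", "n", "beta", "delta_m", "delta_p", "Kd"),
      lower = c(1e-2, 1e-2, 1, 1e-2, 1e-1, 1e-3, 1e-2),
      upper = c(50, 50, 5, 50, 100, 50, 250))
    out <- list(
      id = id, species = c("mX", "mY", "mZ", "X", "Y", "Z"),
      space = space, fixed = double(),
      y0 = c(mX = 0, mY = 0, mZ = 0, X = 150, Y = 0, Z = 0),
      horizon = 48, readout = "X",
      deriv = "viaspace_deriv_rep", initfn = "viaspace_init_rep",
      kernel = 1L)
  } else if (id == "acdc") {
    space <- parameter_space(
      c("alpha", "n", "beta", "delta_m", "delta_p",
        "Kd_a", "Kd_b", "Kd_c", "Kd_d"),
      lower = c(1e-2, 1, 1e-2, 1e-1, 1e-3, 1e-2, 1e-2, 1e-2, 1e-2),
      upper = c(50, 5, 50, 100, 50, 250, 250, 250, 250))
    out <- list(
      id = id, species = c("mX", "mY", "mZ", "X", "Y", "Z"),
      space = space, fixed = double(),
      y0 = c(mX = 0, mY = 0, mZ = 0, X = 37, Y = 280, Z = 280),
      # mirrored bistability scenario: initial X high, Y low
      y0_mirror = c(mX = 0, mY = 0, mZ = 0, X = 280, Y = 37, Z = 280),
      horizon = 48, readout = "X",
      deriv = "viaspace_deriv_acdc", initfn = "viaspace_init_acdc",
      kernel = 2L)
  } else {
    nm <- c("alpha1", "alpha2", "alpha3", "alpha4",
            "delta1", "delta2", "Kd", "n")
    lo <- c(0.1, 0.1, 0.1, 0.1, 1e-3, 1e-3, 1e-2, 1)
    hi <- c(50, 50, 50, 50, 50, 50, 250, 5)
    if (omega2 == 0) { # Michaelian degradation brings K_M and E into play
      nm <- c(nm, "K_M", "E_prot")
      lo <- c(lo, 1e-2, 10)
      hi <- c(hi, 250, 1000)
    }
    space <- parameter_space(nm, lo, hi)
    fixed <- c(delta_dil = 0.6, omega1 = omega1, omega2 = omega2,
               clk_period = clk_period, clk_amplitude = clk_amplitude,
               clk_duty = clk_duty,
               d_mode = if (d_mode == "counter") 0 else 1, d_value = d_value)
    if (omega2 == 1) fixed <- c(K_M = 1, E_prot = 0, fixed) # unused slots
    out <- list(
      id = id, species = c("a", "a_c", "q", "q_c"),
      space = space, fixed = fixed,
      y0 = c(a = 0, a_c = 0, q = 0, q_c = 0),
      horizon = 4 * clk_period, readout = "q",
      deriv = "viaspace_deriv_ff", initfn = "viaspace_init_ff",
      kernel = 3L)
  }
  structure(out, class = "grn_model")
}

#' @export
print.grn_model <- function(x, ...) {
  cat("<grn_model> ", x$id, ": ", length(x$species), " species, ",
      nrow(x$space), " free parameters\n", sep = "")
  invisible(x)
}

# full parameter vector in the order the compiled derivatives expect
c_parms <- function(model, theta) {
  theta <- as_param_matrix(theta, model$space)[1, ]
  if (model$id == "dflipflop") {
    f <- model$fixed
    th <- c(theta, f[setdiff(names(f), names(theta))])
    th[c("alpha1", "alpha2", "alpha3", "alpha4", "delta1", "delta2",
         "Kd", "n", "K_M", "E_prot", "delta_dil", "omega1", "omega2",
         "clk_period", "clk_amplitude", "clk_duty", "d_mode", "d_value")]
  } else {
    theta
  }
}

#' Square-wave clock signal
#'
#' Exogenous synchronisation input for the flip-flop. The wave is high
#' (`amplitude`) on the first `duty` fraction of each period, starting at
#' `t = 0`, and 0 otherwise.
#'
#' @param t time(s) in h (vectorised).
#' @param period clock period in h.
#' @param amplitude high level in nM.
#' @param duty fraction of the period spent high, in (0, 1).
#' @return Numeric vector of clock levels (nM).
#' @examples
#' clk_signal(c(0, 13, 24.5), period = 24, amplitude = 100)
#' @export
clk_signal <- function(t, period, amplitude = 100, duty = 0.5) {
  stopifnot(period > 0, duty > 0, duty < 1)
  ifelse((t %% period) < duty * period, amplitude, 0)
}

#' Model right-hand side
#'
#' Evaluates the time derivatives of the circuit ODEs at one state. This is
#' the reference R implementation of the rate laws; [simulate_grn()] uses an
#' equivalent compiled version.
#'
#' @param model a [grn_model()].
#' @param state named or ordered numeric vector of concentrations (nM).
#' @param t time in h (relevant for the clocked flip-flop).
#' @param theta named numeric vector of free parameters.
#' @return Numeric vector of derivatives (nM/h), in species order.
#' @export
rhs <- function(model, state, t, theta) {
  if (length(state) != length(model$species)) {
    abort("state length does not match the model's species")
  }
  state <- if (is.null(names(state))) setNames(state, model$species)
           else state[model$species]
  p <- c_parms(model, theta)
  kd <- p[grepl("^Kd|^K_M", names(p))]
  if (any(kd < 0)) abort("negative dissociation/Michaelis constant")
  hill <- function(x, Kd, n) if (x <= 0) 0 else (x / Kd)^n

  if (model$id == "repressilator") {
    with(as.list(c(state, p)), {
      c(-delta_m * mX + alpha / (1 + hill(Z, Kd, n)) + alpha0,
        -delta_m * mY + alpha / (1 + hill(X, Kd, n)) + alpha0,
        -delta_m * mZ + alpha / (1 + hill(Y, Kd, n)) + alpha0,
        beta * mX - delta_p * X,
        beta * mY - delta_p * Y,
        beta * mZ - delta_p * Z)
    })
  } else if (model$id == "acdc") {
    with(as.list(c(state, p)), {
      c(-delta_m * mX + alpha / (1 + hill(Z, Kd_a, n) + hill(Y, Kd_b, n)),
        -delta_m * mY + alpha / (1 + hill(X, Kd_c, n)),
        -delta_m * mZ + alpha / (1 + hill(Y, Kd_d, n)),
        beta * mX - delta_p * X,
        beta * mY - delta_p * Y,
        beta * mZ - delta_p * Z)
    })
  } else {
    with(as.list(c(state, p)), {
      CLK <- clk_signal(t, clk_period, clk_amplitude, clk_duty)
      d <- if (d_mode == 0) q_c else d_value
      hd <- hill(d, Kd, n); hc <- hill(CLK, Kd, n)
      ha <- hill(a, Kd, n); hac <- hill(a_c, Kd, n)
      hq <- hill(q, Kd, n); hqc <- hill(q_c, Kd, n)
      den_m <- 1 + hd + hc + omega1 * hd * hc
      P <- a + a_c + q + q_c
      f1 <- if (omega2 == 0) delta1 * E_prot / (K_M + P) + delta_dil else delta1
      f2 <- if (omega2 == 0) delta2 * E_prot / (K_M + P) + delta_dil else delta2
      c(alpha1 * hd / den_m + alpha2 / (1 + hac) - a * f1,
        alpha1 / den_m + alpha2 / (1 + ha) - a_c * f1,
        alpha3 * ha * hc / (1 + ha + hc + ha * hc) + alpha4 / (1 + hqc) - q * f2,
        alpha3 * hac * hc / (1 + hac + hc + hac * hc) + alpha4 / (1 + hq) - q_c * f2)
    })
  }
}
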