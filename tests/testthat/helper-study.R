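# Printed parameter sets of the three case studies, used across tests.

theta_fig3 <- c(alpha = 49.61, alpha0 = 1.43, n = 4.4, beta = 21.83,
                delta_m = 1.72, delta_p = 0.78, Kd = 123.12)

theta_acdc_bistable <- c(alpha = 5.91, n = 4.16, beta = 47.35,
                         delta_m = 0.63, delta_p = 1.12, Kd_a = 165.03,
                         Kd_b = 111.2, Kd_c = 101.5, Kd_d = 0.48)

theta_acdc_osc <- c(alpha = 26.26, n = 3.82, beta = 18.14, delta_m = 0.92,
                    delta_p = 1.29, Kd_a = 151.42, Kd_b = 197.61,
                    Kd_c = 41.88, Kd_d = 11.7)

theta_flipflop <- c(alpha1 = 34.73, alpha2 = 49.36, alpha3 = 32.73,
                    alpha4 = 49.54, delta1 = 1.93, delta2 = 0.69,
                    Kd = 4.44, n = 4.35)

# synthetic viability oracle wrapped as a batch evaluator; the cost is the
# distance to `center` so a GA has a gradient to follow
oracle_evaluator <- function(oracle, center = NULL) {
  function(points) {
    pts <- as.matrix(points)
    v <- oracle(pts)
    cost <- if (is.null(center)) as.numeric(!v)
            else sqrt(rowSums(sweep(pts, 2, center)^2))
    tibble::tibble(cost = cost, viable = v, tag = NA_character_)
  }
}

box_oracle <- function(lo, hi) {
  function(pts) {
    pts <- as.matrix(pts)
    rowSums(sweep(pts, 2, lo, ">=") & sweep(pts, 2, hi, "<=")) == ncol(pts)
  }
}

unit_space <- function(p, lo = 0, hi = 10) {
  parameter_space(paste0("x", seq_len(p)), rep(lo, p), rep(hi, p))
}

# independent brute-force DFT oracle: amplitude of the component at
# frequency f in a uniformly sampled signal
dft_amplitude <- function(y, t, f) {
  y <- y - mean(y)
  Mod(sum(y * exp(-2i * pi * f * t))) * 2 / length(y)
}
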