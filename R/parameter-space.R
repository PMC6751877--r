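#' Construct a parameter space
#'
#' A parameter space is the Cartesian product of per-parameter feasible
#' ranges: the hyper-box every candidate must live in. It is represented as
#' a tibble with one row per free parameter plus an attribute holding fixed
#' (non-searched) constants such as the dilution rate.
#'
#' @param parameter character vector of parameter names.
#' @param lower,upper numeric vectors of per-parameter bounds
#'   (units as in the model definition: rates in 1/h, constants in nM).
#' @param fixed named numeric vector of constants excluded from the search.
#' @return A tibble of class `param_space` with columns `parameter`,
#'   `lower`, `upper` and attribute `fixed`.
#' @examples
#' parameter_space(c("k1", "Kd"), lower = c(0.01, 0.01), upper = c(50, 250))
#' @export
parameter_space <- function(parameter, lower, upper, fixed = double()) {
  stopifnot(length(parameter) == length(lower), length(lower) == length(upper))
  if (any(lower >= upper)) {
    abort("every lower bound must be strictly below its upper bound")
  }
  if (anyDuplicated(parameter)) abort("duplicated parameter names")
  out <- tibble(parameter = as.character(parameter),
                lower = as.numeric(lower), upper = as.numeric(upper))
  attr(out, "fixed") <- fixed
  class(out) <- c("param_space", class(out))
  out
}

#' @export
print.param_space <- function(x, ...) {
  cat("<param_space> ", nrow(x), " free parameters\n", sep = "")
  NextMethod()
  fx <- attr(x, "fixed")
  if (length(fx)) {
    cat("fixed:", paste(names(fx), fx, sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

n_params <- function(space) nrow(space)

space_span <- function(space) setNames(space$upper - space$lower, space$parameter)

#' Volume of the full feasible hyper-box
#'
#' Product of the free-parameter ranges; fixed parameters do not contribute.
#' Used as the denominator of relative viable volumes.
#'
#' @param space a [parameter_space()].
#' @return A single number in the product of the parameter units.
#' @export
space_volume <- function(space) prod(space$upper - space$lower)

#' Check candidate points against parameter bounds
#'
#' @param theta a numeric vector (one candidate) or a matrix / data frame of
#'   candidates in rows, columns ordered or named as `space$parameter`.
#' @param space a [parameter_space()].
#' @return Logical vector, `TRUE` where all coordinates satisfy
#'   `lower <= value <= upper` (bounds inclusive).
#' @examples
#' sp <- parameter_space(c("a", "b"), c(0, 0), c(1, 2))
#' check_bounds(c(a = 0, b = 2), sp)
#' @export
check_bounds <- function(theta, space) {
  m <- as_param_matrix(theta, space)
  ok_lo <- sweep(m, 2, space$lower, ">=")
  ok_hi <- sweep(m, 2, space$upper, "<=")
  unname(rowSums(ok_lo & ok_hi) == ncol(m))
}

# coerce vector/matrix/data frame to a matrix with columns in space order
as_param_matrix <- function(theta, space) {
  if (is.data.frame(theta)) theta <- as.matrix(theta[space$parameter])
  if (is.null(dim(theta))) {
    if (!is.null(names(theta))) theta <- theta[space$parameter]
    theta <- matrix(theta, nrow = 1, dimnames = list(NULL, space$parameter))
  }
  if (ncol(theta) != nrow(space)) {
    abort("candidate dimension does not match the parameter space")
  }
  if (!is.null(colnames(theta))) theta <- theta[, space$parameter, drop = FALSE]
  else colnames(theta) <- space$parameter
  theta
}

clip_to_bounds <- function(m, space) {
  m <- sweep(m, 2, space$lower, pmax)
  sweep(m, 2, space$upper, pmin)
}
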