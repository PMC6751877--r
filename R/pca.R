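#' Principal-component basis of a viable point cloud
#'
#' Fits mean, orthonormal directions and per-direction standard deviations
#' of the cloud (linear coordinates). When the cloud is rank deficient —
#' fewer points than dimensions, or flat directions — the component matrix
#' is completed to a full orthonormal basis with zero standard deviations
#' on the added directions and flagged.
#'
#' @param points matrix of points in rows.
#' @return A `pca_basis`: list with `mean` (length p), `components`
#'   (p x p, rows are principal directions, decreasing variance), `sdevs`
#'   and the `rank_deficient` flag.
#' @export
fit_pca <- function(points) {
  points <- as.matrix(points)
  p <- ncol(points)
  pc <- prcomp(points, center = TRUE, scale. = FALSE)
  comp <- t(pc$rotation)            # rows = principal directions
  sdev <- pc$sdev
  deficient <- nrow(comp) < p || any(sdev < 1e-12)
  if (nrow(comp) < p) {
    base <- qr.Q(qr(t(rbind(comp, matrix(rnorm(p * p), p, p)))))[, seq_len(p)]
    comp <- rbind(comp, t(base[, (nrow(comp) + 1):p, drop = FALSE]))
    sdev <- c(sdev, rep(0, p - length(sdev)))
  }
  structure(list(mean = unname(pc$center), components = unname(comp),
                 sdevs = sdev[seq_len(p)], rank_deficient = deficient,
                 names = colnames(points)),
            class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat("<pca_basis> p =", length(x$mean),
      "sdevs:", paste(signif(x$sdevs, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Gaussian proposals along principal components
#'
#' Draws `n` candidates `mean + sum_j z_j * lam * sdev_j * component_j`
#' with standard normal `z`. The variance inflation `lam >= 1` widens the
#' proposal beyond the cloud's own spread so unexplored viable territory
#' keeps being probed. Proposals are returned unfiltered, with an
#' `in_bounds` attribute marking which fall inside the feasible box (out-
#' of-bounds proposals are discarded before evaluation by the caller).
#'
#' @param basis a [fit_pca()] basis.
#' @param lam variance scaling factor (>= 1).
#' @param n number of proposals.
#' @param space a [parameter_space()] for the bounds flag.
#' @return An `n x p` matrix with attribute `in_bounds` (logical).
#' @export
sample_candidates <- function(basis, lam, n, space) {
  stopifnot(lam >= 1, n > 0)
  p <- length(basis$mean)
  if (all(basis$sdevs == 0)) {
    warn("degenerate basis: all proposals equal the mean")
  }
  z <- matrix(rnorm(n * p), n, p)
  x <- sweep(z, 2, lam * basis$sdevs, "*") %*% basis$components
  x <- sweep(x, 2, basis$mean, "+")
  colnames(x) <- basis$names %||% space$parameter
  attr(x, "in_bounds") <- check_bounds(x, space)
  x
}

#' Variance-scaling schedule
#'
#' Linear interpolation from `lambda_start` in the first iteration to
#' `lambda_end` in the last: wide early exploration, focused late
#' sampling.
#'
#' @param i iteration (1-based).
#' @param config a [sampler_config()].
#' @return The scaling factor for iteration `i`.
#' @export
lambda_at <- function(i, config) {
  stopifnot(i >= 1, i <= config$iterations)
  if (config$iterations == 1) return(config$lambda_start)
  config$lambda_start +
    (i - 1) / (config$iterations - 1) *
      (config$lambda_end - config$lambda_start)
}

#' Convergence of the principal components
#'
#' Frobenius norm of the difference between consecutive component
#' matrices. Principal directions are only defined up to sign, and
#' directions with (near-)equal variance up to relabeling, so the current
#' rows are first matched greedily to the previous rows by absolute inner
#' product and sign-aligned; the norm is computed on the aligned matrix.
#'
#' @param current,previous `pca_basis` objects of equal dimension.
#' @return The alignment-invariant Frobenius norm.
#' @export
convergence_norm <- function(current, previous) {
  a <- current$components
  b <- previous$components
  stopifnot(all(dim(a) == dim(b)))
  p <- nrow(a)
  M <- a %*% t(b)
  ord <- integer(p)
  used_a <- rep(FALSE, p)
  used_b <- rep(FALSE, p)
  absM <- abs(M)
  for (k in seq_len(p)) {
    absM[used_a, ] <- -Inf
    absM[, used_b] <- -Inf
    ij <- arrayInd(which.max(absM), dim(absM))
    ord[ij[2]] <- ij[1]
    used_a[ij[1]] <- TRUE
    used_b[ij[2]] <- TRUE
  }
  aligned <- a[ord, , drop = FALSE]
  flip <- sign(rowSums(aligned * b))
  flip[flip == 0] <- 1
  norm(aligned * flip - b, type = "F")
}
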