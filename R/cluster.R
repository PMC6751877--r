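#' Gap-statistic estimate of the number of clusters
#'
#' Compares `log(W_k)` — the log within-cluster sum of squares from
#' K-means — against its expectation under a null of uniform points drawn
#' over the bounding hyper-box aligned with the principal components of
#' the data (the rotation-invariant reference choice). The gap
#' `G(k) = E*[log W_k] - log W_k` is largest at the true cluster count:
#' for well-separated clusters `log W_k` drops faster than the uniform
#' reference up to the true k and slower after it.
#'
#' @param points matrix of observations in rows. Mixed-unit biochemical
#'   coordinates should be standardised (e.g. by the bounds span) before
#'   clustering; [explore_regions()] does this internally.
#' @param k_max largest cluster count considered.
#' @param n_ref number of uniform reference data sets.
#' @param nstart K-means restarts.
#' @return List of class `gap_statistic`: `k` (the argmax of the gap),
#'   and a `table` tibble with `k`, `logW`, `ElogW`, `gap`.
#' @export
gap_statistic <- function(points, k_max = 2, n_ref = 20, nstart = 10) {
  points <- as.matrix(points)
  n <- nrow(points)
  p <- ncol(points)
  stopifnot(n >= k_max * (p + 1))

  logW <- vapply(seq_len(k_max), function(k) log(within_ss(points, k, nstart)),
                 numeric(1))
  # uniform reference over the PCA-aligned bounding box of the data
  ctr <- colMeans(points)
  rot <- prcomp(points, center = TRUE, scale. = FALSE)$rotation
  proj <- sweep(points, 2, ctr) %*% rot
  lo <- apply(proj, 2, min)
  hi <- apply(proj, 2, max)
  ElogW <- rowMeans(vapply(seq_len(n_ref), function(r) {
    u <- sweep(sweep(matrix(runif(n * ncol(proj)), n), 2, hi - lo, "*"),
               2, lo, "+")
    ref <- sweep(u %*% t(rot), 2, ctr, "+")
    vapply(seq_len(k_max), function(k) log(within_ss(ref, k, nstart)),
           numeric(1))
  }, numeric(k_max)))

  gap <- ElogW - logW
  structure(list(k = which.max(gap),
                 table = tibble(k = seq_len(k_max), logW = logW,
                                ElogW = ElogW, gap = gap)),
            class = "gap_statistic")
}

#' @export
print.gap_statistic <- function(x, ...) {
  cat("<gap_statistic> optimal k =", x$k, "\n")
  print(x$table)
  invisible(x)
}

# within-cluster sum of squares around cluster means; K-means with
# bounded retries on non-convergence
within_ss <- function(points, k, nstart = 10) {
  if (k == 1) return(sum(sweep(points, 2, colMeans(points))^2))
  for (attempt in 1:5) {
    km <- suppressWarnings(kmeans(points, centers = k, nstart = nstart,
                                  iter.max = 50))
    if (km$ifault == 0 || attempt == 5) return(km$tot.withinss)
  }
}

#' Should a region be re-clustered?
#'
#' Clustering is expensive, so it is only attempted when one of three
#' triggers fires: (1) the iteration budget is exhausted; (2) the number
#' of viable points found this iteration collapsed to less than
#' `1/shrink_ratio` of the previous iteration's count — the signature of a
#' sampler straddling well-separated sub-regions; (3) the principal
#' components jumped by more than the convergence threshold `C0` between
#' iterations.
#'
#' @param i current iteration.
#' @param iterations iteration budget.
#' @param n_now,n_prev viable points found in this / the previous
#'   iteration.
#' @param C principal-component change ([convergence_norm()]), or `NA`
#'   when no history exists yet.
#' @param C0 convergence threshold.
#' @param shrink_ratio collapse factor for trigger (2).
#' @return `TRUE` when any trigger fires.
#' @export
should_cluster <- function(i, iterations, n_now, n_prev, C = NA,
                           C0 = Inf, shrink_ratio = 10) {
  crit1 <- i >= iterations
  crit2 <- is.finite(n_prev) && n_now < n_prev / shrink_ratio
  crit3 <- !is.na(C) && C > C0
  crit1 || crit2 || crit3
}
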