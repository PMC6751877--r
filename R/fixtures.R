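#' Synthetic fixtures with known ground truth
#'
#' Reproducible point clouds and analytic viability oracles used to test
#' the clustering, exploration and volume machinery against exact
#' answers:
#'
#' * `"gaussian_blobs"` — `k` isotropic Gaussian clusters of `n` points
#'   each in `p` dimensions, cluster centres `separation * sdev` apart
#'   along the first axis; returns points and true labels.
#' * `"uniform_box"` — `n` uniform points in the box `[lo, hi]^p`.
#' * `"two_boxes_oracle"` — viability oracle that is true inside either
#'   of two disjoint axis-aligned boxes; returns the oracle, the boxes
#'   and the exact viable volume (sum of the box volumes).
#' * `"sphere_oracle"` — oracle true inside the ball of `radius` centred
#'   in the cube `[0, 2 radius]^p`; for `p = 3` the viable fraction of
#'   the cube is exactly pi/6.
#'
#' Randomness comes from the caller's RNG state (use [set.seed()]).
#'
#' @param kind fixture kind.
#' @param n points per cluster / total points.
#' @param p dimension.
#' @param k cluster count (`gaussian_blobs`).
#' @param separation centre separation in units of `sdev`.
#' @param sdev cluster standard deviation.
#' @param lo,hi box bounds (`uniform_box`), recycled over dimensions.
#' @param boxes list of two `list(lo=, hi=)` boxes (`two_boxes_oracle`);
#'   defaults to unit boxes at the origin and at 5 along every axis.
#' @param radius sphere radius.
#' @return See the kind descriptions.
#' @export
make_fixture <- function(kind = c("gaussian_blobs", "uniform_box",
                                  "two_boxes_oracle", "sphere_oracle"),
                         n = 200, p = 3, k = 2, separation = 20, sdev = 1,
                         lo = 0, hi = 1, boxes = NULL, radius = 1) {
  kind <- match.arg(kind)
  switch(kind,
    gaussian_blobs = {
      centers <- matrix(0, k, p)
      centers[, 1] <- (seq_len(k) - 1) * separation * sdev
      pts <- do.call(rbind, lapply(seq_len(k), function(j) {
        sweep(matrix(rnorm(n * p, sd = sdev), n, p), 2, centers[j, ], "+")
      }))
      colnames(pts) <- paste0("x", seq_len(p))
      list(points = pts, labels = rep(seq_len(k), each = n),
           centers = centers)
    },
    uniform_box = {
      lo <- rep_len(lo, p); hi <- rep_len(hi, p)
      pts <- sweep(sweep(matrix(runif(n * p), n, p), 2, hi - lo, "*"),
                   2, lo, "+")
      colnames(pts) <- paste0("x", seq_len(p))
      pts
    },
    two_boxes_oracle = {
      boxes <- boxes %||% list(list(lo = rep(0, p), hi = rep(1, p)),
                               list(lo = rep(5, p), hi = rep(6, p)))
      in_box <- function(pts, b) {
        rowSums(sweep(pts, 2, b$lo, ">=") & sweep(pts, 2, b$hi, "<=")) == p
      }
      list(oracle = function(pts) {
             pts <- as.matrix(pts)
             in_box(pts, boxes[[1]]) | in_box(pts, boxes[[2]])
           },
           boxes = boxes,
           volume = sum(vapply(boxes, function(b) prod(b$hi - b$lo),
                               numeric(1))))
    },
    sphere_oracle = {
      center <- rep(radius, p)
      list(oracle = function(pts) {
             rowSums(sweep(as.matrix(pts), 2, center)^2) <= radius^2
           },
           center = center, radius = radius,
           cube = list(lo = rep(0, p), hi = rep(2 * radius, p)),
           volume = pi^(p / 2) / gamma(p / 2 + 1) * radius^p)
    })
}
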