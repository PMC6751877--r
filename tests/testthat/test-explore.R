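test_that("fit_pca recovers a known covariance structure", {
  set.seed(10)
  n <- 1e4
  sd_true <- c(5, 2, 0.5)
  pts <- cbind(rnorm(n, sd = sd_true[1]), rnorm(n, sd = sd_true[2]),
               rnorm(n, sd = sd_true[3]))
  b <- fit_pca(pts)
  # oracle: eigen-decomposition of the sample covariance
  eig <- eigen(stats::cov(pts))
  expect_equal(b$sdevs, sqrt(eig$values), tolerance = 1e-8)
  expect_gt(abs(b$components[1, ] %*% c(1, 0, 0)), 0.99)
  expect_equal(b$sdevs, sd_true, tolerance = 0.05)
  expect_equal(b$components %*% t(b$components), diag(3),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_false(b$rank_deficient)
})

test_that("degenerate clouds get a completed orthonormal basis", {
  set.seed(11)
  line <- cbind(1:50, (1:50) * 2, rep(3, 50))
  b <- fit_pca(line)
  expect_true(b$rank_deficient)
  expect_equal(sum(b$sdevs > 1e-8), 1)
  expect_equal(b$components %*% t(b$components), diag(3),
               tolerance = 1e-8, ignore_attr = TRUE)

  few <- matrix(rnorm(6), 2, 3) # fewer points than dimensions
  b2 <- fit_pca(few)
  expect_equal(dim(b2$components), c(3, 3))
  expect_equal(b2$components %*% t(b2$components), diag(3),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("candidate sampling matches the scaled PCA covariance", {
  set.seed(12)
  sp <- unit_space(3, lo = -1e3, hi = 1e3)
  pts <- matrix(rnorm(3000), ncol = 3) %*% diag(c(4, 2, 1))
  b <- fit_pca(pts)
  lam <- 2
  s <- sample_candidates(b, lam, 1e5, sp)
  expect_true(all(attr(s, "in_bounds")))
  emp <- stats::cov(s)
  want <- t(b$components) %*% diag((lam * b$sdevs)^2) %*% b$components
  expect_lt(max(abs(emp - want)) / max(abs(want)), 0.03)

  b0 <- b
  b0$sdevs <- rep(0, 3)
  expect_warning(s0 <- sample_candidates(b0, 1, 10, sp), "degenerate")
  expect_equal(max(abs(sweep(s0, 2, b$mean))), 0)
})

test_that("in-bounds retention is high for an interior region", {
  set.seed(13)
  sp <- unit_space(3, lo = 0, hi = 10)
  pts <- matrix(runif(600, 4.5, 5.5), ncol = 3)
  s <- sample_candidates(fit_pca(pts), 1.5, 1e4, sp)
  expect_gt(mean(attr(s, "in_bounds")), 0.99)
})

test_that("the lambda schedule interpolates linearly from 4 to 2", {
  cfg <- sampler_config(iterations = 10)
  expect_equal(lambda_at(1, cfg), 4)
  expect_equal(lambda_at(10, cfg), 2)
  expect_equal(lambda_at(5.5, cfg), 3) # schedule midpoint
  expect_error(lambda_at(11, cfg))
})

test_that("component convergence is alignment-invariant", {
  b1 <- list(components = diag(3), sdevs = c(3, 2, 1), mean = rep(0, 3))
  expect_equal(convergence_norm(b1, b1), 0)

  flipped <- b1
  flipped$components[2, ] <- -flipped$components[2, ]
  expect_equal(convergence_norm(flipped, b1), 0)

  # relabeling of equal-variance components
  perm <- b1
  perm$components <- b1$components[c(2, 1, 3), ]
  expect_equal(convergence_norm(perm, b1), 0)

  # 2x2 rotation vs identity: value frozen from the direct matrix oracle
  phi <- 0.3
  rot <- list(components = matrix(c(cos(phi), -sin(phi),
                                    sin(phi), cos(phi)), 2, byrow = TRUE))
  id2 <- list(components = diag(2))
  direct <- norm(rot$components - diag(2), "F") # no flips/permutation at phi=0.3
  expect_equal(convergence_norm(rot, id2), direct)
  expect_equal(direct, 2 * sqrt(2) * abs(sin(phi / 2)))
})

test_that("gap statistic separates one cloud from two blobs", {
  set.seed(14)
  blobs <- make_fixture("gaussian_blobs", n = 150, p = 3, k = 2,
                        separation = 20)
  expect_equal(gap_statistic(blobs$points, k_max = 2)$k, 2)

  uni <- make_fixture("uniform_box", n = 400, p = 3)
  g1 <- gap_statistic(uni, k_max = 2)
  expect_equal(g1$k, 1)
  # for uniform data the gap decreases in k
  expect_true(all(diff(g1$table$gap) < 0))

  gauss <- matrix(rnorm(900), ncol = 3)
  expect_equal(gap_statistic(gauss, k_max = 2)$k, 1)
})

test_that("clustering triggers fire on budget, collapse and PC jumps", {
  expect_true(should_cluster(10, 10, n_now = 500, n_prev = 600))
  expect_true(should_cluster(3, 10, n_now = 500, n_prev = 6000,
                             shrink_ratio = 10))
  expect_true(should_cluster(3, 10, n_now = 500, n_prev = 600,
                             C = 1.2, C0 = 1))
  expect_false(should_cluster(3, 10, n_now = 500, n_prev = 600,
                              C = 0.1, C0 = 1))
})

test_that("the explorer recovers a single-box viable region", {
  set.seed(15)
  sp <- unit_space(3)
  lo <- rep(2, 3); hi <- rep(4, 3)
  oracle <- box_oracle(lo, hi)
  nu0 <- matrix(runif(60, 2.5, 3.5), ncol = 3)
  colnames(nu0) <- sp$parameter
  rs <- explore_regions(tibble::as_tibble(nu0), oracle_evaluator(oracle),
                        space = sp,
                        config = sampler_config(n_samples = 1500,
                                                iterations = 6, seed = 16))
  expect_equal(length(rs$regions), 1)
  r <- rs$regions[[1]]
  pts <- as.matrix(r$viable[sp$parameter])
  inside <- box_oracle(lo, hi)(pts)
  expect_gte(mean(inside), 0.95)
  expect_gt(nrow(pts), nrow(nu0)) # accumulation grows the set
  expect_true(all(diff(r$history$n_total) >= 0))
  # the PCA box must cover the occupied cube; for an isotropic cube the
  # PCA orientation is arbitrary, so the box may exceed the true volume 8
  # by up to the worst-case diagonal factor
  expect_gt(bounding_box(r)$volume, 4)
  expect_lt(bounding_box(r)$volume, 8 * 3^(3 / 2))
})

test_that("the explorer splits two disjoint boxes into two regions", {
  set.seed(17)
  sp <- unit_space(3)
  fx <- make_fixture("two_boxes_oracle", p = 3,
                     boxes = list(list(lo = rep(1, 3), hi = rep(3, 3)),
                                  list(lo = rep(7, 3), hi = rep(9, 3))))
  nu0 <- rbind(matrix(runif(45, 1.5, 2.5), ncol = 3),
               matrix(runif(45, 7.5, 8.5), ncol = 3))
  colnames(nu0) <- sp$parameter
  rs <- explore_regions(tibble::as_tibble(nu0), oracle_evaluator(fx$oracle),
                        space = sp,
                        config = sampler_config(n_samples = 1500,
                                                iterations = 5, seed = 18))
  expect_equal(length(rs$regions), 2)
  for (r in rs$regions) {
    pts <- as.matrix(r$viable[sp$parameter])
    in1 <- mean(box_oracle(rep(1, 3), rep(3, 3))(pts))
    in2 <- mean(box_oracle(rep(7, 3), rep(9, 3))(pts))
    expect_gte(max(in1, in2), 0.95) # each region maps onto one true box
  }
  td <- tidy(rs)
  expect_equal(nrow(td), 2)
})

test_that("exploration is bit-reproducible under a fixed seed", {
  set.seed(19)
  sp <- unit_space(2)
  oracle <- box_oracle(rep(3, 2), rep(6, 2))
  nu0 <- matrix(runif(40, 3.5, 5.5), ncol = 2)
  colnames(nu0) <- sp$parameter
  cfg <- sampler_config(n_samples = 400, iterations = 3, seed = 20)
  r1 <- explore_regions(tibble::as_tibble(nu0), oracle_evaluator(oracle),
                        space = sp, config = cfg)
  r2 <- explore_regions(tibble::as_tibble(nu0), oracle_evaluator(oracle),
                        space = sp, config = cfg)
  expect_identical(as.data.frame(r1$regions[[1]]$viable),
                   as.data.frame(r2$regions[[1]]$viable))
  expect_identical(r1$regions[[1]]$history, r2$regions[[1]]$history)
})
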