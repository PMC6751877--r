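#' Local-sampler configuration
#'
#' Study defaults: 1e5 Gaussian proposals per iteration for 10 iterations,
#' with the variance inflation decreasing linearly from 4 to 2 (wide early
#' coverage of the still-uncertain region, focused sampling once the
#' principal components stabilise), a 10-fold viable-count collapse as the
#' split trigger, and at most 2 clusters per split.
#'
#' @param n_samples Gaussian proposals per iteration.
#' @param iterations iteration budget per region.
#' @param lambda_start,lambda_end variance-scaling schedule endpoints
#'   (both >= 1; start >= end).
#' @param shrink_ratio viable-count collapse factor triggering clustering.
#' @param convergence_threshold principal-component jump `C0` triggering
#'   clustering; default `0.2 * sqrt(p)` chosen at run time (the Frobenius
#'   norm of a p x p difference grows like sqrt(p)).
#' @param convergence_stop stop refining a region once the aligned
#'   component change drops below this.
#' @param max_clusters cap on the cluster count per split.
#' @param n_ref uniform reference data sets for the gap statistic.
#' @param min_points smallest viable count a region may fall to before it
#'   is retired (defaults to p + 2 at run time).
#' @param seed optional RNG seed.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(n_samples = 1e5, iterations = 10,
                           lambda_start = 4, lambda_end = 2,
                           shrink_ratio = 10, convergence_threshold = NULL,
                           convergence_stop = 0.01, max_clusters = 2,
                           n_ref = 20, min_points = NULL, seed = NULL) {
  stopifnot(n_samples > 0, iterations >= 1,
            lambda_start >= lambda_end, lambda_end >= 1)
  structure(list(n_samples = as.integer(n_samples),
                 iterations = as.integer(iterations),
                 lambda_start = lambda_start, lambda_end = lambda_end,
                 shrink_ratio = shrink_ratio,
                 convergence_threshold = convergence_threshold,
                 convergence_stop = convergence_stop,
                 max_clusters = as.integer(max_clusters),
                 n_ref = as.integer(n_ref), min_points = min_points,
                 seed = seed),
            class = "sampler_config")
}

#' Iterative PCA-directed exploration of viable regions
#'
#' Starting from the GA harvest, each iteration fits a PCA basis to the
#' accumulated viable set, draws Gaussian proposals along the components
#' (variance inflated by the lambda schedule), evaluates the in-bounds
#' proposals and unions the new viable points into the set. Newly found
#' viable points accumulate across iterations: the proposal distribution
#' uses the previous iteration's mean and components either way, and the
#' growing set stabilises the PCA.
#'
#' When a clustering trigger fires ([should_cluster()]) on the root
#' region, the gap statistic ([gap_statistic()], on coordinates
#' standardised by the bounds span) chooses a cluster count up to
#' `max_clusters`; if it exceeds 1 the region is split by K-means and each
#' child is explored independently with a fresh iteration budget. Only the
#' root region may split — consecutive splits are disregarded, which keeps
#' the region count conservative (the gap statistic is known to
#' overestimate on non-uniform data).
#'
#' @param nu0 initial viable set (from [ga_search()] / [run_ga()]), or any
#'   tibble with the parameter columns plus optional `cost` and `tag`.
#' @param evaluate batch evaluator `(points) -> tibble(cost, viable, tag)`.
#' @param space the [parameter_space()]; defaults to the one attached to
#'   `nu0`.
#' @param config a [sampler_config()].
#' @return A `region_set`: list of regions, each carrying its accumulated
#'   `viable` tibble, final `basis`, per-iteration `history`, majority
#'   behaviour `tag` and the gap-statistic decision that created it.
#'   [tidy()] gives one row per region, [glance()] run totals,
#'   [autoplot()] the 2-component projection.
#' @export
explore_regions <- function(nu0, evaluate, space = attr(nu0, "space"),
                            config = sampler_config()) {
  if (is.null(space)) abort("no parameter space attached to nu0; pass `space`")
  if (nrow(nu0) == 0) abort("empty initial viable set")
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- n_params(space)
  C0 <- config$convergence_threshold %||% (0.2 * sqrt(p))
  min_pts <- config$min_points %||% (p + 2)

  nu0 <- as_tibble(nu0)
  if (!"cost" %in% names(nu0)) nu0$cost <- NA_real_
  if (!"tag" %in% names(nu0)) nu0$tag <- NA_character_
  nu0 <- nu0[c(space$parameter, "cost", "tag")]

  counter <- new.env(parent = emptyenv())
  counter$next_id <- 1L
  counter$n_eval <- 0L

  regions <- explore_one(nu0, can_split = TRUE, space = space,
                         config = config, C0 = C0, min_pts = min_pts,
                         evaluate = evaluate, counter = counter,
                         parent = NA_integer_)
  structure(list(regions = regions, space = space, config = config,
                 n_evaluated = counter$n_eval),
            class = "region_set")
}

# depth-limited recursive exploration of one region
explore_one <- function(viable, can_split, space, config, C0, min_pts,
                        evaluate, counter, parent) {
  id <- counter$next_id
  counter$next_id <- id + 1L
  prev_basis <- NULL
  basis <- NULL
  n_prev <- nrow(viable)
  hist <- list()
  gap <- NULL
  retired <- FALSE
  split_done <- FALSE

  for (i in seq_len(config$iterations)) {
    pts <- as.matrix(viable[space$parameter])
    if (nrow(pts) < min_pts) {
      warn(sprintf("region %d retired: only %d viable points", id, nrow(pts)))
      retired <- TRUE
      break
    }
    basis <- fit_pca(pts)
    C <- if (!is.null(prev_basis)) convergence_norm(basis, prev_basis) else NA_real_
    lam <- lambda_at(i, config)
    S <- sample_candidates(basis, lam, config$n_samples, space)
    Sin <- S[attr(S, "in_bounds"), , drop = FALSE]
    n_new <- 0L
    if (nrow(Sin)) {
      res <- evaluate(Sin)
      counter$n_eval <- counter$n_eval + nrow(Sin)
      if (!"tag" %in% names(res)) res$tag <- NA_character_
      keep <- which(res$viable)
      n_new <- length(keep)
      if (n_new) {
        add <- dplyr::bind_cols(as_tibble(Sin[keep, , drop = FALSE]),
                                tibble(cost = res$cost[keep],
                                       tag = res$tag[keep]))
        viable <- dplyr::distinct(
          dplyr::bind_rows(viable, add),
          dplyr::across(dplyr::all_of(space$parameter)), .keep_all = TRUE)
      }
    }
    hist[[i]] <- tibble(iteration = i, lambda = lam, proposed = nrow(Sin),
                        n_new = n_new, n_total = nrow(viable), C = C)

    if (can_split && !split_done &&
        should_cluster(i, config$iterations, n_new, n_prev, C, C0,
                       config$shrink_ratio)) {
      split_done <- TRUE # the root region is clustered at most once
      z <- standardize_points(as.matrix(viable[space$parameter]), space)
      if (nrow(z) >= config$max_clusters * (ncol(z) + 1)) {
        gap <- gap_statistic(z, k_max = config$max_clusters,
                             n_ref = config$n_ref)
        if (gap$k > 1) {
          km <- suppressWarnings(kmeans(z, centers = gap$k, nstart = 10,
                                        iter.max = 50))
          children <- unlist(lapply(seq_len(gap$k), function(j) {
            explore_one(viable[km$cluster == j, , drop = FALSE],
                        can_split = FALSE, space = space, config = config,
                        C0 = C0, min_pts = min_pts, evaluate = evaluate,
                        counter = counter, parent = id)
          }), recursive = FALSE)
          return(children)
        }
      }
    }

    n_prev <- n_new
    prev_basis <- basis
    if (!is.na(C) && C < config$convergence_stop) break
  }

  tags <- viable$tag[!is.na(viable$tag)]
  tag <- if (length(tags)) names(sort(table(tags), decreasing = TRUE))[1]
         else NA_character_
  list(list(id = id, parent = parent,
            viable = new_viable_set(viable, space),
            basis = basis, history = dplyr::bind_rows(hist),
            tag = tag, gap = gap, retired = retired))
}

standardize_points <- function(points, space) {
  sweep(sweep(points, 2, space$lower), 2, space$upper - space$lower, "/")
}

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set>", length(x$regions), "region(s),",
      x$n_evaluated, "candidate evaluations\n")
  print(tidy(x))
  invisible(x)
}

#' @method tidy region_set
#' @export
tidy.region_set <- function(x, ...) {
  purrr::map_dfr(x$regions, function(r) {
    tibble(region = r$id, parent = r$parent, n_viable = nrow(r$viable),
           tag = r$tag, iterations = nrow(r$history),
           gap_k = if (!is.null(r$gap)) r$gap$k else NA_integer_,
           final_C = if (nrow(r$history)) tail(r$history$C, 1) else NA_real_,
           retired = r$retired)
  })
}

#' @method glance region_set
#' @export
glance.region_set <- function(x, ...) {
  tibble(n_regions = length(x$regions),
         n_viable = sum(vapply(x$regions, function(r) nrow(r$viable), 0)),
         n_evaluated = x$n_evaluated)
}

#' @method autoplot region_set
#' @export
autoplot.region_set <- function(object, ...) {
  all_pts <- purrr::map_dfr(object$regions, function(r) {
    dplyr::mutate(as_tibble(r$viable), region = factor(r$id),
                  tag = r$tag %||% NA_character_)
  })
  pts <- as.matrix(all_pts[object$space$parameter])
  pc <- prcomp(pts, center = TRUE, scale. = FALSE)
  dat <- dplyr::bind_cols(all_pts,
                          tibble(PC1 = pc$x[, 1],
                                 PC2 = if (ncol(pc$x) > 1) pc$x[, 2] else 0))
  ggplot2::ggplot(dat, ggplot2::aes(.data$PC1, .data$PC2,
                                    colour = .data$region,
                                    shape = .data$tag)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "PC 1", y = "PC 2") +
    ggplot2::theme_minimal()
}
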