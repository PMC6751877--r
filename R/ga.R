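#' Genetic-algorithm configuration
#'
#' Defaults follow the study settings: 5000 random candidates, 10
#' generations (deliberately few — the GA only sketches the viable
#' regions, the local sampler refines them), per-coordinate multiplicative
#' mutation by U(0.8, 1.2) with probability 0.75, two-point crossover, and
#' tournament selection with a tournament of a tenth of the population.
#'
#' @param population_size number of candidates per generation.
#' @param generations number of generations.
#' @param mutation_prob per-coordinate mutation probability.
#' @param mutation_range range of the multiplicative mutation factor.
#' @param tournament_size candidates per tournament (default:
#'   `population_size / 10`).
#' @param crossover_prob probability a selected pair is recombined.
#' @param seed optional RNG seed for a bit-reproducible run.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 5000, generations = 10,
                      mutation_prob = 0.75, mutation_range = c(0.8, 1.2),
                      tournament_size = NULL, crossover_prob = 1,
                      seed = NULL) {
  tournament_size <- tournament_size %||% max(1L, population_size %/% 10L)
  stopifnot(population_size > 0, generations > 0,
            mutation_prob >= 0, mutation_prob <= 1,
            mutation_range[1] < mutation_range[2],
            tournament_size <= population_size)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 mutation_prob = mutation_prob,
                 mutation_range = mutation_range,
                 tournament_size = as.integer(tournament_size),
                 crossover_prob = crossover_prob, seed = seed),
            class = "ga_config")
}

#' Uniform initial population
#'
#' @param space a [parameter_space()].
#' @param n number of candidates.
#' @param scale `"linear"` (default) draws uniformly on each range;
#'   `"log"` draws log-uniformly, which spreads draws evenly over the
#'   orders of magnitude a rate range spans (all bounds are positive).
#' @return An `n x p` matrix of candidates within bounds, columns named by
#'   parameter.
#' @export
init_population <- function(space, n, scale = c("linear", "log")) {
  stopifnot(n > 0)
  scale <- match.arg(scale)
  p <- n_params(space)
  m <- matrix(runif(n * p), n, p)
  if (scale == "log") {
    m <- sweep(m, 2, log(space$upper) - log(space$lower), "*")
    m <- exp(sweep(m, 2, log(space$lower), "+"))
  } else {
    m <- sweep(m, 2, space$upper - space$lower, "*")
    m <- sweep(m, 2, space$lower, "+")
  }
  colnames(m) <- space$parameter
  m
}

#' Seed a viable set from a known viable point
#'
#' Literature-seeded alternative to the GA harvest: multiplicative
#' Gaussian perturbations around a published viable parameter point are
#' evaluated and the viable ones returned. Useful when a printed viable
#' point exists and the question is the shape and volume of the region
#' around it rather than global discovery.
#'
#' @param model a [grn_model()].
#' @param cost a [cost_spec()] or list of them.
#' @param theta a viable parameter point (named).
#' @param n number of perturbed candidates.
#' @param spread standard deviation of the log-normal perturbation factor.
#' @param dt_out,duration evaluation simulation control.
#' @return A `viable_set` (the point itself is included when viable).
#' @export
seed_from_point <- function(model, cost, theta, n = 200, spread = 0.05,
                            dt_out = 0.1, duration = NULL) {
  theta <- as_param_matrix(theta, model$space)[1, ]
  p <- length(theta)
  pts <- rbind(theta,
               clip_to_bounds(matrix(theta, n, p, byrow = TRUE) *
                                exp(matrix(rnorm(n * p, sd = spread), n, p)),
                              model$space))
  colnames(pts) <- model$space$parameter
  evaluate <- candidate_evaluator(model, cost, dt_out, duration)
  res <- evaluate(pts)
  keep <- which(res$viable)
  out <- dplyr::bind_cols(as_tibble(pts[keep, , drop = FALSE]),
                          tibble(cost = res$cost[keep], tag = res$tag[keep]))
  new_viable_set(out, model$space, n_evaluated = nrow(pts),
                 status = if (length(keep)) "ok" else "no_viable_seed")
}

#' Multiplicative mutation
#'
#' Each coordinate is independently, with probability
#' `cfg$mutation_prob`, multiplied by a factor drawn uniformly from
#' `cfg$mutation_range`; results are clipped to the space bounds so the
#' population always stays feasible.
#'
#' @param points candidate matrix (rows) or a single named vector.
#' @param space a [parameter_space()].
#' @param cfg a [ga_config()].
#' @return Mutated candidates, same shape as a matrix.
#' @export
mutate_points <- function(points, space, cfg) {
  m <- as_param_matrix(points, space)
  hit <- matrix(runif(length(m)) < cfg$mutation_prob, nrow(m), ncol(m))
  fac <- matrix(runif(length(m), cfg$mutation_range[1], cfg$mutation_range[2]),
                nrow(m), ncol(m))
  fac[!hit] <- 1
  clip_to_bounds(m * fac, space)
}

#' Two-point crossover
#'
#' Two cut positions are drawn uniformly from the `p - 1` gaps between
#' coordinates; the middle segment is exchanged between the parents.
#' Coordinate-wise, the children's values are a reshuffling of the
#' parents' (the multiset per position is preserved).
#'
#' @param a,b parent vectors of equal length.
#' @return A list with components `a` and `b`, the two children.
#' @export
crossover <- function(a, b) {
  p <- length(a)
  stopifnot(length(b) == p)
  if (p < 2) return(list(a = a, b = b))
  cuts <- sort(sample.int(p - 1, 2, replace = TRUE))
  if (cuts[1] < cuts[2]) {
    seg <- (cuts[1] + 1):cuts[2]
    tmp <- a[seg]
    a[seg] <- b[seg]
    b[seg] <- tmp
  }
  list(a = a, b = b)
}

#' Tournament selection
#'
#' Draws `k` distinct individuals uniformly and returns the index of the
#' best (lowest cost).
#'
#' @param fitness numeric vector of cost values (lower is better).
#' @param k tournament size.
#' @return The selected index.
#' @export
tournament_select <- function(fitness, k) {
  stopifnot(k >= 1, k <= length(fitness))
  idx <- sample.int(length(fitness), k)
  idx[which.min(fitness[idx])]
}

#' Global harvest of viable candidates with a genetic algorithm
#'
#' Runs a generational GA over the parameter space and — unlike a
#' conventional optimiser — records *every* viable individual encountered
#' in any generation. The union of those individuals (deduplicated) is the
#' initial viable set passed to [explore_regions()].
#'
#' @param space a [parameter_space()].
#' @param evaluate batch evaluator: `function(points)` returning a tibble
#'   with columns `cost`, `viable` and optionally `tag`
#'   (see [candidate_evaluator()]).
#' @param config a [ga_config()].
#' @return A `viable_set`: a tibble with one parameter column per
#'   dimension plus `cost` and `tag`. Attributes: `n_evaluated`,
#'   `status` (`"ok"` or `"no_viable_seed"`), `space`. An empty tibble
#'   (with a message) signals that no viable seed was found — an explicit
#'   outcome, not an error.
#' @export
ga_search <- function(space, evaluate, config = ga_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- n_params(space)
  pop <- init_population(space, config$population_size)
  harvest <- vector("list", config$generations)
  n_eval <- 0L

  for (gen in seq_len(config$generations)) {
    res <- evaluate(pop)
    n_eval <- n_eval + nrow(pop)
    if (!"tag" %in% names(res)) res$tag <- NA_character_
    keep <- which(res$viable)
    if (length(keep)) {
      harvest[[gen]] <- dplyr::bind_cols(
        as_tibble(pop[keep, , drop = FALSE]),
        tibble(cost = res$cost[keep], tag = res$tag[keep], generation = gen))
    }
    if (gen == config$generations) break

    sel_idx <- vapply(seq_len(config$population_size),
                      function(i) tournament_select(res$cost, config$tournament_size),
                      integer(1))
    nxt <- pop[sel_idx, , drop = FALSE]
    for (i in seq(1, config$population_size - 1, by = 2)) {
      if (runif(1) <= config$crossover_prob) {
        ch <- crossover(nxt[i, ], nxt[i + 1, ])
        nxt[i, ] <- ch$a
        nxt[i + 1, ] <- ch$b
      }
    }
    pop <- mutate_points(nxt, space, config)
  }

  out <- dplyr::bind_rows(harvest)
  status <- if (nrow(out) == 0) "no_viable_seed" else "ok"
  if (status == "no_viable_seed") {
    inform("no viable seed found: the GA encountered no viable individual")
    out <- tibble(!!!setNames(rep(list(double()), p), space$parameter),
                  cost = double(), tag = character(), generation = integer())
  } else {
    out <- dplyr::distinct(out,
                           dplyr::across(dplyr::all_of(space$parameter)),
                           .keep_all = TRUE)
  }
  new_viable_set(out, space, n_evaluated = n_eval, status = status)
}

new_viable_set <- function(tbl, space, n_evaluated = NA_integer_,
                           status = "ok") {
  structure(tbl, class = unique(c("viable_set", class(tbl))),
            space = space, n_evaluated = n_evaluated, status = status)
}

viable_points <- function(vs, space = attr(vs, "space")) {
  as.matrix(vs[space$parameter])
}

#' @method glance viable_set
#' @export
glance.viable_set <- function(x, ...) {
  tibble(n_viable = nrow(x),
         n_evaluated = attr(x, "n_evaluated"),
         status = attr(x, "status"))
}

#' Harvest the viable set of a circuit model
#'
#' Convenience wrapper: builds the [candidate_evaluator()] for the model
#' and cost(s) and calls [ga_search()] on the model's parameter space.
#'
#' @param model a [grn_model()].
#' @param cost a [cost_spec()] or list of them.
#' @param config a [ga_config()].
#' @param dt_out,duration simulation control for candidate evaluation.
#' @return A `viable_set`, see [ga_search()].
#' @export
run_ga <- function(model, cost, config = ga_config(), dt_out = 0.1,
                   duration = NULL) {
  ga_search(model$space, candidate_evaluator(model, cost, dt_out, duration),
            config)
}
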