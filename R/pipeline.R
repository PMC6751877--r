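#' Configure a full exploration run
#'
#' Bundles every stage setting — model, cost(s), GA, local sampler,
#' volume estimation — with one master seed, so a run is reproducible
#' end to end from its configuration alone.
#'
#' @param model model id (see [grn_model()]).
#' @param costs character vector of [preset_cost()] names, a
#'   [cost_spec()], or a list of cost specs. Multiple costs define a
#'   multi-modal run: the GA harvests per cost and the local sampler
#'   treats the concatenated harvest as one cloud.
#' @param omega1,omega2 flip-flop structure flags.
#' @param ga,sampler named lists of overrides for [ga_config()] /
#'   [sampler_config()].
#' @param volume list with `delta_frac`, `beta` and optional `n_samples`
#'   override for [region_volume()].
#' @param dt_out,duration candidate-evaluation simulation control.
#' @param seed master RNG seed (all stages draw from one stream).
#' @param out_dir optional directory for artifacts (viable-set CSVs and a
#'   JSON manifest).
#' @return A `run_config`.
#' @export
run_config <- function(model = "repressilator",
                       costs = "repressilator_sine",
                       omega1 = 1, omega2 = 1,
                       ga = list(), sampler = list(),
                       volume = list(delta_frac = 0.01, beta = 0.95,
                                     n_samples = NULL),
                       dt_out = 0.1, duration = NULL,
                       seed = 1, out_dir = NULL) {
  structure(list(model = model, costs = costs, omega1 = omega1,
                 omega2 = omega2, ga = ga, sampler = sampler,
                 volume = modifyList(list(delta_frac = 0.01, beta = 0.95,
                                          n_samples = NULL), volume),
                 dt_out = dt_out, duration = duration,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Flat key-value representation of [run_config()]; nested `ga`,
#' `sampler` and `volume` blocks map onto the override lists.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

resolve_costs <- function(costs) {
  if (inherits(costs, "cost_spec")) return(list(costs))
  if (is.character(costs)) return(lapply(costs, preset_cost))
  costs
}

#' Run the full glocal pipeline
#'
#' GA harvest (one GA per cost function), concatenation of the viable
#' harvests, PCA-directed local exploration with gap-statistic region
#' splitting, and per-region Monte-Carlo volume estimation.
#'
#' @param config a [run_config()].
#' @return A `viaspace_run`: list with the initial viable set `nu0`, the
#'   explored `regions` ([explore_regions()] result), per-region
#'   `volumes`, and a serialisable `manifest` (config snapshot, stage
#'   statistics, timings, versions). With `out_dir` set, artifacts are
#'   written as CSV/JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  t0 <- proc.time()[["elapsed"]]
  model <- grn_model(config$model, omega1 = config$omega1,
                     omega2 = config$omega2)
  costs <- resolve_costs(config$costs)
  gacfg <- do.call(ga_config, config$ga)
  smcfg <- do.call(sampler_config, config$sampler)

  # stage 1: one GA per cost; every viable individual is harvested
  harvests <- lapply(costs, function(cs) {
    run_ga(model, cs, gacfg, dt_out = config$dt_out,
           duration = config$duration)
  })
  nu0 <- dplyr::distinct(
    dplyr::bind_rows(lapply(harvests, as_tibble)),
    dplyr::across(dplyr::all_of(model$space$parameter)), .keep_all = TRUE)
  nu0 <- new_viable_set(nu0, model$space,
                        n_evaluated = sum(vapply(harvests, function(h) {
                          attr(h, "n_evaluated")
                        }, numeric(1))))
  t1 <- proc.time()[["elapsed"]]
  if (nrow(nu0) == 0) {
    return(structure(list(nu0 = nu0, regions = NULL, volumes = NULL,
                          manifest = list(status = "no_viable_seed",
                                          seed = config$seed)),
                     class = "viaspace_run"))
  }

  # stage 2: local sampling, clustering, refinement
  evaluate <- candidate_evaluator(model, costs, config$dt_out,
                                  config$duration)
  regions <- explore_regions(nu0, evaluate, model$space, smcfg)
  t2 <- proc.time()[["elapsed"]]

  # stage 3: robustness as viable volume per region
  volumes <- lapply(regions$regions, function(r) {
    region_volume(r, evaluate, model$space,
                  delta_frac = config$volume$delta_frac,
                  beta = config$volume$beta,
                  n_samples = config$volume$n_samples)
  })
  t3 <- proc.time()[["elapsed"]]

  manifest <- list(
    config = config[setdiff(names(config), "out_dir")],
    model = model$id, p = n_params(model$space),
    status = "ok", seed = config$seed,
    nu0 = list(n_viable = nrow(nu0),
               n_evaluated = attr(nu0, "n_evaluated")),
    regions = tidy(regions),
    volumes = purrr::map_dfr(seq_along(volumes), function(i) {
      dplyr::mutate(tidy(volumes[[i]]), region = regions$regions[[i]]$id,
                    tag = regions$regions[[i]]$tag, .before = 1)
    }),
    timings = list(ga = t1 - t0, explore = t2 - t1, volume = t3 - t2),
    versions = list(viaspace = as.character(utils::packageVersion("viaspace")),
                    R = R.version.string))

  run <- structure(list(nu0 = nu0, regions = regions, volumes = volumes,
                        manifest = manifest),
                   class = "viaspace_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_viable_set(run$nu0, file.path(dir, "nu0.csv"))
  for (r in run$regions$regions) {
    write_viable_set(r$viable, file.path(dir, sprintf("region_%d.csv", r$id)))
  }
  write_manifest(run$manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @export
print.viaspace_run <- function(x, ...) {
  if (is.null(x$regions)) {
    cat("<viaspace_run> no viable seed found\n")
    return(invisible(x))
  }
  cat("<viaspace_run>", x$manifest$model, "—",
      nrow(tidy(x$regions)), "region(s)\n")
  print(x$manifest$volumes)
  invisible(x)
}

#' @method tidy viaspace_run
#' @export
tidy.viaspace_run <- function(x, ...) {
  if (is.null(x$regions)) return(tibble())
  x$manifest$volumes
}

#' @method glance viaspace_run
#' @export
glance.viaspace_run <- function(x, ...) {
  if (is.null(x$regions)) return(tibble(status = "no_viable_seed"))
  tibble(status = "ok", n_regions = length(x$regions$regions),
         n_viable = glance(x$regions)$n_viable,
         total_rel_volume = sum(x$manifest$volumes$vol_rel))
}
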