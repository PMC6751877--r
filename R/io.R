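#' Persist a viable set as CSV
#'
#' Parameter columns in space order (original parameter units, never PCA
#' coordinates) plus `cost` and `tag`, preceded by a one-line unit
#' comment. Reading restores the `viable_set` class and the attached
#' parameter space.
#'
#' @param vs a `viable_set` (from [run_ga()] or a region's `viable`).
#' @param path file path.
#' @param space parameter space to re-attach on read.
#' @return `write_viable_set()` returns `path` invisibly.
#' @export
write_viable_set <- function(vs, path) {
  space <- attr(vs, "space")
  cols <- c(space$parameter, intersect(c("cost", "tag", "generation"),
                                       names(vs)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# rates: 1/h, concentrations/constants: nM", con)
  write.csv(as.data.frame(vs)[cols], con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_viable_set
#' @export
read_viable_set <- function(path, space) {
  tbl <- as_tibble(read.csv(path, comment.char = "#",
                            stringsAsFactors = FALSE))
  new_viable_set(tbl, space)
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
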