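# Plain-text serialization: gridded fields as CSV matrices with a JSON
# sidecar carrying the grid metadata (extent, resolution, label), and
# experiment results as CSV + JSON summary.

#' Write a gridded field to CSV with a JSON metadata sidecar
#'
#' @param x A \code{probability_grid}, \code{potential}, or plain matrix
#'   with \code{grid}.
#' @param path Output CSV path; metadata goes to \code{<path>.json}.
#' @param grid Required when \code{x} is a plain matrix.
#' @return \code{path}, invisibly.
#' @export
write_grid <- function(x, path, grid = NULL) {
  if (inherits(x, c("probability_grid", "potential"))) {
    grid <- x$grid
    values <- x$values
    label <- if (!is.null(x$label)) x$label else class(x)[1]
  } else {
    stopifnot(is.matrix(x), is_grid_spec(grid))
    values <- x
    label <- "field"
  }
  utils::write.table(values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(extent = grid$extent, resolution = grid$resolution,
               label = label)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a gridded field written by \code{\link{write_grid}}
#'
#' @param path CSV path (expects \code{<path>.json} sidecar).
#' @param as \code{"matrix"}, \code{"probability_grid"} or
#'   \code{"potential"}.
#' @return The requested object; plain matrices carry the
#'   \code{grid_spec} as attribute \code{grid}.
#' @export
read_grid <- function(path, as = c("matrix", "probability_grid", "potential")) {
  as <- match.arg(as)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- grid_spec(meta$extent, meta$resolution)
  values <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(values) <- NULL
  switch(as,
    matrix = structure(values, grid = grid),
    probability_grid = probability_grid(grid, values, label = meta$label),
    potential = potential(grid, values)
  )
}

#' Write population centers as CSV with JSON metadata
#'
#' @param pop A \code{population}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_population <- function(pop, path) {
  utils::write.csv(as.data.frame(pop$centers), path, row.names = FALSE)
  meta <- list(sigma = pop$sigma, gain = pop$gain,
               n_neurons = pop$n_neurons,
               warped = !is.null(pop$displacement))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Write an experiment result as CSV + JSON summary
#'
#' @param result An \code{experiment_result}.
#' @param dir Output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_experiment <- function(result, dir) {
  stopifnot(inherits(result, "experiment_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$replicates, file.path(dir, "replicates.csv"),
                   row.names = FALSE)
  summary <- list(
    median_sharpness_cor = result$median_sharpness_cor,
    median_gain_cor = result$median_gain_cor,
    wilcoxon_sharpness = as.list(result$wilcoxon_sharpness),
    wilcoxon_gain = as.list(result$wilcoxon_gain),
    config = result$config
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Solve-and-export convenience runner
#'
#' Solves the encoding potential for a named fixture or density file and
#' writes the potential, displacement components, induced density field,
#' residual map and a JSON run report to a directory. This is the
#' programmatic core of the command-line interface.
#'
#' @param density A \code{probability_grid}, a fixture name
#'   (\code{"gaussian"}, \code{"generalized"}, \code{"nonseparable"},
#'   \code{"uniform_s2"}), or a path to a CSV density written by
#'   \code{\link{write_grid}}.
#' @param out Output directory.
#' @param resolution Grid resolution used when \code{density} is a
#'   fixture name.
#' @param cfg A \code{solver_config}.
#' @return The solved \code{potential}, invisibly.
#' @export
run_solve <- function(density, out, resolution = 65, cfg = solver_config()) {
  p <- if (inherits(density, "probability_grid")) density
       else if (is.character(density) && file.exists(density))
         read_grid(density, as = "probability_grid")
       else fixture_density(density, grid_spec(resolution = resolution))
  if (is.character(density) && !file.exists(density) &&
      density == "uniform_s2" && cfg$interior == "circle")
    cfg$interior <- "square"
  v <- solve_potential(p, cfg = cfg)
  f <- displacement_from_potential(v)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_grid(v, file.path(out, "potential.csv"))
  write_grid(f$fx, file.path(out, "displacement_fx.csv"), grid = v$grid)
  write_grid(f$fy, file.path(out, "displacement_fy.csv"), grid = v$grid)
  write_grid(density_of_mapping(f), file.path(out, "density.csv"),
             grid = v$grid)
  write_grid(remap_residual(v, p, uniform_grid(p$grid)),
             file.path(out, "residual.csv"), grid = v$grid)
  report <- list(
    rms_residual = attr(v, "rms_residual"),
    converged = attr(v, "converged"),
    iterations = lapply(attr(v, "trace"), length),
    config = unclass(cfg)
  )
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(v)
}

#' Named example stimulus distributions
#'
#' The four example 2-D distributions: uniform over \eqn{s_2} with a
#' Gaussian over \eqn{s_1} (\eqn{\sigma = 0.25}); isotropic bivariate
#' Gaussian (\eqn{\sigma = 0.25}); anisotropic leptokurtotic generalized
#' Gaussian (\eqn{\sigma_{s1} = 0.75}, \eqn{\sigma_{s2} = 0.25}, power
#' 1.1); and a non-separable Gaussian over \eqn{s_1} whose bandwidth
#' varies with \eqn{s_2}.
#'
#' @param name One of \code{"gaussian"}, \code{"generalized"},
#'   \code{"nonseparable"}, \code{"uniform_s2"}.
#' @param grid A \code{grid_spec}.
#' @return A \code{probability_grid}.
#' @export
fixture_density <- function(name, grid = grid_spec(resolution = 65)) {
  switch(match.arg(name, c("gaussian", "generalized", "nonseparable",
                           "uniform_s2")),
    gaussian = make_gaussian(grid, sigma = 0.25),
    generalized = make_generalized_gaussian(grid),
    nonseparable = make_nonseparable(grid),
    uniform_s2 = {
      co <- grid_coordinates(grid)
      probability_grid(grid, stats::dnorm(co$s1, 0, 0.25),
                       label = "uniform_s2")
    })
}
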