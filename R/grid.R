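#' Regular square lattice over the stimulus domain
#'
#' Defines the discrete sampling of the square stimulus domain
#' \eqn{[-extent, extent]^2}. Samples are cell-centered with inclusive
#' endpoints at \eqn{\pm extent}, so the cell spacing is
#' \eqn{2\,extent/(resolution-1)}. All integrals over the domain are
#' Riemann sums with weight \code{spacing^2} per cell, consistent with the
#' discrete filters used by the potential solver.
#'
#' @param extent Half-width of the square domain in stimulus units
#'   (default 1, i.e. the domain \eqn{[-1,1]^2}).
#' @param resolution Number of samples per axis (integer, at least 17).
#' @return An object of class \code{grid_spec} with fields \code{extent},
#'   \code{resolution}, \code{spacing} and \code{coords} (axis sample
#'   positions). The same axis is used for both dimensions.
#' @examples
#' g <- grid_spec(extent = 1, resolution = 65)
#' g$spacing # 2/64
#' @export
grid_spec <- function(extent = 1, resolution = 65) {
  resolution <- as.integer(resolution)
  if (!is.finite(extent) || extent <= 0)
    stop("`extent` must be a positive number")
  if (resolution < 17L)
    stop("`resolution` must be an integer >= 17")
  spacing <- 2 * extent / (resolution - 1)
  structure(
    list(
      extent = extent,
      resolution = resolution,
      spacing = spacing,
      coords = seq(-extent, extent, length.out = resolution)
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> [-%g, %g]^2, %d x %d cells, spacing %.5g\n",
              x$extent, x$extent, x$resolution, x$resolution, x$spacing))
  invisible(x)
}

#' @rdname grid_spec
#' @param x Object to test.
#' @export
is_grid_spec <- function(x) inherits(x, "grid_spec")

same_grid <- function(a, b) {
  isTRUE(a$resolution == b$resolution) && isTRUE(all.equal(a$extent, b$extent))
}

#' Matrices of s1 / s2 coordinates for every grid cell
#'
#' Convention: \code{values[i, j]} samples the point
#' \code{(s1 = coords[i], s2 = coords[j])}, i.e. rows index the first
#' stimulus dimension and columns the second.
#'
#' @param grid A \code{grid_spec}.
#' @return A list with matrices \code{s1} and \code{s2} of size
#'   \code{resolution x resolution}.
#' @export
grid_coordinates <- function(grid) {
  n <- grid$resolution
  list(
    s1 = matrix(grid$coords, n, n, byrow = FALSE),
    s2 = matrix(grid$coords, n, n, byrow = TRUE)
  )
}

#' Riemann-sum integral of a gridded field
#'
#' @param grid A \code{grid_spec}.
#' @param values Matrix of per-cell values on \code{grid}.
#' @return Scalar Riemann sum with cell-area weights.
#' @export
grid_integral <- function(grid, values) {
  sum(values) * grid$spacing^2
}

#' Normalized probability density on a grid
#'
#' Wraps a nonnegative per-cell density (probability mass per unit area)
#' on a \code{grid_spec}; the density is renormalized so that its Riemann
#' sum over the finite domain equals one (densities are always truncated
#' to the domain, never treated as unbounded).
#'
#' @param grid A \code{grid_spec}.
#' @param values Matrix of nonnegative densities, \code{resolution x
#'   resolution}, indexed \code{[s1, s2]}.
#' @param label Provenance string.
#' @param normalize Renormalize on construction (default \code{TRUE}).
#' @return An object of class \code{probability_grid}.
#' @export
probability_grid <- function(grid, values, label = "", normalize = TRUE) {
  stopifnot(is_grid_spec(grid))
  values <- as.matrix(values)
  if (!all(dim(values) == grid$resolution))
    stop("`values` must be a resolution x resolution matrix")
  if (any(!is.finite(values)) || any(values < 0))
    stop("density values must be finite and nonnegative")
  total <- grid_integral(grid, values)
  if (normalize) {
    if (total <= 0) stop("density must have positive total mass")
    values <- values / total
  } else if (abs(total - 1) > 1e-9) {
    stop("density does not integrate to 1 (", format(total), ")")
  }
  structure(list(grid = grid, values = values, label = label),
            class = "probability_grid")
}

#' @export
print.probability_grid <- function(x, ...) {
  cat(sprintf("<probability_grid> '%s' on %d^2 grid, mass %.9f\n",
              x$label, x$grid$resolution, grid_integral(x$grid, x$values)))
  invisible(x)
}

#' Uniform reference density on a grid
#'
#' @param grid A \code{grid_spec}.
#' @return A \code{probability_grid} with constant values \eqn{1/area}.
#' @export
uniform_grid <- function(grid) {
  n <- grid$resolution
  probability_grid(grid, matrix(1, n, n), label = "uniform")
}

#' Logical mask for the central analysis crop
#'
#' Analyses are restricted to the central portion of the domain to remove
#' boundary artifacts of the numerical method (default: the central 65%,
#' \eqn{|s_i| \le 0.65\,extent}).
#'
#' @param grid A \code{grid_spec}.
#' @param crop_fraction Fraction of the half-width retained, in (0, 1].
#' @return Logical matrix, \code{TRUE} inside the crop.
#' @export
crop_mask <- function(grid, crop_fraction = 0.65) {
  stopifnot(crop_fraction > 0, crop_fraction <= 1)
  co <- grid_coordinates(grid)
  lim <- crop_fraction * grid$extent
  abs(co$s1) <= lim & abs(co$s2) <= lim
}

#' Bilinear interpolation of a gridded field at arbitrary points
#'
#' @param grid A \code{grid_spec}.
#' @param values Matrix on \code{grid}, indexed \code{[s1, s2]}.
#' @param s1,s2 Numeric vectors of query coordinates (recycled together).
#' @param clamp Clamp queries to the domain instead of erroring
#'   (default \code{TRUE}).
#' @return Numeric vector of interpolated values.
#' @export
grid_interp <- function(grid, values, s1, s2, clamp = TRUE) {
  n <- grid$resolution
  h <- grid$spacing
  s1 <- as.vector(s1); s2 <- as.vector(s2)
  if (!clamp && (any(abs(s1) > grid$extent + 1e-12) ||
                 any(abs(s2) > grid$extent + 1e-12)))
    stop("query point outside the domain")
  x <- pmin(pmax((s1 + grid$extent) / h, 0), n - 1)
  y <- pmin(pmax((s2 + grid$extent) / h, 0), n - 1)
  i0 <- pmin(floor(x), n - 2); j0 <- pmin(floor(y), n - 2)
  tx <- x - i0; ty <- y - j0
  i0 <- i0 + 1; j0 <- j0 + 1  # 1-based
  v00 <- values[cbind(i0, j0)]
  v10 <- values[cbind(i0 + 1, j0)]
  v01 <- values[cbind(i0, j0 + 1)]
  v11 <- values[cbind(i0 + 1, j0 + 1)]
  (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
}
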