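#' Uniform lattice of tuning-curve centers in sensory space
#'
#' Builds a rectangular or hexagonal lattice covering the square domain,
#' including a margin of one spacing beyond the boundary so that the
#' summed population response still tiles the analysis crop when boundary
#' neurons are warped inward. Hexagonal rows are offset by
#' \code{spacing/2} with row pitch \code{spacing * sqrt(3)/2}; every
#' interior center then has nearest-neighbor distance exactly
#' \code{spacing}.
#'
#' @param kind \code{"hex"} or \code{"rect"}.
#' @param spacing Nearest-neighbor distance, stimulus units.
#' @param domain A \code{grid_spec} giving the domain half-width.
#' @param margin Margin beyond the boundary, in units of \code{spacing}.
#' @return Two-column matrix of center coordinates (s1, s2).
#' @examples
#' ctr <- make_lattice("hex", 0.2, grid_spec(resolution = 65))
#' @export
make_lattice <- function(kind = c("hex", "rect"), spacing, domain,
                         margin = 1) {
  kind <- match.arg(kind)
  stopifnot(is_grid_spec(domain))
  if (!is.numeric(spacing) || spacing <= 0) stop("`spacing` must be positive")
  ext <- domain$extent
  if (spacing > 2 * ext) stop("`spacing` exceeds the domain size")
  lim <- ext + margin * spacing
  if (kind == "rect") {
    ax <- seq_symmetric(lim, spacing)
    centers <- as.matrix(expand.grid(s1 = ax, s2 = ax))
  } else {
    pitch <- spacing * sqrt(3) / 2
    rows <- seq_symmetric(lim, pitch)
    pieces <- lapply(seq_along(rows), function(i) {
      off <- if (i %% 2 == 0) spacing / 2 else 0
      x <- seq_symmetric(lim, spacing) + off
      cbind(s1 = x, s2 = rows[i])
    })
    centers <- do.call(rbind, pieces)
  }
  dimnames(centers) <- list(NULL, c("s1", "s2"))
  centers
}

# symmetric arithmetic sequence about 0 with given step, covering [-lim, lim]
seq_symmetric <- function(lim, step) {
  k <- ceiling(lim / step)
  seq(-k, k) * step
}

#' Heterogeneous population of warped Poisson tuning curves
#'
#' A population is a uniform lattice of identical unimodal kernels in
#' sensory space, composed with the forward warp
#' \eqn{s \mapsto \hat{s} = s + f(s)} and multiplied by a gain:
#' \deqn{h_n(s) = g \cdot h(s + f(s) - \hat{s}_n).}
#' With \code{displacement = NULL} the population is the uniform
#' reference. The base kernel is an isotropic Gaussian of width
#' \code{sigma} and unit peak; \code{gain} is the constant peak firing
#' rate (spikes per unit time) of every neuron — the optimal solution
#' calls for constant gain.
#'
#' @param centers Two-column matrix of sensory-space centers
#'   (\code{\link{make_lattice}}).
#' @param sigma Tuning width in sensory-space units; a single value for
#'   isotropic kernels or length 2 for per-axis widths (a very large
#'   second width gives curves effectively constant in \eqn{s_2}).
#' @param gain Constant peak rate, spikes per unit time.
#' @param displacement A \code{displacement_field} or \code{NULL}.
#' @return Object of class \code{population}.
#' @export
population <- function(centers, sigma = 0.05, gain = 1,
                       displacement = NULL) {
  centers <- as.matrix(centers)
  if (length(sigma) == 1) sigma <- rep(sigma, 2)
  stopifnot(ncol(centers) == 2, length(sigma) == 2, all(sigma > 0),
            gain > 0)
  if (!is.null(displacement) && !inherits(displacement, "displacement_field"))
    stop("`displacement` must be a displacement_field or NULL")
  structure(list(centers = centers, sigma = sigma, gain = gain,
                 displacement = displacement, n_neurons = nrow(centers)),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population> %d neurons, sigma (%.3g, %.3g), gain %.3g, %s\n",
              x$n_neurons, x$sigma[1], x$sigma[2], x$gain,
              if (is.null(x$displacement)) "uniform" else "warped"))
  invisible(x)
}

#' Evaluate all tuning curves at a set of stimuli
#'
#' Computes the rate matrix \eqn{h_n(s) = g\,h(\hat{s}(s) - \hat{s}_n)}
#' with the displacement interpolated bilinearly between grid cells.
#'
#' @param pop A \code{population}.
#' @param s1,s2 Stimulus coordinates (vectors, recycled together).
#' @return Matrix of rates, neurons x points.
#' @export
evaluate_population <- function(pop, s1, s2) {
  s1 <- as.vector(s1); s2 <- as.vector(s2)
  if (!is.null(pop$displacement)) {
    fdom <- pop$displacement$grid$extent
    if (any(abs(s1) > fdom + 1e-9) || any(abs(s2) > fdom + 1e-9))
      stop("query point outside the displacement grid")
    fv <- displacement_at(pop$displacement, s1, s2)
    s1 <- s1 + fv$fx; s2 <- s2 + fv$fy
  }
  q <- outer(pop$centers[, 1], s1, "-")^2 / (2 * pop$sigma[1]^2) +
       outer(pop$centers[, 2], s2, "-")^2 / (2 * pop$sigma[2]^2)
  pop$gain * exp(-q)
}

#' Stimulus-space preferred locations of warped neurons
#'
#' Per-neuron stimulus-space location \eqn{s_n} where the forward warp
#' reaches the neuron's sensory-space center, \eqn{s_n + f(s_n) =
#' \hat{s}_n}, obtained from the inverse displacement field. Neurons whose
#' pre-image falls outside the domain are flagged.
#'
#' @param centers Two-column matrix of sensory-space centers.
#' @param f_inverse Inverse \code{displacement_field}
#'   (\code{\link{invert_displacement}}).
#' @return Data frame with columns \code{s1}, \code{s2} (stimulus-space
#'   peaks) and \code{inside} (logical, pre-image inside the domain).
#' @export
warp_centers <- function(centers, f_inverse) {
  stopifnot(inherits(f_inverse, "displacement_field"))
  ext <- f_inverse$grid$extent
  inside0 <- abs(centers[, 1]) <= ext & abs(centers[, 2]) <= ext
  s1 <- pmin(pmax(centers[, 1], -ext), ext)
  s2 <- pmin(pmax(centers[, 2], -ext), ext)
  fwd <- attr(f_inverse, "forward")
  if (!is.null(fwd)) {
    # exact per-point Newton inversion of the forward map
    pre <- invert_at(fwd, s1, s2)
    p1 <- pre$s1; p2 <- pre$s2
  } else {
    gv <- displacement_at(f_inverse, s1, s2)
    p1 <- s1 + gv$fx; p2 <- s2 + gv$fy
  }
  data.frame(s1 = p1, s2 = p2,
             inside = inside0 & abs(p1) <= ext & abs(p2) <= ext)
}

#' Summed population response (tiling diagnostic)
#'
#' @param pop A \code{population}.
#' @param s1,s2 Stimulus coordinates.
#' @return Vector of summed rates \eqn{\sum_n h_n(s)} at each point.
#' @export
population_sum <- function(pop, s1, s2) {
  colSums(evaluate_population(pop, s1, s2))
}

#' Scale the gain so the expected population rate equals a budget
#'
#' Enforces the resource constraint \eqn{\int p(s) \sum_n h_n(s)\,ds = R}
#' by scaling the constant gain: the expected number of spikes emitted per
#' unit time when stimuli are drawn from \code{p} becomes exactly
#' \code{R}.
#'
#' @param pop A \code{population}.
#' @param p A \code{probability_grid}.
#' @param R Expected population rate budget, spikes per unit time.
#' @return The population with rescaled gain.
#' @export
set_rate_budget <- function(pop, p, R) {
  co <- grid_coordinates(p$grid)
  tot <- population_sum(pop, co$s1, co$s2)
  expected <- grid_integral(p$grid, matrix(tot, p$grid$resolution) * p$values)
  if (expected <= 0) stop("population has zero expected rate under p")
  pop$gain <- pop$gain * R / expected
  pop
}

#' Poisson spike counts for one stimulus presentation
#'
#' Independent Poisson draws with mean \eqn{h_n(s) \cdot window} for each
#' neuron.
#'
#' @param pop A \code{population}.
#' @param stimulus Length-2 stimulus vector.
#' @param window Counting window, time units.
#' @param rng_seed Optional integer seed for reproducibility.
#' @return List of class \code{response_sample} with fields
#'   \code{stimulus}, \code{counts} (integer per neuron), \code{window}.
#' @export
sample_responses <- function(pop, stimulus, window = 1, rng_seed = NULL) {
  stopifnot(length(stimulus) == 2, window > 0)
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  rates <- as.vector(evaluate_population(pop, stimulus[1], stimulus[2]))
  if (any(rates < 0)) stop("internal error: negative firing rate")
  structure(list(stimulus = stimulus,
                 counts = stats::rpois(length(rates), rates * window),
                 window = window),
            class = "response_sample")
}
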