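# One-dimensional closed-form machinery: density from displacement,
# cumulative-based optimal mapping, and the information objective. These
# double as independent oracles for the 2-D potential solver.

#' Tuning-curve density induced by a 1-D displacement
#'
#' In one dimension the density of warped tuning curves is
#' \eqn{d(s) = 1 + f'(s)}, the derivative of the mapping
#' \eqn{\hat{s} = s + f(s)}; computed by centered differences (one-sided
#' at the ends).
#'
#' @param s Uniformly spaced sample points.
#' @param f Displacement sampled at \code{s}.
#' @return List of class \code{density_1d} with fields \code{s}, \code{d}
#'   and \code{N} (the integral of \code{d}, i.e. the sensory-space length
#'   covered, proportional to neuron count for a unit-spacing lattice).
#' @export
density_from_displacement_1d <- function(s, f) {
  stopifnot(length(s) == length(f), length(s) >= 3)
  ds <- diff(s)
  if (max(abs(ds - ds[1])) > 1e-9 * abs(ds[1]))
    stop("`s` must be uniformly spaced")
  n <- length(s)
  fp <- c(
    (f[2] - f[1]) / ds[1],
    (f[3:n] - f[1:(n - 2)]) / (2 * ds[1]),
    (f[n] - f[n - 1]) / ds[1]
  )
  d <- 1 + fp
  if (any(d < 0)) stop("non-injective warp: density 1 + f'(s) < 0")
  structure(list(s = s, d = d, N = trapz(s, d)), class = "density_1d")
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Optimal 1-D center positions from a stimulus density
#'
#' The optimal 1-D encoding population has tuning-curve density
#' \eqn{d(s) = N p(s)}; the warped centers are therefore equal quantiles
#' of \eqn{p} — the image of a uniform sensory lattice under the inverse
#' of the scaled cumulative of \eqn{p}. The cumulative is computed by the
#' trapezoid rule and inverted by monotone linear interpolation; regions
#' where \eqn{p = 0} receive no centers.
#'
#' @param s Uniformly spaced sample points of the stimulus interval.
#' @param p Density values at \code{s} (normalized internally).
#' @param N Number of neurons (at least 2).
#' @return Vector of \code{N} center positions in stimulus space.
#' @export
optimal_mapping_1d <- function(s, p, N) {
  stopifnot(length(s) == length(p), all(p >= 0), N >= 2)
  cdf <- c(0, cumsum(diff(s) * (p[-1] + p[-length(p)]) / 2))
  if (cdf[length(cdf)] <= 0) stop("density has zero mass")
  cdf <- cdf / cdf[length(cdf)]
  # mid-quantile targets: center n sits at quantile (n - 1/2)/N
  q <- (seq_len(N) - 0.5) / N
  keep <- c(TRUE, diff(cdf) > 0)  # drop flat (p = 0) stretches for inversion
  stats::approx(cdf[keep], s[keep], xout = q, ties = "ordered")$y
}

#' Information objective of a density/gain allocation
#'
#' The Fisher-approximation objective for a population with tuning-curve
#' density \eqn{d(s)} and gain \eqn{g(s)} encoding stimuli distributed as
#' \eqn{p}:
#' \deqn{\int p(s) \log\left(g(s)^k d(s)^2 U\right) ds,}
#' with the resource constraints \eqn{\int d = N} (neuron budget) and
#' \eqn{\int p g = R} (expected spike budget) reported as residuals. The
#' allocation \eqn{d = N p}, \eqn{g = R} maximizes this objective over
#' all constrained alternatives. Works for 1-D vectors (with \code{s})
#' or 2-D matrix fields (with \code{grid}).
#'
#' @param d Density values (vector or matrix), nonnegative.
#' @param g Gain values, same shape or scalar.
#' @param p Probability density values, same shape.
#' @param U Uniform Fisher reference level.
#' @param k Stimulus dimensionality (1 or 2).
#' @param s Sample points (1-D case).
#' @param grid A \code{grid_spec} (2-D case).
#' @param N,R Optional budgets; when given, constraint residuals
#'   \eqn{\int d - N} and \eqn{\int p g - R} are attached.
#' @return Scalar objective (nats) with attribute \code{constraints}.
#' @export
objective_functional <- function(d, g, p, U = 1, k = NULL,
                                 s = NULL, grid = NULL, N = NULL, R = NULL) {
  if (is.null(k)) k <- if (is.matrix(d)) 2 else 1
  if (length(g) == 1) g <- d * 0 + g
  supp <- p > 0
  if (any(d[supp] <= 0) || any(g[supp] <= 0))
    stop("d and g must be positive on the support of p")
  integrand <- p * 0
  integrand[supp] <- p[supp] * log(g[supp]^k * d[supp]^2 * U)
  if (!is.null(grid)) {
    val <- grid_integral(grid, integrand)
    int_d <- grid_integral(grid, d)
    int_pg <- grid_integral(grid, p * g)
  } else {
    stopifnot(!is.null(s))
    val <- trapz(s, integrand)
    int_d <- trapz(s, d)
    int_pg <- trapz(s, p * g)
  }
  attr(val, "constraints") <- c(
    neurons = if (is.null(N)) NA_real_ else int_d - N,
    rate = if (is.null(R)) NA_real_ else int_pg - R
  )
  val
}
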