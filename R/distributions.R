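#' Bivariate Gaussian stimulus distribution on a grid
#'
#' Density of a (possibly anisotropic, possibly rotated) bivariate normal,
#' truncated to the square domain and renormalized. \code{sigma} may be a
#' single number (isotropic), a length-2 vector (axis-aligned) or a 2x2
#' positive-definite covariance matrix.
#'
#' @param grid A \code{grid_spec}.
#' @param mean Length-2 center, inside the domain.
#' @param sigma Scalar / length-2 standard deviations, or 2x2 covariance.
#' @return A \code{probability_grid}.
#' @examples
#' g <- grid_spec(resolution = 65)
#' p <- make_gaussian(g, sigma = 0.25)
#' @export
make_gaussian <- function(grid, mean = c(0, 0), sigma = 0.25) {
  stopifnot(is_grid_spec(grid), length(mean) == 2)
  if (any(abs(mean) > grid$extent)) stop("`mean` must lie inside the domain")
  if (is.matrix(sigma)) {
    if (!all(dim(sigma) == 2) || abs(sigma[1, 2] - sigma[2, 1]) > 1e-12)
      stop("covariance must be a symmetric 2x2 matrix")
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("covariance must be positive definite")
    cov <- sigma
  } else {
    if (length(sigma) == 1) sigma <- rep(sigma, 2)
    if (any(sigma <= 0)) stop("`sigma` must be positive")
    cov <- diag(sigma^2)
  }
  pr <- solve(cov)
  co <- grid_coordinates(grid)
  d1 <- co$s1 - mean[1]; d2 <- co$s2 - mean[2]
  q <- pr[1, 1] * d1^2 + 2 * pr[1, 2] * d1 * d2 + pr[2, 2] * d2^2
  vals <- exp(-q / 2) / (2 * pi * sqrt(det(cov)))
  probability_grid(grid, vals, label = "gaussian")
}

#' Bivariate generalized Gaussian distribution on a grid
#'
#' Axis-separable leptokurtotic family
#' \deqn{p(s) \propto \exp\{-(|s_1/\sigma_1|^p + |s_2/\sigma_2|^p)\},}
#' truncated to the domain and renormalized. Convention: the exponent is
#' applied per axis and \code{sigma_s1}, \code{sigma_s2} are scale
#' parameters of the kernel, not standard deviations. With
#' \code{power = 2} the kernel is \eqn{\exp(-(s_1/\sigma_1)^2 -
#' (s_2/\sigma_2)^2)}, a Gaussian whose standard deviation is
#' \eqn{\sigma_i/\sqrt{2}}; \code{make_generalized_gaussian(g, s, s, 2)}
#' therefore equals \code{make_gaussian(g, sigma = s/sqrt(2))}.
#'
#' @param grid A \code{grid_spec}.
#' @param mean Length-2 center.
#' @param sigma_s1,sigma_s2 Positive per-axis scale parameters.
#' @param power Positive exponent; \code{power < 2} gives heavier tails
#'   than Gaussian, \code{power = 1.1} matches the leptokurtotic fixture.
#' @return A \code{probability_grid}.
#' @export
make_generalized_gaussian <- function(grid, mean = c(0, 0),
                                      sigma_s1 = 0.75, sigma_s2 = 0.25,
                                      power = 1.1) {
  stopifnot(is_grid_spec(grid), length(mean) == 2)
  if (power <= 0) stop("`power` must be positive")
  if (sigma_s1 <= 0 || sigma_s2 <= 0) stop("scale parameters must be positive")
  co <- grid_coordinates(grid)
  vals <- exp(-(abs((co$s1 - mean[1]) / sigma_s1)^power +
                abs((co$s2 - mean[2]) / sigma_s2)^power))
  probability_grid(grid, vals, label = "generalized_gaussian")
}

#' Default bandwidth profile of the non-separable fixture
#'
#' A smooth stand-in for a conditional bandwidth that varies nonlinearly
#' with \eqn{s_2}: \eqn{\sigma(s_2) = 0.1 + 0.15\,(1 + \cos(\pi s_2))/2},
#' bounded in \eqn{[0.1, 0.25]}.
#'
#' @param s2 Numeric vector in \eqn{[-1, 1]}.
#' @return Positive bandwidths, same length as \code{s2}.
#' @export
default_sigma_profile <- function(s2) {
  0.1 + 0.15 * (1 + cos(pi * s2)) / 2
}

#' Non-separable stimulus distribution on a grid
#'
#' Gaussian over \eqn{s_1} whose standard deviation varies with
#' \eqn{s_2}: \eqn{p(s_1, s_2) \propto q(s_2)\, N(s_1; 0, \sigma(s_2))}
#' with a uniform \eqn{s_2}-marginal \eqn{q} by default. With a constant
#' \code{sigma_fn} the result degenerates to a separable product.
#'
#' @param grid A \code{grid_spec}.
#' @param sigma_fn Function mapping \eqn{s_2 \in [-1,1]} to a positive
#'   bandwidth (default \code{\link{default_sigma_profile}}).
#' @param marginal_s2 Optional function giving the (unnormalized)
#'   \eqn{s_2} marginal; default uniform.
#' @return A \code{probability_grid}.
#' @export
make_nonseparable <- function(grid, sigma_fn = default_sigma_profile,
                              marginal_s2 = NULL) {
  stopifnot(is_grid_spec(grid), is.function(sigma_fn))
  sig <- sigma_fn(grid$coords)
  if (any(!is.finite(sig)) || any(sig <= 0))
    stop("sigma_fn must return positive bandwidths over the domain")
  q2 <- if (is.null(marginal_s2)) rep(1, grid$resolution)
        else marginal_s2(grid$coords)
  if (any(q2 < 0)) stop("s2 marginal must be nonnegative")
  # column j: Normal(s1; 0, sig[j]) scaled by q2[j]
  vals <- outer(grid$coords, seq_along(sig),
                function(s1, j) stats::dnorm(s1, 0, sig[j]) * q2[j])
  probability_grid(grid, vals, label = "nonseparable")
}

#' Draw parameters of a random zero-centered bivariate Gaussian
#'
#' The randomized experiments use zero-centered bivariate Gaussians with a
#' random orientation drawn uniformly on \eqn{[0, \pi)} and major/minor
#' standard deviations drawn uniformly from 0.1 to 0.4 stimulus units.
#'
#' @param rng_seed Integer seed; the draw is deterministic given the seed.
#'   With \code{rng_seed = NULL} the draw consumes the session RNG stream
#'   (used inside seeded experiment loops).
#' @return A list of class \code{random_gaussian_params} with fields
#'   \code{orientation}, \code{sigma_major}, \code{sigma_minor} (major is
#'   the larger of the two draws) and \code{mean = c(0, 0)}.
#' @export
sample_random_gaussian_params <- function(rng_seed = NULL) {
  if (!is.null(rng_seed)) {
    stopifnot(is.numeric(rng_seed), length(rng_seed) == 1)
    set.seed(as.integer(rng_seed))
  }
  rng <- stats::runif(3)
  sds <- 0.1 + 0.3 * rng[1:2]
  structure(
    list(
      orientation = pi * rng[3],
      sigma_major = max(sds),
      sigma_minor = min(sds),
      mean = c(0, 0)
    ),
    class = "random_gaussian_params"
  )
}

#' Covariance matrix of random-Gaussian parameters
#'
#' @param params A \code{random_gaussian_params} object.
#' @return 2x2 covariance matrix \eqn{R\,\mathrm{diag}(\sigma_{maj}^2,
#'   \sigma_{min}^2)\,R^T} for rotation angle \code{orientation}.
#' @export
params_covariance <- function(params) {
  th <- params$orientation
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot %*% diag(c(params$sigma_major^2, params$sigma_minor^2)) %*% t(rot)
}
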