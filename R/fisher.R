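RATE_FLOOR_FRACTION <- 1e-9  # tuning-curve values below this fraction of
                             # the peak are excluded from Fisher sums (0/0 guard)

#' One-dimensional heterogeneous population
#'
#' A 1-D population of identical unimodal Gaussian kernels on a uniform
#' sensory-space lattice, warped by a displacement function and scaled by
#' a gain function: \eqn{h_n(s) = g(s)\,h(s + f(s) - \hat{s}_n)}. Used for
#' the 1-D Fisher-information machinery and the smoothness
#' demonstrations; \code{warp_fn}/\code{gain_fn} of \code{NULL} give the
#' uniform population with constant gain.
#'
#' @param centers Numeric vector of sensory-space centers.
#' @param sigma Tuning width.
#' @param gain Constant peak rate multiplier.
#' @param warp_fn Displacement function \eqn{f(s)} or \code{NULL}.
#' @param gain_fn Gain modulation \eqn{g(s)} (multiplies \code{gain}) or
#'   \code{NULL}.
#' @return Object of class \code{population_1d}.
#' @export
population_1d <- function(centers, sigma = 0.05, gain = 1,
                          warp_fn = NULL, gain_fn = NULL) {
  stopifnot(is.numeric(centers), length(centers) >= 1, sigma > 0, gain > 0)
  structure(list(centers = sort(centers), sigma = sigma, gain = gain,
                 warp_fn = warp_fn, gain_fn = gain_fn),
            class = "population_1d")
}

#' Evaluate a 1-D population
#'
#' @param pop A \code{population_1d}.
#' @param s Stimulus values.
#' @return Rate matrix, neurons x points.
#' @export
evaluate_population_1d <- function(pop, s) {
  shat <- if (is.null(pop$warp_fn)) s else s + pop$warp_fn(s)
  g <- pop$gain * (if (is.null(pop$gain_fn)) 1 else pop$gain_fn(s))
  rates <- exp(-outer(pop$centers, shat, "-")^2 / (2 * pop$sigma^2))
  sweep(rates, 2, g, "*")
}

#' Exact 1-D population Fisher information
#'
#' \eqn{F(s) = \sum_n h_n'(s)^2 / h_n(s)} with tuning-curve derivatives by
#' centered finite differences on the evaluation grid; terms where
#' \eqn{h_n} falls below a small fraction of the peak are excluded to
#' avoid 0/0.
#'
#' @param pop A \code{population_1d}, or a rate matrix (neurons x points).
#' @param s_values Uniformly spaced evaluation grid.
#' @return Fisher information at interior points of \code{s_values}
#'   (first and last point are dropped); attribute \code{s} gives the
#'   corresponding stimulus values.
#' @export
fisher_1d <- function(pop, s_values) {
  rates <- if (inherits(pop, "population_1d"))
    evaluate_population_1d(pop, s_values) else as.matrix(pop)
  if (nrow(rates) == 0) stop("empty population")
  ds <- diff(s_values)
  if (max(abs(ds - ds[1])) > 1e-9 * abs(ds[1]))
    stop("`s_values` must be uniformly spaced")
  np <- length(s_values)
  dr <- (rates[, 3:np, drop = FALSE] - rates[, 1:(np - 2), drop = FALSE]) /
    (2 * ds[1])
  hm <- rates[, 2:(np - 1), drop = FALSE]
  keep <- hm > RATE_FLOOR_FRACTION * max(rates)
  contrib <- matrix(0, nrow(hm), ncol(hm))
  contrib[keep] <- dr[keep]^2 / hm[keep]
  out <- colSums(contrib)
  attr(out, "s") <- s_values[2:(np - 1)]
  out
}

#' Population Fisher information matrix over a grid
#'
#' Per-cell 2x2 Fisher matrix of the independent-Poisson population,
#' \deqn{[F(s)]_{ij} = \sum_n \frac{\partial_i h_n \, \partial_j h_n}{h_n},}
#' with tuning-curve partial derivatives by centered differences at grid
#' resolution. The grid must resolve the tuning curves (at least 4
#' samples per tuning sigma).
#'
#' @param pop A \code{population}.
#' @param grid A \code{grid_spec}.
#' @return Object of class \code{fisher_field}: matrices \code{f11},
#'   \code{f12}, \code{f22}, determinant \code{det}, and the grid.
#' @export
fisher_matrix <- function(pop, grid) {
  stopifnot(inherits(pop, "population"), is_grid_spec(grid))
  if (pop$n_neurons == 0) stop("empty population")
  if (grid$spacing > min(pop$sigma) / 4)
    stop(sprintf(
      "grid resolution too coarse for tuning width: need spacing <= sigma/4 (%.4g), have %.4g",
      min(pop$sigma) / 4, grid$spacing))
  n <- grid$resolution
  h <- grid$spacing
  co <- grid_coordinates(grid)
  if (!is.null(pop$displacement)) {
    fv <- displacement_at(pop$displacement, co$s1, co$s2)
    shat1 <- co$s1 + matrix(fv$fx, n, n)
    shat2 <- co$s2 + matrix(fv$fy, n, n)
  } else {
    shat1 <- co$s1; shat2 <- co$s2
  }
  f11 <- f12 <- f22 <- matrix(0, n, n)
  floor_abs <- RATE_FLOOR_FRACTION * pop$gain
  inv1 <- 1 / (2 * pop$sigma[1]^2)
  inv2 <- 1 / (2 * pop$sigma[2]^2)
  for (m in seq_len(pop$n_neurons)) {
    rate <- pop$gain * exp(-(shat1 - pop$centers[m, 1])^2 * inv1 -
                            (shat2 - pop$centers[m, 2])^2 * inv2)
    if (max(rate) <= floor_abs) next
    d1 <- deriv1(rate, h, 1)
    d2 <- deriv1(rate, h, 2)
    keep <- rate > floor_abs
    inv <- matrix(0, n, n)
    inv[keep] <- 1 / rate[keep]
    f11 <- f11 + d1 * d1 * inv
    f12 <- f12 + d1 * d2 * inv
    f22 <- f22 + d2 * d2 * inv
  }
  structure(list(grid = grid, f11 = f11, f12 = f12, f22 = f22,
                 det = f11 * f22 - f12^2),
            class = "fisher_field")
}

#' @export
print.fisher_field <- function(x, ...) {
  cat(sprintf("<fisher_field> on %d^2 grid, median det %.4g\n",
              x$grid$resolution, stats::median(x$det)))
  invisible(x)
}

#' Reference Fisher level of a uniform population
#'
#' The constant \eqn{U}: for a 2-D population, the median of
#' \eqn{\det F} over the analysis crop of the uniform reference
#' population (measured, not assumed analytically); for a
#' \code{population_1d}, the median of \eqn{F(s)} over the central
#' portion of \code{s_values}.
#'
#' @param pop A \code{population} or \code{population_1d} (unwarped).
#' @param grid A \code{grid_spec} (2-D case).
#' @param s_values Evaluation grid (1-D case).
#' @param crop_fraction Central crop used for the median.
#' @return Scalar \eqn{U}.
#' @export
estimate_U <- function(pop, grid = NULL, s_values = NULL,
                       crop_fraction = 0.65) {
  if (inherits(pop, "population_1d")) {
    fi <- fisher_1d(pop, s_values)
    s <- attr(fi, "s")
    lim <- crop_fraction * max(abs(s_values))
    return(stats::median(fi[abs(s) <= lim]))
  }
  ff <- fisher_matrix(pop, grid)
  stats::median(ff$det[crop_mask(grid, crop_fraction)])
}

#' Smooth-warp approximation of the Fisher determinant
#'
#' For a warped and gain-scaled population with slowly varying
#' displacement and gain, the Fisher determinant is approximately
#' \deqn{|F_{f,g}(s)| = g(s)^k\,|I + J(f)|^2\,U,}
#' the uniform level \eqn{U} rescaled by the gain and the squared
#' Jacobian determinant of the warp (k = 2 here; see
#' \code{\link{approx_fisher_1d}} for the slice form).
#'
#' @param f A \code{displacement_field}.
#' @param gain Constant gain or matrix gain field on the same grid.
#' @param U Uniform reference level (\code{\link{estimate_U}}).
#' @return Matrix field of approximate Fisher determinants.
#' @export
approx_fisher <- function(f, gain, U) {
  stopifnot(inherits(f, "displacement_field"))
  gain^2 * density_of_mapping(f)^2 * U
}

#' @rdname approx_fisher
#' @param density 1-D tuning-curve density \eqn{d(s) = 1 + f'(s)}.
#' @export
approx_fisher_1d <- function(density, gain, U) {
  gain * density^2 * U
}

#' Recover the stimulus distribution from a Fisher field
#'
#' For an optimally warped population the Fisher determinant is
#' proportional to the squared stimulus probability, so
#' \eqn{\hat{p} \propto \sqrt{\det F}} recovers the distribution. The
#' estimate is normalized over the analysis crop (zero outside), since
#' the proportionality only holds away from the boundary.
#'
#' @param fisher A \code{fisher_field}.
#' @param crop_fraction Central crop for normalization.
#' @return A \code{probability_grid} supported on the crop.
#' @export
recover_probability <- function(fisher, crop_fraction = 0.65) {
  stopifnot(inherits(fisher, "fisher_field"))
  d <- pmax(fisher$det, 0)
  if (all(d == 0)) stop("Fisher determinant is identically zero")
  vals <- sqrt(d)
  vals[!crop_mask(fisher$grid, crop_fraction)] <- 0
  probability_grid(fisher$grid, vals, label = "recovered")
}

#' Fisher-based lower bound on mutual information
#'
#' The k-dimensional form of the Fisher lower bound on the mutual
#' information between stimulus and population response,
#' \deqn{M \ge H(p) + \int p(s)\,\tfrac12 \log\frac{\det F(s)}{(2\pi e)^k}\,ds,}
#' evaluated over the analysis crop with \eqn{p} renormalized there
#' (k = 2). The bound tightens in the low-noise (many neurons / many
#' spikes) regime.
#'
#' @param pop A \code{population}.
#' @param p A \code{probability_grid}.
#' @param fisher Optional precomputed \code{fisher_field} on
#'   \code{p$grid}.
#' @param crop_fraction Central analysis crop.
#' @return Scalar bound in nats; \code{-Inf} (with a warning) if the
#'   Fisher determinant vanishes on cells carrying probability mass.
#' @export
mi_lower_bound <- function(pop, p, fisher = NULL, crop_fraction = 0.65) {
  k <- 2
  if (is.null(fisher)) fisher <- fisher_matrix(pop, p$grid)
  stopifnot(same_grid(fisher$grid, p$grid))
  cm <- crop_mask(p$grid, crop_fraction)
  w <- p$grid$spacing^2
  pc <- p$values[cm]
  pc <- pc / (sum(pc) * w)
  dets <- fisher$det[cm]
  pos <- pc > 0
  if (any(dets[pos] <= 0)) {
    warning("det F = 0 on cells with positive probability; bound is -Inf")
    return(-Inf)
  }
  entropy <- -sum(pc[pos] * log(pc[pos])) * w
  entropy + sum(pc[pos] * 0.5 * log(dets[pos] / (2 * pi * exp(1))^k)) * w
}
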