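#' Scalar encoding potential on a grid
#'
#' Container for the scalar potential \eqn{v(s)} (stimulus-units squared)
#' whose gradient is the displacement field warping a uniform population.
#' A 1-cell boundary band replicates the adjacent interior values so that
#' the discrete normal derivative (and hence the normal displacement)
#' vanishes on the boundary; the band is maintained as tied groups during
#' optimization.
#'
#' @param grid A \code{grid_spec}.
#' @param values Matrix of potential values (default zero).
#' @return An object of class \code{potential}.
#' @export
potential <- function(grid, values = NULL) {
  stopifnot(is_grid_spec(grid))
  n <- grid$resolution
  if (is.null(values)) values <- matrix(0, n, n)
  values <- as.matrix(values)
  if (!all(dim(values) == n)) stop("`values` must be resolution x resolution")
  if (any(!is.finite(values))) stop("potential must be finite everywhere")
  structure(list(grid = grid, values = enforce_boundary_tie(values),
                 boundary_pad = FILTER_HALF_WIDTH),
            class = "potential")
}

#' @export
print.potential <- function(x, ...) {
  cat(sprintf("<potential> on %d^2 grid, range [%.4g, %.4g]\n",
              x$grid$resolution, min(x$values), max(x$values)))
  invisible(x)
}

# replicate edge rows/cols from the adjacent interior (zero normal slope)
enforce_boundary_tie <- function(v) {
  n <- nrow(v)
  v[1, ] <- v[2, ]; v[n, ] <- v[n - 1, ]
  v[, 1] <- v[, 2]; v[, n] <- v[, n - 1]
  v
}

#' Discrete Hessian of a potential
#'
#' Second partial derivatives computed with the package's fixed separable
#' stencils; symmetric by construction (single mixed derivative).
#'
#' @param v A \code{potential}, or a plain matrix together with \code{h}.
#' @param h Grid spacing (ignored when \code{v} is a \code{potential}).
#' @return List with matrices \code{v11}, \code{v12}, \code{v22}.
#' @export
hessian_of_potential <- function(v, h = NULL) {
  if (inherits(v, "potential")) { h <- v$grid$spacing; v <- v$values }
  if (nrow(v) < 2 * FILTER_HALF_WIDTH + 1)
    stop("grid too small for the derivative filter support")
  list(
    v11 = deriv2(smooth1(v, 2), h, axis = 1),
    v12 = deriv1(deriv1(v, h, axis = 2), h, axis = 1),
    v22 = deriv2(smooth1(v, 1), h, axis = 2)
  )
}

#' Residual of the density-remapping equation
#'
#' Per-cell residual of the expanded determinant equation
#' \deqn{v_{11} v_{22} - v_{12}^2 + v_{11} + v_{22} + 1 = p(s)/u(s),}
#' i.e. \eqn{\det(I + H(v)) - p/u}. A zero residual means the potential's
#' induced mapping carries the uniform reference density \eqn{u} into the
#' stimulus density \eqn{p}.
#'
#' @param v A \code{potential}.
#' @param p,u \code{probability_grid}s on the same grid; \code{u} must be
#'   strictly positive.
#' @return Matrix of per-cell residuals (meaningful on interior cells).
#' @export
remap_residual <- function(v, p, u) {
  stopifnot(inherits(v, "potential"))
  if (!same_grid(p$grid, v$grid) || !same_grid(u$grid, v$grid))
    stop("p, u and v must share one grid")
  if (any(u$values <= 0)) stop("reference density `u` must be positive")
  H <- hessian_of_potential(v)
  det_field(H) - p$values / u$values
}

det_field <- function(H) {
  H$v11 * H$v22 - H$v12^2 + H$v11 + H$v22 + 1
}

interior_mask <- function(n, pad = FILTER_HALF_WIDTH) {
  m <- matrix(FALSE, n, n)
  m[(1 + pad):(n - pad), (1 + pad):(n - pad)] <- TRUE
  m
}

#' Solver configuration
#'
#' @param levels Number of multigrid levels (coarse-to-fine); the coarse
#'   resolution is obtained by repeated dyadic coarsening of the target
#'   resolution, never below \code{min_resolution}.
#' @param min_resolution Smallest allowed coarse resolution (>= 17).
#' @param max_iter Maximum conjugate-gradient iterations per level.
#' @param tol Relative objective decrease over \code{tol_window}
#'   iterations below which a level stops.
#' @param tol_window Iteration window for the stopping rule.
#' @param rms_tol A level also stops once the interior RMS residual falls
#'   below this value (absolute, on the unit-mean ratio scale).
#' @param interior Interior-region shape, \code{"circle"} or
#'   \code{"square"}; outside it the stimulus and reference densities are
#'   defined to be equal so the effective boundary is the region edge.
#' @param interior_radius Region radius as a fraction of the extent.
#' @param ramp Width of the smooth probability blend at the region edge,
#'   fraction of the extent.
#' @param crop_fraction Central crop used by analyses.
#' @param verbose Print per-level progress.
#' @return List of class \code{solver_config}.
#' @export
solver_config <- function(levels = 2, min_resolution = 17L, max_iter = 600L,
                          tol = 1e-8, tol_window = 10L, rms_tol = 1e-4,
                          interior = c("circle", "square"),
                          interior_radius = 0.9, ramp = 0.05,
                          crop_fraction = 0.65, verbose = FALSE) {
  interior <- match.arg(interior)
  stopifnot(min_resolution >= 17L, tol > 0, rms_tol > 0,
            crop_fraction > 0, crop_fraction <= 1)
  structure(list(levels = levels, min_resolution = as.integer(min_resolution),
                 max_iter = as.integer(max_iter), tol = tol,
                 tol_window = as.integer(tol_window), rms_tol = rms_tol,
                 interior = interior,
                 interior_radius = interior_radius, ramp = ramp,
                 crop_fraction = crop_fraction, verbose = verbose),
            class = "solver_config")
}

#' Target density ratio with interior-region blending
#'
#' Builds the right-hand side \eqn{p/u} of the remapping equation with the
#' stimulus density smoothly blended into the reference outside the
#' interior region (a cosine ramp of width \code{ramp}), band-limited by
#' one pass of the solver's separable prefilter (an \eqn{O(h^2)}
#' perturbation, the same order as the discretization error, which removes
#' near-Nyquist content the filtered operators cannot represent), and
#' rescaled so the ratio has exact unit mean — the discrete solvability
#' condition for a mapping with zero normal boundary displacement.
#'
#' @param p,u \code{probability_grid}s on one grid.
#' @param cfg A \code{solver_config}.
#' @return Matrix of target ratio values with \code{mean == 1}.
#' @export
target_ratio <- function(p, u, cfg = solver_config()) {
  stopifnot(same_grid(p$grid, u$grid))
  if (any(u$values <= 0)) stop("reference density `u` must be positive")
  co <- grid_coordinates(p$grid)
  rr <- if (cfg$interior == "circle") sqrt(co$s1^2 + co$s2^2) / p$grid$extent
        else pmax(abs(co$s1), abs(co$s2)) / p$grid$extent
  r1 <- cfg$interior_radius - cfg$ramp
  w <- ifelse(rr <= r1, 1,
              ifelse(rr >= cfg$interior_radius, 0,
                     0.5 * (1 + cos(pi * (rr - r1) / cfg$ramp))))
  raw <- p$values / u$values
  sw <- mean(w); swr <- mean(w * raw)
  if (swr <= 0) stop("stimulus density vanishes on the interior region")
  out <- 1 + w * ((sw / swr) * raw - 1)
  out <- smooth1(smooth1(out, 1), 2)
  out / mean(out)
}

# ---- objective / gradient -------------------------------------------------

solver_objective <- function(v, ratio, h, inner) {
  H <- list(v11 = deriv2(smooth1(v, 2), h, 1),
            v12 = deriv1(deriv1(v, h, 2), h, 1),
            v22 = deriv2(smooth1(v, 1), h, 2))
  r <- det_field(H) - ratio
  r[!inner] <- 0
  list(value = sum(r * r), r = r, H = H)
}

solver_gradient <- function(obj, h) {
  r <- obj$r; H <- obj$H
  g <- smooth1_adj(deriv2_adj(r * (H$v22 + 1), h, 1), 2) +
       smooth1_adj(deriv2_adj(r * (H$v11 + 1), h, 2), 1) +
       deriv1_adj(deriv1_adj(-2 * r * H$v12, h, 1), h, 2)
  2 * g
}

# Free parametrization: the optimization variables are the (n-2)^2
# interior values; the boundary band is an exact replica of the adjacent
# interior row/col (expand), and the gradient of the band folds back into
# its interior partner (collapse, the adjoint of expand).
expand_free <- function(vf) {
  m <- nrow(vf); n <- m + 2
  v <- matrix(0, n, n)
  v[2:(n - 1), 2:(n - 1)] <- vf
  enforce_boundary_tie(v)
}

collapse_grad <- function(g) {
  n <- nrow(g)
  g[2, ] <- g[2, ] + g[1, ]; g[n - 1, ] <- g[n - 1, ] + g[n, ]
  g[, 2] <- g[, 2] + g[, 1]; g[, n - 1] <- g[, n - 1] + g[, n]
  g[2:(n - 1), 2:(n - 1)]
}

# Spectral preconditioner. At v = 0 the Gauss-Newton Hessian of the
# squared-residual objective in the free parametrization is A^2 with
# A = T (x) P + P (x) T, where T is the 1-D second-difference operator
# with Neumann (replicated-edge) boundary rows and P the matching
# prefilter. P = I + (h^2/4) T exactly, so both share T's eigenbasis and
# A is diagonalized by it: inverting A^2 spectrally gives a near-ideal
# preconditioner for the mildly nonlinear problem. The constant mode
# (zero eigenvalue, objective-invariant) is annihilated.
precond_setup <- function(m, h) {
  T1 <- diag(-2, m)
  T1[cbind(1:(m - 1), 2:m)] <- 1
  T1[cbind(2:m, 1:(m - 1))] <- 1
  T1[1, 1] <- -1; T1[m, m] <- -1
  T1 <- T1 / h^2
  e <- eigen(T1, symmetric = TRUE)
  mu <- e$values
  pp <- 1 + h^2 * mu / 4
  denom <- (outer(mu, pp) + outer(pp, mu))^2
  denom[denom < 1e-12 * max(denom)] <- Inf
  # modes near Nyquist in BOTH axes are (near-)invisible to the
  # prefiltered operators; project them out rather than amplify them
  denom[outer(pp < 0.15, pp < 0.15, "&")] <- Inf
  list(V = e$vectors, denom = denom)
}

precond_apply <- function(pc, g) {
  pc$V %*% ((crossprod(pc$V, g %*% pc$V)) / pc$denom) %*% t(pc$V)
}

# Preconditioned nonlinear conjugate gradient (Polak-Ribiere+ with
# restarts) at one resolution. Backtracking line search with an Armijo
# sufficient-decrease condition; the accepted objective sequence is
# monotone.
cg_solve_level <- function(v, ratio, h, cfg) {
  n <- nrow(v)
  inner <- interior_mask(n)
  vf <- v[2:(n - 1), 2:(n - 1)]
  pc <- precond_setup(n - 2L, h)
  obj <- solver_objective(expand_free(vf), ratio, h, inner)
  g <- collapse_grad(solver_gradient(obj, h))
  y <- precond_apply(pc, g)
  d <- -y
  gy <- sum(g * y)
  trace <- numeric(0)
  step <- 1
  restart_every <- n
  for (it in seq_len(cfg$max_iter)) {
    slope <- sum(g * d)
    if (slope >= 0 || !is.finite(slope)) { d <- -y; slope <- -gy }
    a <- min(step * 2, 4)
    accepted <- FALSE
    for (k in 1:50) {
      cand <- solver_objective(expand_free(vf + a * d), ratio, h, inner)
      if (is.finite(cand$value) &&
          cand$value <= obj$value + 1e-4 * a * slope) { accepted <- TRUE; break }
      a <- a / 2
    }
    if (!accepted) break
    step <- a
    vf <- vf + a * d
    obj <- cand
    g_new <- collapse_grad(solver_gradient(obj, h))
    y_new <- precond_apply(pc, g_new)
    beta <- max(0, sum((g_new - g) * y_new) / gy)
    if (it %% restart_every == 0) beta <- 0
    d <- -y_new + beta * d
    g <- g_new; y <- y_new; gy <- sum(g * y)
    trace <- c(trace, obj$value)
    if (obj$value <= cfg$rms_tol^2 * sum(inner)) break
    tw <- cfg$tol_window
    if (length(trace) > tw) {
      prev <- trace[length(trace) - tw]
      if ((prev - obj$value) <= cfg$tol * max(prev, .Machine$double.eps))
        break
    }
  }
  list(v = expand_free(vf), objective = obj$value, trace = trace,
       iterations = length(trace))
}

#' Solve for the optimal encoding potential
#'
#' Minimizes the accumulated squared residual of the density-remapping
#' equation \eqn{\det(I + H(v)) = p/u} over the discrete domain by
#' nonlinear conjugate gradients, wrapped in a coarse-to-fine multigrid
#' scheme (the potential is first estimated at low resolution, then
#' bilinearly upsampled and refined). The stimulus density is blended into
#' the reference outside the interior region (see
#' \code{\link{target_ratio}}); analyses of the result should be
#' restricted to the central crop.
#'
#' @param p Stimulus \code{probability_grid}.
#' @param u Reference \code{probability_grid}; default uniform on the
#'   same grid.
#' @param cfg A \code{solver_config}.
#' @return A \code{potential} with attributes \code{rms_residual}
#'   (root-mean-square residual over interior cells, final level),
#'   \code{trace} (per-level objective traces), \code{converged}.
#' @export
solve_potential <- function(p, u = NULL, cfg = solver_config()) {
  if (is.null(u)) u <- uniform_grid(p$grid)
  stopifnot(same_grid(p$grid, u$grid))
  n_final <- p$grid$resolution
  # dyadic level resolutions, coarse to fine
  res_seq <- n_final
  while (length(res_seq) < cfg$levels) {
    nxt <- (res_seq[1] - 1) %/% 2 + 1
    if (nxt < cfg$min_resolution) break
    res_seq <- c(nxt, res_seq)
  }
  v <- NULL
  traces <- list()
  for (res in res_seq) {
    g_lvl <- grid_spec(p$grid$extent, res)
    p_lvl <- if (res == n_final) p else resample_probability(p, g_lvl)
    u_lvl <- if (res == n_final) u else resample_probability(u, g_lvl)
    ratio <- target_ratio(p_lvl, u_lvl, cfg)
    v0 <- if (is.null(v)) matrix(0, res, res) else {
      co <- grid_coordinates(g_lvl)
      matrix(grid_interp(v$grid, v$values, co$s1, co$s2), res, res)
    }
    v0 <- enforce_boundary_tie(v0)
    fit <- cg_solve_level(v0, ratio, g_lvl$spacing, cfg)
    if (cfg$verbose)
      message(sprintf("level %d^2: %d iterations, objective %.3e",
                      res, fit$iterations, fit$objective))
    v <- potential(g_lvl, fit$v)
    traces[[as.character(res)]] <- fit$trace
  }
  inner <- interior_mask(n_final)
  rfin <- remap_residual(v, p, u) +
    (p$values / u$values - target_ratio(p, u, cfg))  # det - blended ratio
  attr(v, "rms_residual") <- sqrt(mean(rfin[inner]^2))
  attr(v, "trace") <- traces
  attr(v, "converged") <-
    length(traces[[length(traces)]]) < cfg$max_iter
  v
}

resample_probability <- function(p, grid) {
  co <- grid_coordinates(grid)
  vals <- matrix(grid_interp(p$grid, p$values, co$s1, co$s2),
                 grid$resolution, grid$resolution)
  probability_grid(grid, pmax(vals, 0), label = p$label)
}

#' Displacement field of a potential
#'
#' The conservative displacement \eqn{f(s) = \nabla v(s)}; curl-free by
#' construction, with zero normal component on the boundary (enforced by
#' the potential's replicated boundary band).
#'
#' @param v A \code{potential}.
#' @return An object of class \code{displacement_field} with matrices
#'   \code{fx} (\eqn{\partial v/\partial s_1}) and \code{fy}.
#' @export
displacement_from_potential <- function(v) {
  stopifnot(inherits(v, "potential"))
  h <- v$grid$spacing
  structure(list(grid = v$grid,
                 fx = deriv1(smooth1(v$values, 2), h, 1),
                 fy = deriv1(smooth1(v$values, 1), h, 2)),
            class = "displacement_field")
}

#' Zero displacement field
#'
#' @param grid A \code{grid_spec}.
#' @return A \code{displacement_field} with zero components.
#' @export
zero_displacement <- function(grid) {
  n <- grid$resolution
  structure(list(grid = grid, fx = matrix(0, n, n), fy = matrix(0, n, n)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("<displacement_field> on %d^2 grid, max |f| = %.4g\n",
              x$grid$resolution, max(sqrt(x$fx^2 + x$fy^2))))
  invisible(x)
}

#' Evaluate a displacement field at arbitrary points
#'
#' Bilinear interpolation of both components.
#'
#' @param f A \code{displacement_field}.
#' @param s1,s2 Query coordinates.
#' @return List with vectors \code{fx}, \code{fy}.
#' @export
displacement_at <- function(f, s1, s2) {
  list(fx = grid_interp(f$grid, f$fx, s1, s2),
       fy = grid_interp(f$grid, f$fy, s1, s2))
}

jacobian_of_displacement <- function(f) {
  h <- f$grid$spacing
  list(j11 = deriv1(smooth1(f$fx, 2), h, 1), j12 = deriv1(smooth1(f$fx, 1), h, 2),
       j21 = deriv1(smooth1(f$fy, 2), h, 1), j22 = deriv1(smooth1(f$fy, 1), h, 2))
}

#' Relative density induced by a mapping
#'
#' Per-cell \eqn{\det(I + J(f))}, the determinant of the Jacobian of the
#' mapping \eqn{s \mapsto s + f(s)}. This determinant defines the relative
#' density between sensory and stimulus space: for an optimal potential it
#' is proportional to \eqn{p(s)} over the analysis crop.
#'
#' @param f A \code{displacement_field}.
#' @return Matrix of per-cell determinants.
#' @export
density_of_mapping <- function(f) {
  J <- jacobian_of_displacement(f)
  (1 + J$j11) * (1 + J$j22) - J$j12 * J$j21
}

#' Invert a displacement field
#'
#' Finds the field \eqn{g} with \eqn{s \approx \hat{s} + g(\hat{s})} for
#' the forward mapping \eqn{\hat{s} = s + f(s)}, by per-cell Newton
#' iteration on \eqn{s + f(s) - \hat{s} = 0} (plain fixed-point iteration
#' diverges where the warp compresses strongly). The forward map must be
#' injective, checked via \eqn{\det(I + J(f)) > 0} everywhere.
#'
#' @param f A \code{displacement_field}.
#' @param tol Max-norm convergence tolerance (stimulus units).
#' @param max_iter Maximum Newton iterations.
#' @return A \code{displacement_field} holding \eqn{g}; attribute
#'   \code{max_error} gives the final max-norm residual \eqn{|s + f(s) -
#'   \hat{s}|}, \code{converged} whether it fell below \code{tol}.
#' @export
invert_displacement <- function(f, tol = 1e-6, max_iter = 100L) {
  dets <- density_of_mapping(f)
  if (any(dets <= 0)) {
    bad <- which(dets <= 0, arr.ind = TRUE)
    stop(sprintf(
      "forward map is non-injective: det(I+J) <= 0 at %d cell(s), first [%d,%d]",
      nrow(bad), bad[1, 1], bad[1, 2]))
  }
  J <- jacobian_of_displacement(f)
  co <- grid_coordinates(f$grid)
  ext <- f$grid$extent
  s1 <- co$s1; s2 <- co$s2  # current estimate of the pre-image of (co)
  err <- Inf
  pre <- invert_at(f, as.vector(co$s1), as.vector(co$s2), J = J,
                   tol = tol, max_iter = max_iter)
  g <- structure(list(grid = f$grid,
                      fx = matrix(pre$s1 - co$s1, f$grid$resolution),
                      fy = matrix(pre$s2 - co$s2, f$grid$resolution)),
                 class = "displacement_field")
  attr(g, "forward") <- f
  attr(g, "max_error") <- pre$max_error
  attr(g, "converged") <- pre$max_error < tol
  g
}

#' Pre-images of arbitrary points under a forward warp
#'
#' Solves \eqn{s + f(s) = \hat{s}} for each query point by damped Newton
#' iteration (exact to \code{tol} at any point, unlike interpolating the
#' gridded inverse field).
#'
#' @param f A forward \code{displacement_field}.
#' @param s1hat,s2hat Sensory-space query coordinates.
#' @param J Optional precomputed Jacobian (internal reuse).
#' @param tol Max-norm tolerance on the residual.
#' @param max_iter Newton iteration cap.
#' @return List with pre-image coordinates \code{s1}, \code{s2} and the
#'   final \code{max_error}.
#' @export
invert_at <- function(f, s1hat, s2hat, J = NULL, tol = 1e-6,
                      max_iter = 100L) {
  if (is.null(J)) J <- jacobian_of_displacement(f)
  ext <- f$grid$extent
  t1 <- as.vector(s1hat); t2 <- as.vector(s2hat)
  s1 <- pmin(pmax(t1, -ext), ext)
  s2 <- pmin(pmax(t2, -ext), ext)
  resid <- function(s1, s2) {
    fv <- displacement_at(f, s1, s2)
    list(r1 = s1 + fv$fx - t1, r2 = s2 + fv$fy - t2)
  }
  r <- resid(s1, s2)
  err <- Inf
  for (it in seq_len(max_iter)) {
    rn <- sqrt(r$r1^2 + r$r2^2)
    err <- max(abs(r$r1), abs(r$r2))
    if (err < tol) break
    a11 <- 1 + grid_interp(f$grid, J$j11, s1, s2)
    a12 <- grid_interp(f$grid, J$j12, s1, s2)
    a21 <- grid_interp(f$grid, J$j21, s1, s2)
    a22 <- 1 + grid_interp(f$grid, J$j22, s1, s2)
    det <- pmax(a11 * a22 - a12 * a21, 1e-8)
    d1 <- (a22 * r$r1 - a12 * r$r2) / det
    d2 <- (-a21 * r$r1 + a11 * r$r2) / det
    # damped step: halve per point until the residual norm decreases
    step <- rep(1, length(det))
    n1 <- s1; n2 <- s2; rc <- r
    for (k in 1:8) {
      n1 <- pmin(pmax(s1 - step * d1, -ext), ext)
      n2 <- pmin(pmax(s2 - step * d2, -ext), ext)
      rc <- resid(n1, n2)
      worse <- sqrt(rc$r1^2 + rc$r2^2) > rn & step > 1e-3
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
    }
    s1 <- n1; s2 <- n2; r <- rc
  }
  list(s1 = s1, s2 = s2, max_error = err)
}
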