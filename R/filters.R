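# Discrete derivative operators used consistently by the potential solver
# and all diagnostics. Separable pairs: centered 3-tap derivative stencils
# combined with a [1 2 1]/4 smoothing prefilter along the orthogonal axis:
#   first derivative   [ -1  0  1 ] / (2h)
#   second derivative  [  1 -2  1 ] / h^2
#   prefilter          [  1  2  1 ] / 4
# All pairs are exact on quadratic polynomials (second-order accurate) and
# share the same parity coupling: every operator annihilates the
# checkerboard mode, which removes the spurious high-frequency residual
# modes that plague unfiltered centered discretizations of
# determinant-of-Hessian equations. Boundary rows/cols use replicate
# padding, which together with the solver's boundary-band tie (edge row ==
# adjacent row) makes the normal derivative exactly zero on the boundary.
# Convention: values[i, j] with i -> s1, j -> s2.

FILTER_HALF_WIDTH <- 1L

#' First partial derivative of a gridded field
#'
#' Centered second-order difference along axis 1 (\eqn{s_1}, rows) or
#' axis 2 (\eqn{s_2}, columns), with replicate padding at the boundary.
#'
#' @param m Matrix of values, indexed \code{[s1, s2]}.
#' @param h Grid spacing.
#' @param axis 1 or 2.
#' @return Matrix of the same size.
#' @export
deriv1 <- function(m, h, axis = 1) {
  n <- nrow(m); k <- ncol(m)
  if (axis == 1) {
    p <- rbind(m[1, , drop = FALSE], m, m[n, , drop = FALSE])
    (p[3:(n + 2), , drop = FALSE] - p[1:n, , drop = FALSE]) / (2 * h)
  } else {
    p <- cbind(m[, 1, drop = FALSE], m, m[, k, drop = FALSE])
    (p[, 3:(k + 2), drop = FALSE] - p[, 1:k, drop = FALSE]) / (2 * h)
  }
}

#' Second partial derivative of a gridded field
#'
#' @inheritParams deriv1
#' @return Matrix of the same size.
#' @export
deriv2 <- function(m, h, axis = 1) {
  n <- nrow(m); k <- ncol(m)
  if (axis == 1) {
    p <- rbind(m[1, , drop = FALSE], m, m[n, , drop = FALSE])
    (p[1:n, , drop = FALSE] - 2 * m + p[3:(n + 2), , drop = FALSE]) / h^2
  } else {
    p <- cbind(m[, 1, drop = FALSE], m, m[, k, drop = FALSE])
    (p[, 1:k, drop = FALSE] - 2 * m + p[, 3:(k + 2), drop = FALSE]) / h^2
  }
}

#' Smoothing prefilter of the separable derivative pairs
#'
#' The \code{[1 2 1]/4} binomial filter applied along one axis with
#' replicate padding; paired with \code{\link{deriv1}}/\code{\link{deriv2}}
#' on the orthogonal axis when building gradients, Jacobians and Hessians.
#'
#' @inheritParams deriv1
#' @return Matrix of the same size.
#' @export
smooth1 <- function(m, axis = 1) {
  n <- nrow(m); k <- ncol(m)
  if (axis == 1) {
    p <- rbind(m[1, , drop = FALSE], m, m[n, , drop = FALSE])
    (p[1:n, , drop = FALSE] + 2 * m + p[3:(n + 2), , drop = FALSE]) / 4
  } else {
    p <- cbind(m[, 1, drop = FALSE], m, m[, k, drop = FALSE])
    (p[, 1:k, drop = FALSE] + 2 * m + p[, 3:(k + 2), drop = FALSE]) / 4
  }
}

# Adjoint operators for weights supported on the interior (zero on the
# 1-cell border). With zero padding D2 and the prefilter are self-adjoint
# and D1 is anti-self-adjoint; these are only ever applied to
# interior-supported residual weights, for which replicate and zero
# padding coincide.
shift1 <- function(m, by, axis) {
  # shift with zero fill: result[i] = m[i - by] along `axis`
  n <- nrow(m); k <- ncol(m)
  out <- matrix(0, n, k)
  if (axis == 1) {
    if (by > 0) out[(1 + by):n, ] <- m[1:(n - by), , drop = FALSE]
    else if (by < 0) out[1:(n + by), ] <- m[(1 - by):n, , drop = FALSE]
    else out <- m
  } else {
    if (by > 0) out[, (1 + by):k] <- m[, 1:(k - by), drop = FALSE]
    else if (by < 0) out[, 1:(k + by)] <- m[, (1 - by):k, drop = FALSE]
    else out <- m
  }
  out
}

deriv1_adj <- function(w, h, axis = 1) {
  (shift1(w, 1, axis) - shift1(w, -1, axis)) / (2 * h)
}

deriv2_adj <- function(w, h, axis = 1) {
  (shift1(w, 1, axis) - 2 * w + shift1(w, -1, axis)) / h^2
}

smooth1_adj <- function(w, axis = 1) {
  (shift1(w, 1, axis) + 2 * w + shift1(w, -1, axis)) / 4
}
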