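test_that("discrete Hessian is exact on polynomial potentials", {
  g <- grid65()
  co <- grid_coordinates(g)
  n <- g$resolution
  inner <- abs(co$s1) < 0.9 & abs(co$s2) < 0.9
  # zero potential
  H0 <- hessian_of_potential(potential(g))
  expect_true(all(H0$v11 == 0 & H0$v12 == 0 & H0$v22 == 0))
  # quadratic bowl: H = a I (evaluate away from the tied boundary band)
  a <- 0.7
  vq <- potential(g, a * (co$s1^2 + co$s2^2) / 2)
  Hq <- hessian_of_potential(vq)
  expect_lt(max(abs(Hq$v11[inner] - a)), 1e-10)
  expect_lt(max(abs(Hq$v22[inner] - a)), 1e-10)
  expect_lt(max(abs(Hq$v12[inner])), 1e-10)
  # bilinear: pure cross term
  vb <- potential(g, co$s1 * co$s2)
  Hb <- hessian_of_potential(vb)
  expect_lt(max(abs(Hb$v12[inner] - 1)), 1e-10)
  expect_lt(max(abs(Hb$v11[inner])), 1e-10)
})

test_that("remap residual matches a direct determinant oracle", {
  g <- grid65()
  u <- uniform_grid(g)
  # identity mapping
  expect_true(all(remap_residual(potential(g), u, u) == 0))
  # quadratic potential: det(I + aI) = (1+a)^2 exactly at interior cells
  a <- 0.3
  co <- grid_coordinates(g)
  vq <- potential(g, a * (co$s1^2 + co$s2^2) / 2)
  H <- hessian_of_potential(vq)
  detq <- H$v11 * H$v22 - H$v12^2 + H$v11 + H$v22 + 1
  inner <- abs(co$s1) < 0.9 & abs(co$s2) < 0.9
  expect_lt(max(abs(detq[inner] - (1 + a)^2)), 1e-10)
  # random smooth potential vs per-cell 2x2 determinant oracle
  set.seed(3)
  v <- smooth_test_potential(amp = 0.08)
  H <- hessian_of_potential(v)
  det_oracle <- vapply(seq_along(H$v11), function(i) {
    det(diag(2) + matrix(c(H$v11[i], H$v12[i], H$v12[i], H$v22[i]), 2))
  }, numeric(1))
  r2 <- remap_residual(v, u, u)
  expect_lt(max(abs(r2 - (matrix(det_oracle, g$resolution) - 1))), 1e-12)
  # reference density with zeros is refused
  uz <- matrix(1, 65, 65); uz[1, 1] <- 0
  expect_error(remap_residual(v, u, probability_grid(g, uz)), "positive")
})

test_that("solver objective gradient matches finite differences", {
  set.seed(4)
  n <- 11; h <- 0.2
  v <- matrix(rnorm(n * n) * 0.01, n, n)
  vf <- v[2:(n - 1), 2:(n - 1)]
  ratio <- matrix(runif(n * n, 0.7, 1.3), n, n)
  inner <- effcode:::interior_mask(n)
  objf <- function(vf) effcode:::solver_objective(
    effcode:::expand_free(vf), ratio, h, inner)$value
  obj <- effcode:::solver_objective(effcode:::expand_free(vf), ratio, h, inner)
  g_an <- effcode:::collapse_grad(effcode:::solver_gradient(obj, h))
  eps <- 1e-6
  m <- n - 2
  idx <- cbind(sample(m, 25, replace = TRUE), sample(m, 25, replace = TRUE))
  for (k in seq_len(nrow(idx))) {
    e <- matrix(0, m, m); e[idx[k, 1], idx[k, 2]] <- eps
    fd <- (objf(vf + e) - objf(vf - e)) / (2 * eps)
    expect_lt(abs(fd - g_an[idx[k, 1], idx[k, 2]]) /
                max(abs(fd), 1e-8), 1e-5)
  }
})

test_that("solving p = u returns the zero transformation", {
  g <- grid65()
  v <- solve_potential(uniform_grid(g))
  f <- displacement_from_potential(v)
  expect_lt(sqrt(mean(f$fx^2 + f$fy^2)), 1e-3)
})

test_that("solved gaussian fixture has small residual and objective decreases monotonically", {
  v <- solved_gauss()
  expect_lt(attr(v, "rms_residual"), 1e-3)  # mean(p/u) = 1 on this domain
  for (tr in attr(v, "trace")) expect_true(all(diff(tr) <= 0))
})

test_that("displacement of polynomial potentials matches closed forms and is curl-free", {
  g <- grid65()
  co <- grid_coordinates(g)
  expect_true(all(displacement_from_potential(potential(g))$fx == 0))
  a <- 0.4
  vq <- potential(g, a * (co$s1^2 + co$s2^2) / 2)
  f <- displacement_from_potential(vq)
  inner <- abs(co$s1) < 0.9 & abs(co$s2) < 0.9
  expect_lt(max(abs(f$fx - a * co$s1)[inner]), 1e-10)
  expect_lt(max(abs(f$fy - a * co$s2)[inner]), 1e-10)
  # discrete curl of a gradient field stays at the filter-consistency level
  fs <- solved_gauss_f()
  h <- g$spacing
  curl <- deriv1(smooth1(fs$fy, 2), h, 1) - deriv1(smooth1(fs$fx, 1), h, 2)
  scale <- sqrt(mean(deriv1(smooth1(fs$fx, 2), h, 1)^2))
  expect_lt(sqrt(mean(curl[crop_mask(g)]^2)), 0.05 * max(scale, 1e-12))
})

test_that("density of the solved mapping is proportional to the stimulus density", {
  g <- grid65()
  expect_true(all(density_of_mapping(zero_displacement(g)) == 1))
  d <- density_of_mapping(solved_gauss_f())
  cm <- crop_mask(g)
  expect_gt(cor(d[cm], gauss_p()$values[cm]), 0.99)
})

test_that("mass is conserved by the solved mapping", {
  g <- grid65()
  d <- density_of_mapping(solved_gauss_f())
  # mean of det(I+J) * u over the interior region equals the mass of the
  # blended target there (both sides integrate p over the region)
  cfg <- solver_config()
  ratio <- target_ratio(gauss_p(), uniform_grid(g), cfg)
  co <- grid_coordinates(g)
  reg <- sqrt(co$s1^2 + co$s2^2) <= 0.9
  expect_equal(mean(d[reg]), mean(ratio[reg]), tolerance = 0.01)
})

test_that("solution transposes under axis relabeling and is radial for radial input", {
  g <- grid_spec(resolution = 33)
  p <- make_gaussian(g, sigma = c(0.2, 0.35))
  cfg <- solver_config(levels = 1)
  v1 <- solve_potential(p, cfg = cfg)
  v2 <- solve_potential(probability_grid(g, t(p$values)), cfg = cfg)
  expect_lt(max(abs(v2$values - t(v1$values))),
            1e-4 * max(abs(v1$values)))
  # radial p -> radial displacement field
  f <- solved_gauss_f()
  co <- grid_coordinates(grid65())
  rr <- pmax(sqrt(co$s1^2 + co$s2^2), 1e-9)
  er1 <- co$s1 / rr; er2 <- co$s2 / rr
  rad <- f$fx * er1 + f$fy * er2
  tang <- -f$fx * er2 + f$fy * er1
  cm <- crop_mask(grid65()) & rr > 0.05
  expect_lt(sqrt(mean(tang[cm]^2)), 0.05 * sqrt(mean(rad[cm]^2)))
})

test_that("displacement inversion recovers closed forms and round-trips", {
  g <- grid65()
  z <- zero_displacement(g)
  expect_true(all(invert_displacement(z)$fx == 0))
  # linear map f = a s: inverse is -(a/(1+a)) shat
  a <- 0.25
  co <- grid_coordinates(g)
  fl <- structure(list(grid = g, fx = a * co$s1, fy = a * co$s2),
                  class = "displacement_field")
  gi <- invert_displacement(fl)
  cm <- crop_mask(g)
  expect_lt(max(abs(gi$fx + (a / (1 + a)) * co$s1)[cm]), 1e-5)
  # round trip through the solved fixture (per-point Newton inversion)
  fs <- solved_gauss_f()
  gs <- invert_displacement(fs)
  expect_true(attr(gs, "converged"))
  pts <- expand.grid(s1 = seq(-0.6, 0.6, 0.2), s2 = seq(-0.6, 0.6, 0.2))
  fv <- displacement_at(fs, pts$s1, pts$s2)
  shat1 <- pts$s1 + fv$fx; shat2 <- pts$s2 + fv$fy
  pre <- invert_at(fs, shat1, shat2)
  expect_lt(max(abs(pre$s1 - pts$s1)), 1e-5)
  expect_lt(max(abs(pre$s2 - pts$s2)), 1e-5)
  # the gridded inverse agrees at its own cells to the same tolerance
  co65 <- grid_coordinates(grid65())
  fv2 <- displacement_at(fs, co65$s1 + gs$fx, co65$s2 + gs$fy)
  expect_lt(max(abs(co65$s1 + gs$fx + fv2$fx - co65$s1)), 1e-5)
  # non-injective map is refused
  bad <- structure(list(grid = g, fx = -1.5 * co$s1, fy = 0 * co$s2),
                   class = "displacement_field")
  expect_error(invert_displacement(bad), "non-injective")
})
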