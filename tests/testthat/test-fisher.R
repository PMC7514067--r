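test_that("1-D Fisher information matches the analytic single-curve form", {
  pop1 <- population_1d(centers = 0, sigma = 0.05, gain = 1)
  s <- seq(-0.3, 0.3, length.out = 4001)
  fi <- fisher_1d(pop1, s)
  sv <- attr(fi, "s")
  # F(s) = (s^2 / sigma^4) exp(-s^2 / 2 sigma^2) for a unit-gain curve
  analytic <- (sv^2 / 0.05^4) * exp(-sv^2 / (2 * 0.05^2))
  inb <- abs(sv) > 0.01  # away from the F = 0 point
  expect_lt(max(abs(fi[inb] - analytic[inb]) / analytic[inb]), 0.01)
  # frozen spot value at s = 0.05 (analytic 242.612)
  expect_equal(fi[which.min(abs(sv - 0.05))], 242.612, tolerance = 0.01)
  # doubling gain doubles F pointwise
  fi2 <- fisher_1d(population_1d(0, 0.05, gain = 2), s)
  expect_equal(as.vector(fi2), as.vector(2 * fi), tolerance = 1e-9)
  expect_error(fisher_1d(matrix(0, 0, 10), s), "empty")
})

test_that("uniform populations have flat Fisher information", {
  pop <- population_1d(seq(-1.5, 1.5, by = 0.05), sigma = 0.05)
  s <- seq(-1, 1, length.out = 2001)
  fi <- fisher_1d(pop, s)
  inb <- abs(attr(fi, "s")) <= 0.65
  expect_cov_lt(fi[inb], 0.10)
  g <- grid_spec(resolution = 161)
  popU <- population(make_lattice("hex", 0.1, g), sigma = 0.05, gain = 1)
  ff <- fisher_matrix(popU, g)
  cm <- crop_mask(g)
  expect_cov_lt(ff$det[cm], 0.15)
  expect_true(all(ff$det >= -1e-6 * max(ff$det)))
})

test_that("fisher matrix has the expected symmetries", {
  g <- grid_spec(resolution = 161)
  # single isotropic curve at the origin: diagonal, equal entries
  pop <- population(cbind(0, 0), sigma = 0.05, gain = 1)
  ff <- fisher_matrix(pop, g)
  expect_equal(ff$f11[41, 81], ff$f22[81, 41], tolerance = 1e-9)
  ctr <- which(abs(g$coords - 0.025) < 1e-9)
  mid <- which(abs(g$coords) < 1e-9)
  expect_lt(abs(ff$f12[ctr, mid]), 1e-8 * max(ff$f11))
  # axis swap of an anisotropic population transposes the matrix field
  popA <- population(cbind(0.2, -0.1), sigma = c(0.05, 0.08))
  popB <- population(cbind(-0.1, 0.2), sigma = c(0.08, 0.05))
  fa <- fisher_matrix(popA, g)
  fb <- fisher_matrix(popB, g)
  expect_equal(fa$f11, t(fb$f22), tolerance = 1e-9)
  expect_equal(fa$f12, t(fb$f12), tolerance = 1e-9)
  # effectively-1-D population: F11 equals the 1-D Fisher information
  c1 <- seq(-1.6, 1.6, by = 0.05)
  pop2 <- population(cbind(c1, 0), sigma = c(0.05, 1e3))
  f2 <- fisher_matrix(pop2, g)
  f1 <- fisher_1d(population_1d(c1, 0.05), g$coords)
  expect_equal(f2$f11[2:(g$resolution - 1), mid], as.vector(f1),
               tolerance = 1e-9)
})

test_that("smooth-warp approximation tracks exact Fisher and fails for rapid gain", {
  centers <- seq(-1.6, 1.6, by = 0.05)
  s <- seq(-1, 1, length.out = 2001)
  U <- estimate_U(population_1d(centers, 0.05), s_values = s)
  warp <- function(x) -0.3 * sin(pi * x / 2)
  warp_d <- function(x) -0.3 * (pi / 2) * cos(pi * x / 2)
  gain_slow <- function(x) 1 + 0.5 * sin(pi * x / 2)
  pop <- population_1d(centers, 0.05, warp_fn = warp, gain_fn = gain_slow)
  fe <- fisher_1d(pop, s)
  sv <- attr(fe, "s")
  inb <- abs(sv) <= 0.65
  fa <- approx_fisher_1d(1 + warp_d(sv), gain_slow(sv), U)
  expect_lt(sqrt(mean((fe[inb] - fa[inb])^2)) / mean(fe[inb]), 0.15)
  # rapidly varying gain (wavelength ~ 3 tuning widths): approximation breaks
  gain_fast <- function(x) 1 + 0.9 * sin(40 * x)
  popf <- population_1d(centers, 0.05, warp_fn = warp, gain_fn = gain_fast)
  fef <- fisher_1d(popf, s)
  faf <- approx_fisher_1d(1 + warp_d(sv), gain_fast(sv), U)
  expect_gt(sqrt(mean((fef[inb] - faf[inb])^2)) / mean(fef[inb]), 0.50)
  # 2-D approx form: zero warp, unit gain -> the constant U
  fzero <- zero_displacement(grid65())
  expect_true(all(approx_fisher(fzero, 1, U) == U))
})

test_that("probability is recovered from the Fisher determinant", {
  g <- grid_spec(resolution = 161)
  cm <- crop_mask(g)
  popU <- population(make_lattice("hex", 0.1, g), sigma = 0.05, gain = 1)
  ffU <- fisher_matrix(popU, g)
  phU <- recover_probability(ffU)
  expect_cov_lt(phU$values[cm], 0.10)
  # warped population: recovered density matches the stimulus density
  f <- solved_gauss_f()
  popW <- population(make_lattice("hex", 0.1, g), sigma = 0.05, gain = 1,
                     displacement = f)
  ffW <- fisher_matrix(popW, g)
  ph <- recover_probability(ffW)
  co <- grid_coordinates(g)
  pv <- grid_interp(grid65(), gauss_p()$values, co$s1, co$s2)
  expect_gt(cor(ph$values[cm], pv[cm]), 0.95)
  # gain scaling cancels in the normalized recovery
  popW2 <- popW; popW2$gain <- 7
  ph2 <- recover_probability(fisher_matrix(popW2, g))
  expect_equal(ph2$values, ph$values, tolerance = 1e-9)
})

test_that("MI lower bound scales with the counting window and favors the warped population", {
  g <- grid_spec(resolution = 161)
  p161 <- resample_probability_161(gauss_p(), g)
  popU <- population(make_lattice("hex", 0.1, g), sigma = 0.05, gain = 1)
  ff <- fisher_matrix(popU, g)
  b1 <- mi_lower_bound(popU, p161, fisher = ff)
  # doubling all rates doubles F, adding (k/2) log 2 = log 2 to the bound
  ff2 <- ff; ff2$f11 <- 2 * ff$f11; ff2$f12 <- 2 * ff$f12
  ff2$f22 <- 2 * ff$f22; ff2$det <- 4 * ff$det
  b2 <- mi_lower_bound(popU, p161, fisher = ff2)
  expect_equal(b2 - b1, log(2), tolerance = 1e-12)
  # fixed-budget comparison: warped bound >= uniform bound under p
  f <- solved_gauss_f()
  popW <- population(make_lattice("hex", 0.1, g), sigma = 0.05, gain = 1,
                     displacement = f)
  popUb <- set_rate_budget(popU, p161, 100)
  popWb <- set_rate_budget(popW, p161, 100)
  expect_gte(mi_lower_bound(popWb, p161), mi_lower_bound(popUb, p161))
})
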