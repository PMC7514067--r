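test_that("lattices have the right geometry and counts", {
  g <- grid65()
  # rect, spacing 0.5, margin 1: points at 0, +-0.5, ..., +-1.5 -> 7 per axis
  ctr <- make_lattice("rect", 0.5, g)
  expect_equal(nrow(ctr), 49)
  d <- as.matrix(dist(ctr))
  diag(d) <- Inf
  expect_equal(min(d), 0.5)
  # hex: nearest-neighbor distance = spacing for every center
  hc <- make_lattice("hex", 0.2, g)
  dh <- as.matrix(dist(hc))
  diag(dh) <- Inf
  nn <- apply(dh, 1, min)
  expect_equal(max(abs(nn - 0.2)), 0, tolerance = 1e-9)
  # closed-form count oracle: rows at pitch sqrt(3)/2 * s, cols at s
  s <- 0.2; lim <- 1 + s
  n_rows <- 2 * ceiling(lim / (s * sqrt(3) / 2)) + 1
  n_cols <- 2 * ceiling(lim / s) + 1
  expect_equal(nrow(hc), n_rows * n_cols)
  expect_error(make_lattice("hex", 5, g), "exceeds")
})

test_that("population evaluation matches closed forms", {
  g <- grid65()
  ctr <- make_lattice("rect", 0.5, g)
  pop <- population(ctr, sigma = 0.1, gain = 3)
  # unwarped response at a center equals the gain
  r <- evaluate_population(pop, ctr[5, 1], ctr[5, 2])
  expect_equal(r[5, 1], 3)
  expect_true(all(r >= 0))
  # anisotropic widths
  pa <- population(cbind(0, 0), sigma = c(0.1, 0.4))
  expect_equal(as.vector(evaluate_population(pa, 0.1, 0)),
               exp(-0.5), tolerance = 1e-12)
  expect_equal(as.vector(evaluate_population(pa, 0, 0.4)),
               exp(-0.5), tolerance = 1e-12)
})

test_that("uniform population tiles the crop and budget scaling hits R", {
  g <- grid65()
  co <- grid_coordinates(g)
  cm <- crop_mask(g)
  pop <- population(make_lattice("hex", 0.1, g), sigma = 0.05, gain = 1)
  tot <- matrix(population_sum(pop, co$s1, co$s2), g$resolution)
  expect_cov_lt(tot[cm], 0.05)
  # budget: expected population rate under p equals R within 2%
  p <- gauss_p()
  popb <- set_rate_budget(pop, p, 50)
  tot2 <- matrix(population_sum(popb, co$s1, co$s2), g$resolution)
  expect_equal(grid_integral(g, tot2 * p$values), 50, tolerance = 0.02)
})

test_that("warped population retains tiling and tracks stimulus density", {
  g <- grid65()
  co <- grid_coordinates(g)
  cm <- crop_mask(g)
  f <- solved_gauss_f()
  pop <- population(make_lattice("hex", 0.1, g), sigma = 0.05, gain = 1,
                    displacement = f)
  tot <- matrix(population_sum(pop, co$s1, co$s2), g$resolution)
  expect_cov_lt(tot[cm], 0.10)
  # local density of warped centers correlates with p (kernel density
  # of the mapped centers, isotropic Gaussian kernel, bandwidth 0.1)
  gi <- invert_displacement(f)
  wc <- warp_centers(pop$centers, gi)
  keep <- wc$inside
  kde_pop <- population(cbind(wc$s1[keep], wc$s2[keep]), sigma = 0.1)
  kde <- matrix(population_sum(kde_pop, co$s1, co$s2), g$resolution)
  expect_gt(cor(kde[cm], gauss_p()$values[cm]), 0.95)
})

test_that("warp_centers inverts the mapping and returns local maxima", {
  g <- grid65()
  ctr <- make_lattice("hex", 0.2, g)
  # no warp: peaks are the centers (for centers inside the domain; the
  # lattice margin beyond the boundary is flagged, not inverted)
  z <- zero_displacement(g)
  wc0 <- warp_centers(ctr, invert_displacement(z))
  in0 <- abs(ctr[, 1]) <= 1 & abs(ctr[, 2]) <= 1
  expect_equal(wc0$s1[in0], ctr[in0, 1], tolerance = 1e-12)
  # linear warp f = a s: peaks at centers / (1 + a)
  a <- 0.25
  co <- grid_coordinates(g)
  fl <- structure(list(grid = g, fx = a * co$s1, fy = a * co$s2),
                  class = "displacement_field")
  wcl <- warp_centers(ctr, invert_displacement(fl))
  inb <- abs(ctr[, 1]) < 0.8 & abs(ctr[, 2]) < 0.8
  expect_equal(wcl$s1[inb], ctr[inb, 1] / (1 + a), tolerance = 1e-4)
  # solved warp: each peak is a local maximum of its tuning curve
  f <- solved_gauss_f()
  pop <- population(ctr, sigma = 0.05, gain = 1, displacement = f)
  wc <- warp_centers(ctr, invert_displacement(f))
  sel <- which(wc$inside & abs(wc$s1) < 0.6 & abs(wc$s2) < 0.6)
  h <- g$spacing
  for (i in sel[seq(1, length(sel), length.out = 12)]) {
    ctr_resp <- evaluate_population(pop, wc$s1[i], wc$s2[i])[i, 1]
    probe <- evaluate_population(pop, wc$s1[i] + c(h, -h, 0, 0),
                                 wc$s2[i] + c(0, 0, h, -h))[i, ]
    expect_true(all(ctr_resp >= probe - 1e-9))
  }
})

test_that("poisson sampling has the right moments", {
  g <- grid65()
  pop <- population(cbind(c(0, 0.9), c(0, 0.9)), sigma = 0.1, gain = 8)
  rates <- as.vector(evaluate_population(pop, 0, 0))
  set.seed(99)
  counts <- replicate(1e4, sample_responses(pop, c(0, 0))$counts)
  # neuron 2 is ~13 sigma away: rate is numerically zero
  expect_lt(rates[2], 1e-30)
  expect_true(all(counts[2, ] == 0))
  emp_mean <- mean(counts[1, ]); emp_var <- var(counts[1, ])
  expect_lt(abs(emp_mean - rates[1]), 3 * sqrt(rates[1] / 1e4))
  expect_gt(emp_var / emp_mean, 0.95)
  expect_lt(emp_var / emp_mean, 1.05)
  # determinism given a seed
  expect_identical(sample_responses(pop, c(0.1, 0), rng_seed = 5),
                   sample_responses(pop, c(0.1, 0), rng_seed = 5))
})
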