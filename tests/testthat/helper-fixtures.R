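# Shared fixtures. Solved potentials are cached per session because the
# solver is the expensive step; everything is generated in code.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

grid65 <- function() cached("grid65", grid_spec(extent = 1, resolution = 65))

gauss_p <- function() cached("gauss_p", make_gaussian(grid65(), sigma = 0.25))

solved_gauss <- function() cached(
  "solved_gauss",
  solve_potential(gauss_p(), cfg = solver_config())
)

solved_gauss_f <- function() cached(
  "solved_gauss_f",
  displacement_from_potential(solved_gauss())
)

# distribution uniform over s2, Gaussian (sigma 0.25) over s1
uniform_s2_p <- function() cached(
  "uniform_s2_p",
  fixture_density("uniform_s2", grid65())
)

solved_uniform_s2 <- function() cached(
  "solved_uniform_s2",
  solve_potential(uniform_s2_p(),
                  cfg = solver_config(interior = "square"))
)

# smooth tied potential for operator-level tests
smooth_test_potential <- function(grid = grid65(), amp = 0.05, width = 0.3) {
  co <- grid_coordinates(grid)
  potential(grid, amp * exp(-(co$s1^2 + co$s2^2) / (2 * width^2)))
}

trapz_oracle <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

# endpoint-inclusive quantile oracle (criterion 4)
optimal_mapping_1d_quantiles <- function(s, p, n) {
  cdf <- c(0, cumsum(diff(s) * (p[-1] + p[-length(p)]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  stats::approx(cdf, s, xout = seq(0, 1, length.out = n),
                ties = "ordered")$y
}

resample_probability_161 <- function(p, grid) {
  effcode:::resample_probability(p, grid)
}

expect_cov_lt <- function(x, limit) {
  expect_lt(stats::sd(x) / mean(x), limit)
}
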