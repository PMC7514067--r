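# Slice measurements: 1-D experiments through 2-D populations. A slice
# holds one stimulus dimension constant and measures each neuron's 1-D
# tuning curve over the other, summarized by gain (maximum response) and
# sharpness (inverse full width at half maximum), then related to the
# joint stimulus probability at the neuron's peak.

#' 1-D slice through a 2-D population
#'
#' Evaluates every neuron's response along a line where one stimulus
#' variable is held constant, on a fine uniform grid spanning the
#' analysis crop. Neurons whose maximum normalized response (relative to
#' the population's constant peak rate) within the slice is below
#' \code{min_response} are excluded.
#'
#' @param pop A \code{population} with constant gain.
#' @param axis Which variable is held constant: 1 (slice varies
#'   \eqn{s_2}) or 2 (slice varies \eqn{s_1}).
#' @param value Value of the held variable; must lie inside the crop.
#' @param n_points Number of evaluation points (default 2001).
#' @param crop_fraction Crop defining the slice extent.
#' @param min_response Exclusion threshold on normalized response.
#' @return List of class \code{slice}: \code{s} (free-axis values),
#'   \code{responses} (retained neurons x points), \code{neuron}
#'   (retained neuron indices), \code{axis}, \code{value}.
#' @export
take_slice <- function(pop, axis, value, n_points = 2001,
                       crop_fraction = 0.65, min_response = 0.2) {
  stopifnot(inherits(pop, "population"), axis %in% c(1, 2))
  ext <- if (!is.null(pop$displacement)) pop$displacement$grid$extent else 1
  lim <- crop_fraction * ext
  if (abs(value) > lim) stop("slice value outside the analysis crop")
  s <- seq(-lim, lim, length.out = n_points)
  resp <- if (axis == 1)
    evaluate_population(pop, rep(value, n_points), s)
  else
    evaluate_population(pop, s, rep(value, n_points))
  peak <- pop$gain  # constant-gain population: common 2-D peak rate
  keep <- apply(resp, 1, max) >= min_response * peak
  structure(list(s = s, responses = resp[keep, , drop = FALSE],
                 neuron = which(keep), axis = axis, value = value),
            class = "slice")
}

#' Gain, width and sharpness of a 1-D tuning curve
#'
#' Gain is the maximum response; the full width at half maximum is found
#' by linear interpolation of the two half-maximum crossings nearest the
#' peak; sharpness is 1/FWHM. Curves whose maximum sits at the end of the
#' sampled range, or that lack a half-maximum crossing on either side,
#' are flagged as unmeasurable (\code{NA} width).
#'
#' @param s Sample points (increasing).
#' @param y Response values at \code{s}.
#' @return Named vector: \code{gain}, \code{fwhm}, \code{sharpness},
#'   \code{peak} (stimulus value of the maximum). \code{fwhm} and
#'   \code{sharpness} are \code{NA} for unmeasurable curves.
#' @export
measure_curve <- function(s, y) {
  i <- which.max(y)
  g <- y[i]
  out <- c(gain = g, fwhm = NA_real_, sharpness = NA_real_, peak = s[i])
  if (i == 1 || i == length(y) || g <= 0) return(out)
  half <- g / 2
  cross <- function(idx_range) {
    # crossing of `half` nearest the peak, linearly interpolated
    yy <- y[idx_range]; ss <- s[idx_range]
    below <- which(yy < half)
    if (length(below) == 0) return(NA_real_)
    j <- max(below)
    if (j == length(yy)) return(NA_real_)
    ss[j] + (half - yy[j]) / (yy[j + 1] - yy[j]) * (ss[j + 1] - ss[j])
  }
  left <- cross(1:i)
  right_rev <- cross(length(y):i)  # reversed: walks from the right end in
  if (is.na(left) || is.na(right_rev)) return(out)
  fwhm <- right_rev - left
  if (fwhm <= 0) return(out)
  out["fwhm"] <- fwhm
  out["sharpness"] <- 1 / fwhm
  out
}

#' Measure all retained neurons in a slice
#'
#' Applies \code{\link{measure_curve}} to each retained neuron and looks
#' up the joint stimulus probability at the neuron's 2-D peak within the
#' slice (free-axis argmax, held axis at the slice value).
#'
#' @param sl A \code{slice}.
#' @param p A \code{probability_grid} (for the probability lookup).
#' @return Data frame: \code{neuron}, \code{gain}, \code{fwhm},
#'   \code{sharpness}, \code{peak}, \code{prob} (rows with \code{NA}
#'   width are dropped).
#' @export
measure_slice <- function(sl, p) {
  stopifnot(inherits(sl, "slice"))
  if (nrow(sl$responses) == 0)
    return(data.frame(neuron = integer(), gain = numeric(),
                      fwhm = numeric(), sharpness = numeric(),
                      peak = numeric(), prob = numeric()))
  m <- t(apply(sl$responses, 1, function(y) measure_curve(sl$s, y)))
  s1 <- if (sl$axis == 1) rep(sl$value, nrow(m)) else m[, "peak"]
  s2 <- if (sl$axis == 1) m[, "peak"] else rep(sl$value, nrow(m))
  out <- data.frame(neuron = sl$neuron, gain = m[, "gain"],
                    fwhm = m[, "fwhm"], sharpness = m[, "sharpness"],
                    peak = m[, "peak"],
                    prob = grid_interp(p$grid, p$values, s1, s2))
  out[!is.na(out$fwhm), , drop = FALSE]
}

#' Randomized slice-measurement experiment
#'
#' Repeats the simulated 1-D experiment: draw a random zero-centered
#' bivariate Gaussian stimulus distribution (orientation uniform on
#' \eqn{[0,\pi)}, major/minor sigma uniform on 0.1-0.4), solve for its
#' optimal encoding potential, warp an isotropic-Gaussian population
#' (tuning sigma uniform on 0.03-0.07, hexagonal lattice with spacing
#' two tuning sigmas so the population tiles the space), take one random
#' 1-D slice within the crop, sample
#' up to \code{n_neurons_per_slice} retained neurons, and correlate each
#' neuron's tuning sharpness and gain with the joint stimulus probability
#' at its peak. Median correlations across replicates are tested against
#' zero with a two-sided Wilcoxon signed-rank test.
#'
#' @param n_reps Number of replicates (at least 10; 500 matches the full
#'   published experiment, 100 the desk-scale version).
#' @param n_neurons_per_slice Neurons sampled per slice (default 25).
#' @param rng_seed Integer seed; results are deterministic given the
#'   seed.
#' @param solver_cfg A \code{solver_config} (default: 65^2 target
#'   resolution settings).
#' @param resolution Solver grid resolution per replicate.
#' @param n_points Slice evaluation points.
#' @param progress Print a dot every 10 replicates.
#' @return List of class \code{experiment_result}: data frame
#'   \code{replicates} (distribution parameters, tuning sigma, slice
#'   axis/value, neuron count, both correlations), \code{median_sharpness_cor},
#'   \code{median_gain_cor}, \code{wilcoxon_sharpness} and
#'   \code{wilcoxon_gain} (statistic + p-value), and a config echo.
#' @export
run_randomized_experiment <- function(n_reps = 100, n_neurons_per_slice = 25,
                                      rng_seed = 1,
                                      solver_cfg = solver_config(),
                                      resolution = 65, n_points = 2001,
                                      progress = FALSE) {
  stopifnot(n_reps >= 10)
  set.seed(as.integer(rng_seed))
  grid <- grid_spec(extent = 1, resolution = resolution)
  crop <- solver_cfg$crop_fraction
  rows <- vector("list", n_reps)
  for (rep_i in seq_len(n_reps)) {
    par <- sample_random_gaussian_params()
    sigma_t <- stats::runif(1, 0.03, 0.07)
    axis <- sample(1:2, 1)
    value <- stats::runif(1, -crop, crop)
    p <- make_gaussian(grid, sigma = params_covariance(par))
    v <- solve_potential(p, cfg = solver_cfg)
    f <- displacement_from_potential(v)
    pop <- population(make_lattice("hex", spacing = 2 * sigma_t, domain = grid),
                      sigma = sigma_t, gain = 1, displacement = f)
    meas <- NULL
    for (try_i in 1:10) {
      sl <- take_slice(pop, axis, value, n_points = n_points,
                       crop_fraction = crop)
      meas <- measure_slice(sl, p)
      if (nrow(meas) >= 3) break
      axis <- sample(1:2, 1)          # resample the slice (logged in row)
      value <- stats::runif(1, -crop, crop)
    }
    if (nrow(meas) > n_neurons_per_slice)
      meas <- meas[sample(nrow(meas), n_neurons_per_slice), , drop = FALSE]
    rows[[rep_i]] <- data.frame(
      rep = rep_i, orientation = par$orientation,
      sigma_major = par$sigma_major, sigma_minor = par$sigma_minor,
      sigma_tuning = sigma_t, axis = axis, value = value,
      n_neurons = nrow(meas),
      solver_converged = isTRUE(attr(v, "converged")),
      sharpness_cor = safe_cor(meas$sharpness, meas$prob),
      gain_cor = safe_cor(meas$gain, meas$prob)
    )
    if (progress && rep_i %% 10 == 0) cat(".")
  }
  if (progress) cat("\n")
  reps <- do.call(rbind, rows)
  structure(list(
    replicates = reps,
    median_sharpness_cor = stats::median(reps$sharpness_cor, na.rm = TRUE),
    median_gain_cor = stats::median(reps$gain_cor, na.rm = TRUE),
    wilcoxon_sharpness = wilcoxon_vs_zero(reps$sharpness_cor),
    wilcoxon_gain = wilcoxon_vs_zero(reps$gain_cor),
    config = list(n_reps = n_reps, n_neurons_per_slice = n_neurons_per_slice,
                  rng_seed = rng_seed, resolution = resolution,
                  n_points = n_points, sigma_range = c(0.1, 0.4),
                  tuning_sigma_range = c(0.03, 0.07))
  ), class = "experiment_result")
}

safe_cor <- function(x, y) {
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(NA_real_)
  stats::cor(x, y)
}

wilcoxon_vs_zero <- function(x) {
  x <- x[!is.na(x)]
  wt <- stats::wilcox.test(x, mu = 0, alternative = "two.sided", exact = FALSE)
  c(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf(
    "<experiment_result> %d replicates\n  median sharpness-probability r = %.3f (signed-rank p = %.2e)\n  median gain-probability r      = %.3f (signed-rank p = %.2e)\n",
    nrow(x$replicates), x$median_sharpness_cor,
    x$wilcoxon_sharpness["p_value"], x$median_gain_cor,
    x$wilcoxon_gain["p_value"]))
  invisible(x)
}
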