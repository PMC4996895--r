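#' Configuration of the tabular noise simulation
#'
#' Describes a controlled regression problem used to study tail bias:
#' `n_predictors` standard-normal predictors with constant pairwise
#' correlation, a linear response `Y = slope * mean(X) + intercept` perturbed
#' by Gaussian noise, and additive Gaussian measurement noise on the
#' predictors. Two predictor-noise scenarios are of particular interest:
#' moderate noise (fraction 0.2 of the unit predictor SD) and severe noise
#' (0.8), the latter emulating satellite signals that have largely lost
#' sensitivity to the response.
#'
#' @param n_samples Number of rows.
#' @param n_predictors Number of predictors (default 5).
#' @param pairwise_correlation Common correlation between predictors, in
#'   `[0, 1)` (default 0.2).
#' @param signal_slope,signal_intercept Linear signal coefficients
#'   (defaults 10 and 20).
#' @param y_noise_fraction SD of the response noise as a fraction of the SD of
#'   the noiseless signal (default 0.10).
#' @param x_noise_fraction SD of the predictor noise as a fraction of the unit
#'   predictor SD (scenarios of interest: 0.2 and 0.8).
#' @param seed Integer seed.
#' @return An object of class `mch_sim_config`.
#' @export
sim_config <- function(n_samples = 10000, n_predictors = 5,
                       pairwise_correlation = 0.2,
                       signal_slope = 10, signal_intercept = 20,
                       y_noise_fraction = 0.10, x_noise_fraction = 0.2,
                       seed = 1L) {
  if (n_samples < 1 || n_predictors < 1)
    stop("configuration error: sizes must be positive", call. = FALSE)
  if (pairwise_correlation < 0 || pairwise_correlation >= 1)
    stop("configuration error: pairwise_correlation must be in [0, 1)", call. = FALSE)
  # equicorrelation matrix is positive definite iff rho > -1/(p-1); with
  # rho >= 0 that always holds
  if (y_noise_fraction < 0 || x_noise_fraction < 0)
    stop("configuration error: noise fractions must be >= 0", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 n_predictors = as.integer(n_predictors),
                 pairwise_correlation = pairwise_correlation,
                 signal_slope = signal_slope,
                 signal_intercept = signal_intercept,
                 y_noise_fraction = y_noise_fraction,
                 x_noise_fraction = x_noise_fraction,
                 seed = as.integer(seed)),
            class = "mch_sim_config")
}

#' Theoretical SD of the noiseless simulated signal
#'
#' `Var(slope * mean(X)) = slope^2 (1 + (p-1) rho) / p` for equicorrelated
#' unit-variance predictors; with the defaults (slope 10, p = 5, rho = 0.2)
#' this is 36, i.e. SD 6.
#'
#' @param config An [sim_config()].
#' @return The signal standard deviation.
#' @export
sim_signal_sd <- function(config) {
  p <- config$n_predictors
  rho <- config$pairwise_correlation
  abs(config$signal_slope) * sqrt((1 + (p - 1) * rho) / p)
}

#' Generate the tabular simulation data
#'
#' Steps: (1) draw clean predictors from a zero-mean multivariate normal with
#' unit variances and constant pairwise correlation; (2) compute
#' `Y = slope * mean(X) + intercept + e`, `e ~ N(0, (y_noise_fraction * signal SD)^2)`;
#' (3) add independent `N(0, x_noise_fraction^2)` noise to the predictors. The
#' returned table carries the noisy predictors (what a model sees); the clean
#' predictors and the noiseless signal are attached for diagnostics.
#'
#' @param config An [sim_config()].
#' @return A `data.frame` with columns `response`, `X1..Xp`; attributes
#'   `"predictors"`, `"x_clean"` (matrix), `"y_signal"` (noiseless signal
#'   vector), and `"config"`.
#' @export
generate_simulation <- function(config = sim_config()) {
  stopifnot(inherits(config, "mch_sim_config"))
  set.seed(config$seed)
  n <- config$n_samples; p <- config$n_predictors
  rho <- config$pairwise_correlation
  sigma <- matrix(rho, p, p); diag(sigma) <- 1
  r <- chol(sigma)
  x_clean <- matrix(stats::rnorm(n * p), n, p) %*% r
  y_signal <- config$signal_slope * rowMeans(x_clean) + config$signal_intercept
  sd_sig <- sim_signal_sd(config)
  y <- y_signal + stats::rnorm(n, 0, config$y_noise_fraction * sd_sig)
  x <- x_clean + matrix(stats::rnorm(n * p, 0, config$x_noise_fraction), n, p)
  nm <- paste0("X", seq_len(p))
  colnames(x) <- colnames(x_clean) <- nm
  out <- data.frame(response = y, x)
  attr(out, "predictors") <- nm
  attr(out, "x_clean") <- x_clean
  attr(out, "y_signal") <- y_signal
  attr(out, "config") <- config
  out
}

#' Configuration of a synthetic landscape
#'
#' Describes a spatially autocorrelated canopy-height field plus a stack of
#' pseudo-satellite bands. Each band is a saturating monotone transform of MCH,
#' `gain * (1 - exp(-MCH / saturation))`, plus independent Gaussian noise —
#' emulating optical and radar signals that progressively lose sensitivity in
#' tall, dense forest. Defaults emulate a ~33,000-pixel scene of 100 m pixels
#' with MCH spanning 0-45 m: four optical bands (early saturation), two L-band
#' backscatter bands (deeper penetration, later saturation), and one
#' near-linear elevation-proxy band.
#'
#' @param nrow,ncol Grid dimensions (default 182 x 182).
#' @param mch_range Range (min, max) of the height field in metres.
#' @param autocorrelation_length Gaussian smoothing SD in pixels (>= 1).
#' @param nugget_fraction Fraction of the field variance that is spatially
#'   uncorrelated fine-scale structure (default 0.25), giving the
#'   semi-variogram the non-zero intercept seen in real canopy-height maps.
#' @param band_specs `data.frame` with columns `name`, `role` (L/A/S),
#'   `saturation` (metres), `noise_sd` (band units; bands have unit gain).
#' @param seed Integer seed.
#' @param pixel_size Pixel side in metres (default 100).
#' @return An object of class `mch_landscape_config`.
#' @export
landscape_config <- function(nrow = 182, ncol = 182, mch_range = c(0, 45),
                             autocorrelation_length = 6,
                             nugget_fraction = 0.25,
                             band_specs = default_band_specs(),
                             seed = 1L, pixel_size = 100) {
  if (nugget_fraction < 0 || nugget_fraction >= 1)
    stop("configuration error: nugget_fraction must be in [0, 1)", call. = FALSE)
  if (mch_range[2] <= mch_range[1] || mch_range[1] < 0)
    stop("configuration error: need max > min >= 0 in mch_range", call. = FALSE)
  if (autocorrelation_length < 1)
    stop("configuration error: autocorrelation_length must be >= 1", call. = FALSE)
  if (min(nrow, ncol) < 4 * autocorrelation_length)
    stop("configuration error: grid too small for the requested autocorrelation length",
         call. = FALSE)
  need <- c("name", "role", "saturation", "noise_sd")
  if (!all(need %in% names(band_specs)))
    stop("band_specs must have columns name, role, saturation, noise_sd", call. = FALSE)
  if (!all(c("L", "A", "S") %in% band_specs$role))
    stop("configuration error: need at least one band per role L, A, S", call. = FALSE)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 mch_range = as.numeric(mch_range),
                 autocorrelation_length = autocorrelation_length,
                 nugget_fraction = nugget_fraction,
                 band_specs = band_specs, seed = as.integer(seed),
                 pixel_size = pixel_size),
            class = "mch_landscape_config")
}

#' Default pseudo-satellite band specification
#'
#' @return A `data.frame` usable as `band_specs` in [landscape_config()].
#' @export
default_band_specs <- function() {
  data.frame(
    name = c("L1", "L2", "L3", "L4", "A_HH", "A_HV", "S_elev"),
    role = c("L", "L", "L", "L", "A", "A", "S"),
    saturation = c(14, 16, 18, 20, 32, 28, 60),
    noise_sd = c(0.20, 0.20, 0.20, 0.20, 0.15, 0.15, 0.10)
  )
}

#' Generate a synthetic landscape: MCH raster + predictor stack
#'
#' The height field is a Gaussian random field (white noise smoothed with a
#' Gaussian kernel of SD `autocorrelation_length`) rescaled linearly to
#' `mch_range`, so its empirical semi-variogram rises with lag and plateaus at
#' a sill. Bands are saturating transforms of MCH plus independent pixel noise
#' (see [landscape_config()]).
#'
#' @param config An [landscape_config()].
#' @return A list with elements `mch` (an `mch_raster`) and `stack`
#'   (an `mch_stack`), plus the `config`.
#' @export
generate_landscape <- function(config = landscape_config()) {
  stopifnot(inherits(config, "mch_landscape_config"))
  set.seed(config$seed)
  acl <- config$autocorrelation_length
  z <- matrix(stats::rnorm(config$nrow * config$ncol), config$nrow, config$ncol)
  win <- 2L * as.integer(ceiling(3 * acl)) + 1L
  k <- gaussian_kernel_1d(win, acl)
  num <- conv2d_sep(z, k)
  den <- conv2d_sep(matrix(1, config$nrow, config$ncol), k)
  f <- num / den                      # edge-renormalized smooth field
  f <- (f - mean(f)) / stats::sd(f)
  if (config$nugget_fraction > 0) {
    nug <- matrix(stats::rnorm(length(f)), nrow(f), ncol(f))
    f <- sqrt(1 - config$nugget_fraction) * f +
      sqrt(config$nugget_fraction) * nug
  }
  lo <- config$mch_range[1]; hi <- config$mch_range[2]
  mch_vals <- (f - min(f)) / (max(f) - min(f)) * (hi - lo) + lo
  mch <- raster_grid(mch_vals, pixel_size = config$pixel_size)
  bs <- config$band_specs
  bands <- vector("list", nrow(bs))
  for (i in seq_len(nrow(bs))) {
    signal <- 1 - exp(-mch_vals / bs$saturation[i])
    noise <- if (bs$noise_sd[i] > 0)
      matrix(stats::rnorm(length(signal), 0, bs$noise_sd[i]),
             nrow(signal), ncol(signal))
    else 0
    bands[[i]] <- signal + noise
  }
  names(bands) <- bs$name
  stack <- layer_stack(bands, roles = bs$role,
                       pixel_size = config$pixel_size)
  list(mch = mch, stack = stack, config = config)
}
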