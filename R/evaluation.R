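#' Accuracy and tail-bias metrics
#'
#' Computes RMSE, R-squared (`1 - SS_res / SS_tot`), the mean signed deviation
#' `MSD = mean(predicted - measured)`, and the two tail diagnostics: `MSD1`
#' over pairs whose `predicted + measured` sum is strictly below `small_sum`
#' (small trees; positive values mean overestimation) and `MSD2` over pairs
#' whose sum is strictly above `large_sum` (large trees; negative values mean
#' the underestimation typical of saturating predictors). A tail metric whose
#' subset is empty is `NA` (undefined), never zero.
#'
#' @param predicted,measured Equal-length numeric vectors (metres for MCH).
#' @param small_sum,large_sum Tail thresholds on `predicted + measured`
#'   (defaults 20 and 60 m, the conventions for 1-ha tropical-forest MCH).
#' @return A one-row `data.frame` with `rmse`, `r2`, `msd`, `msd1`, `msd2`,
#'   `n_test`, `n_msd1`, `n_msd2`.
#' @export
compute_metrics <- function(predicted, measured, small_sum = 20, large_sum = 60) {
  if (length(predicted) != length(measured))
    stop("invalid input: predicted and measured differ in length", call. = FALSE)
  err <- predicted - measured
  s <- predicted + measured
  i1 <- s < small_sum
  i2 <- s > large_sum
  sstot <- sum((measured - mean(measured))^2)
  data.frame(
    rmse = sqrt(mean(err^2)),
    r2 = if (length(measured) >= 2 && sstot > 0) 1 - sum(err^2) / sstot else NA_real_,
    msd = mean(err),
    msd1 = if (any(i1)) mean(err[i1]) else NA_real_,
    msd2 = if (any(i2)) mean(err[i2]) else NA_real_,
    n_test = length(err),
    n_msd1 = sum(i1),
    n_msd2 = sum(i2)
  )
}

#' Monte Carlo cross-validation by repeated random subsampling
#'
#' Per repetition: draw a fresh random train/test split, fit via
#' `model_factory`, predict the test rows, and score with [compute_metrics()].
#' Reports the per-repetition metrics and their mean and standard deviation
#' (the spread quoted as "mean +/- sd").
#'
#' @param samples Sample table (rows are available pixels/observations).
#' @param model_factory Function `function(train) -> function(newdata) -> predictions`.
#' @param n_train Training rows per repetition.
#' @param n_test Test rows per repetition, or `"rest"` for all remaining rows.
#' @param n_reps Number of repetitions (default 25).
#' @param seed Integer seed governing every split.
#' @param small_sum,large_sum Tail thresholds passed to [compute_metrics()].
#' @return A list of class `mch_cv`: `per_rep` (data.frame, one row per
#'   repetition) and `summary` (mean/sd per metric).
#' @export
monte_carlo_cv <- function(samples, model_factory, n_train,
                           n_test = "rest", n_reps = 25, seed = 1L,
                           small_sum = 20, large_sum = 60) {
  n <- nrow(samples)
  numeric_test <- !identical(n_test, "rest")
  if (n_train >= n || (numeric_test && n_train + n_test > n))
    stop("configuration error: infeasible train/test split sizes", call. = FALSE)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    perm <- sample.int(n)
    tr <- perm[seq_len(n_train)]
    te <- if (numeric_test) perm[n_train + seq_len(n_test)] else perm[-seq_len(n_train)]
    train <- samples[tr, , drop = FALSE]
    test <- samples[te, , drop = FALSE]
    attr(train, "predictors") <- attr(samples, "predictors")
    attr(test, "predictors") <- attr(samples, "predictors")
    predictor <- model_factory(train)
    pred <- predictor(test)
    m <- compute_metrics(pred, test$response, small_sum, large_sum)
    m$rep <- r
    rows[[r]] <- m
  }
  per_rep <- do.call(rbind, rows)
  metrics <- c("rmse", "r2", "msd", "msd1", "msd2")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_rep[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(per_rep[[m]], na.rm = TRUE), numeric(1)),
    n_reps = n_reps,
    row.names = NULL
  )
  structure(list(per_rep = per_rep, summary = summary,
                 n_train = n_train, n_test = n_test, seed = seed),
            class = "mch_cv")
}

#' @export
print.mch_cv <- function(x, ...) {
  cat(sprintf("<mch_cv> %d repetition(s), n_train = %d, n_test = %s\n",
              max(x$per_rep$rep), x$n_train, as.character(x$n_test)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-5s %8.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Empirical semi-variogram
#'
#' `gamma(h) = (1 / (2 N(h))) * sum over pairs in lag bin h of (z_i - z_j)^2`,
#' with pairs binned by Euclidean distance between pixel centres. For large
#' point sets, a uniform random subsample of `max_points` points is used
#' (all-pairs cost is quadratic). Bins with no pairs are reported with
#' `NA` semivariance.
#'
#' @param x An `mch_raster`, or a 2-column coordinate matrix (metres) when
#'   `values` is given.
#' @param values Numeric vector matched to the coordinate rows (ignored for
#'   rasters).
#' @param max_lag Largest pair distance retained; default half the extent
#'   diagonal.
#' @param n_bins Number of equal-width lag bins (default 30).
#' @param max_points Subsample cap (default 3000).
#' @param seed Seed for the subsample.
#' @return A `data.frame` of class `mch_variogram` with `lag` (bin centre,
#'   metres), `gamma` (semivariance), `n_pairs`.
#' @export
semivariogram <- function(x, values = NULL, max_lag = NULL, n_bins = 30,
                          max_points = 3000, seed = 1L) {
  if (inherits(x, "mch_raster")) {
    idx <- which(!is.na(x$values))
    nr <- nrow(x$values)
    coords <- pixel_centers(x, ((idx - 1L) %% nr) + 1L, ((idx - 1L) %/% nr) + 1L)
    values <- x$values[idx]
  } else {
    coords <- as.matrix(x)
    if (is.null(values) || nrow(coords) != length(values))
      stop("invalid input: coordinates and values must match", call. = FALSE)
  }
  n <- nrow(coords)
  if (n < 2L) stop("invalid input: need at least two points", call. = FALSE)
  if (n > max_points) {
    set.seed(seed)
    keep <- sample.int(n, max_points)
    coords <- coords[keep, , drop = FALSE]
    values <- values[keep]
    n <- max_points
  }
  d <- stats::dist(coords)
  if (is.null(max_lag)) {
    ext <- apply(coords, 2L, function(v) diff(range(v)))
    max_lag <- sqrt(sum(ext^2)) / 2
  }
  if (max_lag <= 0) stop("invalid parameter: max_lag must be positive", call. = FALSE)
  dz2 <- stats::dist(values)^2
  keep <- d > 0 & d <= max_lag
  bin <- ceiling(as.numeric(d[keep]) / (max_lag / n_bins))
  bin[bin < 1L] <- 1L
  dz2 <- as.numeric(dz2[keep])
  npairs <- tabulate(bin, nbins = n_bins)
  ssum <- vapply(seq_len(n_bins), function(b) sum(dz2[bin == b]), numeric(1))
  gamma <- ifelse(npairs > 0, ssum / (2 * npairs), NA_real_)
  width <- max_lag / n_bins
  out <- data.frame(lag = (seq_len(n_bins) - 0.5) * width,
                    gamma = gamma, n_pairs = npairs)
  class(out) <- c("mch_variogram", "data.frame")
  out
}
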