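#' Bin a continuous response into classes
#'
#' Uniform-width, left-open/right-closed bins `(a, a + w], (a + w, a + 2w], ...`
#' spanning the response range, starting at 0 when all responses are positive.
#' Empty bins are dropped. Each class carries a nominal value (class centre):
#' the mean of its member responses.
#'
#' @param responses Numeric vector (e.g. MCH in metres), non-empty.
#' @param bin_width Bin width in response units (> 0; default 2).
#' @return An object of class `mch_binning` with `edges`, `centers`, `counts`.
#' @export
make_binning <- function(responses, bin_width = 2) {
  if (length(responses) == 0L || anyNA(responses))
    stop("invalid input: responses must be non-empty and complete", call. = FALSE)
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("invalid parameter: `bin_width` must be positive", call. = FALSE)
  start <- if (min(responses) > 0) 0 else {
    s <- bin_width * floor(min(responses) / bin_width)
    if (s == min(responses)) s - bin_width else s   # bins are left-open
  }
  n_bins <- ceiling((max(responses) - start) / bin_width)
  n_bins <- max(n_bins, 1L)
  edges <- start + bin_width * (0:n_bins)
  # guard: max(responses) exactly on the last edge is fine (right-closed)
  cls <- findInterval(responses, edges, left.open = TRUE, rightmost.closed = FALSE)
  counts <- tabulate(cls, nbins = n_bins)
  keep <- which(counts > 0L)
  centers <- vapply(keep, function(k) mean(responses[cls == k]), numeric(1))
  structure(list(edges = edges, keep = keep,
                 lower = edges[keep], upper = edges[keep + 1L],
                 centers = centers, counts = counts[keep],
                 bin_width = bin_width),
            class = "mch_binning")
}

#' Class index of responses under a binning
#'
#' @param binning An [make_binning()] result.
#' @param responses Numeric vector.
#' @return Integer vector of class indices into `binning$centers`
#'   (`NA` for values outside every retained class).
#' @export
assign_class <- function(binning, responses) {
  raw <- findInterval(responses, binning$edges, left.open = TRUE)
  match(raw, binning$keep)
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Feature expansion: standardized values and their squares.
me_features <- function(x, center, scale) {
  xs <- sweep(sweep(as.matrix(x), 2L, center), 2L, scale, "/")
  cbind(xs, xs^2)
}

#' Fit a maximum-entropy class-probability regressor
#'
#' The response is binned ([make_binning()]); for each class `k` a Gibbs
#' density over the background, `q_k(x) %prop% exp(lambda_k . f(x))`, is fit by
#' maximizing the L2-regularized log-likelihood of the class-`k` training
#' samples, so that regularized feature expectations under `q_k` match the
#' class's empirical feature means (the maximum-entropy solution). Features
#' `f(x)` are the background-standardized predictor values and their squares.
#' The raw output `p_k^raw(x) = q_k(x) / background density` is a density
#' ratio; class priors are the empirical training proportions `N_k / N_total`.
#'
#' @param train Sample table with a `response` column (see [extract_samples()]).
#' @param background Predictor matrix covering the prediction domain (e.g. all
#'   valid pixels via [stack_pixels()]); defaults to the training predictors.
#'   Uniformly subsampled to `background_cap` rows.
#' @param bin_width Response bin width (default 2 m).
#' @param regularization L2 penalty weight on the per-sample log-likelihood
#'   scale (default 0.05).
#' @param power_m Default power weight for prediction (default 3; the
#'   bias-corrected MEBC predictor. `m = 1` is the plain expectation).
#' @param background_cap Maximum background rows (default 1e5).
#' @param maxit Optimizer iteration budget per class (default 500).
#' @param grad_tol Gradient-norm threshold declaring convergence (default 1e-4).
#' @param seed Seed for the background subsample.
#' @return An object of class `mch_me`.
#' @export
fit_me <- function(train, background = NULL, bin_width = 2,
                   regularization = 0.05, power_m = 3,
                   background_cap = 1e5, maxit = 500, grad_tol = 1e-4,
                   seed = 1L) {
  y <- train$response
  x <- sample_predictors(train)
  if (is.null(background)) background <- x
  background <- as.matrix(background)
  if (nrow(background) > background_cap) {
    set.seed(seed)
    background <- background[sample(nrow(background), background_cap), , drop = FALSE]
  }
  binning <- make_binning(y, bin_width)
  cls <- assign_class(binning, y)
  k_n <- length(binning$centers)
  center <- colMeans(background)
  scale <- apply(background, 2L, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  f_bg <- me_features(background, center, scale)
  f_tr <- me_features(x, center, scale)
  b <- nrow(f_bg)
  d <- ncol(f_bg)
  lambda <- matrix(0, k_n, d)
  log_z <- numeric(k_n)
  conv <- logical(k_n)
  for (k in seq_len(k_n)) {
    fbar <- colMeans(f_tr[cls == k, , drop = FALSE])
    obj <- function(l) {
      lz <- logsumexp(f_bg %*% l) - log(b)
      -(sum(fbar * l) - lz - regularization * sum(l^2))
    }
    grd <- function(l) {
      s <- drop(f_bg %*% l)
      w <- exp(s - max(s)); w <- w / sum(w)
      -(fbar - drop(crossprod(f_bg, w)) - 2 * regularization * l)
    }
    # BFGS occasionally stalls with a poor Hessian approximation; restarting
    # from the stalled point resets it (the regularized objective is strictly
    # convex, so restarts make progress)
    par <- numeric(d)
    for (attempt in 1:4) {
      fit <- stats::optim(par, obj, grd, method = "BFGS",
                          control = list(maxit = maxit, reltol = 1e-12))
      par <- fit$par
      gn <- sqrt(sum(grd(par)^2))
      if (gn <= grad_tol) break
    }
    conv[k] <- gn <= grad_tol
    if (!conv[k])
      stop(sprintf("convergence error: class %d did not converge (gradient norm %.3g)",
                   k, gn), call. = FALSE)
    lambda[k, ] <- fit$par
    log_z[k] <- logsumexp(f_bg %*% fit$par) - log(b)
  }
  structure(list(binning = binning,
                 priors = binning$counts / sum(binning$counts),
                 lambda = lambda, log_z = log_z,
                 feature_center = center, feature_scale = scale,
                 predictors = colnames(x),
                 regularization = regularization, power_m = power_m,
                 converged = conv),
            class = "mch_me")
}

#' @export
print.mch_me <- function(x, ...) {
  cat(sprintf("<mch_me> %d classes, %d features, m = %g\n",
              length(x$binning$centers), ncol(x$lambda), x$power_m))
  invisible(x)
}

#' Log raw outputs (log density ratios) of a fitted ME model
#'
#' @param model An `mch_me` model.
#' @param newdata Predictor matrix or sample table.
#' @return `n x K` matrix of `log p_k^raw(x)`.
#' @export
me_log_raw <- function(model, newdata) {
  x <- if (is.data.frame(newdata)) sample_predictors(newdata) else as.matrix(newdata)
  if (!is.null(model$predictors) && !is.null(colnames(x)))
    x <- x[, model$predictors, drop = FALSE]
  f <- me_features(x, model$feature_center, model$feature_scale)
  sweep(f %*% t(model$lambda), 2L, model$log_z)
}

# Core of the prediction expectation, in log space for numerical safety.
me_expectation_log <- function(log_raw, priors, centers, m) {
  lw <- m * log_raw + rep(log(priors), each = nrow(log_raw))
  mx <- apply(lw, 1L, max)
  if (any(!is.finite(mx)))
    stop("degenerate-probability error: all raw outputs vanish for some rows",
         call. = FALSE)
  w <- exp(lw - mx)
  drop(w %*% centers) / rowSums(w)
}

#' Power-weighted expectation over classes
#'
#' Computes `sum_k raw_k^m prior_k center_k / sum_k raw_k^m prior_k` per row:
#' with `m = 1` the posterior expectation of the class centres, with `m > 1`
#' the bias-corrected variant that concentrates weight on the most probable
#' classes.
#'
#' @param raw `n x K` matrix (or vector, one row) of raw outputs.
#' @param priors Length-`K` non-negative class priors.
#' @param centers Length-`K` class centres.
#' @param m Power weight (>= 1).
#' @return Numeric vector of expectations.
#' @export
me_expectation <- function(raw, priors, centers, m = 1) {
  if (is.vector(raw)) raw <- matrix(raw, nrow = 1L)
  me_expectation_log(log(raw), priors, centers, m)
}

#' Predict from a maximum-entropy model
#'
#' `m = 1` gives the plain class-expectation prediction; `m = 3` (the model
#' default) the bias-corrected MEBC prediction, which reduces the
#' towards-the-mean bias at both tails of the height distribution at some cost
#' in overall RMSE.
#'
#' @param model An `mch_me` model.
#' @param newdata Predictor matrix or sample table.
#' @param m Power weight (default `model$power_m`).
#' @return Numeric vector of predicted response values (metres for MCH).
#' @export
predict_me <- function(model, newdata, m = model$power_m) {
  if (m < 1) stop("invalid parameter: m must be >= 1", call. = FALSE)
  me_expectation_log(me_log_raw(model, newdata), model$priors,
                     model$binning$centers, m)
}

#' @export
predict.mch_me <- function(object, newdata, m = object$power_m, ...) {
  predict_me(object, newdata, m)
}

#' Serialize / restore an ME model as JSON
#'
#' @param model An `mch_me` model.
#' @param path File path.
#' @export
write_me_model <- function(model, path) {
  obj <- list(edges = model$binning$edges, keep = model$binning$keep,
              lower = model$binning$lower, upper = model$binning$upper,
              centers = model$binning$centers, counts = model$binning$counts,
              bin_width = model$binning$bin_width,
              priors = model$priors, lambda = model$lambda, log_z = model$log_z,
              feature_center = model$feature_center,
              feature_scale = model$feature_scale,
              predictors = model$predictors,
              regularization = model$regularization, power_m = model$power_m)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_me_model
#' @export
read_me_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  binning <- structure(list(edges = o$edges, keep = as.integer(o$keep),
                            lower = o$lower, upper = o$upper,
                            centers = o$centers, counts = as.integer(o$counts),
                            bin_width = o$bin_width),
                       class = "mch_binning")
  structure(list(binning = binning, priors = o$priors,
                 lambda = as.matrix(o$lambda), log_z = o$log_z,
                 feature_center = o$feature_center,
                 feature_scale = o$feature_scale,
                 predictors = o$predictors,
                 regularization = o$regularization, power_m = o$power_m,
                 converged = NULL),
            class = "mch_me")
}
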