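#' Random-forest configuration
#'
#' @param n_trees Number of trees (default 500).
#' @param max_features Predictors tried per split; `NULL` means the regression
#'   default `max(1, floor(p / 3))`; a value in (0, 1) is taken as a fraction
#'   of the predictor count.
#' @param min_leaf Minimum terminal-node size (default 5).
#' @param seed Integer seed.
#' @return An object of class `mch_rf_config`.
#' @export
rf_config <- function(n_trees = 500, max_features = NULL, min_leaf = 5,
                      seed = 1L) {
  if (n_trees < 1) stop("invalid parameter: n_trees must be >= 1", call. = FALSE)
  structure(list(n_trees = as.integer(n_trees), max_features = max_features,
                 min_leaf = as.integer(min_leaf), seed = as.integer(seed)),
            class = "mch_rf_config")
}

resolve_mtry <- function(max_features, p) {
  if (is.null(max_features)) return(max(1L, p %/% 3L))
  if (max_features > 0 && max_features < 1) return(max(1L, floor(max_features * p)))
  m <- as.integer(max_features)
  if (m < 1L || m > p)
    stop("invalid parameter: max_features outside 1..n_predictors", call. = FALSE)
  m
}

fit_ensemble <- function(x, y, config, seed) {
  d <- data.frame(.response = y, x, check.names = FALSE)
  ranger::ranger(
    dependent.variable.name = ".response", data = d,
    num.trees = config$n_trees,
    mtry = resolve_mtry(config$max_features, ncol(x)),
    min.node.size = config$min_leaf,
    num.threads = 1L, seed = seed, oob.error = TRUE
  )
}

predict_ensemble <- function(fit, x) {
  d <- as.data.frame(x)
  want <- fit$forest$independent.variable.names
  if (!all(want %in% names(d)) && ncol(d) == length(want)) names(d) <- want
  stats::predict(fit, data = d, num.threads = 1L)$predictions
}

#' Fit a bagged regression forest with out-of-bag predictions
#'
#' The ensemble prediction is the unweighted average of the trees; each
#' training row additionally receives an out-of-bag (OOB) prediction averaged
#' over the trees whose bootstrap sample excluded it. Rows that were in-bag in
#' every tree (vanishingly rare for realistic tree counts) receive the
#' full-ensemble prediction and are flagged in `oob_fallback`.
#'
#' @param train Sample table with a `response` column, or a predictor matrix
#'   when `y` is given.
#' @param config An [rf_config()].
#' @param y Optional response vector when `train` is a bare matrix.
#' @return An object of class `mch_rf` with elements `fit` (ranger object),
#'   `oob` (OOB predictions), `oob_fallback` (logical), `config`.
#' @export
fit_rf <- function(train, config = rf_config(), y = NULL) {
  if (is.null(y)) {
    y <- train$response
    x <- sample_predictors(train)
  } else {
    x <- as.matrix(train)
  }
  if (length(y) < 2L)
    stop("invalid input: need at least two training rows", call. = FALSE)
  fit <- fit_ensemble(x, y, config, seed = config$seed)
  oob <- fit$predictions
  fallback <- !is.finite(oob)
  if (any(fallback)) {
    full <- predict_ensemble(fit, x)
    oob[fallback] <- full[fallback]
    message(sprintf("fit_rf: %d row(s) never out-of-bag; using full-ensemble prediction",
                    sum(fallback)))
  }
  structure(list(fit = fit, oob = oob, oob_fallback = fallback,
                 predictors = colnames(x), config = config),
            class = "mch_rf")
}

#' @export
predict.mch_rf <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata) && "response" %in% names(newdata))
    sample_predictors(newdata) else newdata
  x <- as.matrix(x)
  if (ncol(x) != length(object$predictors))
    stop("invalid input: predictor dimensionality differs from training", call. = FALSE)
  predict_ensemble(object$fit, x)
}

#' Reflect training targets through their out-of-bag predictions
#'
#' The bias-stage target: `y_new = oob - (y - oob) = 2 * oob - y`, i.e. the
#' OOB estimate minus the regression residual, pushing the systematic bias in
#' the opposite direction so a second model can learn it.
#'
#' @param y Measured responses.
#' @param oob Out-of-bag predictions for the same rows.
#' @return Reflected target vector.
#' @export
rfbc_reflect <- function(y, oob) {
  if (length(y) != length(oob))
    stop("invalid input: length mismatch", call. = FALSE)
  2 * oob - y
}

#' Fit the two-pass bias-corrected random forest (RFBC)
#'
#' Fits the primary forest, reflects the training targets through the primary
#' forest's out-of-bag predictions ([rfbc_reflect()]), and fits a second
#' ("bias") forest on the reflected targets with an independent seed stream.
#' Predictions then subtract the estimated bias: see [predict_rfbc()].
#'
#' @inheritParams fit_rf
#' @return An object of class `mch_rfbc` with `primary`, `bias`, `config`.
#' @export
fit_rfbc <- function(train, config = rf_config(), y = NULL) {
  primary <- fit_rf(train, config, y = y)
  x <- if (is.null(y)) sample_predictors(train) else as.matrix(train)
  y0 <- if (is.null(y)) train$response else y
  y_new <- rfbc_reflect(y0, primary$oob)
  bias_cfg <- config
  bias_cfg$seed <- config$seed + 1000003L   # independent substream
  bias <- fit_ensemble(x, y_new, bias_cfg, seed = bias_cfg$seed)
  structure(list(primary = primary, bias = bias,
                 predictors = primary$predictors, config = config),
            class = "mch_rfbc")
}

#' Bias-corrected random-forest prediction
#'
#' `prediction = 2 * primary(x) - bias(x)`: the primary estimate minus the
#' systematic bias inferred from the reflected-target forest.
#'
#' @param model An `mch_rfbc` model.
#' @param newdata Predictor matrix or sample table.
#' @return Numeric vector of bias-corrected predictions.
#' @export
predict_rfbc <- function(model, newdata) {
  x <- if (is.data.frame(newdata) && "response" %in% names(newdata))
    sample_predictors(newdata) else newdata
  x <- as.matrix(x)
  if (ncol(x) != length(model$predictors))
    stop("invalid input: predictor dimensionality differs from training", call. = FALSE)
  2 * predict_ensemble(model$primary$fit, x) - predict_ensemble(model$bias, x)
}

#' @export
predict.mch_rfbc <- function(object, newdata, ...) predict_rfbc(object, newdata)
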