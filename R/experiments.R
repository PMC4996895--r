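#' Model factories for cross-validation
#'
#' Each factory returns a `function(train) -> function(newdata) -> predictions`
#' closure suitable for [monte_carlo_cv()] and the experiment runners.
#' `me_factory`'s `background` should cover the prediction domain (e.g. the
#' predictor columns of [stack_pixels()]); when `NULL` the training predictors
#' are used.
#'
#' @param config An [rf_config()].
#' @param m Power weight for the ME expectation (1 = plain ME, 3 = MEBC).
#' @param background Background predictor matrix for [fit_me()].
#' @param bin_width,regularization,background_cap Passed to [fit_me()].
#' @return A model factory function.
#' @name model_factories
NULL

#' @rdname model_factories
#' @export
rf_factory <- function(config = rf_config()) {
  function(train) {
    fit <- fit_rf(train, config)
    function(newdata) stats::predict(fit, newdata)
  }
}

#' @rdname model_factories
#' @export
rfbc_factory <- function(config = rf_config()) {
  function(train) {
    fit <- fit_rfbc(train, config)
    function(newdata) predict_rfbc(fit, newdata)
  }
}

#' @rdname model_factories
#' @export
me_factory <- function(m = 1, background = NULL, bin_width = 2,
                       regularization = 0.05, background_cap = 1e5) {
  function(train) {
    fit <- fit_me(train, background = background, bin_width = bin_width,
                  regularization = regularization,
                  background_cap = background_cap)
    function(newdata) predict_me(fit, newdata, m = m)
  }
}

# Predictor-name sets for a layer combination code like "L", "LA", "LAST".
combo_roles <- function(code) {
  if (code == "BC") code <- "LAST"
  roles <- strsplit(code, "")[[1]]
  if (!all(roles %in% c("L", "A", "S", "T")))
    stop(sprintf("configuration error: unknown layer combination '%s'", code),
         call. = FALSE)
  roles
}

subset_samples <- function(samples, predictors) {
  out <- samples[, c(intersect(c("row", "col", "x", "y", "response"),
                               names(samples)), predictors), drop = FALSE]
  attr(out, "predictors") <- predictors
  out
}

#' Layer-combination benchmark
#'
#' Runs Monte Carlo cross-validation of each model over nested predictor sets
#' (optical only, + radar, + elevation, + texture), plus the bias-corrected
#' variants on the full set: the `"BC"` combination uses the same input layers
#' as `"LAST"` but scores RFBC (for RF) and the `m = 3` MEBC expectation
#' (for ME). Texture bands are built with the default [texture_spec()] if the
#' plan needs them and the stack has none.
#'
#' @param stack An `mch_stack` of predictors.
#' @param response Co-registered response raster (MCH, metres).
#' @param combos Layer combinations over roles L/A/S/T, plus `"BC"`.
#' @param models Base model families, subset of `c("RF", "ME")`.
#' @param train_size Training pixels per repetition (default 400).
#' @param n_reps CV repetitions (default 10).
#' @param rf_cfg An [rf_config()] (its seed is superseded per repetition).
#' @param bin_width,regularization ME settings.
#' @param me_background_cap Background cap for [fit_me()] (default 20000).
#' @param seed Top-level seed: determines all splits and fits.
#' @return A `data.frame` (one row per combo x model x repetition) with the
#'   [compute_metrics()] columns plus bookkeeping columns `combo`, `model`,
#'   `n_train`, `seed`; summarize with [experiment_table()].
#' @export
run_layer_experiment <- function(stack, response,
                                 combos = c("L", "LA", "LAS", "LAST", "BC"),
                                 models = c("RF", "ME"),
                                 train_size = 400, n_reps = 10,
                                 rf_cfg = rf_config(),
                                 bin_width = 2, regularization = 0.05,
                                 me_background_cap = 20000, seed = 1L) {
  needs_t <- any(vapply(combos, function(cc) "T" %in% combo_roles(cc), logical(1)))
  if (needs_t && !any(stack$roles == "T")) {
    message("run_layer_experiment: building default texture layers")
    stack <- build_texture_stack(stack)
  }
  all_px <- stack_pixels(stack, response)
  set.seed(seed)
  rep_seeds <- sample.int(2^30, n_reps)
  rows <- list()
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    perm <- sample.int(nrow(all_px))
    tr_idx <- perm[seq_len(train_size)]
    te_idx <- perm[-seq_len(train_size)]
    cache <- new.env(parent = emptyenv())
    for (cc in combos) {
      pred_names <- stack$names[stack$roles %in% combo_roles(cc)]
      key <- paste(pred_names, collapse = "|")
      train <- subset_samples(all_px[tr_idx, ], pred_names)
      test <- subset_samples(all_px[te_idx, ], pred_names)
      for (mod in models) {
        if (mod == "RF") {
          cfg <- rf_cfg; cfg$seed <- rep_seeds[r]
          if (cc == "BC") {
            ck <- paste0("rfbc:", key)
            if (is.null(cache[[ck]])) cache[[ck]] <- fit_rfbc(train, cfg)
            pred <- predict_rfbc(cache[[ck]], test)
            label <- "RFBC"
          } else {
            ck <- paste0("rf:", key)
            if (is.null(cache[[ck]])) cache[[ck]] <- fit_rf(train, cfg)
            pred <- stats::predict(cache[[ck]], test)
            label <- "RF"
          }
        } else if (mod == "ME") {
          ck <- paste0("me:", key)
          if (is.null(cache[[ck]]))
            cache[[ck]] <- fit_me(train,
                                  background = as.matrix(all_px[, pred_names,
                                                                drop = FALSE]),
                                  bin_width = bin_width,
                                  regularization = regularization,
                                  background_cap = me_background_cap,
                                  seed = rep_seeds[r])
          if (cc == "BC") {
            pred <- predict_me(cache[[ck]], test, m = 3)
            label <- "MEBC"
          } else {
            pred <- predict_me(cache[[ck]], test, m = 1)
            label <- "ME"
          }
        } else stop(sprintf("unknown model family '%s'", mod), call. = FALSE)
        met <- compute_metrics(pred, test$response)
        met$combo <- cc; met$model <- label; met$rep <- r
        met$n_train <- train_size; met$seed <- rep_seeds[r]
        rows[[length(rows) + 1L]] <- met
      }
    }
  }
  do.call(rbind, rows)
}

#' Training-sample-size benchmark
#'
#' Monte Carlo CV of each model at every training size in `sizes`, with a
#' fixed-size test set drawn disjointly from the training rows each
#' repetition.
#'
#' @inheritParams run_layer_experiment
#' @param samples Pre-extracted sample table (e.g. [stack_pixels()] on the
#'   full stack, or [generate_simulation()] output).
#' @param sizes Ascending training sizes (default `c(40, 100, 400, 1600)`).
#' @param test_size Fixed test rows per repetition (default 5000).
#' @param models Subset of `c("RF", "RFBC", "ME", "MEBC")`.
#' @param me_background Background matrix for the ME fits (default: all
#'   sample predictors).
#' @return Long `data.frame`: one row per size x model x repetition.
#' @export
run_sample_size_experiment <- function(samples,
                                       sizes = c(40, 100, 400, 1600),
                                       test_size = 5000,
                                       models = c("RF", "RFBC"),
                                       n_reps = 10, rf_cfg = rf_config(),
                                       bin_width = 2, regularization = 0.05,
                                       me_background = NULL,
                                       me_background_cap = 20000, seed = 1L) {
  if (is.unsorted(sizes)) stop("configuration error: sizes must ascend", call. = FALSE)
  if (max(sizes) + test_size > nrow(samples))
    stop("configuration error: largest size plus test size exceeds samples", call. = FALSE)
  if (is.null(me_background)) me_background <- sample_predictors(samples)
  set.seed(seed)
  rep_seeds <- sample.int(2^30, n_reps)
  rows <- list()
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    perm <- sample.int(nrow(samples))
    te_idx <- perm[seq_len(test_size)]
    pool <- perm[-seq_len(test_size)]
    test <- samples[te_idx, , drop = FALSE]
    attr(test, "predictors") <- attr(samples, "predictors")
    for (sz in sizes) {
      train <- samples[pool[seq_len(sz)], , drop = FALSE]
      attr(train, "predictors") <- attr(samples, "predictors")
      cfg <- rf_cfg; cfg$seed <- rep_seeds[r]
      fits <- list()
      if ("RFBC" %in% models) fits$rfbc <- fit_rfbc(train, cfg)
      for (mod in models) {
        pred <- switch(
          mod,
          RF = {
            # the RFBC primary stage *is* the plain forest for this split
            if (!is.null(fits$rfbc)) stats::predict(fits$rfbc$primary, test)
            else {
              if (is.null(fits$rf)) fits$rf <- fit_rf(train, cfg)
              stats::predict(fits$rf, test)
            }
          },
          RFBC = predict_rfbc(fits$rfbc, test),
          ME = ,
          MEBC = {
            if (is.null(fits$me))
              fits$me <- fit_me(train, background = me_background,
                                bin_width = bin_width,
                                regularization = regularization,
                                background_cap = me_background_cap,
                                seed = rep_seeds[r])
            predict_me(fits$me, test, m = if (mod == "MEBC") 3 else 1)
          },
          stop(sprintf("unknown model '%s'", mod), call. = FALSE)
        )
        met <- compute_metrics(pred, test$response)
        met$model <- mod; met$n_train <- sz; met$rep <- r
        met$seed <- rep_seeds[r]
        rows[[length(rows) + 1L]] <- met
      }
    }
  }
  do.call(rbind, rows)
}

#' Noise-simulation benchmark (RF vs RFBC)
#'
#' Generates the tabular simulation ([generate_simulation()]) at each
#' predictor-noise level, splits it half/half at random into training and
#' test, fits RF and RFBC, and scores the test half. Because the simulated
#' response is centred at the intercept (not on the MCH scale), the tail rules
#' are re-expressed: MSD1/MSD2 use `predicted + measured` below/above the
#' `tail_quantiles` of `2 * response`. Conditional mean deviations over two
#' fixed response slices (`low_y_range`, `high_y_range`) are also reported.
#'
#' @param n_samples Simulation rows (default 10000; half train, half test).
#' @param x_noise Predictor-noise fractions to compare (default `c(0.2, 0.8)`).
#' @param n_reps Independent repetitions (fresh data + split) per noise level.
#' @param rf_cfg An [rf_config()].
#' @param tail_quantiles Quantiles of `2 * response` defining small/large tails
#'   (default `c(0.1, 0.9)`).
#' @param low_y_range,high_y_range Response slices for the conditional bias
#'   curves (defaults `c(5, 6)` and `c(34, 35)`).
#' @param seed Top-level seed.
#' @param sim_args Extra arguments passed to [sim_config()].
#' @return Long `data.frame`: one row per noise level x model x repetition,
#'   with metrics plus `msd_low_y`, `msd_high_y`.
#' @export
run_simulation_experiment <- function(n_samples = 10000,
                                      x_noise = c(0.2, 0.8),
                                      n_reps = 5, rf_cfg = rf_config(),
                                      tail_quantiles = c(0.1, 0.9),
                                      low_y_range = c(5, 6),
                                      high_y_range = c(34, 35),
                                      seed = 1L, sim_args = list()) {
  set.seed(seed)
  rep_seeds <- sample.int(2^30, n_reps)
  rows <- list()
  for (r in seq_len(n_reps)) {
    for (nz in x_noise) {
      cfg <- do.call(sim_config, c(list(n_samples = n_samples,
                                        x_noise_fraction = nz,
                                        seed = rep_seeds[r]), sim_args))
      sim <- generate_simulation(cfg)
      set.seed(rep_seeds[r] + 1L)
      n <- nrow(sim)
      tr <- sample.int(n, n %/% 2L)
      train <- sim[tr, , drop = FALSE]
      test <- sim[-tr, , drop = FALSE]
      attr(train, "predictors") <- attr(sim, "predictors")
      attr(test, "predictors") <- attr(sim, "predictors")
      qq <- stats::quantile(2 * sim$response, tail_quantiles, names = FALSE)
      cfg_rf <- rf_cfg; cfg_rf$seed <- rep_seeds[r]
      rfbc <- fit_rfbc(train, cfg_rf)
      preds <- list(RF = stats::predict(rfbc$primary, test),
                    RFBC = predict_rfbc(rfbc, test))
      for (mod in names(preds)) {
        met <- compute_metrics(preds[[mod]], test$response,
                               small_sum = qq[1], large_sum = qq[2])
        err <- preds[[mod]] - test$response
        lo <- test$response > low_y_range[1] & test$response < low_y_range[2]
        hi <- test$response > high_y_range[1] & test$response < high_y_range[2]
        met$msd_low_y <- if (any(lo)) mean(err[lo]) else NA_real_
        met$msd_high_y <- if (any(hi)) mean(err[hi]) else NA_real_
        met$model <- mod; met$x_noise <- nz; met$rep <- r
        met$n_train <- length(tr); met$seed <- rep_seeds[r]
        rows[[length(rows) + 1L]] <- met
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize a long experiment table as mean +/- sd
#'
#' @param result Long `data.frame` from an experiment runner.
#' @param by Grouping columns (defaults to whichever of `combo`, `model`,
#'   `n_train`, `x_noise` are present).
#' @param metrics Metric columns to aggregate.
#' @return A `data.frame` with `<metric>_mean` and `<metric>_sd` columns, plus
#'   a formatted `"mean +/- sd"` string column per metric.
#' @export
experiment_table <- function(result,
                             by = intersect(c("combo", "model", "n_train",
                                              "x_noise"), names(result)),
                             metrics = intersect(c("rmse", "r2", "msd",
                                                   "msd1", "msd2"),
                                                 names(result))) {
  key <- interaction(result[by], drop = TRUE, lex.order = TRUE)
  groups <- split(result, key)
  out <- do.call(rbind, lapply(groups, function(g) {
    row <- g[1L, by, drop = FALSE]
    for (m in metrics) {
      mu <- mean(g[[m]], na.rm = TRUE)
      sdv <- stats::sd(g[[m]], na.rm = TRUE)
      row[[paste0(m, "_mean")]] <- mu
      row[[paste0(m, "_sd")]] <- sdv
      row[[m]] <- sprintf("%.2f +/- %.2f", mu, sdv)
    }
    row$n_reps <- nrow(g)
    row
  }))
  rownames(out) <- NULL
  out
}
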