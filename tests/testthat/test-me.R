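test_that("response binning partitions the training responses", {
  b <- make_binning(c(5, 5, 5), bin_width = 2)
  expect_equal(length(b$centers), 1)
  expect_equal(b$centers, 5)
  b2 <- make_binning(c(3, 4, 11), bin_width = 10)
  expect_equal(b2$lower, c(0, 10))
  expect_equal(b2$upper, c(10, 20))
  expect_equal(b2$centers, c(3.5, 11))
  expect_equal(b2$counts, c(2L, 1L))
  # partition: class counts sum to the sample count; centres inside bins
  set.seed(1)
  y <- runif(500, 0.5, 44)
  b3 <- make_binning(y, 2)
  expect_equal(sum(b3$counts), 500L)
  expect_true(all(b3$centers > b3$lower & b3$centers <= b3$upper))
  expect_false(anyNA(assign_class(b3, y)))
  expect_error(make_binning(y, 0), "invalid parameter")
  expect_error(make_binning(numeric(0), 1), "invalid input")
})

test_that("power-weighted class expectation reproduces hand-worked cases", {
  # raw (0.2, 0.8), priors (0.5, 0.5), centres (10, 30)
  expect_equal(me_expectation(c(0.2, 0.8), c(0.5, 0.5), c(10, 30), m = 1),
               26.0, tolerance = 1e-12)
  expect_equal(me_expectation(c(0.2, 0.8), c(0.5, 0.5), c(10, 30), m = 3),
               (0.008 * 10 + 0.512 * 30) / (0.008 + 0.512), tolerance = 1e-12)
  # uniform raw output: prediction is the prior-weighted mean of centres
  expect_equal(me_expectation(c(1, 1, 1), c(0.2, 0.3, 0.5), c(5, 15, 30), m = 2),
               0.2 * 5 + 0.3 * 15 + 0.5 * 30, tolerance = 1e-12)
})

test_that("a single-class model predicts its centre everywhere", {
  set.seed(2)
  train <- data.frame(response = rep(12, 30) + runif(30, -0.5, 0.5),
                      X1 = rnorm(30))
  attr(train, "predictors") <- "X1"
  fit <- fit_me(train, bin_width = 50)
  expect_equal(length(fit$binning$centers), 1)
  pred <- predict_me(fit, matrix(rnorm(10), ncol = 1), m = 1)
  expect_equal(pred, rep(fit$binning$centers, 10), tolerance = 1e-12)
  pred3 <- predict_me(fit, matrix(rnorm(10), ncol = 1), m = 3)
  expect_equal(pred3, pred, tolerance = 1e-12)
})

test_that("well-separated classes recover sharp posteriors matching a histogram oracle", {
  set.seed(7)
  n <- 400
  x <- c(rnorm(n, -3, 0.5), rnorm(n, 3, 0.5))
  y <- c(rnorm(n, 5, 0.2), rnorm(n, 25, 0.2))
  train <- data.frame(response = y, X1 = x)
  attr(train, "predictors") <- "X1"
  bg <- matrix(c(rnorm(4000, -3, 0.5), rnorm(4000, 3, 0.5)), ncol = 1)
  colnames(bg) <- "X1"
  fit <- fit_me(train, background = bg, bin_width = 15, regularization = 0.01)
  expect_equal(length(fit$binning$centers), 2)
  # posterior p(k | x) ~ raw_k * prior_k, normalized
  lr <- me_log_raw(fit, matrix(c(-3, 3), ncol = 1, dimnames = list(NULL, "X1")))
  post <- exp(lr) * rep(fit$priors, each = 2)
  post <- post / rowSums(post)
  expect_true(all(abs(rowSums(post) - 1) < 1e-12))
  expect_gt(post[1, 1], 0.9)
  expect_gt(post[2, 2], 0.9)
  # histogram density-ratio oracle at the two centroids: the class density
  # over the background density, estimated by binned counts
  brk <- seq(-6.5, 6.5, by = 1)   # -3 and 3 are bin centres
  for (cl in 1:2) {
    xk <- x[assign_class(fit$binning, y) == cl]
    hk <- hist(xk, breaks = brk, plot = FALSE)$density
    hb <- hist(bg, breaks = brk, plot = FALSE)$density
    at <- findInterval(c(-3, 3)[cl], brk)
    oracle_raw <- hk[at] / hb[at]
    got_raw <- exp(lr[cl, cl])
    expect_equal(got_raw, oracle_raw, tolerance = 0.35)   # density estimate
  }
})

test_that("the fit depends on the data only through feature means and counts", {
  set.seed(11)
  train <- data.frame(response = runif(60, 1, 30), X1 = rnorm(60),
                      X2 = rnorm(60))
  attr(train, "predictors") <- c("X1", "X2")
  dup <- rbind(train, train)
  attr(dup, "predictors") <- c("X1", "X2")
  bg <- cbind(X1 = rnorm(500), X2 = rnorm(500))
  f1 <- fit_me(train, background = bg, bin_width = 10)
  f2 <- fit_me(dup, background = bg, bin_width = 10)
  expect_equal(f1$lambda, f2$lambda, tolerance = 1e-5)
  expect_equal(f1$priors, f2$priors, tolerance = 1e-12)
})

test_that("predictions are convex combinations of class centres and priors sum to 1", {
  ls <- small_landscape(seed = 4, nrow = 48, ncol = 48)
  s <- extract_samples(ls$stack, ls$mch, 300, seed = 5)
  px <- stack_pixels(ls$stack)
  fit <- fit_me(s, background = sample_predictors(px), bin_width = 4,
                background_cap = 3000)
  expect_equal(sum(fit$priors), 1, tolerance = 1e-12)
  pred <- predict_me(fit, px, m = 1)
  expect_true(all(pred >= min(fit$binning$centers) - 1e-9))
  expect_true(all(pred <= max(fit$binning$centers) + 1e-9))
})

test_that("raising the power weight moves top-class samples toward their centre", {
  set.seed(13)
  ls <- small_landscape(seed = 4, nrow = 48, ncol = 48)
  s <- extract_samples(ls$stack, ls$mch, 500, seed = 6)
  px <- stack_pixels(ls$stack, ls$mch)
  fit <- fit_me(s, background = sample_predictors(px), bin_width = 4,
                background_cap = 3000)
  top_lo <- fit$binning$lower[length(fit$binning$lower)]
  top_center <- fit$binning$centers[length(fit$binning$centers)]
  idx <- which(px$response > top_lo)
  p1 <- predict_me(fit, px[idx, , drop = FALSE], m = 1)
  p3 <- predict_me(fit, px[idx, , drop = FALSE], m = 3)
  expect_lt(abs(mean(p3) - top_center), abs(mean(p1) - top_center))
})

test_that("ME models serialize to JSON and back without changing predictions", {
  set.seed(17)
  train <- data.frame(response = runif(80, 1, 30), X1 = rnorm(80),
                      X2 = rnorm(80))
  attr(train, "predictors") <- c("X1", "X2")
  fit <- fit_me(train, bin_width = 10)
  path <- tempfile(fileext = ".json")
  write_me_model(fit, path)
  back <- read_me_model(path)
  newx <- cbind(X1 = rnorm(20), X2 = rnorm(20))
  expect_equal(predict_me(back, newx, m = 1), predict_me(fit, newx, m = 1),
               tolerance = 1e-10)
  expect_equal(predict_me(back, newx, m = 3), predict_me(fit, newx, m = 3),
               tolerance = 1e-10)
  expect_equal(back$power_m, fit$power_m)
})
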