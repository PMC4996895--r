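test_that("metrics reproduce hand-worked values and trivial identities", {
  y <- c(5, 10, 20, 35)
  perfect <- compute_metrics(y, y)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$msd, 0)
  expect_equal(perfect$r2, 1)
  shifted <- compute_metrics(y + 2, y)
  expect_equal(shifted$msd, 2)
  # tail rules: (8,6) sums to 14 (< 20); (30,33) and (40,35) sum above 60
  m <- compute_metrics(c(8, 30, 40), c(6, 33, 35))
  expect_equal(m$msd1, 2)
  expect_equal(m$msd2, mean(c(-3, 5)))
  expect_equal(m$n_msd1, 1L)
  expect_equal(m$n_msd2, 2L)
  expect_equal(m$rmse, sqrt(mean(c(2, -3, 5)^2)))
})

test_that("tail subsets are strict, disjoint, and undefined when empty", {
  # sums exactly 20 and exactly 60 fall in neither subset
  m <- compute_metrics(c(10, 30), c(10, 30))
  expect_equal(m$n_msd1 + m$n_msd2, 0L)
  expect_true(is.na(m$msd1))
  expect_true(is.na(m$msd2))
  # disjoint by construction on random data
  set.seed(2)
  p <- runif(200, 0, 50); o <- runif(200, 0, 50)
  mm <- compute_metrics(p, o)
  expect_lte(mm$n_msd1 + mm$n_msd2, mm$n_test)
  # RMSE^2 >= MSD^2
  expect_gte(mm$rmse^2, mm$msd^2)
  expect_error(compute_metrics(1:3, 1:4), "invalid input")
})

test_that("single-repetition CV equals a direct metric computation", {
  set.seed(8)
  samples <- data.frame(response = runif(200, 1, 40), X1 = rnorm(200))
  attr(samples, "predictors") <- "X1"
  mean_factory <- function(train) {
    mu <- mean(train$response)
    function(newdata) rep(mu, nrow(newdata))
  }
  cv <- monte_carlo_cv(samples, mean_factory, n_train = 50, n_reps = 1,
                       seed = 31)
  # recompute the same split by hand
  set.seed(31)
  rs <- sample.int(.Machine$integer.max, 1)
  set.seed(rs)
  perm <- sample.int(200)
  train <- samples[perm[1:50], ]; test <- samples[perm[-(1:50)], ]
  direct <- compute_metrics(rep(mean(train$response), 150), test$response)
  expect_equal(cv$per_rep$rmse, direct$rmse)
  expect_equal(cv$per_rep$msd, direct$msd)
  expect_equal(cv$summary$sd, rep(NA_real_, 5))   # sd undefined for one rep
})

test_that("CV on a constant response with the mean model is exact", {
  samples <- data.frame(response = rep(10, 100), X1 = rnorm(100))
  attr(samples, "predictors") <- "X1"
  mean_factory <- function(train) {
    mu <- mean(train$response)
    function(newdata) rep(mu, nrow(newdata))
  }
  cv <- monte_carlo_cv(samples, mean_factory, n_train = 20, n_reps = 4, seed = 2)
  expect_equal(cv$summary$mean[cv$summary$metric == "rmse"], 0)
  expect_equal(cv$summary$sd[cv$summary$metric == "rmse"], 0)
  expect_error(monte_carlo_cv(samples, mean_factory, n_train = 100),
               "configuration error")
})

test_that("CV respects fixed numeric test sizes and reports repetition counts", {
  set.seed(3)
  samples <- data.frame(response = runif(300, 1, 40), X1 = rnorm(300))
  attr(samples, "predictors") <- "X1"
  fac <- function(train) function(newdata) rep(20, nrow(newdata))
  cv <- monte_carlo_cv(samples, fac, n_train = 40, n_test = 100, n_reps = 3,
                       seed = 5)
  expect_equal(unique(cv$per_rep$n_test), 100L)
  expect_equal(cv$summary$n_reps, rep(3, 5))
  cv_rest <- monte_carlo_cv(samples, fac, n_train = 40, n_reps = 2, seed = 5)
  expect_equal(unique(cv_rest$per_rep$n_test), 260L)
})

test_that("semi-variogram matches closed forms and the all-pairs oracle", {
  # two points at distance d with values 0 and 2: gamma = 2
  v <- semivariogram(rbind(c(0, 0), c(30, 40)), values = c(0, 2),
                     max_lag = 100, n_bins = 4)
  expect_equal(v$gamma[v$n_pairs > 0], 2)
  expect_equal(v$n_pairs[2], 1L)     # distance 50 falls in bin (25, 50]
  # constant field: zero in every populated bin
  ls <- raster_grid(matrix(5, 10, 10), pixel_size = 1)
  vc <- semivariogram(ls, max_lag = 5, n_bins = 5)
  expect_true(all(vc$gamma[vc$n_pairs > 0] == 0))
  # random 20x20 grid against the brute-force oracle
  set.seed(12)
  r <- raster_grid(matrix(rnorm(400), 20, 20), pixel_size = 1)
  got <- semivariogram(r, max_lag = 10, n_bins = 10)
  idx <- which(!is.na(r$values))
  coords <- pixel_centers(r, ((idx - 1) %% 20) + 1, ((idx - 1) %/% 20) + 1)
  want <- oracle_variogram(coords, r$values[idx], max_lag = 10, n_bins = 10)
  expect_equal(got$gamma, want$gamma, tolerance = 1e-10)
  expect_equal(got$n_pairs, want$n_pairs)
})

test_that("variogram handles empty bins and degenerate inputs", {
  v <- semivariogram(rbind(c(0, 0), c(0, 100)), values = c(1, 2),
                     max_lag = 200, n_bins = 10)
  expect_true(is.na(v$gamma[1]))          # no short-range pairs
  expect_equal(sum(v$n_pairs), 1L)
  expect_error(semivariogram(rbind(c(0, 0)), values = 1), "two points")
  expect_error(semivariogram(rbind(c(0, 0), c(1, 1)), values = c(1, 2),
                             max_lag = 0), "invalid parameter")
})
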