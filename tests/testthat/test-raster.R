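test_that("block aggregation averages valid fine cells", {
  # constant block
  r <- raster_grid(matrix(10, 100, 100), pixel_size = 1)
  expect_equal(aggregate_mean(r, 100)$values, matrix(10, 1, 1))
  # symmetric 2x2 block
  r2 <- raster_grid(matrix(c(0, 20, 0, 20), 2, 2), pixel_size = 1)
  expect_equal(aggregate_mean(r2, 2)$values, matrix(10, 1, 1))
  # random grid against the direct loop oracle, including masked cells
  set.seed(5)
  m <- matrix(rnorm(64), 8, 8)
  m[sample(64, 10)] <- NA
  agg <- aggregate_mean(raster_grid(m, pixel_size = 1), 4)
  expect_equal(agg$values, oracle_block_mean(m, 4), tolerance = 1e-12)
  expect_equal(agg$pixel_size, 4)
})

test_that("aggregation conserves the grand mean on fully valid grids", {
  set.seed(9)
  m <- matrix(runif(60 * 40), 60, 40)
  agg <- aggregate_mean(raster_grid(m, pixel_size = 1), 10)
  expect_equal(mean(agg$values), mean(m), tolerance = 1e-12)
})

test_that("partial trailing blocks are dropped, fully masked blocks stay masked", {
  m <- matrix(1, 5, 7)
  expect_message(agg <- aggregate_mean(raster_grid(m, pixel_size = 1), 2),
                 "partial")
  expect_equal(dim(agg$values), c(2L, 3L))
  m2 <- matrix(1, 4, 4)
  m2[1:2, 1:2] <- NA
  agg2 <- aggregate_mean(raster_grid(m2, pixel_size = 1), 2)
  expect_true(is.na(agg2$values[1, 1]))
  expect_equal(agg2$values[2, 2], 1)
})

test_that("aggregation rejects bad factors and empty rasters", {
  r <- raster_grid(matrix(1, 4, 4))
  expect_error(aggregate_mean(r, 0), "invalid parameter")
  expect_error(aggregate_mean(r, 2.5), "invalid parameter")
  expect_error(raster_grid(matrix(numeric(0), 0, 0)), "at least one cell")
})

test_that("validity mask applies the vegetation and minimum-height rules", {
  mch <- raster_grid(matrix(c(0.5, 25, 1.0, 1.5, 3, 40), 2, 3), pixel_size = 100)
  veg <- raster_grid(matrix(c(1, 1, 1, 1, 0, 1), 2, 3), pixel_size = 100)
  out <- apply_validity_mask(mch, veg, min_height = 1.0)
  # 0.5 m and exactly 1.0 m fail the strict "> 1 m" rule; the non-vegetated
  # pixel is dropped regardless of height
  expect_true(is.na(out$values[1, 1]))
  expect_true(is.na(out$values[1, 2]))
  expect_true(is.na(out$values[1, 3]))
  expect_equal(out$values[2, 1], 25)
  expect_equal(attr(out, "removed"), c(landcover = 1L, min_height = 2L))
})

test_that("retained count matches a direct scan and masking is idempotent", {
  vals <- matrix(seq(0.5, 4.5, by = 0.5), 3, 3)
  mch <- raster_grid(vals, pixel_size = 100)
  veg <- raster_grid(matrix(1, 3, 3), pixel_size = 100)
  out <- apply_validity_mask(mch, veg)
  expect_equal(sum(!is.na(out$values)), sum(vals > 1.0))
  again <- apply_validity_mask(out, veg)
  expect_identical(again$values, out$values)
  expect_equal(sum(attr(again, "removed")), 0L)
})

test_that("masking requires co-registered grids", {
  mch <- raster_grid(matrix(1, 3, 3))
  veg <- raster_grid(matrix(1, 3, 4))
  expect_error(apply_validity_mask(mch, veg), "co-registration")
})

test_that("pixel sampling is uniform, exhaustive and reproducible", {
  set.seed(1)
  resp <- raster_grid(matrix(runif(100, 2, 40), 10, 10), pixel_size = 100)
  resp$values[1:5] <- NA
  stk <- layer_stack(list(b1 = matrix(rnorm(100), 10, 10)), roles = "L",
                     pixel_size = 100)
  n_valid <- sum(!is.na(resp$values))
  all_s <- extract_samples(stk, resp, n = NULL, seed = 3)
  expect_equal(nrow(all_s), n_valid)
  expect_false(any(duplicated(all_s[, c("row", "col")])))
  expect_setequal(all_s$response, resp$values[!is.na(resp$values)])
  # determinism
  s1 <- extract_samples(stk, resp, 20, seed = 11)
  s2 <- extract_samples(stk, resp, 20, seed = 11)
  expect_identical(s1, s2)
  # over-ask names both counts
  expect_error(extract_samples(stk, resp, n_valid + 1, seed = 1),
               sprintf("sampling error.*%d.*%d", n_valid + 1, n_valid))
})

test_that("a 400-pixel training draw leaves the rest as test set", {
  ls <- small_landscape(seed = 2, nrow = 60, ncol = 60)
  s <- extract_samples(ls$stack, ls$mch, 400, seed = 7)
  expect_equal(nrow(s), 400)
  n_valid <- sum(stack_valid_mask(ls$stack, ls$mch))
  expect_gt(n_valid - 400, 0)        # the remainder is available for testing
  expect_equal(ncol(sample_predictors(s)), 7)
})

test_that("layer stacks validate roles and co-registration", {
  expect_error(layer_stack(list(a = matrix(1, 2, 2)), roles = "Z"), "role tags")
  expect_error(layer_stack(list(a = matrix(1, 2, 2), b = matrix(1, 3, 2)),
                           roles = c("L", "A")), "co-registration")
  stk <- layer_stack(list(a = matrix(1, 2, 2), b = matrix(2, 2, 2)),
                     roles = c("L", "A"))
  expect_equal(subset_roles(stk, "A")$names, "b")
  expect_error(subset_roles(stk, "T"), "configuration error")
})

test_that("ASCII grid and CSV sample tables round-trip", {
  set.seed(4)
  m <- matrix(rnorm(30), 5, 6)
  m[2, 3] <- NA
  r <- raster_grid(m, pixel_size = 100, origin = c(500, 1200))
  path <- tempfile(fileext = ".asc")
  write_ascii_grid(r, path)
  back <- read_ascii_grid(path)
  expect_equal(back$values, m, tolerance = 1e-8)
  expect_equal(back$pixel_size, 100)
  expect_equal(back$origin, c(500, 1200))

  ls <- small_landscape(seed = 3, nrow = 40, ncol = 40)
  s <- extract_samples(ls$stack, ls$mch, 25, seed = 1)
  csv <- tempfile(fileext = ".csv")
  write_samples(s, csv)
  s2 <- read_samples(csv)
  expect_equal(attr(s2, "predictors"), attr(s, "predictors"))
  expect_equal(sample_predictors(s2), sample_predictors(s), tolerance = 1e-12)
})
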