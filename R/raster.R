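#' Create a single-band raster grid
#'
#' A minimal in-memory raster: a numeric matrix plus a square pixel size and
#' the coordinate of the grid's lower-left corner. Invalid (nodata) cells are
#' stored as `NA` and are excluded from every statistic computed downstream.
#' Row 1 is the top row of the scene (image convention); pixel `(r, c)` covers
#' the half-open square whose centre is returned by [pixel_centers()].
#'
#' @param values Numeric matrix of cell values (`NA` = invalid).
#' @param pixel_size Side length of a pixel in metres (> 0).
#' @param origin Length-2 numeric, `c(x, y)` of the lower-left corner in metres.
#' @return An object of class `mch_raster`.
#' @export
raster_grid <- function(values, pixel_size = 100, origin = c(0, 0)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("invalid input: raster must have at least one cell", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("invalid parameter: `pixel_size` must be a positive scalar", call. = FALSE)
  structure(
    list(values = values, pixel_size = as.numeric(pixel_size),
         origin = as.numeric(origin)),
    class = "mch_raster"
  )
}

#' @export
print.mch_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<mch_raster> %d x %d, pixel %g m, %d valid / %d cells\n",
              nrow(v), ncol(v), x$pixel_size, sum(!is.na(v)), length(v)))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  if (is.finite(rng[1])) cat(sprintf("  range: [%.3g, %.3g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Pixel-centre coordinates of a raster
#'
#' @param raster An `mch_raster`.
#' @param rows,cols Integer vectors of (matching) row/column indices.
#' @return Two-column matrix of x, y coordinates in metres.
#' @export
pixel_centers <- function(raster, rows, cols) {
  s <- raster$pixel_size
  nr <- nrow(raster$values)
  cbind(x = raster$origin[1] + (cols - 0.5) * s,
        y = raster$origin[2] + (nr - rows + 0.5) * s)
}

#' Aggregate a fine raster to a coarser resolution by block averaging
#'
#' Each coarse cell is the arithmetic mean of the valid fine cells in its
#' `factor` x `factor` block (e.g. a 1 m canopy height model averaged to 100 m
#' mean canopy height with `factor = 100`). A coarse cell is invalid only when
#' its whole block is invalid. Trailing rows/columns that do not fill a
#' complete block are dropped with a message.
#'
#' @param fine An `mch_raster`.
#' @param factor Positive integer aggregation factor.
#' @return An `mch_raster` with pixel size `factor * fine$pixel_size`.
#' @export
aggregate_mean <- function(fine, factor) {
  stopifnot(inherits(fine, "mch_raster"))
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor))
    stop("invalid parameter: `factor` must be a positive integer", call. = FALSE)
  factor <- as.integer(factor)
  v <- fine$values
  if (all(dim(v) < factor))
    stop("invalid input: raster smaller than one aggregation block", call. = FALSE)
  nr <- (nrow(v) %/% factor) * factor
  nc <- (ncol(v) %/% factor) * factor
  if (nr < nrow(v) || nc < ncol(v))
    message(sprintf("aggregate_mean: dropping %d trailing row(s) and %d column(s) (partial blocks)",
                    nrow(v) - nr, ncol(v) - nc))
  v <- v[seq_len(nr), seq_len(nc), drop = FALSE]
  # group-sum both values and validity, then divide
  rgrp <- rep(seq_len(nr %/% factor), each = factor)
  cgrp <- rep(seq_len(nc %/% factor), each = factor)
  ok <- !is.na(v)
  v0 <- v
  v0[!ok] <- 0
  sums <- rowsum(t(rowsum(v0, rgrp)), cgrp)            # coarse-cols x coarse-rows
  cnts <- rowsum(t(rowsum(ok + 0, rgrp)), cgrp)
  out <- t(sums / cnts)                                 # NaN where count 0
  out[t(cnts) == 0] <- NA
  dimnames(out) <- NULL
  # origin: top-left of the kept area coincides with the fine top-left; since
  # trailing (bottom/right) blocks are dropped, the lower-left corner shifts up
  new_origin <- c(fine$origin[1],
                  fine$origin[2] + (nrow(fine$values) - nr) * fine$pixel_size)
  raster_grid(out, pixel_size = fine$pixel_size * factor, origin = new_origin)
}

#' Mask a canopy-height raster by land cover and a minimum-height rule
#'
#' Keeps only pixels that are vegetated according to `landcover_mask`
#' (non-zero = vegetated) and whose height exceeds `min_height` (strict,
#' default 1 m). Counts of pixels removed by each rule are attached as the
#' `"removed"` attribute (a pixel already invalid in the input is counted by
#' neither rule; a pixel failing both rules is counted under land cover).
#'
#' @param mch Response raster (metres).
#' @param landcover_mask Co-registered raster; non-zero/non-`NA` = vegetated.
#' @param min_height Strict lower bound in metres (default 1).
#' @return The masked `mch_raster`, with attribute
#'   `removed = c(landcover = ..., min_height = ...)`.
#' @export
apply_validity_mask <- function(mch, landcover_mask, min_height = 1.0) {
  stopifnot(inherits(mch, "mch_raster"), inherits(landcover_mask, "mch_raster"))
  if (!identical(dim(mch$values), dim(landcover_mask$values)) ||
      !isTRUE(all.equal(mch$pixel_size, landcover_mask$pixel_size)))
    stop("co-registration error: mch and landcover_mask grids differ", call. = FALSE)
  v <- mch$values
  valid_in <- !is.na(v)
  veg <- !is.na(landcover_mask$values) & landcover_mask$values != 0
  rm_lc <- valid_in & !veg
  rm_ht <- valid_in & veg & v <= min_height
  v[rm_lc | rm_ht] <- NA
  out <- raster_grid(v, mch$pixel_size, mch$origin)
  attr(out, "removed") <- c(landcover = sum(rm_lc), min_height = sum(rm_ht))
  out
}

#' Assemble co-registered predictor bands into a layer stack
#'
#' @param bands Named list of `mch_raster` objects (or numeric matrices, which
#'   inherit grid geometry from the first raster / the `pixel_size` argument).
#' @param roles Character vector of per-band role tags, one of `"L"` (optical),
#'   `"A"` (radar backscatter), `"S"` (elevation), `"T"` (texture).
#' @param pixel_size,origin Grid geometry, used when all bands are plain matrices.
#' @return An object of class `mch_stack`.
#' @export
layer_stack <- function(bands, roles, pixel_size = 100, origin = c(0, 0)) {
  if (length(bands) == 0L) stop("invalid input: empty stack", call. = FALSE)
  if (length(roles) != length(bands))
    stop("`roles` must match `bands` in length", call. = FALSE)
  if (!all(roles %in% c("L", "A", "S", "T")))
    stop("role tags must be in {L, A, S, T}", call. = FALSE)
  nm <- names(bands)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    stop("`bands` must be a fully named list", call. = FALSE)
  first <- bands[[1]]
  if (inherits(first, "mch_raster")) {
    pixel_size <- first$pixel_size
    origin <- first$origin
  }
  mats <- lapply(bands, function(b) if (inherits(b, "mch_raster")) b$values else b)
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("co-registration error: bands differ in shape", call. = FALSE)
  structure(
    list(bands = mats, roles = as.character(roles), names = nm,
         pixel_size = pixel_size, origin = origin),
    class = "mch_stack"
  )
}

#' @export
print.mch_stack <- function(x, ...) {
  cat(sprintf("<mch_stack> %d band(s), %d x %d, pixel %g m\n",
              length(x$bands), nrow(x$bands[[1]]), ncol(x$bands[[1]]),
              x$pixel_size))
  cat("  roles:", paste(sprintf("%s=%d", names(table(x$roles)), table(x$roles)),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Joint validity mask of a stack (and optionally a response raster)
#'
#' @param stack An `mch_stack`.
#' @param response Optional co-registered `mch_raster`.
#' @return Logical matrix, `TRUE` where every band (and the response) is valid.
#' @export
stack_valid_mask <- function(stack, response = NULL) {
  ok <- Reduce(`&`, lapply(stack$bands, function(m) !is.na(m)))
  if (!is.null(response)) {
    if (!identical(dim(response$values), dim(ok)))
      stop("co-registration error: response grid differs from stack", call. = FALSE)
    ok <- ok & !is.na(response$values)
  }
  ok
}

#' Select stack bands by role
#'
#' @param stack An `mch_stack`.
#' @param roles Character vector of roles to keep, e.g. `c("L", "A")`.
#' @return An `mch_stack` restricted to those roles.
#' @export
subset_roles <- function(stack, roles) {
  keep <- stack$roles %in% roles
  if (!any(keep))
    stop(sprintf("configuration error: no band with role(s) %s in stack",
                 paste(setdiff(roles, stack$roles), collapse = ", ")), call. = FALSE)
  structure(
    list(bands = stack$bands[keep], roles = stack$roles[keep],
         names = stack$names[keep], pixel_size = stack$pixel_size,
         origin = stack$origin),
    class = "mch_stack"
  )
}

#' Draw training/test samples from a stack and response raster
#'
#' Samples `n` jointly valid pixels uniformly without replacement and returns
#' a sample table: one row per pixel with grid indices, pixel-centre
#' coordinates, the response value, and one column per predictor band.
#'
#' @param stack An `mch_stack` of predictors.
#' @param response Co-registered `mch_raster` (e.g. MCH in metres).
#' @param n Number of pixels to draw; `NULL` takes every valid pixel (in
#'   random order).
#' @param seed Integer seed; sampling is reproducible given the seed.
#' @return A `data.frame` with columns `row`, `col`, `x`, `y`, `response`,
#'   then predictor bands; attribute `"predictors"` holds the band names.
#' @export
extract_samples <- function(stack, response, n = NULL, seed = 1L) {
  ok <- stack_valid_mask(stack, response)
  idx <- which(ok)
  if (is.null(n)) n <- length(idx)
  if (n > length(idx))
    stop(sprintf("sampling error: requested %d samples but only %d valid pixels",
                 n, length(idx)), call. = FALSE)
  set.seed(seed)
  take <- sample(idx, n)
  nr <- nrow(response$values)
  rows <- ((take - 1L) %% nr) + 1L
  cols <- ((take - 1L) %/% nr) + 1L
  xy <- pixel_centers(response, rows, cols)
  out <- data.frame(row = rows, col = cols, x = xy[, 1], y = xy[, 2],
                    response = response$values[take])
  for (i in seq_along(stack$bands)) out[[stack$names[i]]] <- stack$bands[[i]][take]
  attr(out, "predictors") <- stack$names
  out
}

#' Predictor matrix of a sample table
#'
#' @param samples A sample table from [extract_samples()] or
#'   [generate_simulation()].
#' @return Numeric matrix of the predictor columns.
#' @export
sample_predictors <- function(samples) {
  pn <- attr(samples, "predictors")
  if (is.null(pn)) pn <- setdiff(names(samples), c("row", "col", "x", "y", "response"))
  as.matrix(samples[, pn, drop = FALSE])
}

#' Flatten all valid pixels of a stack into a prediction table
#'
#' @inheritParams extract_samples
#' @return As [extract_samples()] but covering every valid pixel in grid order
#'   (response column included when `response` is given).
#' @export
stack_pixels <- function(stack, response = NULL) {
  ok <- stack_valid_mask(stack, response)
  idx <- which(ok)
  nr <- nrow(stack$bands[[1]])
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  ref <- raster_grid(stack$bands[[1]], stack$pixel_size, stack$origin)
  xy <- pixel_centers(ref, rows, cols)
  out <- data.frame(row = rows, col = cols, x = xy[, 1], y = xy[, 2])
  if (!is.null(response)) out$response <- response$values[idx]
  for (i in seq_along(stack$bands)) out[[stack$names[i]]] <- stack$bands[[i]][idx]
  attr(out, "predictors") <- stack$names
  out
}

# ---- plain-text raster and table I/O ---------------------------------------

#' Write a raster as an ESRI ASCII grid
#'
#' @param raster An `mch_raster`.
#' @param path Output file path.
#' @param nodata Value written for invalid cells (default -9999).
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999) {
  v <- raster$values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", raster$origin[1]),
    sprintf("yllcorner %.10g", raster$origin[2]),
    sprintf("cellsize %.10g", raster$pixel_size),
    sprintf("NODATA_value %.10g", nodata)
  )
  body <- apply(v, 1L, function(r) paste(format(r, trim = TRUE, digits = 10),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File path.
#' @return An `mch_raster`; cells equal to the file's nodata value become `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  nr <- as.integer(val["nrows"]); nc <- as.integer(val["ncols"])
  dat <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(dat) != nr * nc)
    stop("invalid input: grid body does not match header dimensions", call. = FALSE)
  m <- matrix(dat, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == val["nodata_value"]] <- NA
  raster_grid(m, pixel_size = val["cellsize"],
              origin = c(val["xllcorner"], val["yllcorner"]))
}

#' Write / read a sample table as CSV
#'
#' The predictor band names are recovered from the column order on read
#' (everything after `response`).
#'
#' @param samples Sample table.
#' @param path File path.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  s <- utils::read.csv(path)
  meta <- c("row", "col", "x", "y", "response")
  attr(s, "predictors") <- setdiff(names(s), meta)
  s
}
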