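# Separable windowed convolution. `k` is the 1-D kernel (odd length); values
# outside the grid contribute 0, so pairing a pass over the data with a pass
# over the validity indicator yields mask-aware renormalized filters.
conv1d_cols <- function(m, k) {
  h <- (length(k) - 1L) %/% 2L
  nc <- ncol(m)
  out <- matrix(0, nrow(m), nc)
  for (d in -h:h) {
    w <- k[d + h + 1L]
    if (w == 0) next
    src <- seq_len(nc) + d
    keep <- src >= 1L & src <= nc
    out[, keep] <- out[, keep] + w * m[, src[keep], drop = FALSE]
  }
  out
}

conv2d_sep <- function(m, k) t(conv1d_cols(t(conv1d_cols(m, k)), k))

gaussian_kernel_1d <- function(window, sigma) {
  h <- (window - 1L) %/% 2L
  exp(-(seq(-h, h))^2 / (2 * sigma^2))   # unnormalized; normalization is per-pixel
}

check_window <- function(window) {
  if (!is.numeric(window) || length(window) != 1L || window < 3 ||
      window %% 2 == 0)
    stop("invalid parameter: `window` must be an odd integer >= 3", call. = FALSE)
  as.integer(window)
}

as_band_matrix <- function(band) {
  if (inherits(band, "mch_raster")) band$values
  else if (is.matrix(band)) band
  else stop("`band` must be an mch_raster or a matrix", call. = FALSE)
}

wrap_like <- function(values, band) {
  if (inherits(band, "mch_raster"))
    raster_grid(values, band$pixel_size, band$origin)
  else values
}

#' Gaussian-weighted texture layer
#'
#' Convolves a band with a truncated Gaussian window: the output at a pixel is
#' the weighted mean of its `window` x `window` neighbourhood with weights
#' `exp(-(x^2 + y^2) / (2 sigma^2))`, normalized to sum to one over the
#' in-grid, valid part of the window. Invalid neighbours are excluded and the
#' remaining weights renormalized; a pixel whose whole window is invalid stays
#' invalid.
#'
#' @param band An `mch_raster` or numeric matrix (`NA` = invalid).
#' @param window Odd window side length (pixels).
#' @param sigma Gaussian standard deviation (pixels).
#' @return Filtered band of the same type and shape as the input.
#' @export
gaussian_texture <- function(band, window, sigma) {
  window <- check_window(window)
  if (!is.numeric(sigma) || sigma <= 0)
    stop("invalid parameter: `sigma` must be positive", call. = FALSE)
  m <- as_band_matrix(band)
  k <- gaussian_kernel_1d(window, sigma)
  ok <- !is.na(m)
  m0 <- m
  m0[!ok] <- 0
  num <- conv2d_sep(m0, k)
  den <- conv2d_sep(ok + 0, k)
  out <- num / den
  out[den <= 0] <- NA
  out[!ok] <- NA
  wrap_like(out, band)
}

#' Local standard deviation texture layer
#'
#' The population standard deviation (divide-by-N) of the valid values in each
#' pixel's `window` x `window` neighbourhood.
#'
#' @inheritParams gaussian_texture
#' @return Filtered band of the same type and shape as the input.
#' @export
local_sd_texture <- function(band, window) {
  window <- check_window(window)
  m <- as_band_matrix(band)
  k <- rep(1, window)
  ok <- !is.na(m)
  m0 <- m
  m0[!ok] <- 0
  s1 <- conv2d_sep(m0, k)
  s2 <- conv2d_sep(m0^2, k)
  n <- conv2d_sep(ok + 0, k)
  mu <- s1 / n
  v <- s2 / n - mu^2
  v[v < 0] <- 0                      # guard tiny negative round-off
  out <- sqrt(v)
  out[n <= 0] <- NA
  out[!ok] <- NA
  wrap_like(out, band)
}

#' Texture specification
#'
#' Default scales follow common practice for 100 m canopy mapping stacks:
#' windows 5/9/17/33 pixels with Gaussian sigma 1/2/4/8.
#'
#' @param window_sizes Odd window side lengths (pixels).
#' @param sigmas Gaussian standard deviations, one per window.
#' @param include_local_sd Also compute a local-SD layer per window?
#' @return An object of class `mch_texture_spec`.
#' @export
texture_spec <- function(window_sizes = c(5, 9, 17, 33),
                         sigmas = c(1, 2, 4, 8),
                         include_local_sd = TRUE) {
  if (length(window_sizes) != length(sigmas))
    stop("`window_sizes` and `sigmas` must have equal length", call. = FALSE)
  for (w in window_sizes) check_window(w)
  if (any(sigmas <= 0)) stop("all sigmas must be positive", call. = FALSE)
  structure(list(window_sizes = as.integer(window_sizes), sigmas = sigmas,
                 include_local_sd = isTRUE(include_local_sd)),
            class = "mch_texture_spec")
}

#' Append multi-scale texture layers to a stack
#'
#' For every existing non-texture band, adds one Gaussian layer per
#' (window, sigma) pair and, when `spec$include_local_sd`, one local-SD layer
#' per window. New bands are tagged with role `"T"` and named
#' `<band>_gauss_w<window>_s<sigma>` / `<band>_sd_w<window>`.
#'
#' @param stack An `mch_stack`.
#' @param spec An [texture_spec()].
#' @return The input stack with texture bands appended.
#' @export
build_texture_stack <- function(stack, spec = texture_spec()) {
  stopifnot(inherits(stack, "mch_stack"), inherits(spec, "mch_texture_spec"))
  src <- which(stack$roles != "T")
  bands <- stack$bands; roles <- stack$roles; nms <- stack$names
  for (i in src) {
    b <- stack$bands[[i]]
    for (j in seq_along(spec$window_sizes)) {
      w <- spec$window_sizes[j]; s <- spec$sigmas[j]
      bands[[length(bands) + 1L]] <- gaussian_texture(b, w, s)
      roles <- c(roles, "T")
      nms <- c(nms, sprintf("%s_gauss_w%d_s%g", stack$names[i], w, s))
    }
    if (spec$include_local_sd) {
      for (w in spec$window_sizes) {
        bands[[length(bands) + 1L]] <- local_sd_texture(b, w)
        roles <- c(roles, "T")
        nms <- c(nms, sprintf("%s_sd_w%d", stack$names[i], w))
      }
    }
  }
  names(bands) <- nms
  structure(list(bands = bands, roles = roles, names = nms,
                 pixel_size = stack$pixel_size, origin = stack$origin),
            class = "mch_stack")
}
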