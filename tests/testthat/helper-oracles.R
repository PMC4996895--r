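# Brute-force reference implementations used as independent oracles.
# Deliberately written as direct double loops over window offsets / point
# pairs, sharing no code with the package internals.

oracle_gaussian_texture <- function(m, window, sigma) {
  h <- (window - 1) %/% 2
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(m[r, c])) next
    wsum <- 0; vsum <- 0
    for (dx in -h:h) for (dy in -h:h) {
      rr <- r + dx; cc <- c + dy
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (is.na(m[rr, cc])) next
      w <- exp(-(dx^2 + dy^2) / (2 * sigma^2))
      wsum <- wsum + w
      vsum <- vsum + w * m[rr, cc]
    }
    if (wsum > 0) out[r, c] <- vsum / wsum
  }
  out
}

oracle_local_sd <- function(m, window) {
  h <- (window - 1) %/% 2
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(m[r, c])) next
    vals <- c()
    for (dx in -h:h) for (dy in -h:h) {
      rr <- r + dx; cc <- c + dy
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (!is.na(m[rr, cc])) vals <- c(vals, m[rr, cc])
    }
    if (length(vals) > 0) {
      mu <- mean(vals)
      out[r, c] <- sqrt(mean((vals - mu)^2))   # population form
    }
  }
  out
}

oracle_variogram <- function(coords, values, max_lag, n_bins) {
  n <- length(values)
  width <- max_lag / n_bins
  ssum <- numeric(n_bins); cnt <- integer(n_bins)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (d <= 0 || d > max_lag) next
    b <- max(1L, as.integer(ceiling(d / width)))
    ssum[b] <- ssum[b] + (values[i] - values[j])^2
    cnt[b] <- cnt[b] + 1L
  }
  gamma <- ifelse(cnt > 0, ssum / (2 * cnt), NA_real_)
  data.frame(lag = (seq_len(n_bins) - 0.5) * width, gamma = gamma,
             n_pairs = cnt)
}

oracle_block_mean <- function(m, f) {
  nr <- (nrow(m) %/% f); nc <- (ncol(m) %/% f)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    blk <- m[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)]
    if (any(!is.na(blk))) out[i, j] <- mean(blk, na.rm = TRUE)
  }
  out
}

# small fully valid landscape for fast model tests
small_landscape <- function(seed = 42, nrow = 90, ncol = 90) {
  generate_landscape(landscape_config(nrow = nrow, ncol = ncol, seed = seed))
}
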