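# Independent oracles used by the derived-value tests. These deliberately
# use naive loops / exhaustive enumeration, not the package's code paths.

# Per-cell nearest-reservoir + ring classification by explicit loop.
oracle_assign <- function(cells, layout, max_extent, depth) {
  layout <- layout[order(layout$reservoir_id), ]
  res <- data.frame(reservoir_id = rep(NA, nrow(cells)), ring = NA_integer_)
  for (i in seq_len(nrow(cells))) {
    d <- sqrt((layout$x - cells$x[i])^2 + (layout$y - cells$y[i])^2)
    j <- which.min(d) # first minimum = lowest reservoir_id after sorting
    if (d[j] < max_extent) {
      res$reservoir_id[i] <- layout$reservoir_id[j]
      res$ring[i] <- floor(d[j] / depth)
    }
  }
  res
}

# Exhaustive hypergeometric upper tail: enumerate all size-n draws from the
# universe and count those overlapping the set by >= k.
oracle_hyper_tail <- function(N, set_size, n_sig, k) {
  draws <- utils::combn(N, n_sig)
  hits <- apply(draws, 2, function(d) sum(d <= set_size) >= k)
  mean(hits)
}

# Closed-form two-sample (pooled or Welch) and one-sample t p-values.
oracle_t2 <- function(x, y, var_equal = TRUE) {
  n1 <- length(x); n2 <- length(y)
  if (var_equal) {
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- var(x) / n1 + var(y) / n2
    t <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((var(x) / n1)^2 / (n1 - 1) + (var(y) / n2)^2 / (n2 - 1))
  }
  2 * stats::pt(-abs(t), df)
}

oracle_t1 <- function(d) {
  t <- mean(d) / (sd(d) / sqrt(length(d)))
  2 * stats::pt(-abs(t), length(d) - 1)
}

# Fine-grid rasterization of annulus-in-rectangle area (mm^2).
oracle_raster_area <- function(center, inner, outer, bounds, step = 1) {
  xs <- seq(max(bounds[1], center[1] - outer) + step / 2,
            min(bounds[3], center[1] + outer), by = step)
  ys <- seq(max(bounds[2], center[2] - outer) + step / 2,
            min(bounds[4], center[2] + outer), by = step)
  d2 <- outer(ys - center[2], xs - center[1], function(a, b) a * a + b * b)
  sum(d2 >= inner^2 & d2 < outer^2) * step^2 / 1e6
}

# Direct per-pixel kernel-mass evaluation (double loop over pixels, sum over
# cells), with the same unit-mass-per-cell edge correction contract.
oracle_density_map <- function(cells, grid, bandwidth) {
  cx <- grid$origin[1] + (seq_len(grid$nx) - 0.5) * grid$pixel_size
  cy <- grid$origin[2] + (seq_len(grid$ny) - 0.5) * grid$pixel_size
  h <- grid$pixel_size / 2
  # per-cell in-grid mass for normalization
  tot <- numeric(nrow(cells))
  for (c in seq_len(nrow(cells))) {
    mx <- pnorm((max(cx) + h - cells$x[c]) / bandwidth) -
      pnorm((min(cx) - h - cells$x[c]) / bandwidth)
    my <- pnorm((max(cy) + h - cells$y[c]) / bandwidth) -
      pnorm((min(cy) - h - cells$y[c]) / bandwidth)
    tot[c] <- mx * my
  }
  v <- matrix(0, grid$ny, grid$nx)
  for (i in seq_len(grid$ny)) for (j in seq_len(grid$nx)) {
    s <- 0
    for (c in seq_len(nrow(cells))) {
      mx <- pnorm((cx[j] + h - cells$x[c]) / bandwidth) -
        pnorm((cx[j] - h - cells$x[c]) / bandwidth)
      my <- pnorm((cy[i] + h - cells$y[c]) / bandwidth) -
        pnorm((cy[i] - h - cells$y[c]) / bandwidth)
      s <- s + mx * my / tot[c]
    }
    v[i, j] <- s / (grid$pixel_size^2 / 1e6)
  }
  v
}

# Small ion image built by hand for extraction tests.
make_test_image <- function(nx, ny, pixel_size, channels) {
  counts <- array(0, dim = c(ny, nx, length(channels)),
                  dimnames = list(NULL, NULL, names(channels)))
  for (m in names(channels)) counts[, , m] <- channels[[m]]
  structure(list(pixel_size = pixel_size, origin = c(0, 0), nx = nx, ny = ny,
                 metabolites = names(channels), counts = counts),
            class = "ion_image")
}
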