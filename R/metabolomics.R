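# Marker-guided paired-ROI spatial metabolomics: density maps, hotspot
# detection, equal-area pairing, ion-count extraction, paired statistics,
# pathway over-representation, signature matrices and opposite-trend calls.

pixel_centers <- function(g) {
  list(x = g$origin[1] + (seq_len(g$nx) - 0.5) * g$pixel_size,
       y = g$origin[2] + (seq_len(g$ny) - 0.5) * g$pixel_size)
}

#' Kernel-smoothed marker density map on an ion-image grid
#'
#' Places a Gaussian kernel of the given bandwidth at every marker-positive
#' cell and accumulates, per pixel, the kernel mass falling in that pixel
#' (separable CDF differences). Each cell's in-grid mass is renormalized to
#' exactly 1 (edge correction), so the map integrates to the total
#' marker-positive cell count. Values are densities in cells/mm^2.
#'
#' @param cells Cell table with `x`, `y` and marker flag columns.
#' @param marker Marker column used to select cells.
#' @param grid An `ion_image` (or any list with `pixel_size`, `origin`,
#'   `nx`, `ny`) defining the target grid.
#' @param bandwidth Gaussian kernel sd in micrometres (> 0).
#' @return A `density_map`: list with `values` (ny x nx matrix), grid fields,
#'   `marker`, `n_cells` and `bandwidth`.
#' @export
density_map <- function(cells, marker, grid, bandwidth = 200) {
  check_number(bandwidth, "bandwidth", lower = 0, strict_lower = TRUE)
  if (!marker %in% names(cells)) schema_error("cell table has no column '", marker, "'")
  sel <- cells[cells[[marker]], , drop = FALSE]
  ctr <- pixel_centers(grid)
  px <- grid$pixel_size
  out <- structure(list(values = matrix(0, grid$ny, grid$nx),
                        pixel_size = px, origin = grid$origin,
                        nx = grid$nx, ny = grid$ny, marker = marker,
                        n_cells = nrow(sel), bandwidth = bandwidth),
                   class = "density_map")
  if (nrow(sel) == 0L) {
    warning("no ", marker, "-positive cells: density map is all zero")
    return(out)
  }
  # per-pixel kernel mass along each axis (nx x n and ny x n)
  mx <- stats::pnorm(outer(ctr$x + px / 2, sel$x, "-") / bandwidth) -
    stats::pnorm(outer(ctr$x - px / 2, sel$x, "-") / bandwidth)
  my <- stats::pnorm(outer(ctr$y + px / 2, sel$y, "-") / bandwidth) -
    stats::pnorm(outer(ctr$y - px / 2, sel$y, "-") / bandwidth)
  scale <- 1 / (colSums(mx) * colSums(my)) # edge correction: unit mass per cell
  mass <- my %*% (t(mx) * scale)
  out$values <- mass / (px * px / 1e6)
  out
}

#' Detect marker hotspots as fixed-area discs
#'
#' Thresholds the density map at its `quantile` (strictly above), labels
#' connected components, drops components smaller than `min_area`, and
#' converts each surviving component to a disc of radius `disc_radius` at
#' the component's density-weighted centroid, so paired ROIs of exactly
#' equivalent area can be constructed downstream.
#'
#' @param map A [density_map()].
#' @param cells Optional cell table used to count marker-positive cells
#'   inside each disc.
#' @param quantile Density quantile in (0, 1) defining the super-level set.
#' @param min_area Minimum component area in mm^2; the default rejects the
#'   single-cell density bumps of a sparse background while keeping any
#'   component of a plausible cluster scale (a 400 um disc is ~0.5 mm^2).
#' @param disc_radius Output disc radius in micrometres.
#' @return A `hotspot_rois` data.frame: roi_id, x, y, radius, area_mm2,
#'   n_pixels, marker, marker_count.
#' @export
detect_hotspots <- function(map, cells = NULL, quantile = 0.95,
                            min_area = 0.2, disc_radius = 400) {
  if (!is.numeric(quantile) || length(quantile) != 1L || quantile <= 0 || quantile >= 1)
    validation_error("quantile must lie strictly inside (0, 1)")
  v <- map$values
  thr <- stats::quantile(v, quantile)
  mask <- v > thr
  empty <- data.frame(roi_id = integer(0), x = numeric(0), y = numeric(0),
                      radius = numeric(0), area_mm2 = numeric(0),
                      n_pixels = integer(0), marker = character(0),
                      marker_count = numeric(0))
  class(empty) <- c("hotspot_rois", class(empty))
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(mask * 1)
  lab <- as.matrix(lab)
  ctr <- pixel_centers(map)
  px_area <- map$pixel_size^2 / 1e6
  rows <- list()
  for (l in seq_len(max(lab))) {
    idx <- which(lab == l, arr.ind = TRUE)
    if (nrow(idx) * px_area < min_area) next
    w <- v[idx]
    cx <- sum(ctr$x[idx[, 2]] * w) / sum(w)
    cy <- sum(ctr$y[idx[, 1]] * w) / sum(w)
    cnt <- NA_real_
    if (!is.null(cells)) {
      pos <- cells[cells[[map$marker]], , drop = FALSE]
      cnt <- sum((pos$x - cx)^2 + (pos$y - cy)^2 <= disc_radius^2)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      roi_id = length(rows) + 1L, x = cx, y = cy, radius = disc_radius,
      area_mm2 = pi * disc_radius^2 / 1e6, n_pixels = nrow(idx),
      marker = map$marker, marker_count = cnt)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  class(out) <- c("hotspot_rois", class(out))
  out
}

count_in_disc <- function(cells, marker, cx, cy, r) {
  pos <- cells[cells[[marker]], , drop = FALSE]
  sum((pos$x - cx)^2 + (pos$y - cy)^2 <= r^2)
}

#' Pair each hotspot with a nearby equal-area marker-low region
#'
#' Hotspots are processed by descending marker count (ties by `roi_id`).
#' For each, candidate discs of identical radius are scanned outward by
#' increasing centroid distance (then by angle); the nearest candidate that
#' (a) does not overlap any hotspot disc or previously accepted region,
#' (b) lies fully inside the grid and within `max_separation`, and (c)
#' satisfies `log2((n_high + pseudocount) / (n_low + pseudocount)) >=
#' min_fold` is accepted. Hotspots with no valid candidate are dropped from
#' pairing and listed in the `skipped` attribute.
#'
#' @param hotspots A [detect_hotspots()] result.
#' @param cells Cell table for marker counting.
#' @param grid The ion image (defines the admissible region).
#' @param min_fold Minimum high-vs-low log2 fold change of marker counts.
#' @param max_separation Maximum centroid separation in micrometres.
#' @param pseudocount Added to both counts before the ratio.
#' @param n_angles Candidate directions per search radius.
#' @param step Radial search step in micrometres (default: one pixel).
#' @return A `roi_pairs` data.frame, one row per accepted pair.
#' @export
pair_rois <- function(hotspots, cells, grid, min_fold = 0.5,
                      max_separation = 3000, pseudocount = 0.5,
                      n_angles = 16L, step = NULL) {
  empty <- data.frame(pair_id = integer(0), marker = character(0),
                      high_id = integer(0), high_x = numeric(0), high_y = numeric(0),
                      count_high = numeric(0), low_x = numeric(0), low_y = numeric(0),
                      count_low = numeric(0), radius = numeric(0),
                      area_mm2 = numeric(0), area_ratio = numeric(0),
                      count_log2fc = numeric(0), separation = numeric(0))
  class(empty) <- c("roi_pairs", class(empty))
  if (nrow(hotspots) == 0L) return(empty)
  if (is.null(step)) step <- grid$pixel_size
  marker <- hotspots$marker[1]
  if (any(is.na(hotspots$marker_count)))
    hotspots$marker_count <- vapply(seq_len(nrow(hotspots)), function(i)
      count_in_disc(cells, marker, hotspots$x[i], hotspots$y[i], hotspots$radius[i]),
      numeric(1))
  ord <- order(-hotspots$marker_count, hotspots$roi_id)
  hotspots <- hotspots[ord, , drop = FALSE]
  bounds <- c(grid$origin[1], grid$origin[2],
              grid$origin[1] + grid$nx * grid$pixel_size,
              grid$origin[2] + grid$ny * grid$pixel_size)
  blocked <- hotspots[, c("x", "y", "radius")]
  rows <- list(); skipped <- integer(0)
  angles <- (seq_len(n_angles) - 1L) * 2 * pi / n_angles
  for (i in seq_len(nrow(hotspots))) {
    h <- hotspots[i, ]
    nh <- h$marker_count
    found <- FALSE
    radii <- seq(2 * h$radius + step, max_separation, by = step)
    for (d in radii) {
      for (a in angles) {
        cx <- h$x + d * cos(a); cy <- h$y + d * sin(a)
        if (cx - h$radius < bounds[1] || cx + h$radius > bounds[3] ||
            cy - h$radius < bounds[2] || cy + h$radius > bounds[4]) next
        sep2 <- (blocked$x - cx)^2 + (blocked$y - cy)^2
        if (any(sep2 < (blocked$radius + h$radius)^2)) next
        nl <- count_in_disc(cells, marker, cx, cy, h$radius)
        fc <- log2((nh + pseudocount) / (nl + pseudocount))
        if (fc >= min_fold) {
          rows[[length(rows) + 1L]] <- data.frame(
            pair_id = length(rows) + 1L, marker = marker, high_id = h$roi_id,
            high_x = h$x, high_y = h$y, count_high = nh,
            low_x = cx, low_y = cy, count_low = nl, radius = h$radius,
            area_mm2 = pi * h$radius^2 / 1e6, area_ratio = 1,
            count_log2fc = fc, separation = d)
          blocked <- rbind(blocked, data.frame(x = cx, y = cy, radius = h$radius))
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (!found) skipped <- c(skipped, h$roi_id)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  if (length(skipped))
    message("pair_rois: no valid low-region candidate for hotspot(s) ",
            paste(skipped, collapse = ", "))
  attr(out, "skipped") <- skipped
  class(out) <- c("roi_pairs", class(out))
  out
}

#' Extract raw ion counts of every metabolite inside a disc ROI
#'
#' Sums counts over pixels whose centres fall in the disc (centre distance
#' <= radius); the mean is the total divided by the pixel count.
#'
#' @param image An `ion_image`.
#' @param roi List or one-row data.frame with `x`, `y`, `radius` (um).
#' @return data.frame: metabolite, total, mean, n_pixels.
#' @export
extract_ion_counts <- function(image, roi) {
  ctr <- pixel_centers(image)
  d2 <- outer((ctr$y - roi$y)^2, (ctr$x - roi$x)^2, "+")
  inside <- d2 <= roi$radius^2
  n_px <- sum(inside)
  if (n_px == 0L)
    validation_error("ROI does not cover any pixel centre of the ion-image grid")
  totals <- vapply(image$metabolites, function(m) sum(image$counts[, , m][inside]),
                   numeric(1))
  data.frame(metabolite = image$metabolites, total = unname(totals),
             mean = unname(totals) / n_px, n_pixels = n_px, row.names = NULL)
}

#' Paired differential abundance of metabolites across ROI pairs
#'
#' For every metabolite: per-pair log2 fold change of mean raw ion counts
#' (high vs low, pseudocount added to both means), then a paired two-tailed
#' t-test of the per-pair fold changes against 0. Raw p-values drive the
#' per-metabolite significance flag at 0.05 (matching how single-metabolite
#' panels are reported); BH-adjusted p-values are exported alongside for the
#' enrichment step.
#'
#' @param pairs A [pair_rois()] result (>= 2 pairs).
#' @param image The `ion_image` the pairs live on.
#' @param pseudocount Added to both mean counts before the log ratio.
#' @param alpha Significance level for the flag.
#' @return A `metabolite_stats` data.frame: metabolite, mean_log2fc,
#'   p_value, adjusted_p, significant, n_pairs.
#' @export
paired_stats <- function(pairs, image, pseudocount = 0.5, alpha = 0.05) {
  if (nrow(pairs) < 2L) validation_error("paired statistics need at least 2 ROI pairs")
  fc <- vapply(seq_len(nrow(pairs)), function(i) {
    hi <- extract_ion_counts(image, list(x = pairs$high_x[i], y = pairs$high_y[i],
                                         radius = pairs$radius[i]))
    lo <- extract_ion_counts(image, list(x = pairs$low_x[i], y = pairs$low_y[i],
                                         radius = pairs$radius[i]))
    log2((hi$mean + pseudocount) / (lo$mean + pseudocount))
  }, numeric(length(image$metabolites)))
  fc <- matrix(fc, nrow = length(image$metabolites)) # metabolites x pairs
  p <- apply(fc, 1, safe_t_pvalue)
  out <- data.frame(metabolite = image$metabolites,
                    mean_log2fc = rowMeans(fc), p_value = p,
                    adjusted_p = stats::p.adjust(p, "BH"),
                    significant = p < alpha, n_pairs = nrow(pairs),
                    row.names = NULL)
  class(out) <- c("metabolite_stats", class(out))
  out
}

#' Hypergeometric over-representation analysis of metabolite or gene sets
#'
#' One-sided upper-tail hypergeometric p-value per set for the overlap
#' between the significant list and the set (both intersected with the
#' universe first), BH-adjusted across sets and ranked by adjusted p.
#'
#' @param significant Character vector of significant features (must be a
#'   subset of `universe`).
#' @param universe Character vector of all tested features (non-empty).
#' @param sets Named list of character vectors (the pathway definitions).
#' @return An `enrichment_result` data.frame: set, set_size, overlap,
#'   p_value, adjusted_p, ordered by adjusted then raw p.
#' @export
pathway_ora <- function(significant, universe, sets) {
  if (length(universe) == 0L) validation_error("empty universe")
  universe <- unique(universe)
  significant <- unique(significant)
  if (!all(significant %in% universe))
    validation_error("significant features must be a subset of the universe")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    validation_error("sets must be a named list")
  N <- length(universe); n_sig <- length(significant)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    m <- length(members)
    k <- length(intersect(members, significant))
    p <- if (m == 0L) 1 else stats::phyper(k - 1, m, N - m, n_sig, lower.tail = FALSE)
    data.frame(set = nm, set_size = m, overlap = k, p_value = p)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, "BH")
  out <- out[order(out$adjusted_p, out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Mean-ion-count matrix of paired ROIs
#'
#' Builds the ROI x metabolite abundance matrix (mean raw counts) over the
#' high (or low) members of a set of ROI pairs, the input to
#' [signature_matrix()].
#'
#' @param pairs A [pair_rois()] result.
#' @param image The `ion_image`.
#' @param which `"high"` or `"low"` member of each pair.
#' @return Numeric matrix, one row per ROI, one column per metabolite.
#' @export
roi_abundance_matrix <- function(pairs, image, which = c("high", "low")) {
  which <- match.arg(which)
  xs <- pairs[[paste0(which, "_x")]]; ys <- pairs[[paste0(which, "_y")]]
  m <- t(vapply(seq_len(nrow(pairs)), function(i)
    extract_ion_counts(image, list(x = xs[i], y = ys[i], radius = pairs$radius[i]))$mean,
    numeric(length(image$metabolites))))
  colnames(m) <- image$metabolites
  rownames(m) <- paste0(which, "_", pairs$pair_id)
  m
}

#' Metabolic signature: correlation matrix plus abundance categories
#'
#' Pearson correlations across ROIs of log2-transformed mean counts of the
#' selected metabolites, with each metabolite categorized as low,
#' intermediate or high by tertiles of its mean log abundance. Metabolites
#' with zero variance across ROIs get `NA` correlations (reported, with a
#' warning).
#'
#' @param abundances ROI x metabolite matrix of mean raw counts (>= 3 ROIs).
#' @param metabolites Columns to include (default: all).
#' @param pseudocount Added before the log transform.
#' @return A `signature_matrix`: list with `correlation` (symmetric, unit
#'   diagonal), `categories` (factor low/intermediate/high) and
#'   `mean_abundance` (log2 scale).
#' @export
signature_matrix <- function(abundances, metabolites = colnames(abundances),
                             pseudocount = 0.5) {
  if (nrow(abundances) < 3L)
    validation_error("signature matrix needs at least 3 ROIs")
  x <- log2(abundances[, metabolites, drop = FALSE] + pseudocount)
  sds <- apply(x, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(x))
  if (any(sds == 0)) {
    warning("constant metabolite(s) reported as NA correlations: ",
            paste(metabolites[sds == 0], collapse = ", "))
    cc[sds == 0, ] <- NA_real_; cc[, sds == 0] <- NA_real_
    diag(cc) <- ifelse(sds == 0, NA_real_, 1)
  }
  mu <- colMeans(x)
  br <- stats::quantile(mu, c(1 / 3, 2 / 3))
  cat3 <- cut(mu, breaks = c(-Inf, br, Inf),
              labels = c("low", "intermediate", "high"))
  names(cat3) <- metabolites
  structure(list(correlation = cc, categories = cat3, mean_abundance = mu),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("signature_matrix: %d metabolites (%s)\n", ncol(x$correlation),
              paste(table(x$categories), names(table(x$categories)),
                    collapse = " / ")))
  invisible(x)
}

#' Metabolites with significant opposite trends between two markers
#'
#' Returns metabolites flagged significant in both stat tables whose mean
#' log2 fold changes have strictly opposite signs.
#'
#' @param stats_a,stats_b [paired_stats()] results for the two marker
#'   analyses (shared metabolite namespace).
#' @return Character vector of metabolite names (sorted).
#' @export
opposite_trend <- function(stats_a, stats_b) {
  shared <- intersect(stats_a$metabolite, stats_b$metabolite)
  if (length(shared) == 0L) {
    warning("the two analyses share no metabolites")
    return(character(0))
  }
  a <- stats_a[match(shared, stats_a$metabolite), ]
  b <- stats_b[match(shared, stats_b$metabolite), ]
  hit <- a$significant & b$significant & (sign(a$mean_log2fc) * sign(b$mean_log2fc) < 0)
  sort(shared[hit])
}
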