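# Synthetic-data generators: device/tumor cell tables, dual-modality ion
# images, and ST ROI tables with planted effects.

ROI_EXTENT <- 1200 # um; effect kernel is clipped to 0 beyond this radius

kernel_fun <- function(scenario) {
  if (scenario$kernel == "flat") {
    function(r) as.numeric(r < ROI_EXTENT)
  } else {
    L <- scenario$decay_length
    function(r) exp(-r / L) * (r < ROI_EXTENT)
  }
}

runif_rect <- function(n, bounds) {
  cbind(x = stats::runif(n, bounds[1], bounds[3]),
        y = stats::runif(n, bounds[2], bounds[4]))
}

# n points uniform over disc-intersect-bounds (rejection from the disc).
runif_disc_in_bounds <- function(n, center, radius, bounds) {
  out <- matrix(numeric(0), ncol = 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    r <- radius * sqrt(stats::runif(m))
    th <- stats::runif(m, 0, 2 * pi)
    p <- cbind(center[1] + r * cos(th), center[2] + r * sin(th))
    keep <- p[, 1] >= bounds[1] & p[, 1] <= bounds[3] &
      p[, 2] >= bounds[2] & p[, 2] <= bounds[4]
    out <- rbind(out, p[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Default single-device layout for a perturbation scenario
#'
#' One condition reservoir flanked by two empty (internal-control)
#' reservoirs at 3,000 um spacing, so the 1,200 um ROIs of distinct
#' conditions cannot overlap.
#'
#' @param scenario A `perturbation_scenario` (supplies the condition label).
#' @param spacing Reservoir spacing in micrometres.
#' @return A device layout data.frame.
#' @export
default_device_layout <- function(scenario, spacing = 3000) {
  data.frame(reservoir_id = 1:3,
             x = c(0, spacing, 2 * spacing), y = 0,
             condition = c(scenario$name, "empty", "empty"),
             is_control = c(FALSE, TRUE, TRUE))
}

check_roi_overlap <- function(layout, roi_extent = ROI_EXTENT) {
  n <- nrow(layout)
  if (n < 2L) return(invisible(TRUE))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (layout$condition[i] == layout$condition[j]) next
    d <- sqrt((layout$x[i] - layout$x[j])^2 + (layout$y[i] - layout$y[j])^2)
    if (d < 2 * roi_extent)
      layout_error("ROIs of distinct conditions overlap (reservoirs ",
                   layout$reservoir_id[i], " and ", layout$reservoir_id[j],
                   ", separation ", round(d), " um < ", 2 * roi_extent, " um)")
  }
  invisible(TRUE)
}

# One subtype point process: homogeneous at `base` plus, inside each
# condition ROI, an intensity increment `incr * k(r)` (cells/mm^2) realised
# by superposition (incr > 0) or thinning (incr < 0).
gen_subtype_points <- function(base, incr, layout, bounds, kfun) {
  area_mm2 <- (bounds[3] - bounds[1]) * (bounds[4] - bounds[2]) / 1e6
  pts <- runif_rect(stats::rpois(1L, base * area_mm2), bounds)
  cond <- layout[!layout$is_control, , drop = FALSE]
  if (incr != 0 && nrow(cond)) {
    for (i in seq_len(nrow(cond))) {
      ctr <- c(cond$x[i], cond$y[i])
      if (incr > 0) {
        a_int <- region_area(ctr, 0, ROI_EXTENT, bounds)
        n_new <- stats::rpois(1L, incr * a_int)
        if (n_new > 0) {
          cand <- runif_disc_in_bounds(n_new, ctr, ROI_EXTENT, bounds)
          r <- sqrt((cand[, 1] - ctr[1])^2 + (cand[, 2] - ctr[2])^2)
          keep <- stats::runif(n_new) < kfun(r)
          pts <- rbind(pts, cand[keep, , drop = FALSE])
        }
      } else if (base > 0) {
        r <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
        p_keep <- pmax(0, 1 + (incr / base) * kfun(r))
        drop <- r < ROI_EXTENT & stats::runif(nrow(pts)) >= p_keep
        pts <- pts[!drop, , drop = FALSE]
      }
    }
  }
  pts
}

#' Generate device layouts and segmented-cell tables for a scenario
#'
#' Simulates `n_tumors` tumors, each with one device (one condition
#' reservoir, two empty internal controls). Marker-negative tumor cells form
#' a homogeneous Poisson background; each marker's positive cells follow the
#' inhomogeneous Poisson intensity
#' `lambda_m(r) = baseline_m * (1 + effect_m * k(r))` around the condition
#' reservoir, with `k` the scenario's decay kernel clipped to 0 beyond
#' 1,200 um. CD8+ and FOXP3+ cells are also CD3+; the generator draws the
#' three disjoint subtype processes (CD8+, FOXP3+, CD3-only) whose derived
#' intensities reproduce all three marker laws exactly. The same scenario and
#' seed give bit-identical output.
#'
#' @param scenario A [perturbation_scenario()].
#' @param layout Optional device layout to use for every tumor; defaults to
#'   [default_device_layout()]. Distinct-condition ROIs must not overlap.
#' @param margin Tissue margin beyond the outermost ROI, micrometres.
#' @return An object of class `imd_experiment`: list with `scenario` and
#'   `tumors`, each tumor a list of `tumor_id`, `layout`, `cells` (cell
#'   table) and `bounds` (tissue rectangle, um).
#' @export
gen_device_tumor <- function(scenario, layout = NULL, margin = 1300) {
  stopifnot(inherits(scenario, "perturbation_scenario"))
  if (is.null(layout)) layout <- default_device_layout(scenario)
  layout <- validate_layout(layout, require_control = TRUE)
  check_roi_overlap(layout)
  bounds <- c(min(layout$x) - margin, min(layout$y) - margin,
              max(layout$x) + margin, max(layout$y) + margin)
  kfun <- kernel_fun(scenario)
  b <- scenario$baseline_density
  e <- scenario$marker_effects
  # subtype base densities and ROI intensity increments (cells/mm^2)
  sub <- list(
    CD8    = list(base = b[["CD8"]],  incr = b[["CD8"]] * e[["CD8"]],
                  flags = c(CD3 = TRUE, CD8 = TRUE, FOXP3 = FALSE)),
    FOXP3  = list(base = b[["FOXP3"]], incr = b[["FOXP3"]] * e[["FOXP3"]],
                  flags = c(CD3 = TRUE, CD8 = FALSE, FOXP3 = TRUE)),
    CD3only = list(base = b[["CD3"]] - b[["CD8"]] - b[["FOXP3"]],
                   incr = b[["CD3"]] * e[["CD3"]] - b[["CD8"]] * e[["CD8"]] -
                     b[["FOXP3"]] * e[["FOXP3"]],
                   flags = c(CD3 = TRUE, CD8 = FALSE, FOXP3 = FALSE)))
  area_mm2 <- (bounds[3] - bounds[1]) * (bounds[4] - bounds[2]) / 1e6
  tumors <- with_preserved_seed(scenario$seed, {
    lapply(seq_len(scenario$n_tumors), function(t) {
      tumor_id <- sprintf("T%02d", t)
      xy <- runif_rect(stats::rpois(1L, scenario$tumor_cell_density * area_mm2), bounds)
      flags <- matrix(FALSE, nrow(xy), 3, dimnames = list(NULL, MARKERS))
      for (s in sub) {
        p <- gen_subtype_points(s$base, s$incr, layout, bounds, kfun)
        if (nrow(p)) {
          xy <- rbind(xy, p)
          flags <- rbind(flags, matrix(rep(s$flags[MARKERS], each = nrow(p)),
                                       nrow(p), 3, dimnames = list(NULL, MARKERS)))
        }
      }
      cells <- data.frame(cell_id = seq_len(nrow(xy)), # unique within tumor
                          x = xy[, 1], y = xy[, 2], tumor_id = tumor_id,
                          CD3 = flags[, "CD3"], CD8 = flags[, "CD8"],
                          FOXP3 = flags[, "FOXP3"], nucleus = TRUE)
      list(tumor_id = tumor_id, layout = layout, cells = cells, bounds = bounds)
    })
  })
  structure(list(scenario = scenario, tumors = tumors), class = "imd_experiment")
}

#' @export
print.imd_experiment <- function(x, ...) {
  cat(sprintf("imd_experiment '%s': %d tumor(s), %d reservoirs/device\n",
              x$scenario$name, length(x$tumors), nrow(x$tumors[[1]]$layout)))
  invisible(x)
}

# Smooth spatial field: coarse iid normal nodes, bilinear interpolation.
smooth_field <- function(nx, ny, sd, n_nodes = 8L) {
  if (sd <= 0) return(matrix(0, ny, nx))
  ncx <- max(2L, min(n_nodes, nx)); ncy <- max(2L, min(n_nodes, ny))
  nodes <- matrix(stats::rnorm(ncx * ncy, 0, sd), ncy, ncx)
  ux <- if (nx == 1L) 1 else (seq_len(nx) - 1) / (nx - 1) * (ncx - 1) + 1
  uy <- if (ny == 1L) 1 else (seq_len(ny) - 1) / (ny - 1) * (ncy - 1) + 1
  ix <- pmin(floor(ux), ncx - 1L); fx <- ux - ix
  iy <- pmin(floor(uy), ncy - 1L); fy <- uy - iy
  f00 <- nodes[iy, ix, drop = FALSE]; f01 <- nodes[iy, ix + 1L, drop = FALSE]
  f10 <- nodes[iy + 1L, ix, drop = FALSE]; f11 <- nodes[iy + 1L, ix + 1L, drop = FALSE]
  wfx <- matrix(fx, ny, nx, byrow = TRUE); wfy <- matrix(fy, ny, nx)
  f00 * (1 - wfx) * (1 - wfy) + f01 * wfx * (1 - wfy) +
    f10 * (1 - wfx) * wfy + f11 * wfx * wfy
}

place_hotspots <- function(scenario) {
  W <- scenario$grid_extent[1]; H <- scenario$grid_extent[2]
  r <- scenario$hotspot_radius
  margin <- 2 * r
  min_sep <- 4 * r
  if (W - 2 * margin <= 0 || H - 2 * margin <= 0)
    layout_error("grid too small to hold hotspots of radius ", r)
  centers <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(centers) < scenario$n_hotspots) {
    tries <- tries + 1L
    if (tries > 10000L)
      layout_error("grid too small to hold ", scenario$n_hotspots,
                   " disjoint hotspots (pairwise separation >= ", min_sep, " um)")
    p <- c(stats::runif(1, margin, W - margin), stats::runif(1, margin, H - margin))
    if (nrow(centers) == 0L ||
        all(sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2) >= min_sep))
      centers <- rbind(centers, p)
  }
  colnames(centers) <- c("x", "y")
  centers
}

#' Generate a co-registered ion image and cell table for a scenario
#'
#' Marker-positive cells cluster at hotspot centres (isotropic Gaussian, sd
#' = radius/2) over a sparse uniform background. Per-pixel ion counts per
#' metabolite channel are negative-binomial (Poisson when `count_noise` is
#' 0) with log2 mean `baseline_m + effect_m * inside_hotspot + field`,
#' where the smooth spatial field is shared across channels. Hotspot centres
#' are rejection-sampled to a pairwise separation of at least 4 radii so
#' every hotspot has a pairable neighbourhood.
#'
#' @param scenario A [metabolomics_scenario()].
#' @return List with `image` (an `ion_image`), `cells` (cell table),
#'   `hotspots` (ground-truth centres) and `scenario`.
#' @export
gen_ion_image <- function(scenario) {
  stopifnot(inherits(scenario, "metabolomics_scenario"))
  W <- scenario$grid_extent[1]; H <- scenario$grid_extent[2]
  px <- scenario$pixel_size
  nx <- max(1L, round(W / px)); ny <- max(1L, round(H / px))
  mets <- scenario$metabolites
  with_preserved_seed(scenario$seed, {
    centers <- place_hotspots(scenario)
    # cells
    marker <- scenario$hotspot_marker
    pts <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(nrow(centers))) {
      n_i <- stats::rpois(1L, scenario$cells_per_hotspot)
      got <- matrix(numeric(0), ncol = 2)
      while (nrow(got) < n_i) {
        m <- 2L * max(n_i - nrow(got), 8L)
        p <- cbind(stats::rnorm(m, centers[i, 1], scenario$hotspot_radius / 2),
                   stats::rnorm(m, centers[i, 2], scenario$hotspot_radius / 2))
        keep <- p[, 1] >= 0 & p[, 1] <= W & p[, 2] >= 0 & p[, 2] <= H
        got <- rbind(got, p[keep, , drop = FALSE])
      }
      pts <- rbind(pts, got[seq_len(n_i), , drop = FALSE])
    }
    n_bg <- stats::rpois(1L, scenario$background_cell_density * W * H / 1e6)
    pts <- rbind(pts, runif_rect(n_bg, c(0, 0, W, H)))
    flags <- matrix(FALSE, nrow(pts), 3, dimnames = list(NULL, MARKERS))
    flags[, marker] <- TRUE
    flags[, "CD3"] <- TRUE # CD8/FOXP3 imply CD3; CD3 hotspots are CD3 anyway
    cells <- data.frame(cell_id = sprintf("M_%06d", seq_len(nrow(pts))),
                        x = pts[, 1], y = pts[, 2], tumor_id = scenario$name,
                        CD3 = flags[, "CD3"], CD8 = flags[, "CD8"],
                        FOXP3 = flags[, "FOXP3"], nucleus = TRUE)
    # ion image
    base_log2 <- stats::runif(length(mets), 6, 10)
    names(base_log2) <- mets
    cx <- (seq_len(nx) - 0.5) * px
    cy <- (seq_len(ny) - 0.5) * px
    member <- matrix(0, ny, nx)
    for (i in seq_len(nrow(centers))) {
      d2 <- outer(cy - centers[i, 2], cx - centers[i, 1],
                  function(a, b) a * a + b * b)
      member[d2 <= scenario$hotspot_radius^2] <- 1
    }
    field <- smooth_field(nx, ny, scenario$field_sd)
    counts <- array(0, dim = c(ny, nx, length(mets)),
                    dimnames = list(NULL, NULL, mets))
    phi <- scenario$count_noise
    for (m in mets) {
      mu <- 2^(base_log2[[m]] + scenario$metabolite_effects[[m]] * member + field)
      counts[, , m] <- if (phi > 0)
        stats::rnbinom(length(mu), mu = mu, size = 1 / phi)
      else stats::rpois(length(mu), mu)
    }
    image <- structure(list(pixel_size = px, origin = c(0, 0), nx = nx, ny = ny,
                            metabolites = mets, counts = counts),
                       class = "ion_image")
    list(image = image, cells = cells,
         hotspots = as.data.frame(centers), scenario = scenario)
  })
}

#' @export
print.ion_image <- function(x, ...) {
  cat(sprintf("ion_image: %d x %d pixels (%g um raster), %d channel(s)\n",
              x$nx, x$ny, x$pixel_size, length(x$metabolites)))
  invisible(x)
}

#' Generate a spatial-transcriptomics ROI table for a scenario
#'
#' Positive indices are drawn inside the class bands implied by
#' `class_counts` (high > 20%, intermediate (5%, 20%], low < 5%) with safety
#' margins so integer rounding of CD8 counts cannot cross a boundary.
#' Expression is log-normal around per-gene baselines, with the scenario's
#' planted gene-set log2 shifts applied in CD8-high ROIs.
#'
#' @param scenario An [st_scenario()].
#' @return An object of class `st_roi_table`: list with `rois` (data.frame
#'   of `roi_id`, `cd8_count`, `nuclei_count`, `positive_index`,
#'   `cd8_class`), `expression` (gene x ROI matrix of positive values),
#'   `gene_sets` and `scenario`.
#' @export
gen_st_rois <- function(scenario) {
  stopifnot(inherits(scenario, "st_scenario"))
  cc <- scenario$class_counts
  with_preserved_seed(scenario$seed, {
    idx <- c(stats::runif(cc[["high"]], 0.21, 0.45),
             stats::runif(cc[["intermediate"]], 0.055, 0.195),
             stats::runif(cc[["low"]], 0.005, 0.045))
    n <- length(idx)
    nuclei <- pmax(200L, as.integer(round(stats::rnorm(n, scenario$nuclei_mean,
                                                       scenario$nuclei_mean * 0.08))))
    cd8 <- as.integer(round(idx * nuclei))
    pos_idx <- positive_index(cd8, nuclei)
    cls <- classify_roi(pos_idx)
    rois <- data.frame(roi_id = sprintf("ROI%02d", seq_len(n)),
                       cd8_count = cd8, nuclei_count = nuclei,
                       positive_index = pos_idx, cd8_class = cls,
                       stringsAsFactors = FALSE)
    genes <- scenario$genes
    base <- stats::runif(length(genes), 3, 8)
    shift <- stats::setNames(numeric(length(genes)), genes)
    for (set_name in names(scenario$pathway_effects)) {
      members <- intersect(scenario$gene_sets[[set_name]], genes)
      shift[members] <- shift[members] + scenario$pathway_effects[[set_name]]
    }
    is_high <- cls == "high"
    log2x <- matrix(base, length(genes), n) +
      outer(shift, as.numeric(is_high)) +
      matrix(stats::rnorm(length(genes) * n, 0, scenario$noise_sd), length(genes), n)
    expression <- 2^log2x
    dimnames(expression) <- list(genes, rois$roi_id)
    structure(list(rois = rois, expression = expression,
                   gene_sets = scenario$gene_sets, scenario = scenario),
              class = "st_roi_table")
  })
}

#' @export
print.st_roi_table <- function(x, ...) {
  tab <- table(factor(x$rois$cd8_class, levels = c("high", "intermediate", "low")))
  cat(sprintf("st_roi_table: %d ROIs (%d high / %d intermediate / %d low), %d genes\n",
              nrow(x$rois), tab[["high"]], tab[["intermediate"]], tab[["low"]],
              nrow(x$expression)))
  invisible(x)
}
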