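#' Concentric sub-ROI specification around a reservoir
#'
#' The drug-diffusion region around each reservoir extends `max_extent`
#' micrometres from the reservoir centre and is divided into contiguous
#' annular sub-ROIs of equal radial `depth`. The defaults (1,200 um split
#' into 300 um rings) give the four sub-ROIs used for per-ring quality
#' control while the headline effect pools all rings.
#'
#' @param max_extent Outer radius of the ROI in micrometres (> 0).
#' @param depth Radial depth of each sub-ROI ring in micrometres (> 0);
#'   `max_extent` must be an integer multiple of `depth`.
#' @return An object of class `ring_spec`.
#' @examples
#' build_rings(ring_spec(1200, 300))
#' @export
ring_spec <- function(max_extent = 1200, depth = 300) {
  check_number(max_extent, "max_extent", lower = 0, strict_lower = TRUE)
  check_number(depth, "depth", lower = 0, strict_lower = TRUE)
  k <- max_extent / depth
  if (abs(k - round(k)) > 1e-9)
    validation_error("max_extent (", max_extent,
                     ") must be an integer multiple of depth (", depth, ")")
  structure(list(max_extent = max_extent, depth = depth, n_rings = as.integer(round(k))),
            class = "ring_spec")
}

#' @export
print.ring_spec <- function(x, ...) {
  cat(sprintf("ring_spec: %g um extent, %d ring(s) of %g um depth\n",
              x$max_extent, x$n_rings, x$depth))
  invisible(x)
}

#' Build the half-open annular rings of a ring specification
#'
#' @param spec A [ring_spec()].
#' @return A data.frame with `ring_index` (0-based), `inner` and `outer`
#'   radii in micrometres. Rings are half-open intervals `[inner, outer)`
#'   contiguous from 0.
#' @export
build_rings <- function(spec = ring_spec()) {
  if (!inherits(spec, "ring_spec")) spec <- do.call(ring_spec, as.list(spec))
  idx <- seq_len(spec$n_rings) - 1L
  data.frame(ring_index = idx, inner = idx * spec$depth, outer = (idx + 1L) * spec$depth)
}

#' Validate a device layout table
#'
#' @param layout data.frame with columns `reservoir_id`, `x`, `y`,
#'   `condition`, `is_control` (coordinates in micrometres).
#' @param require_control Require at least one control (empty) reservoir.
#' @return The layout, invisibly, columns coerced.
#' @export
validate_layout <- function(layout, require_control = FALSE) {
  if (!is.data.frame(layout) || nrow(layout) == 0L)
    validation_error("device layout must be a non-empty data.frame")
  need <- c("reservoir_id", "x", "y", "condition", "is_control")
  miss <- setdiff(need, names(layout))
  if (length(miss)) schema_error("layout is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(layout$reservoir_id))
    validation_error("reservoir ids must be unique")
  if (!all(is.finite(layout$x)) || !all(is.finite(layout$y)))
    validation_error("reservoir coordinates must be finite")
  layout$is_control <- as.logical(layout$is_control)
  if (require_control && !any(layout$is_control))
    validation_error("layout needs at least one control (empty) reservoir")
  invisible(layout)
}

#' Assign cells to their nearest reservoir and sub-ROI ring
#'
#' Each cell is assigned to its nearest reservoir by Euclidean distance from
#' the reservoir centre (ties broken towards the lowest `reservoir_id`) and
#' to the half-open ring `[inner, outer)` containing that distance. Cells
#' farther than `max_extent` from every reservoir are left unassigned
#' (`NA` reservoir and ring).
#'
#' @param cells Cell table with `x`, `y` columns in micrometres.
#' @param layout Device layout (see [validate_layout()]).
#' @param spec A [ring_spec()].
#' @return `cells` with added columns `reservoir_id`, `distance` (um) and
#'   `ring_index` (0-based, `NA` beyond `max_extent`).
#' @export
assign_cells <- function(cells, layout, spec = ring_spec()) {
  layout <- validate_layout(layout)
  if (!inherits(spec, "ring_spec")) spec <- do.call(ring_spec, as.list(spec))
  layout <- layout[order(layout$reservoir_id), , drop = FALSE]
  out <- cells
  if (nrow(cells) == 0L) {
    out$reservoir_id <- layout$reservoir_id[0]
    out$distance <- numeric(0)
    out$ring_index <- integer(0)
    return(out)
  }
  dx <- outer(cells$x, layout$x, "-")
  dy <- outer(cells$y, layout$y, "-")
  d <- sqrt(dx * dx + dy * dy)
  nearest <- max.col(-d, ties.method = "first")
  dist <- d[cbind(seq_len(nrow(d)), nearest)]
  res_id <- layout$reservoir_id[nearest]
  ring <- as.integer(floor(dist / spec$depth))
  beyond <- dist >= spec$max_extent
  ring[beyond] <- NA_integer_
  res_id[beyond] <- if (is.character(res_id)) NA_character_ else NA
  dist_out <- dist
  out$reservoir_id <- res_id
  out$distance <- dist_out
  out$ring_index <- ring
  out
}

# --- polygon helpers: Sutherland-Hodgman clipping against a rectangle -------

circle_polygon <- function(cx, cy, r, n = 1024L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# Clip polygon (matrix with columns x, y) against half-plane keep(p) >= 0,
# defined by signed distance function sdf(x, y). Vectorized: each edge emits
# its start vertex (if inside) then the boundary intersection (if crossing).
clip_halfplane <- function(poly, sdf) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  x <- poly[, 1]; y <- poly[, 2]
  d <- sdf(x, y)
  j <- c(seq_len(n)[-1], 1L)
  inside <- d >= 0
  cross <- inside != inside[j]
  t <- ifelse(cross, d / (d - d[j]), 0)
  ix <- x + t * (x[j] - x); iy <- y + t * (y[j] - y)
  keep <- rbind(inside, cross) # column-major gather keeps edge order
  cbind(x = rbind(x, ix)[keep], y = rbind(y, iy)[keep])
}

clip_polygon_rect <- function(poly, bounds) {
  poly <- clip_halfplane(poly, function(x, y) x - bounds[1])
  poly <- clip_halfplane(poly, function(x, y) bounds[3] - x)
  poly <- clip_halfplane(poly, function(x, y) y - bounds[2])
  clip_halfplane(poly, function(x, y) bounds[4] - y)
}

polygon_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3L) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

check_bounds <- function(bounds) {
  if (is.list(bounds)) bounds <- unlist(bounds)
  if (length(bounds) != 4L || !all(is.finite(bounds)))
    validation_error("tissue bounds must be finite c(xmin, ymin, xmax, ymax)")
  if (bounds[3] <= bounds[1] || bounds[4] <= bounds[2])
    validation_error("degenerate tissue bounds: xmax must exceed xmin and ymax exceed ymin")
  bounds
}

#' Area of an annular sub-ROI clipped to rectangular tissue bounds
#'
#' The annulus is approximated by a fine polygon and clipped to the
#' rectangle with Sutherland-Hodgman half-plane clipping; the clipped
#' annulus area is the clipped outer-disc area minus the clipped inner-disc
#' area. Relative error is far below 1% at the default resolution.
#'
#' @param center Reservoir centre `c(x, y)` in micrometres.
#' @param inner,outer Ring radii in micrometres (`inner < outer`).
#' @param bounds Tissue bounds `c(xmin, ymin, xmax, ymax)` in micrometres,
#'   or `NULL` for the unclipped analytic annulus area.
#' @param n_vertices Number of polygon vertices per circle.
#' @return Area in mm^2.
#' @examples
#' region_area(c(0, 0), 0, 300) # pi * 0.3^2
#' @export
region_area <- function(center, inner, outer, bounds = NULL, n_vertices = 1024L) {
  check_number(inner, "inner", lower = 0)
  check_number(outer, "outer", lower = 0, strict_lower = TRUE)
  if (inner >= outer) validation_error("inner radius must be < outer radius")
  if (is.null(bounds)) return(pi * (outer^2 - inner^2) / 1e6)
  bounds <- check_bounds(bounds)
  # fast path: ROI entirely inside the tissue rectangle
  if (center[1] - outer >= bounds[1] && center[1] + outer <= bounds[3] &&
      center[2] - outer >= bounds[2] && center[2] + outer <= bounds[4])
    return(pi * (outer^2 - inner^2) / 1e6)
  a_out <- polygon_area(clip_polygon_rect(circle_polygon(center[1], center[2], outer, n_vertices), bounds))
  a_in <- if (inner > 0)
    polygon_area(clip_polygon_rect(circle_polygon(center[1], center[2], inner, n_vertices), bounds))
  else 0
  (a_out - a_in) / 1e6
}
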