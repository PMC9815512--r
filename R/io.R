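# Readers and writers. All tables are tab-delimited text with '#' comment
# headers; coordinates are Cartesian micrometres, origin bottom-left, y up.

COORD_HEADER <- "# coordinates: Cartesian micrometres, origin bottom-left, y up"

fmt_num <- function(x) sprintf("%.17g", x) # lossless double round trip

write_tsv_with_header <- function(df, path, comments) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comments, con)
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_table <- function(path, required, numeric_cols, what) {
  if (!file.exists(path)) schema_error(what, " file not found: ", path)
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  header_line <- which(!is_comment)[1]
  df <- utils::read.delim(text = lines[!is_comment], sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  miss <- setdiff(required, names(df))
  if (length(miss))
    schema_error(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  for (cl in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !(df[[cl]] %in% c("NA", "")))
    if (length(bad))
      schema_error(what, ": non-numeric value '", df[[cl]][bad[1]], "' in column '",
                   cl, "' at line ", header_line + bad[1])
    df[[cl]] <- v
  }
  df
}

as_flag <- function(x) as.logical(x) | x %in% c("1", "TRUE", "true")

#' Write / read a segmented-cell table
#'
#' Tab-delimited text: `cell_id`, `x`, `y` (micrometres), `tumor_id`, marker
#' flags `CD3`, `CD8`, `FOXP3` and a `nucleus` flag. Numeric columns are
#' written losslessly, so write-then-read round trips exactly.
#'
#' @param cells Cell table data.frame.
#' @param path File path.
#' @return `read_cell_table` returns the validated cell table; malformed
#'   rows raise schema errors naming the offending line.
#' @export
write_cell_table <- function(cells, path) {
  write_tsv_with_header(
    cells[, c("cell_id", "x", "y", "tumor_id", "CD3", "CD8", "FOXP3", "nucleus")],
    path, c("# imdspatial cell table", COORD_HEADER))
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  df <- read_tsv_table(path, c("cell_id", "x", "y", "tumor_id", "CD3", "CD8",
                               "FOXP3", "nucleus"),
                       numeric_cols = c("x", "y"), what = "cell table")
  for (cl in c("CD3", "CD8", "FOXP3", "nucleus")) df[[cl]] <- as_flag(df[[cl]])
  df
}

#' Write / read a device layout
#'
#' Tab-delimited text: `reservoir_id`, `x`, `y` (micrometres), `condition`,
#' `is_control`.
#' @param layout Layout data.frame.
#' @param path File path.
#' @export
write_device_layout <- function(layout, path) {
  write_tsv_with_header(
    layout[, c("reservoir_id", "x", "y", "condition", "is_control")],
    path, c("# imdspatial device layout", COORD_HEADER))
}

#' @rdname write_device_layout
#' @export
read_device_layout <- function(path) {
  df <- read_tsv_table(path, c("reservoir_id", "x", "y", "condition", "is_control"),
                       numeric_cols = c("x", "y"), what = "device layout")
  df$reservoir_id <- utils::type.convert(df$reservoir_id, as.is = TRUE)
  df$is_control <- as_flag(df$is_control)
  validate_layout(df)
  df
}

#' Write / read an ion image in the long-format text dialect
#'
#' One row per (pixel, channel): `x`, `y` (pixel-centre micrometres),
#' `metabolite`, `count` (raw ion counts). The reader reconstructs the pixel
#' grid from the unique coordinates, checks the raster is complete and
#' uniform, and rejects duplicate (x, y, metabolite) rows. Write-then-read
#' is bit-identical.
#'
#' @param image An `ion_image`.
#' @param path File path.
#' @export
write_ion_image <- function(image, path) {
  ctr <- pixel_centers(image)
  long <- do.call(rbind, lapply(image$metabolites, function(m)
    data.frame(x = rep(ctr$x, each = image$ny), y = rep(ctr$y, image$nx),
               metabolite = m,
               count = as.vector(image$counts[, , m]))))
  write_tsv_with_header(long, path,
                        c("# imdspatial ion image (long format)", COORD_HEADER,
                          paste0("# pixel_size_um: ", fmt_num(image$pixel_size))))
}

#' @rdname write_ion_image
#' @export
read_ion_image <- function(path) {
  df <- read_tsv_table(path, c("x", "y", "metabolite", "count"),
                       numeric_cols = c("x", "y", "count"), what = "ion image")
  key <- paste(df$x, df$y, df$metabolite)
  if (anyDuplicated(key))
    format_error("duplicate (x, y, metabolite) rows in ion image: ",
                 key[which(duplicated(key))[1]])
  xs <- sort(unique(df$x)); ys <- sort(unique(df$y))
  spacing <- function(v) if (length(v) > 1L) diff(v) else numeric(0)
  sp <- c(spacing(xs), spacing(ys))
  if (length(sp) && (max(sp) - min(sp)) > 1e-6 * max(sp))
    format_error("inconsistent pixel grid: raster spacing is not uniform")
  px <- if (length(sp)) sp[1] else 1
  mets <- unique(df$metabolite)
  nx <- length(xs); ny <- length(ys)
  if (nrow(df) != nx * ny * length(mets))
    format_error("inconsistent pixel grid: expected ", nx * ny * length(mets),
                 " rows (", nx, " x ", ny, " x ", length(mets), "), found ", nrow(df))
  counts <- array(0, dim = c(ny, nx, length(mets)), dimnames = list(NULL, NULL, mets))
  row <- match(df$y, ys); col <- match(df$x, xs); ch <- match(df$metabolite, mets)
  counts[cbind(row, col, ch)] <- df$count
  structure(list(pixel_size = px, origin = c(xs[1] - px / 2, ys[1] - px / 2),
                 nx = nx, ny = ny, metabolites = mets, counts = counts),
            class = "ion_image")
}

#' Write / read an ST ROI table (counts plus wide expression columns)
#'
#' Tab-delimited text with `roi_id`, `cd8_count`, `nuclei_count` followed by
#' one column per gene. Positive index and class are recomputed on read.
#'
#' @param st An `st_roi_table`.
#' @param path File path.
#' @export
write_st_rois <- function(st, path) {
  wide <- cbind(st$rois[, c("roi_id", "cd8_count", "nuclei_count")],
                as.data.frame(t(st$expression)))
  write_tsv_with_header(wide, path, "# imdspatial ST ROI table")
}

#' @rdname write_st_rois
#' @export
read_st_rois <- function(path, gene_sets = NULL) {
  df <- read_tsv_table(path, c("roi_id", "cd8_count", "nuclei_count"),
                       numeric_cols = c("cd8_count", "nuclei_count"),
                       what = "ST ROI table")
  genes <- setdiff(names(df), c("roi_id", "cd8_count", "nuclei_count"))
  expr <- t(as.matrix(vapply(df[genes], as.numeric, numeric(nrow(df)))))
  colnames(expr) <- df$roi_id
  pos <- positive_index(df$cd8_count, df$nuclei_count)
  rois <- data.frame(roi_id = df$roi_id, cd8_count = df$cd8_count,
                     nuclei_count = df$nuclei_count, positive_index = pos,
                     cd8_class = classify_roi(pos), stringsAsFactors = FALSE)
  structure(list(rois = rois, expression = expr, gene_sets = gene_sets,
                 scenario = NULL), class = "st_roi_table")
}

#' Read / write gene or metabolite sets in GMT format
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>member...`.
#' @param path File path.
#' @param sets Named list of character vectors.
#' @param descriptions Optional descriptions (defaults to set names).
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) format_error("GMT line ", bad[1], " has fewer than 3 fields")
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[`, character(1), 1))
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

# --- GeoJSON export ---------------------------------------------------------

ring_coords <- function(cx, cy, r, n = 72L) {
  p <- circle_polygon(cx, cy, r, n)
  p <- rbind(p, p[1, , drop = FALSE]) # close the ring
  lapply(seq_len(nrow(p)), function(i) c(p[i, 1], p[i, 2]))
}

geojson_feature <- function(geometry, properties) {
  list(type = "Feature", geometry = geometry, properties = properties)
}

#' Export sub-ROI annuli of a device layout as GeoJSON polygons
#'
#' One polygon feature per (reservoir, ring); rings with a positive inner
#' radius carry the inner circle as a polygon hole. Coordinates are
#' micrometres in the package's Cartesian frame.
#'
#' @param layout Device layout.
#' @param spec A [ring_spec()].
#' @param path Optional output file; omit to get the list structure.
#' @return The GeoJSON list, invisibly if written to file.
#' @export
subroi_geojson <- function(layout, spec = ring_spec(), path = NULL) {
  layout <- validate_layout(layout)
  rings <- build_rings(spec)
  feats <- list()
  for (i in seq_len(nrow(layout))) for (k in seq_len(nrow(rings))) {
    coords <- list(ring_coords(layout$x[i], layout$y[i], rings$outer[k]))
    if (rings$inner[k] > 0)
      coords <- c(coords, list(ring_coords(layout$x[i], layout$y[i], rings$inner[k])))
    feats[[length(feats) + 1L]] <- geojson_feature(
      list(type = "Polygon", coordinates = coords),
      list(reservoir_id = layout$reservoir_id[i], condition = layout$condition[i],
           is_control = layout$is_control[i], ring_index = rings$ring_index[k],
           inner_um = rings$inner[k], outer_um = rings$outer[k]))
  }
  gj <- list(type = "FeatureCollection", features = feats)
  if (is.null(path)) return(gj)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(gj)
}

#' Export paired ROIs as GeoJSON disc polygons
#'
#' @param pairs A [pair_rois()] result.
#' @param path Optional output file.
#' @return The GeoJSON list, invisibly if written to file.
#' @export
pairs_geojson <- function(pairs, path = NULL) {
  feats <- list()
  for (i in seq_len(nrow(pairs))) for (role in c("high", "low")) {
    cx <- pairs[[paste0(role, "_x")]][i]; cy <- pairs[[paste0(role, "_y")]][i]
    feats[[length(feats) + 1L]] <- geojson_feature(
      list(type = "Polygon", coordinates = list(ring_coords(cx, cy, pairs$radius[i]))),
      list(pair_id = pairs$pair_id[i], role = role, marker = pairs$marker[i],
           count = pairs[[paste0("count_", role)]][i],
           count_log2fc = pairs$count_log2fc[i]))
  }
  gj <- list(type = "FeatureCollection", features = feats)
  if (is.null(path)) return(gj)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(gj)
}
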