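# Perturbation response: marker counts per condition ROI vs internal
# control, log2 fold changes, cross-tumor aggregation and t-tests.

#' Density-normalized log2 fold change of ROI vs control counts
#'
#' `log2( ((count_roi + pseudocount) / area_roi) /
#'        ((count_control + pseudocount) / area_control) )`.
#' With equal areas this reduces to the plain count ratio. Vectorized.
#'
#' @param count_roi,count_control Marker-positive cell counts (>= 0).
#' @param area_roi,area_control ROI areas in mm^2 (> 0).
#' @param pseudocount Added to both counts before the ratio (>= 0); the
#'   default 0 matches plain count normalization, 0.5 guards sparse data.
#' @return log2 fold change(s).
#' @examples
#' fold_change(35, 1, 20, 1) # log2(1.75): a +75% change
#' @export
fold_change <- function(count_roi, area_roi, count_control, area_control,
                        pseudocount = 0) {
  if (any(area_roi <= 0) || any(area_control <= 0))
    validation_error("areas must be positive")
  if (pseudocount < 0) validation_error("pseudocount must be >= 0")
  if (any(count_roi < 0) || any(count_control < 0))
    validation_error("counts must be >= 0")
  if (pseudocount == 0 && any(count_roi == 0 & count_control == 0))
    abort("fold change undefined: both counts are 0 with pseudocount 0",
          class = "imdspatial_undefined_value")
  log2(((count_roi + pseudocount) / area_roi) /
         ((count_control + pseudocount) / area_control))
}

#' Convert a log2 fold change to a percent change
#'
#' @param log2fc Finite log2 fold change(s).
#' @return `(2^log2fc - 1) * 100`, so -1 maps to -50% and log2(1.75) to +75%.
#' @export
percent_change <- function(log2fc) {
  if (any(!is.finite(log2fc))) validation_error("log2fc must be finite")
  (2^log2fc - 1) * 100
}

ring_qc_flags <- function(density) {
  k <- length(density)
  vapply(seq_len(k), function(i) {
    nb <- density[setdiff(c(i - 1L, i + 1L), c(0L, k + 1L))]
    m <- mean(nb)
    if (m == 0) return(density[i] > 0)
    density[i] > 3 * m || density[i] < m / 3
  }, logical(1))
}

#' Marker-positive counts per condition ROI and internal control
#'
#' For every tumor of an experiment, counts marker-positive cells assigned
#' (nearest-reservoir, half-open rings) to each condition reservoir's pooled
#' 0-`max_extent` ROI and to the pooled empty-reservoir control of the same
#' device. Areas are clipped to the tissue bounds. Per-ring counts are
#' retained with a QC flag marking rings whose density deviates more than
#' 3-fold from the mean of their neighbours (flagged, never auto-excluded).
#'
#' @param experiment An `imd_experiment` from [gen_device_tumor()], or a list
#'   of `list(tumor_id, layout, cells, bounds)` entries of the same shape.
#' @param spec A [ring_spec()].
#' @param markers Markers to quantify.
#' @return A `condition_counts` data.frame (tumor_id, condition, marker,
#'   count_roi, count_control, area_roi, area_control) with attributes
#'   `per_ring` (ring breakdown incl. `qc_flag`) and `control_null`
#'   (first-empty vs remaining-empties counts for the null fold changes).
#' @export
condition_counts <- function(experiment, spec = ring_spec(), markers = MARKERS) {
  tumors <- if (inherits(experiment, "imd_experiment")) experiment$tumors else experiment
  rings <- build_rings(spec)
  rows <- list(); ring_rows <- list(); null_rows <- list()
  for (tum in tumors) {
    layout <- validate_layout(tum$layout, require_control = TRUE)
    cells <- tum$cells
    pos <- cells[cells$CD3 | cells$CD8 | cells$FOXP3, , drop = FALSE]
    asg <- assign_cells(pos, layout, spec)
    asg <- asg[!is.na(asg$ring_index), , drop = FALSE]
    # per (reservoir, ring, marker) counts and areas
    res_info <- lapply(seq_len(nrow(layout)), function(i) {
      ctr <- c(layout$x[i], layout$y[i])
      in_res <- asg[asg$reservoir_id == layout$reservoir_id[i], , drop = FALSE]
      area <- vapply(seq_len(nrow(rings)), function(k)
        region_area(ctr, rings$inner[k], rings$outer[k], tum$bounds), numeric(1))
      cnt <- sapply(markers, function(m)
        vapply(seq_len(nrow(rings)), function(k)
          sum(in_res[[m]] & in_res$ring_index == rings$ring_index[k]), numeric(1)),
        simplify = FALSE)
      list(area = area, count = cnt)
    })
    for (i in seq_len(nrow(layout))) for (m in markers) {
      d <- res_info[[i]]$count[[m]] / res_info[[i]]$area
      ring_rows[[length(ring_rows) + 1L]] <- data.frame(
        tumor_id = tum$tumor_id, reservoir_id = layout$reservoir_id[i],
        condition = layout$condition[i], is_control = layout$is_control[i],
        marker = m, ring_index = rings$ring_index,
        count = res_info[[i]]$count[[m]], area_mm2 = res_info[[i]]$area,
        density = d, qc_flag = ring_qc_flags(d))
    }
    ctrl_i <- which(layout$is_control)
    cond_i <- which(!layout$is_control)
    for (m in markers) {
      c_ctrl <- sum(vapply(ctrl_i, function(i) sum(res_info[[i]]$count[[m]]), numeric(1)))
      a_ctrl <- sum(vapply(ctrl_i, function(i) sum(res_info[[i]]$area), numeric(1)))
      for (i in cond_i) {
        rows[[length(rows) + 1L]] <- data.frame(
          tumor_id = tum$tumor_id, condition = layout$condition[i], marker = m,
          count_roi = sum(res_info[[i]]$count[[m]]),
          count_control = c_ctrl,
          area_roi = sum(res_info[[i]]$area), area_control = a_ctrl)
      }
      if (length(ctrl_i) >= 2L) {
        i1 <- ctrl_i[1]; rest <- ctrl_i[-1]
        null_rows[[length(null_rows) + 1L]] <- data.frame(
          tumor_id = tum$tumor_id, marker = m,
          count_a = sum(res_info[[i1]]$count[[m]]),
          area_a = sum(res_info[[i1]]$area),
          count_b = sum(vapply(rest, function(i) sum(res_info[[i]]$count[[m]]), numeric(1))),
          area_b = sum(vapply(rest, function(i) sum(res_info[[i]]$area), numeric(1))))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "per_ring") <- do.call(rbind, ring_rows)
  attr(out, "control_null") <- if (length(null_rows)) do.call(rbind, null_rows) else NULL
  class(out) <- c("condition_counts", class(out))
  out
}

#' Aggregate per-tumor fold changes into a per-condition effect table
#'
#' Per (condition, marker): per-tumor density log2 fold changes of the
#' condition ROI vs the same tumor's pooled empty-reservoir control are
#' aggregated as mean +/- SEM; the p-value is a two-tailed unpaired t-test
#' of those fold changes against the same tumors' control-vs-control fold
#' changes (a null centred at 0). Stars mark p < 0.05 (`*`) and p < 0.005
#' (`**`). With a single tumor the effect is reported and p is `NA`.
#'
#' @param counts A [condition_counts()] table.
#' @param pseudocount Passed to [fold_change()].
#' @param var_equal Equal-variance Student's t (default) or Welch.
#' @return An `imd_effect_table` data.frame: condition, marker, mean_log2fc,
#'   sem, n_tumors, p_value, percent_change, stars.
#' @export
effect_table <- function(counts, pseudocount = 0, var_equal = TRUE) {
  if (nrow(counts) == 0L) validation_error("empty condition_counts")
  nulls <- attr(counts, "control_null")
  null_fc <- NULL
  if (!is.null(nulls))
    null_fc <- data.frame(marker = nulls$marker,
                          fc = fold_change(nulls$count_a, nulls$area_a,
                                           nulls$count_b, nulls$area_b, pseudocount))
  keys <- unique(counts[, c("condition", "marker")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- counts$condition == keys$condition[i] & counts$marker == keys$marker[i]
    sub <- counts[sel, , drop = FALSE]
    fc <- fold_change(sub$count_roi, sub$area_roi,
                      sub$count_control, sub$area_control, pseudocount)
    n <- length(fc)
    y <- if (!is.null(null_fc)) null_fc$fc[null_fc$marker == keys$marker[i]] else NULL
    p <- if (n >= 2L && !is.null(y) && length(y) >= 2L)
      safe_t_pvalue(fc, y, var_equal = var_equal) else NA_real_
    data.frame(condition = keys$condition[i], marker = keys$marker[i],
               mean_log2fc = mean(fc),
               sem = if (n >= 2L) stats::sd(fc) / sqrt(n) else NA_real_,
               n_tumors = n, p_value = p,
               percent_change = percent_change(mean(fc)),
               stars = significance_stars(p))
  }))
  class(out) <- c("imd_effect_table", class(out))
  out
}

#' @export
print.imd_effect_table <- function(x, digits = 3, ...) {
  cat("Perturbation effect table (log2 FC vs same-tumor empty-reservoir control)\n")
  df <- as.data.frame(x)
  df$mean_log2fc <- round(df$mean_log2fc, digits)
  df$sem <- round(df$sem, digits)
  df$percent_change <- round(df$percent_change, 1)
  df$p_value <- signif(df$p_value, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Run the full perturbation-response pipeline on an experiment
#'
#' Convenience wrapper: [condition_counts()] then [effect_table()].
#'
#' @inheritParams condition_counts
#' @inheritParams effect_table
#' @return An `imd_effect_table`.
#' @export
run_perturbation <- function(experiment, spec = ring_spec(), markers = MARKERS,
                             pseudocount = 0, var_equal = TRUE) {
  effect_table(condition_counts(experiment, spec, markers),
               pseudocount = pseudocount, var_equal = var_equal)
}
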