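# Spatial-transcriptomics ROI workflow: CD8 positive index, three-class
# thresholding, geometric-mean normalization and class-vs-class DE feeding
# the shared over-representation test.

#' CD8 positive index of an ROI
#'
#' @param cd8_count CD8-positive cell count (0 <= cd8_count <= nuclei_count).
#' @param nuclei_count Nuclei count (> 0).
#' @return `cd8_count / nuclei_count`, a fraction in \[0, 1\]. Vectorized.
#' @export
positive_index <- function(cd8_count, nuclei_count) {
  if (any(nuclei_count <= 0)) validation_error("nuclei_count must be positive")
  if (any(cd8_count < 0) || any(cd8_count > nuclei_count))
    validation_error("cd8_count must lie in [0, nuclei_count]")
  cd8_count / nuclei_count
}

#' Classify an ROI by its CD8 positive index
#'
#' High for index > 0.20, low for index < 0.05, intermediate otherwise:
#' the outer-class inequalities are strict, so indices exactly at 0.05 or
#' 0.20 classify as intermediate.
#'
#' @param index Positive index in \[0, 1\]. Vectorized.
#' @return Character vector over `"high"`, `"intermediate"`, `"low"`.
#' @export
classify_roi <- function(index) {
  if (any(index < 0 | index > 1)) validation_error("index must lie in [0, 1]")
  ifelse(index > 0.20, "high", ifelse(index < 0.05, "low", "intermediate"))
}

#' Normalize expression to the per-ROI geometric mean of a target group
#'
#' Divides every gene's value in an ROI by that ROI's geometric mean over
#' the target-group genes, so the normalized target group has geometric
#' mean exactly 1 per ROI. Idempotent.
#'
#' @param expression Gene x ROI numeric matrix (or a vector for one ROI);
#'   rownames are gene names.
#' @param target_group Character vector of target-group genes (non-empty,
#'   all present in the expression rows).
#' @param pseudocount Added before normalization; target values must be
#'   positive afterwards.
#' @return Matrix (or vector) of the same shape.
#' @export
geomean_normalize <- function(expression, target_group, pseudocount = 0) {
  vec <- is.null(dim(expression))
  x <- if (vec) matrix(expression, ncol = 1, dimnames = list(names(expression), NULL))
  else expression
  if (length(target_group) == 0L) validation_error("empty target group")
  miss <- setdiff(target_group, rownames(x))
  if (length(miss)) validation_error("target gene(s) missing from expression: ",
                                     paste(miss, collapse = ", "))
  x <- x + pseudocount
  if (any(x[target_group, , drop = FALSE] <= 0))
    validation_error("target-group values must be positive after pseudocount")
  gm <- exp(colMeans(log(x[target_group, , drop = FALSE])))
  out <- sweep(x, 2, gm, "/")
  if (vec) out[, 1] else out
}

#' Class-vs-class differential expression with set enrichment
#'
#' Per-gene two-tailed unpaired t-test on log2 geometric-mean-normalized
#' expression between two CD8 classes, BH-adjusted across genes; genes
#' passing the BH threshold feed the shared hypergeometric
#' over-representation test against the supplied gene sets.
#'
#' @param st An `st_roi_table` (from [gen_st_rois()] or [read_st_rois()]).
#' @param class_a,class_b The two CD8 classes to compare (each >= 2 ROIs);
#'   fold changes are `class_a` over `class_b`.
#' @param target_group Genes for [geomean_normalize()] (required).
#' @param gene_sets Named list of gene sets for enrichment (default: the
#'   table's own sets; `NULL` skips enrichment).
#' @param fdr BH threshold selecting the enrichment input list.
#' @param var_equal Equal-variance Student's t (default) or Welch.
#' @return List with `de` (gene, mean_a, mean_b, log2fc, p_value,
#'   adjusted_p) and `enrichment` (an `enrichment_result` or `NULL`).
#' @export
class_de <- function(st, class_a = "high", class_b = "low", target_group,
                     gene_sets = st$gene_sets, fdr = 0.05, var_equal = TRUE) {
  cls <- st$rois$cd8_class
  ia <- which(cls == class_a); ib <- which(cls == class_b)
  if (length(ia) < 2L || length(ib) < 2L)
    validation_error("each class needs at least 2 ROIs (", class_a, ": ",
                     length(ia), ", ", class_b, ": ", length(ib), ")")
  norm <- geomean_normalize(st$expression, target_group)
  lx <- log2(norm)
  a <- lx[, ia, drop = FALSE]; b <- lx[, ib, drop = FALSE]
  p <- vapply(seq_len(nrow(lx)), function(g)
    safe_t_pvalue(a[g, ], b[g, ], var_equal = var_equal), numeric(1))
  de <- data.frame(gene = rownames(lx),
                   mean_a = rowMeans(a), mean_b = rowMeans(b),
                   log2fc = rowMeans(a) - rowMeans(b),
                   p_value = p, adjusted_p = stats::p.adjust(p, "BH"),
                   row.names = NULL)
  enr <- NULL
  if (!is.null(gene_sets)) {
    sig <- de$gene[de$adjusted_p < fdr]
    enr <- pathway_ora(sig, de$gene, gene_sets)
  }
  list(de = de, enrichment = enr)
}
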