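# Internal helpers shared across modules.

#' @keywords internal
abort <- function(..., class = "imdspatial_error") {
  stop(errorCondition(paste0(...), class = c(class, "imdspatial_error")))
}

validation_error <- function(...) abort(..., class = "imdspatial_validation_error")
layout_error <- function(...) abort(..., class = "imdspatial_layout_error")
schema_error <- function(...) abort(..., class = "imdspatial_schema_error")
format_error <- function(...) abort(..., class = "imdspatial_format_error")

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    validation_error(name, " must be a single finite number")
  if (strict_lower && x <= lower)
    validation_error(name, " must be > ", lower, " (got ", x, ")")
  if (!strict_lower && x < lower)
    validation_error(name, " must be >= ", lower, " (got ", x, ")")
  if (strict_upper && x >= upper)
    validation_error(name, " must be < ", upper, " (got ", x, ")")
  if (!strict_upper && x > upper)
    validation_error(name, " must be <= ", upper, " (got ", x, ")")
  invisible(x)
}

# Run code under a given seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Two-tailed t p-value that tolerates zero-variance inputs (identical groups
# or identical pair differences give p = 1 when the mean difference is 0).
safe_t_pvalue <- function(x, y = NULL, paired = FALSE, var_equal = TRUE) {
  if (paired) {
    d <- x - y
    return(safe_t_pvalue(d))
  }
  if (is.null(y)) {
    if (length(x) < 2L) return(NA_real_)
    if (stats::sd(x) == 0) return(if (mean(x) == 0) 1 else 0)
    return(stats::t.test(x, mu = 0)$p.value)
  }
  if (length(x) < 2L || length(y) < 2L) return(NA_real_)
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (mean(x) == mean(y)) 1 else 0)
  stats::t.test(x, y, var.equal = var_equal)$p.value
}

significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.005, "**", ifelse(p < 0.05, "*", "")))
}

MARKERS <- c("CD3", "CD8", "FOXP3")
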