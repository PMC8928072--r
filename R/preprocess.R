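#' Divide each sample by its median expression
#'
#' Per-sample median normalization: every sample (column) is divided by the
#' median of its values across all genes in the matrix, so that each sample's
#' post-normalization median is exactly 1.  The median is taken over the full
#' (post-intersection) gene universe, zeros included.
#'
#' @param m Expression matrix (genes x samples).
#' @return Matrix of the same shape with per-sample median 1.
#' @export
median_normalize <- function(m) {
  validate_expression_matrix(m)
  med <- apply(m, 2L, median)
  zero <- med <= 0
  if (any(zero)) {
    stop("zero median in sample(s): ",
         paste(colnames(m)[zero], collapse = ", "), call. = FALSE)
  }
  sweep(m, 2L, med, "/")
}

#' Log-transform linear-scale expression
#'
#' Elementwise `x -> log2(1 + scale * x)`.  With the default `scale = 1023`
#' an input of 0 maps to 0 and an input of 1 maps to exactly 10
#' (`log2(1024)`), so values in `[0, 1]` land in `[0, 10]`.
#'
#' @param m Expression matrix (or any non-negative numeric array).
#' @param scale Positive multiplier inside the log (default 1023).
#' @return Transformed values, same shape as `m`.
#' @export
log_transform <- function(m, scale = 1023) {
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    stop("`scale` must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("log_transform requires non-negative finite values", call. = FALSE)
  }
  log2(1 + scale * m)
}

#' Classify breast cancer samples into clinical subtype-like groups
#'
#' Samples are grouped by ESR1 and ERBB2 expression into three advisory
#' labels: `"HER2+"` when ERBB2 >= `erbb2_threshold`; otherwise
#' `"HR+/HER2-"` when ESR1 >= `esr1_threshold`; otherwise `"TN"`
#' (triple-negative-like).  Thresholds are mandatory and must be on the same
#' scale as the matrix (typically applied after [log_transform()]); no
#' default cutoffs are shipped.  A suggested procedure for choosing them is
#' the antimode of a two-component fit to each gene's distribution.
#'
#' @param m Expression matrix containing ESR1 and ERBB2 rows.
#' @param esr1_threshold,erbb2_threshold Numeric cutoffs (no defaults).
#' @return Named character vector: sample_id -> subtype label.
#' @export
classify_breast_subtypes <- function(m, esr1_threshold, erbb2_threshold) {
  validate_expression_matrix(m)
  if (missing(esr1_threshold) || missing(erbb2_threshold) ||
      is.null(esr1_threshold) || is.null(erbb2_threshold)) {
    stop("supply `esr1_threshold` and `erbb2_threshold` explicitly; ",
         "no default cutoffs are provided", call. = FALSE)
  }
  missing_genes <- setdiff(c("ESR1", "ERBB2"), rownames(m))
  if (length(missing_genes)) {
    stop("matrix lacks required gene(s): ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  esr1 <- m["ESR1", ]
  erbb2 <- m["ERBB2", ]
  out <- ifelse(erbb2 >= erbb2_threshold, "HER2+",
         ifelse(esr1 >= esr1_threshold, "HR+/HER2-", "TN"))
  setNames(out, colnames(m))
}
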