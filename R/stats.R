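#' Two-sided Wilcoxon rank-sum test
#'
#' Thin, explicit wrapper around the standard two-sample Wilcoxon (Mann-
#' Whitney) test: exact null enumeration when the combined sample size is at
#' most `exact_cutoff` and the data are tie-free, otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param exact_cutoff Combined-size cutoff for the exact distribution
#'   (default 12).
#' @return List: `statistic` (W, number of (x, y) pairs with x > y counting
#'   ties half), `p_value` (two-sided), `method` ("exact enumeration" or
#'   "normal approximation"), `n1`, `n2`.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value  # 1/3
wilcoxon_rank_sum <- function(x, y, exact_cutoff = 12L) {
  if (!length(x) || !length(y)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n1 <- length(x)
  n2 <- length(y)
  exact <- (n1 + n2) <= exact_cutoff && !anyDuplicated(c(x, y))
  ht <- wilcox.test(x, y, alternative = "two.sided", exact = exact,
                    correct = TRUE)
  list(
    statistic = unname(ht$statistic),
    p_value = unname(ht$p.value),
    method = if (exact) "exact enumeration" else "normal approximation",
    n1 = n1, n2 = n2
  )
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; the p-value comes from the t-distribution
#' transform of r, two-sided.  Constant input is rejected (r undefined).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List: `r`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3L) stop("need >= 3 paired observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  ht <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ht$estimate), p_value = unname(ht$p.value), n = length(x))
}

#' Stratified two-group comparison table
#'
#' For each stratum, compares a numeric value between two groups with the
#' two-sided Wilcoxon rank-sum test and reports group medians, the direction
#' of the difference, the p-value and a significance flag at p < 0.05 (the
#' flat threshold used throughout; optional Benjamini-Hochberg adjustment
#' across strata is available).  Strata missing either group are reported as
#' not testable rather than dropped.
#'
#' @param data Data.frame holding the value, group and stratum columns.
#' @param value Name of the numeric column to compare.
#' @param group Name of the two-level grouping column (e.g. condition).
#' @param strata Name of the stratum column, or NULL for a single pooled
#'   stratum.
#' @param groups Optional length-2 character vector fixing the group order
#'   (difference reported as first minus second); defaults to sorted levels.
#' @param p_adjust "none" (default) or "BH".
#' @return Data.frame: one row per stratum with columns `stratum`, `n_<g1>`,
#'   `n_<g2>`, `median_<g1>`, `median_<g2>`, `direction`, `statistic`, `p`,
#'   `significant`, `testable`.
#' @export
groupwise_compare <- function(data, value, group, strata = NULL,
                              groups = NULL, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  for (col in c(value, group, strata)) {
    if (!col %in% names(data)) {
      stop(sprintf("unknown column '%s'", col), call. = FALSE)
    }
  }
  if (is.null(groups)) groups <- sort(unique(as.character(data[[group]])))
  if (length(groups) != 2L) {
    stop("`group` must have exactly two levels (or supply `groups`)",
         call. = FALSE)
  }
  strat_vals <- if (is.null(strata)) rep("all", nrow(data)) else
    as.character(data[[strata]])
  rows <- lapply(sort(unique(strat_vals)), function(s) {
    d <- data[strat_vals == s, , drop = FALSE]
    v1 <- d[[value]][d[[group]] == groups[[1L]]]
    v2 <- d[[value]][d[[group]] == groups[[2L]]]
    if (!length(v1) || !length(v2)) {
      return(data.frame(
        stratum = s, n1 = length(v1), n2 = length(v2),
        median1 = if (length(v1)) median(v1) else NA_real_,
        median2 = if (length(v2)) median(v2) else NA_real_,
        direction = NA_character_, statistic = NA_real_, p = NA_real_,
        significant = NA, testable = FALSE, stringsAsFactors = FALSE
      ))
    }
    wt <- wilcoxon_rank_sum(v1, v2)
    m1 <- median(v1)
    m2 <- median(v2)
    data.frame(
      stratum = s, n1 = wt$n1, n2 = wt$n2, median1 = m1, median2 = m2,
      direction = if (m1 > m2) ">" else if (m1 < m2) "<" else "=",
      statistic = wt$statistic, p = wt$p_value, significant = NA,
      testable = TRUE, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") out$p[out$testable] <- p.adjust(out$p[out$testable], "BH")
  out$significant <- ifelse(out$testable, out$p < 0.05, NA)
  names(out)[names(out) == "n1"] <- paste0("n_", groups[[1L]])
  names(out)[names(out) == "n2"] <- paste0("n_", groups[[2L]])
  names(out)[names(out) == "median1"] <- paste0("median_", groups[[1L]])
  names(out)[names(out) == "median2"] <- paste0("median_", groups[[2L]])
  out
}

#' Stratified Pearson correlation table
#'
#' Pearson r (with two-sided p) between two paired per-sample quantities
#' within each stratum.  Strata with fewer than 3 complete pairs or a
#' constant input are flagged not testable.
#'
#' @param data Data.frame holding both value columns and the stratum column.
#' @param x,y Names of the two numeric columns.
#' @param strata Name of the stratum column, or NULL for one pooled stratum.
#' @return Data.frame: `stratum`, `n`, `r`, `p`, `significant`, `testable`.
#' @export
correlation_by_stratum <- function(data, x, y, strata = NULL) {
  for (col in c(x, y, strata)) {
    if (!col %in% names(data)) {
      stop(sprintf("unknown column '%s'", col), call. = FALSE)
    }
  }
  strat_vals <- if (is.null(strata)) rep("all", nrow(data)) else
    as.character(data[[strata]])
  rows <- lapply(sort(unique(strat_vals)), function(s) {
    d <- data[strat_vals == s, , drop = FALSE]
    xv <- d[[x]]
    yv <- d[[y]]
    keep <- is.finite(xv) & is.finite(yv)
    xv <- xv[keep]
    yv <- yv[keep]
    if (length(xv) < 3L || sd(xv) == 0 || sd(yv) == 0) {
      return(data.frame(stratum = s, n = length(xv), r = NA_real_,
                        p = NA_real_, significant = NA, testable = FALSE,
                        stringsAsFactors = FALSE))
    }
    ct <- pearson_cor(xv, yv)
    data.frame(stratum = s, n = ct$n, r = ct$r, p = ct$p_value,
               significant = ct$p_value < 0.05, testable = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
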