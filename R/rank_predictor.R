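#' Rank samples across the cohort for each gene
#'
#' For each requested gene present in the matrix, samples are ranked by that
#' gene's expression, ascending (lowest expression = rank 1), ties averaged.
#' Absent genes are dropped with a warning; it is an error if none remain.
#' Because ranking absorbs any per-gene strictly increasing transform, the
#' result is insensitive to the expression unit or normalization.
#'
#' @param m Expression matrix (genes x samples, >= 2 samples).
#' @param genes Character vector of gene symbols to rank on.
#' @return Numeric matrix (genes x samples) of per-gene sample ranks.
#' @export
rank_samples_per_gene <- function(m, genes) {
  validate_expression_matrix(m)
  if (ncol(m) < 2L) stop("need at least 2 samples to rank", call. = FALSE)
  present <- intersect(genes, rownames(m))
  absent <- setdiff(genes, rownames(m))
  if (!length(present)) {
    stop("none of the requested genes are present in the matrix",
         call. = FALSE)
  }
  if (length(absent)) {
    warning("gene(s) absent from matrix dropped from ranking: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  t(apply(m[present, , drop = FALSE], 1L,
          function(x) rank(x, ties.method = "average")))
}

#' Sum of per-gene cohort ranks
#'
#' A sample's score is the sum, over the available panel genes, of its
#' across-cohort rank for that gene; higher sums predict response.  With G
#' genes over S samples every score lies in `[G, G*S]`.  When some panel
#' genes are unavailable the sum runs over those present, without rescaling;
#' `rescale = TRUE` divides by the number of genes used (mean rank) for
#' cross-cohort comparability.
#'
#' @param gene_ranks Matrix from [rank_samples_per_gene()].
#' @param rescale Divide by the number of genes used (default FALSE).
#' @return Data.frame with `sample_id`, `sum_of_ranks`, `genes_used`.
#' @export
sum_of_ranks <- function(gene_ranks, rescale = FALSE) {
  if (!is.matrix(gene_ranks) || nrow(gene_ranks) < 1L) {
    stop("`gene_ranks` must be a matrix with >= 1 gene row", call. = FALSE)
  }
  s <- colSums(gene_ranks)
  g <- nrow(gene_ranks)
  if (rescale) s <- s / g
  data.frame(sample_id = colnames(gene_ranks), sum_of_ranks = unname(s),
             genes_used = g, row.names = NULL, stringsAsFactors = FALSE)
}

#' ROC curve and tie-aware AUC
#'
#' Sweeps thresholds over the unique score values (predicting "responder"
#' for scores at or above the threshold) to build the ROC polygon, and
#' computes the AUC through the tie-aware Mann-Whitney identity:
#' the probability that a random responder outscores a random non-responder,
#' ties counted half.  The trapezoidal area of the polygon and the
#' Mann-Whitney value agree exactly and this is asserted internally.
#'
#' @param scores Numeric vector of per-sample scores.
#' @param labels Vector parallel to `scores`: logical (TRUE = responder) or
#'   character/factor with values "responder"/"non-responder".
#' @return List of class `roc_result`: `points` (data.frame `fpr`, `tpr`
#'   from (0,0) to (1,1)), `auc`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_auc(c(3, 1, 2, 1), c(TRUE, TRUE, FALSE, FALSE))$auc  # 0.625
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` differ in length", call. = FALSE)
  }
  if (is.logical(labels)) {
    pos <- labels
  } else {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), c("responder", "non-responder"))
    if (length(bad)) {
      stop("labels must be 'responder'/'non-responder'; found: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    pos <- labels == "responder"
  }
  if (any(is.na(scores)) || any(is.na(pos))) {
    stop("missing scores or labels", call. = FALSE)
  }
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("need at least one responder and one non-responder", call. = FALSE)
  }
  # Mann-Whitney with half credit for ties
  r <- rank(scores, ties.method = "average")
  u <- sum(r[pos]) - n_pos * (n_pos + 1) / 2
  auc_u <- u / (n_pos * n_neg)
  # threshold sweep: walk scores in decreasing order, closing each tie block
  ord <- order(-scores)
  s_ord <- scores[ord]
  block_end <- c(s_ord[-1L] != s_ord[-length(s_ord)], TRUE)
  tp <- cumsum(pos[ord])[block_end]
  fp <- cumsum(!pos[ord])[block_end]
  points <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  auc_trap <- sum(diff(points$fpr) *
                  (points$tpr[-1L] + points$tpr[-nrow(points)]) / 2)
  stopifnot(abs(auc_trap - auc_u) < 1e-12)
  structure(list(points = points, auc = auc_u, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d responders vs %d non-responders, %d points)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' Sum-of-ranks response prediction for an on-treatment cohort
#'
#' Computes the panel sum-of-ranks score for every on-treatment sample and
#' evaluates it against the response labels by ROC/AUC, pooled across
#' treatment arms and per arm.  Ranking is cohort-relative: with
#' `ranking = "pooled"` (default) samples are ranked across the whole
#' on-treatment cohort before summing; `ranking = "per_arm"` ranks within
#' each arm separately.  When `control_genes` is supplied the identical
#' evaluation is produced for the control signature.
#'
#' @param m Expression matrix over the cohort.
#' @param meta Metadata data.frame with columns `sample_id`, `arm`
#'   (anti-PD-1 / anti-CTLA-4 / none) and `response`
#'   (responder / non-responder / not-applicable).
#' @param panel_genes Character vector of panel gene symbols (default: the
#'   15-gene immunogenicity panel).
#' @param control_genes Optional character vector of control gene symbols.
#' @param ranking "pooled" or "per_arm".
#' @param rescale Passed to [sum_of_ranks()].
#' @return List with elements `panel` and (if requested) `control`, each a
#'   list of `scores` (data.frame), `roc_pooled` (`roc_result`) and
#'   `roc_by_arm` (named list of `roc_result`, arms with a single response
#'   class reported as NULL).
#' @export
predict_cohort <- function(m, meta, panel_genes = panel_definition()$immunogenicity,
                           control_genes = NULL,
                           ranking = c("pooled", "per_arm"),
                           rescale = FALSE) {
  ranking <- match.arg(ranking)
  validate_expression_matrix(m)
  unmatched <- setdiff(colnames(m), meta$sample_id)
  if (length(unmatched)) {
    stop("samples missing from metadata: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  on_trt <- meta$arm != "none" & meta$response %in% c("responder", "non-responder")
  if (sum(on_trt) < 2L) {
    stop("need >= 2 on-treatment samples with response labels", call. = FALSE)
  }
  m <- m[, on_trt, drop = FALSE]
  meta <- meta[on_trt, , drop = FALSE]

  eval_set <- function(genes) {
    if (ranking == "pooled") {
      scores <- sum_of_ranks(rank_samples_per_gene(m, genes),
                             rescale = rescale)
    } else {
      per_arm <- lapply(split(seq_len(ncol(m)), meta$arm), function(idx) {
        if (length(idx) < 2L) return(NULL)
        sum_of_ranks(rank_samples_per_gene(m[, idx, drop = FALSE], genes),
                     rescale = rescale)
      })
      scores <- do.call(rbind, per_arm[!vapply(per_arm, is.null, logical(1L))])
      scores <- scores[match(colnames(m), scores$sample_id), , drop = FALSE]
      rownames(scores) <- NULL
    }
    resp <- meta$response[match(scores$sample_id, meta$sample_id)]
    arm <- meta$arm[match(scores$sample_id, meta$sample_id)]
    roc_by_arm <- lapply(split(seq_along(resp), arm), function(idx) {
      if (length(unique(resp[idx])) < 2L) return(NULL)
      roc_auc(scores$sum_of_ranks[idx], resp[idx])
    })
    list(scores = scores,
         roc_pooled = roc_auc(scores$sum_of_ranks, resp),
         roc_by_arm = roc_by_arm)
  }

  out <- list(panel = eval_set(panel_genes))
  if (!is.null(control_genes)) out$control <- eval_set(control_genes)
  out
}
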