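#' Consistency check: tumor vs normal scores and activation/checkpoint coupling
#'
#' Per tissue: two-sided Wilcoxon comparisons of the activation and
#' checkpoint scores between tumor and normal samples, and per tissue x
#' condition the Pearson correlation between the two scores.  Tissues whose
#' tumor-sample correlation falls below `r_threshold` (default 0.5) are
#' flagged for exclusion from any combined 15-gene score, since a single
#' immunogenicity score is only justified where the two component scores
#' move together.
#'
#' @param m Expression matrix.
#' @param meta Metadata with `sample_id`, `tissue`, `condition`.
#' @param panel Panel definition, see [panel_definition()].
#' @param alpha ssGSEA exponent.
#' @param r_threshold Minimum tumor activation-checkpoint correlation
#'   (default 0.5).
#' @return List: `tests` (per tissue x score comparison table),
#'   `correlations` (per tissue x condition r), `excluded_tissues`,
#'   `scores`, or a skip record (`skipped = TRUE`, `reason`) when only one
#'   condition is present.
#' @export
run_consistency_check <- function(m, meta, panel = panel_definition(),
                                  alpha = 0.25, r_threshold = 0.5) {
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  if (length(unique(meta$condition)) < 2L) {
    return(list(skipped = TRUE,
                reason = "both tumor and normal samples are required"))
  }
  scores <- compute_panel_scores(m, panel, alpha = alpha)
  d <- cbind(scores, meta[match(scores$sample_id, meta$sample_id),
                          c("tissue", "condition")])
  tests <- do.call(rbind, lapply(c("activation", "checkpoint"), function(sc) {
    t <- groupwise_compare(d, value = sc, group = "condition",
                           strata = "tissue", groups = c("tumor", "normal"))
    cbind(score = sc, t, stringsAsFactors = FALSE)
  }))
  corr <- do.call(rbind, lapply(split(d, list(d$tissue, d$condition),
                                      drop = TRUE), function(dd) {
    ct <- correlation_by_stratum(dd, "activation", "checkpoint")
    data.frame(tissue = dd$tissue[[1L]], condition = dd$condition[[1L]],
               n = ct$n, r = ct$r, p = ct$p, testable = ct$testable,
               stringsAsFactors = FALSE)
  }))
  rownames(corr) <- NULL
  tumor_r <- corr[corr$condition == "tumor", , drop = FALSE]
  excluded <- tumor_r$tissue[!is.na(tumor_r$r) & tumor_r$r < r_threshold |
                               !tumor_r$testable]
  list(skipped = FALSE, tests = tests, correlations = corr,
       excluded_tissues = excluded, scores = scores)
}

#' Validation: immunogenicity score against infiltration readouts
#'
#' Per-tissue Pearson correlation of the 15-gene immunogenicity score with
#' the pathology-based infiltration score and/or the in-silico infiltration
#' estimate, whichever the metadata provides, and the identical table for a
#' control signature to show the association is panel-specific.
#'
#' @param m Expression matrix.
#' @param meta Metadata with `sample_id`, `tissue` and at least one of
#'   `pathology_score`, `true_infiltration`.
#' @param panel Panel definition.
#' @param control_genes Control signature (default [control_panel_genes()]);
#'   NULL to skip the control analysis.
#' @param alpha ssGSEA exponent.
#' @return List: one correlation table per available readout for the panel
#'   (`pathology`, `infiltration`) and the control signature
#'   (`control_pathology`, `control_infiltration`), plus `scores`; or a skip
#'   record when no readout is present.
#' @export
run_validation <- function(m, meta, panel = panel_definition(),
                           control_genes = control_panel_genes(),
                           alpha = 0.25) {
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  readouts <- intersect(c("pathology_score", "true_infiltration"), names(meta))
  readouts <- readouts[vapply(readouts,
                              function(r) any(is.finite(meta[[r]])),
                              logical(1L))]
  if (!length(readouts)) {
    return(list(skipped = TRUE,
                reason = "no pathology_score or true_infiltration in metadata"))
  }
  sets <- list(immunogenicity = intersect(panel$immunogenicity, rownames(m)))
  if (!is.null(control_genes)) {
    sets$control <- intersect(control_genes, rownames(m))
  }
  scores <- score_matrix(m, sets, alpha = alpha)
  d <- cbind(scores, meta[match(scores$sample_id, meta$sample_id),
                          c("tissue", readouts), drop = FALSE])
  out <- list(skipped = FALSE, scores = scores)
  labels <- c(pathology_score = "pathology", true_infiltration = "infiltration")
  for (r in readouts) {
    out[[labels[[r]]]] <-
      correlation_by_stratum(d, "immunogenicity", r, strata = "tissue")
    if (!is.null(control_genes)) {
      out[[paste0("control_", labels[[r]])]] <-
        correlation_by_stratum(d, "control", r, strata = "tissue")
    }
  }
  out
}

#' Prediction: sum-of-ranks response scoring with ROC/AUC
#'
#' Runs [predict_cohort()] for the 15-gene panel and, when supplied, the
#' control signature, returning scores, pooled and per-arm ROC results and a
#' compact AUC summary table.
#'
#' @param m Expression matrix of an on-treatment cohort.
#' @param meta Metadata with `sample_id`, `arm`, `response`.
#' @param panel Panel definition.
#' @param control_genes Control signature or NULL.
#' @param ranking,rescale Passed to [predict_cohort()].
#' @return List: `prediction` (the [predict_cohort()] result), `auc_summary`
#'   (data.frame of signature x arm AUCs); or a skip record when the cohort
#'   has no labelled on-treatment samples of both classes.
#' @export
run_prediction <- function(m, meta, panel = panel_definition(),
                           control_genes = control_panel_genes(),
                           ranking = "pooled", rescale = FALSE) {
  meta_m <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  on_trt <- meta_m$arm != "none" &
    meta_m$response %in% c("responder", "non-responder")
  if (length(unique(meta_m$response[on_trt])) < 2L) {
    return(list(skipped = TRUE,
                reason = "need on-treatment samples of both response classes"))
  }
  pred <- predict_cohort(m, meta, panel_genes = panel$immunogenicity,
                         control_genes = control_genes, ranking = ranking,
                         rescale = rescale)
  summarize <- function(res, label) {
    rows <- data.frame(signature = label, arm = "pooled",
                       auc = res$roc_pooled$auc,
                       n_pos = res$roc_pooled$n_pos,
                       n_neg = res$roc_pooled$n_neg,
                       stringsAsFactors = FALSE)
    for (a in names(res$roc_by_arm)) {
      r <- res$roc_by_arm[[a]]
      if (is.null(r)) next
      rows <- rbind(rows, data.frame(signature = label, arm = a, auc = r$auc,
                                     n_pos = r$n_pos, n_neg = r$n_neg,
                                     stringsAsFactors = FALSE))
    }
    rows
  }
  auc_summary <- summarize(pred$panel, "panel")
  if (!is.null(pred$control)) {
    auc_summary <- rbind(auc_summary, summarize(pred$control, "control"))
  }
  list(skipped = FALSE, prediction = pred, auc_summary = auc_summary)
}

#' Run all three analysis stages and assemble a report
#'
#' Orchestrates the consistency check (tumor/normal cohort), the validation
#' stage (infiltration readouts) and the response prediction stage
#' (on-treatment cohort).  Each stage runs when its inputs allow and is
#' otherwise recorded as skipped with a reason, since the three stages use
#' different cohorts.  The report carries full provenance (configs, seeds,
#' package version) and is byte-reproducible for identical inputs.
#'
#' @param tissue_cohort Optional list with `matrix` and `meta` (e.g. a
#'   [generate_tissue_cohort()] result) for the consistency and validation
#'   stages.
#' @param icb_cohort Optional list with `matrix` and `meta` for the
#'   prediction stage.
#' @param panel Panel definition.
#' @param control_genes Control signature or NULL.
#' @param alpha ssGSEA exponent.
#' @param ranking Passed to [run_prediction()].
#' @return List of class `run_report`: `consistency`, `validation`,
#'   `prediction`, `provenance`.
#' @export
run_report <- function(tissue_cohort = NULL, icb_cohort = NULL,
                       panel = panel_definition(),
                       control_genes = control_panel_genes(),
                       alpha = 0.25, ranking = "pooled") {
  skip <- function(reason) list(skipped = TRUE, reason = reason)
  consistency <- if (is.null(tissue_cohort)) skip("no tumor/normal cohort") else
    run_consistency_check(tissue_cohort$matrix, tissue_cohort$meta, panel,
                          alpha = alpha)
  validation <- if (is.null(tissue_cohort)) skip("no tumor/normal cohort") else
    run_validation(tissue_cohort$matrix, tissue_cohort$meta, panel,
                   control_genes = control_genes, alpha = alpha)
  prediction <- if (is.null(icb_cohort)) skip("no on-treatment cohort") else
    run_prediction(icb_cohort$matrix, icb_cohort$meta, panel,
                   control_genes = control_genes, ranking = ranking)
  provenance <- list(
    alpha = alpha, ranking = ranking,
    panel = panel, control_genes = control_genes,
    tissue_config = tissue_cohort$truth$config,
    icb_config = icb_cohort$truth$config,
    package_version = as.character(packageVersion("immunopanel"))
  )
  structure(list(consistency = consistency, validation = validation,
                 prediction = prediction, provenance = provenance),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  stage_line <- function(name, s) {
    if (isTRUE(s$skipped)) {
      cat(sprintf("  %s: skipped (%s)\n", name, s$reason))
    } else {
      cat(sprintf("  %s: run\n", name))
    }
  }
  cat("immunopanel run report\n")
  stage_line("consistency", x$consistency)
  stage_line("validation", x$validation)
  stage_line("prediction", x$prediction)
  if (!isTRUE(x$prediction$skipped)) {
    print(x$prediction$auc_summary, row.names = FALSE)
  }
  invisible(x)
}
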