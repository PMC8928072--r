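#' The fixed 15-gene immune activation/checkpoint panel
#'
#' Six immune activation genes covering the interferon-gamma axis, T-cell
#' chemotaxis, cytotoxic T-cell infiltration and effector function, and nine
#' checkpoint-pathway genes covering the PD-1 axis (receptor and both
#' ligands), the CTLA-4 axis (receptor and both ligands) and three further
#' checkpoints (LAG3, HAVCR2/TIM-3, BTLA).  The immunogenicity set is the
#' union of the two.
#'
#' @return List with character vectors `activation` (6 genes), `checkpoint`
#'   (9 genes) and `immunogenicity` (all 15).
#' @export
#' @examples
#' lengths(panel_definition())
panel_definition <- function() {
  activation <- c("IFNG", "CXCL9", "CXCL10", "CD8A", "PRF1", "GZMB")
  checkpoint <- c("PDCD1", "CD274", "PDCD1LG2", "CTLA4", "CD80", "CD86",
                  "LAG3", "HAVCR2", "BTLA")
  list(
    activation = activation,
    checkpoint = checkpoint,
    immunogenicity = c(activation, checkpoint)
  )
}

#' The fixed 15-gene non-immune control panel
#'
#' Fifteen genes drawn once from non-immune genes, used as a negative-control
#' signature: every analysis run for the immune panel can be repeated with
#' these genes to show the result is panel-specific.
#'
#' @return Character vector of 15 gene symbols.
#' @export
control_panel_genes <- function() {
  c("AMIGO1", "CDH1", "CYCS", "EFNA3", "EFNA5", "EPHA7", "NFKBIE",
    "NKIRAS1", "P4HA2", "S100A5", "S1PR2", "SDHA", "SEMA3F", "SEMA4B",
    "SEMA5A")
}

#' Compute activation, checkpoint and immunogenicity scores
#'
#' ssGSEA scores of the 6-gene activation set, the 9-gene checkpoint set and
#' their 15-gene union, one row per sample.  Panel genes absent from the
#' matrix are dropped with a warning (as when a platform does not measure a
#' gene, e.g. a panel assay lacking BTLA) rather than imputed; it is an error
#' for either the activation or the checkpoint set to vanish entirely.
#'
#' @param m Expression matrix (genes x samples).
#' @param panel Panel definition as from [panel_definition()].
#' @param alpha Rank-weighting exponent, see [ssgsea_score()].
#' @param rescale Passed to [score_matrix()].
#' @return Data.frame with columns `sample_id`, `activation`, `checkpoint`,
#'   `immunogenicity`.
#' @export
compute_panel_scores <- function(m, panel = panel_definition(), alpha = 0.25,
                                 rescale = FALSE) {
  validate_expression_matrix(m)
  act <- intersect(panel$activation, rownames(m))
  chk <- intersect(panel$checkpoint, rownames(m))
  dropped <- setdiff(c(panel$activation, panel$checkpoint), rownames(m))
  if (length(act) == 0L || length(chk) == 0L) {
    stop("no activation and/or checkpoint panel genes present in the matrix",
         call. = FALSE)
  }
  if (length(dropped)) {
    warning("panel gene(s) absent from matrix, scoring without them: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  sets <- list(activation = act, checkpoint = chk,
               immunogenicity = c(act, chk))
  score_matrix(m, sets, alpha = alpha, rescale = rescale)
}

#' Draw a random control panel from the non-immune universe
#'
#' Uniform sample without replacement of `n` genes from
#' `universe \ excluded`, reproducible for a fixed seed.
#'
#' @param universe Character vector of candidate gene symbols.
#' @param n Number of genes to draw (default 15).
#' @param excluded Gene symbols never eligible (e.g. the immune panel);
#'   default is the 15-gene panel itself.
#' @param seed Integer seed.
#' @return Character vector of `n` gene symbols.
#' @export
draw_control_panel <- function(universe, n = 15L,
                               excluded = panel_definition()$immunogenicity,
                               seed = 1L) {
  eligible <- setdiff(unique(universe), excluded)
  if (length(eligible) < n) {
    stop(sprintf("only %d eligible genes for a control panel of %d",
                 length(eligible), n), call. = FALSE)
  }
  with_seed(seed, sort(sample(eligible, n)))
}
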