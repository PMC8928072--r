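#' Rank genes within one sample
#'
#' Ascending ranks of expression within a single sample: the highest-expressed
#' gene gets rank N, ties receive the average of the positions they cover.
#'
#' @param values Numeric vector of per-gene expression for one sample
#'   (length >= 2).
#' @return Numeric vector of ranks in `[1, N]`, names preserved.
#' @export
#' @examples
#' rank_within_sample(c(A = 10, B = 20, C = 30))
rank_within_sample <- function(values) {
  if (length(values) < 2L) stop("need at least 2 genes", call. = FALSE)
  rank(values, ties.method = "average")
}

# Running-sum enrichment from precomputed ranks.
# r:      average ranks of all genes in the sample
# ord:    positions ordering genes by decreasing rank
# in_set: logical membership vector over genes
# Tied ranks are walked as one atomic block: every position inside a tied
# block takes the block-end cumulative fractions, so the score does not
# depend on the arbitrary order within ties and an all-tied sample scores 0
# for every set.
.es_walk <- function(r, ord, in_set, alpha) {
  n_total <- length(r)
  n_in <- sum(in_set)
  io <- in_set[ord]
  w <- numeric(n_total)
  w[io] <- r[ord][io]^alpha
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!io) / (n_total - n_in)
  rr <- r[ord]
  block_end <- c(rr[-1L] != rr[-n_total], TRUE)
  sizes <- diff(c(0L, which(block_end)))
  sum(sizes * (p_in[block_end] - p_out[block_end]))
}

#' Single-sample gene-set enrichment score (ssGSEA)
#'
#' Per-sample running-sum enrichment statistic.  Genes are ranked within the
#' sample (ascending; ties averaged) and walked in order of decreasing rank.
#' At each position the weighted in-set cumulative fraction (weights
#' `rank^alpha`) minus the unweighted out-of-set cumulative fraction is
#' accumulated; the score is the sum of these differences over all
#' positions.  Tied ranks are walked as one atomic block (every position in
#' a tied block takes the block-end cumulative fractions), which makes the
#' score independent of any arbitrary ordering within ties and gives a
#' constant sample a score of exactly 0 for every set.  Being purely
#' rank-based, the score is invariant to any strictly increasing transform
#' of the sample's values.
#'
#' @param sample_values Named numeric vector: per-gene expression of one
#'   sample.  Names are the gene universe.
#' @param gene_set Character vector of gene symbols, or a gene-set list with a
#'   `genes` element (as from [read_gmt()]).
#' @param alpha Non-negative rank-weighting exponent (default 0.25, the
#'   convention of the ssGSEA implementation used for immune scoring;
#'   `alpha = 0` gives the unweighted Kolmogorov-Smirnov-style running sum).
#' @return A single numeric enrichment score.
#' @export
#' @examples
#' x <- c(A = 5, B = 4, C = 3, D = 2, E = 1)
#' ssgsea_score(x, c("A", "B"), alpha = 0)  # 2.5
ssgsea_score <- function(sample_values, gene_set, alpha = 0.25) {
  if (is.list(gene_set)) gene_set <- gene_set$genes
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0) {
    stop("`alpha` must be a single non-negative number", call. = FALSE)
  }
  genes <- names(sample_values)
  if (is.null(genes) || length(sample_values) < 2L) {
    stop("`sample_values` must be a named vector of >= 2 genes",
         call. = FALSE)
  }
  absent <- setdiff(gene_set, genes)
  if (length(absent)) {
    warning("gene(s) absent from universe dropped: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  in_set <- genes %in% gene_set
  if (!any(in_set)) stop("gene set has no genes in the universe", call. = FALSE)
  if (all(in_set)) {
    stop("gene set covers the whole universe; enrichment undefined",
         call. = FALSE)
  }
  r <- rank_within_sample(sample_values)
  ord <- order(-r, genes, method = "radix")
  .es_walk(r, ord, in_set, alpha)
}

#' Score every sample of a matrix against a list of gene sets
#'
#' Each sample is scored independently (no cross-sample normalization by
#' default), so scores are unchanged by adding, removing or permuting other
#' samples.  Set `rescale = TRUE` for the dialect that divides each set's
#' scores by their range across samples.
#'
#' @param m Expression matrix (genes x samples).
#' @param sets Named list of gene sets: character vectors or gene-set lists
#'   with a `genes` element.
#' @param alpha Rank-weighting exponent, see [ssgsea_score()].
#' @param rescale Divide each set's column by its range across samples
#'   (default FALSE).
#' @return Data.frame with `sample_id` plus one numeric column per set.
#' @export
score_matrix <- function(m, sets, alpha = 0.25, rescale = FALSE) {
  validate_expression_matrix(m)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("`sets` must be a named list", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate set names in `sets`", call. = FALSE)
  }
  genes <- rownames(m)
  memberships <- lapply(sets, function(s) {
    if (is.list(s)) s <- s$genes
    absent <- setdiff(s, genes)
    if (length(absent)) {
      warning("gene(s) absent from universe dropped: ",
              paste(absent, collapse = ", "), call. = FALSE)
    }
    in_set <- genes %in% s
    if (!any(in_set)) {
      stop("a gene set has no genes in the matrix universe", call. = FALSE)
    }
    if (all(in_set)) {
      stop("a gene set covers the whole universe; enrichment undefined",
           call. = FALSE)
    }
    in_set
  })
  scores <- matrix(NA_real_, nrow = ncol(m), ncol = length(sets),
                   dimnames = list(colnames(m), names(sets)))
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j], ties.method = "average")
    ord <- order(-r, genes, method = "radix")
    for (k in seq_along(memberships)) {
      scores[j, k] <- .es_walk(r, ord, memberships[[k]], alpha)
    }
  }
  if (rescale) {
    rng <- apply(scores, 2L, function(x) diff(range(x)))
    rng[rng == 0] <- 1
    scores <- sweep(scores, 2L, rng, "/")
  }
  data.frame(sample_id = colnames(m), scores, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
}
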