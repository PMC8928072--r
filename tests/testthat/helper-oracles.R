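# Independent brute-force oracles, implemented from the definitions by
# explicit per-gene summation / pairwise enumeration, sharing no code path
# with the package internals.

# Enrichment score by direct summation: for each distinct rank level
# (walked from the top), the in-set weighted fraction and out-of-set
# fraction at the end of that level's block, each computed by explicit set
# comprehension over all genes; the block contributes its size times the
# difference.
oracle_ssgsea <- function(values, set_genes, alpha) {
  genes <- names(values)
  r <- rank(values, ties.method = "average")
  in_set <- genes %in% set_genes
  stopifnot(any(in_set), !all(in_set))
  denom_in <- sum(r[in_set]^alpha)
  n_out <- sum(!in_set)
  es <- 0
  for (lev in sort(unique(r), decreasing = TRUE)) {
    size <- sum(r == lev)
    p_in <- sum(r[in_set][r[in_set] >= lev]^alpha) / denom_in
    p_out <- sum(r[!in_set] >= lev) / n_out
    es <- es + size * (p_in - p_out)
  }
  es
}

# Average rank by counting: (number strictly below) + (ties + 1) / 2.
oracle_rank <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
}

# AUC by exhaustive pairwise comparison, ties counted half.
oracle_auc <- function(scores, is_responder) {
  pos <- scores[is_responder]
  neg <- scores[!is_responder]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Small random expression matrix with positive values and optional ties.
random_matrix <- function(n_genes, n_samples, with_ties = FALSE) {
  vals <- if (with_ties) {
    matrix(sample(1:max(3L, n_genes %/% 2), n_genes * n_samples,
                  replace = TRUE), n_genes, n_samples)
  } else {
    matrix(rexp(n_genes * n_samples, rate = 0.2), n_genes, n_samples)
  }
  dimnames(vals) <- list(sprintf("G%03d", seq_len(n_genes)),
                         sprintf("S%03d", seq_len(n_samples)))
  vals * 1.0
}

# Random strictly increasing map on [0, Inf): positive-coefficient mix of
# identity, log1p and square terms plus a non-negative offset.
random_monotone_map <- function() {
  a <- runif(1, 0.1, 2)
  b <- runif(1, 0.1, 2)
  c0 <- runif(1, 0, 0.5)
  d <- runif(1, 0, 5)
  function(x) a * x + b * log1p(x) + c0 * x^2 + d
}

# Small fast generator config for replicate-heavy tests.
small_config <- function(...) {
  cohort_config(n_background_genes = 40L, ...)
}
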