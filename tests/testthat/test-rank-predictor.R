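test_that("per-gene sample ranks are ascending with averaged ties", {
  m <- rbind(g1 = c(3, 1, 2), g2 = c(4, 4, 9))
  colnames(m) <- c("s1", "s2", "s3")
  r <- rank_samples_per_gene(m, c("g1", "g2"))
  expect_equal(r["g1", ], c(s1 = 3, s2 = 1, s3 = 2))
  expect_equal(r["g2", ], c(s1 = 1.5, s2 = 1.5, s3 = 3))
  expect_warning(r2 <- rank_samples_per_gene(m, c("g1", "nope")), "nope")
  expect_identical(rownames(r2), "g1")
  expect_error(rank_samples_per_gene(m, "nope"), "none")
})

test_that("per-gene ranks match a counting oracle on random fixtures", {
  set.seed(31)
  m <- random_matrix(15, 6, with_ties = TRUE)
  r <- rank_samples_per_gene(m, rownames(m))
  for (g in rownames(m)) {
    expect_equal(r[g, ], oracle_rank(m[g, ]), ignore_attr = TRUE)
  }
})

test_that("sum_of_ranks attains its bounds and sums hand-checked fixtures", {
  # one sample highest in every gene: score = G * S
  m <- rbind(g1 = c(1, 2, 9), g2 = c(3, 1, 8), g3 = c(2, 3, 9))
  colnames(m) <- c("a", "b", "top")
  s <- sum_of_ranks(rank_samples_per_gene(m, rownames(m)))
  expect_equal(s$sum_of_ranks[s$sample_id == "top"], 3 * 3)
  expect_true(all(s$sum_of_ranks >= 3 & s$sum_of_ranks <= 9))
  expect_equal(s$genes_used, rep(3L, 3))
  # single gene: score equals that gene's rank
  s1 <- sum_of_ranks(rank_samples_per_gene(m, "g1"))
  expect_equal(s1$sum_of_ranks, c(1, 2, 3))
  # rescaled variant divides by genes used
  expect_equal(sum_of_ranks(rank_samples_per_gene(m, rownames(m)),
                            rescale = TRUE)$sum_of_ranks,
               s$sum_of_ranks / 3)
})

test_that("a 14-gene cohort sums ranks over the available genes only", {
  set.seed(32)
  panel <- panel_definition()$immunogenicity
  m <- random_matrix(20, 5)
  rownames(m)[1:14] <- setdiff(panel, "BTLA")
  expect_warning(r <- rank_samples_per_gene(m, panel), "BTLA")
  s <- sum_of_ranks(r)
  expect_equal(s$genes_used, rep(14L, 5))
  hand <- colSums(apply(m[rownames(m) %in% panel, ], 1, rank) |> t())
  expect_equal(s$sum_of_ranks, unname(hand))
})

test_that("ROC/AUC reproduces hand-enumerated cases", {
  expect_equal(roc_auc(c(3, 2, 1), c(TRUE, TRUE, FALSE))$auc, 1)
  expect_equal(roc_auc(rep(2, 5), c(TRUE, TRUE, FALSE, FALSE, FALSE))$auc, 0.5)
  r <- roc_auc(c(3, 1, 2, 1),
               c("responder", "responder", "non-responder", "non-responder"))
  expect_equal(r$auc, 0.625)  # pairwise: (1 + 1 + 0.5 + 0) / 4
  expect_equal(r$points[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(r$points[nrow(r$points), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "non-responder")
  expect_error(roc_auc(1:3, c("responder", "maybe", "non-responder")), "maybe")
})

test_that("trapezoid, Mann-Whitney, pROC and the pairwise oracle agree", {
  set.seed(33)
  for (rep in 1:40) {
    n <- sample(4:25, 1)
    scores <- sample(1:8, n, replace = TRUE)  # heavy ties
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    r <- roc_auc(scores, labels)  # internally asserts trapezoid == U
    expect_equal(r$auc, oracle_auc(scores, labels))
    if (requireNamespace("pROC", quietly = TRUE)) {
      expect_equal(r$auc,
                   as.numeric(pROC::auc(pROC::roc(as.integer(labels), scores,
                                                  quiet = TRUE,
                                                  direction = "<"))))
    }
  }
})

test_that("sum-of-ranks is invariant under per-gene monotone transforms", {
  set.seed(34)
  m <- random_matrix(10, 12)
  base <- sum_of_ranks(rank_samples_per_gene(m, rownames(m)))
  m2 <- m
  for (g in seq_len(nrow(m))) m2[g, ] <- random_monotone_map()(m[g, ])
  expect_identical(sum_of_ranks(rank_samples_per_gene(m2, rownames(m2))),
                   base)
})

test_that("predict_cohort separates panel from control on ICB cohorts", {
  co <- generate_icb_cohort(small_config(seed = 35L),
                            n_responders = 30L, n_nonresponders = 30L)
  pred <- predict_cohort(co$matrix, co$meta,
                         control_genes = control_panel_genes())
  expect_gt(pred$panel$roc_pooled$auc, pred$control$roc_pooled$auc)
  expect_gt(pred$panel$roc_pooled$auc, 0.9)
  # per-arm evaluations exist for both arms
  expect_setequal(names(pred$panel$roc_by_arm),
                  c("anti-PD-1", "anti-CTLA-4"))
  # per-arm ranking mode also runs and spans both arms
  pred2 <- predict_cohort(co$matrix, co$meta, ranking = "per_arm")
  expect_equal(nrow(pred2$panel$scores), ncol(co$matrix))
})

test_that("predict_cohort handles degenerate cohorts and unmatched samples", {
  co <- generate_icb_cohort(small_config(seed = 36L),
                            n_responders = 1L, n_nonresponders = 1L)
  pred <- predict_cohort(co$matrix, co$meta)
  expect_true(pred$panel$roc_pooled$auc %in% c(0, 0.5, 1))
  m_bad <- co$matrix
  colnames(m_bad)[1] <- "GHOST"
  expect_error(predict_cohort(m_bad, co$meta), "GHOST")
})

test_that("panel AUC centers on 0.5 when the responder effect is zero", {
  cfg0 <- function(s) small_config(responder_effect = 0, seed = s)
  aucs <- vapply(1:100, function(s) {
    co <- generate_icb_cohort(cfg0(s), n_responders = 25L,
                              n_nonresponders = 25L)
    predict_cohort(co$matrix, co$meta)$panel$roc_pooled$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})
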