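test_that("config validation rejects impossible settings", {
  expect_error(cohort_config(samples_per_group = 1))
  expect_error(cohort_config(infiltration_sd = 0))
  expect_error(cohort_config(responder_fraction = 1.2))
  cfg <- cohort_config()
  expect_s3_class(cfg, "cohort_config")
  expect_equal(cfg$n_background_genes, 2000L)
  expect_equal(cfg$responder_effect, 1.5)
})

test_that("YAML config round-trips through read_cohort_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_tissues: 2", "samples_per_group: 10", "seed: 99"), path)
  cfg <- read_cohort_config(path)
  expect_equal(cfg$n_tissues, 2L)
  expect_equal(cfg$seed, 99L)
  expect_equal(cfg$noise_sd, cohort_config()$noise_sd)
  writeLines("not_a_key: 1", path)
  expect_error(read_cohort_config(path), "not_a_key")
})

test_that("generation is deterministic in the seed and leaves RNG state alone", {
  cfg <- small_config(samples_per_group = 10L, seed = 61L)
  a <- generate_tissue_cohort(cfg)
  set.seed(1234)
  before <- .Random.seed
  b <- generate_tissue_cohort(cfg)
  expect_identical(.Random.seed, before)
  expect_identical(a, b)
  c2 <- generate_tissue_cohort(small_config(samples_per_group = 10L,
                                            seed = 62L))
  expect_false(identical(a$matrix, c2$matrix))
})

test_that("generated cohorts satisfy the structural invariants", {
  co <- generate_tissue_cohort(small_config(samples_per_group = 15L,
                                            seed = 63L))
  expect_silent(validate_expression_matrix(co$matrix))
  expect_true(all(co$matrix > 0))
  expect_true(all(apply(co$matrix, 2, median) > 0))
  expect_identical(colnames(co$matrix), co$meta$sample_id)
  expect_true(all(panel_definition()$immunogenicity %in% rownames(co$matrix)))
  expect_true(all(control_panel_genes() %in% rownames(co$matrix)))
  expect_true(all(co$meta$pathology_score %in% 0:3))
  expect_setequal(unique(co$meta$condition), c("tumor", "normal"))
  # pathology score tracks the latent factor
  expect_gt(cor(co$meta$pathology_score, co$truth$latent,
                method = "spearman"), 0.5)
})

test_that("panel loadings are recoverable by regression on the readout", {
  co <- generate_tissue_cohort(cohort_config(n_tissues = 1L,
                                             samples_per_group = 150L,
                                             n_background_genes = 60L,
                                             seed = 64L))
  logm <- log2(co$matrix)
  infil <- co$meta$true_infiltration
  for (g in panel_definition()$activation) {
    slope <- unname(coef(lm(logm[g, ] ~ infil))[2])
    expect_lt(abs(slope - co$truth$loading[[g]]), 0.15)
  }
  # control genes recover a near-zero loading
  for (g in control_panel_genes()[1:5]) {
    expect_lt(abs(unname(coef(lm(logm[g, ] ~ infil))[2])), 0.15)
  }
})

test_that("ICB cohorts couple response to panel genes only", {
  co <- generate_icb_cohort(small_config(seed = 65L),
                            n_responders = 40L, n_nonresponders = 40L)
  expect_equal(sum(co$meta$response == "responder"), 40L)
  expect_setequal(unique(co$meta$arm), c("anti-PD-1", "anti-CTLA-4"))
  resp <- co$meta$response == "responder"
  # responders have elevated latent infiltration
  expect_gt(mean(co$truth$latent[resp]), mean(co$truth$latent[!resp]) + 1)
  # control gene expression is independent of response
  p_ctrl <- wilcoxon_rank_sum(
    colMeans(log2(co$matrix[control_panel_genes(), resp])),
    colMeans(log2(co$matrix[control_panel_genes(), !resp])))$p_value
  expect_gt(p_ctrl, 0.01)
  # Bernoulli-draw variant works too
  co2 <- generate_icb_cohort(small_config(samples_per_group = 20L,
                                          seed = 66L))
  expect_equal(ncol(co2$matrix), 40L)
  expect_true(all(co2$meta$response %in% c("responder", "non-responder")))
})

test_that("drop_btla reproduces the 14-gene measurement scenario", {
  co <- generate_icb_cohort(small_config(samples_per_group = 10L, seed = 67L),
                            drop_btla = TRUE)
  expect_false("BTLA" %in% rownames(co$matrix))
  expect_warning(
    r <- rank_samples_per_gene(co$matrix, panel_definition()$immunogenicity),
    "BTLA")
  expect_equal(nrow(r), 14L)
})

test_that("expected panel AUC increases with the responder effect", {
  mean_auc <- function(effect) {
    mean(vapply(1:30, function(s) {
      co <- generate_icb_cohort(
        small_config(responder_effect = effect, seed = 1000L + s),
        n_responders = 20L, n_nonresponders = 20L)
      predict_cohort(co$matrix, co$meta)$panel$roc_pooled$auc
    }, numeric(1)))
  }
  aucs <- vapply(c(0, 0.5, 1.5), mean_auc, numeric(1))
  expect_true(all(diff(aucs) > 0))
  expect_lt(aucs[1], 0.6)
  expect_gt(aucs[3], 0.9)
})

test_that("equal checkpoint coupling removes the tumor-normal coupling gap", {
  gap <- function(cfg_seed, equal) {
    cfg <- small_config(
      n_tissues = 1L, samples_per_group = 40L,
      checkpoint_coupling_normal = if (equal) 1.0 else 0.3,
      seed = cfg_seed)
    co <- generate_tissue_cohort(cfg)
    sc <- compute_panel_scores(co$matrix)
    cond <- co$meta$condition[match(sc$sample_id, co$meta$sample_id)]
    cor(sc$activation[cond == "tumor"], sc$checkpoint[cond == "tumor"]) -
      cor(sc$activation[cond == "normal"], sc$checkpoint[cond == "normal"])
  }
  gaps_equal <- vapply(1:25, gap, numeric(1), equal = TRUE)
  gaps_diff <- vapply(1:25, gap, numeric(1), equal = FALSE)
  expect_lt(abs(mean(gaps_equal)), 0.1)
  expect_gt(mean(gaps_diff), mean(gaps_equal) + 0.05)
})
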