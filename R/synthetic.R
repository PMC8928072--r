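#' Configuration for synthetic cohort generation
#'
#' Defines the generative model shared by [generate_tissue_cohort()] and
#' [generate_icb_cohort()].  Each sample carries a latent immune-infiltration
#' factor L (Gaussian on the log2-expression scale); activation genes load on
#' L directly, checkpoint genes load on L through a condition-specific
#' coupling (tighter in tumors than normals), control genes are independent
#' of L, and a small fraction of background genes is weakly loaded to mimic
#' transcriptome bleed-through.  Linear-scale expression is 2^(log2 value).
#'
#' @param n_tissues Number of tissues in a tissue cohort (default 3).
#' @param samples_per_group Samples per tissue x condition group, or per
#'   response class in an ICB cohort (default 100).
#' @param n_background_genes Unstructured background genes (default 2000).
#' @param infiltration_mean_tumor,infiltration_mean_normal Latent means by
#'   condition (defaults 1.5, 0.5).
#' @param infiltration_sd Latent SD within a group (default 0.5).
#' @param panel_loading_range Uniform range for panel-gene loadings on L
#'   (default 0.8-1.2).
#' @param checkpoint_coupling_tumor,checkpoint_coupling_normal Multiplier on
#'   checkpoint-gene loadings by condition (defaults 1.0, 0.3).
#' @param noise_sd Per-gene log2-scale noise SD (default 0.3).
#' @param responder_effect Upward shift of the latent factor in ICB
#'   responders, on the latent (log2) scale (default 1.5; three latent SDs at
#'   the default `infiltration_sd`, emulating the near-complete separation of
#'   responders seen in on-treatment melanoma cohorts).
#' @param responder_fraction Probability a patient is a responder when class
#'   counts are not fixed (default 0.4).
#' @param background_loading_fraction Fraction of background genes weakly
#'   loaded on L (default 0.05).
#' @param background_loading_range Uniform range for those weak loadings
#'   (default 0.05-0.25).
#' @param tissue_offset_sd SD of per-tissue shifts of the latent mean
#'   (default 0.2).
#' @param baseline_mean,baseline_sd Per-gene log2 baseline distribution
#'   (defaults 5, 1).
#' @param pathology_flip Probability the ordinal pathology readout is
#'   perturbed by one level (default 0.2).
#' @param infiltration_readout_sd SD of the noise added to L to form the
#'   `true_infiltration` readout (default 0.2).
#' @param seed Integer seed; the single source of randomness.
#' @return Validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_tissues = 3L,
                          samples_per_group = 100L,
                          n_background_genes = 2000L,
                          infiltration_mean_tumor = 1.5,
                          infiltration_mean_normal = 0.5,
                          infiltration_sd = 0.5,
                          panel_loading_range = c(0.8, 1.2),
                          checkpoint_coupling_tumor = 1.0,
                          checkpoint_coupling_normal = 0.3,
                          noise_sd = 0.3,
                          responder_effect = 1.5,
                          responder_fraction = 0.4,
                          background_loading_fraction = 0.05,
                          background_loading_range = c(0.05, 0.25),
                          tissue_offset_sd = 0.2,
                          baseline_mean = 5,
                          baseline_sd = 1,
                          pathology_flip = 0.2,
                          infiltration_readout_sd = 0.2,
                          seed = 1L) {
  cfg <- list(
    n_tissues = as.integer(n_tissues),
    samples_per_group = as.integer(samples_per_group),
    n_background_genes = as.integer(n_background_genes),
    infiltration_mean_tumor = infiltration_mean_tumor,
    infiltration_mean_normal = infiltration_mean_normal,
    infiltration_sd = infiltration_sd,
    panel_loading_range = panel_loading_range,
    checkpoint_coupling_tumor = checkpoint_coupling_tumor,
    checkpoint_coupling_normal = checkpoint_coupling_normal,
    noise_sd = noise_sd,
    responder_effect = responder_effect,
    responder_fraction = responder_fraction,
    background_loading_fraction = background_loading_fraction,
    background_loading_range = background_loading_range,
    tissue_offset_sd = tissue_offset_sd,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    pathology_flip = pathology_flip,
    infiltration_readout_sd = infiltration_readout_sd,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_tissues >= 1L,
    cfg$samples_per_group >= 2L,
    cfg$n_background_genes >= 30L,
    cfg$infiltration_sd > 0,
    cfg$noise_sd > 0,
    cfg$baseline_sd > 0,
    cfg$tissue_offset_sd >= 0,
    cfg$infiltration_readout_sd >= 0,
    length(cfg$panel_loading_range) == 2L,
    all(cfg$panel_loading_range > 0),
    cfg$checkpoint_coupling_tumor >= 0,
    cfg$checkpoint_coupling_normal >= 0,
    cfg$responder_fraction > 0, cfg$responder_fraction < 1,
    cfg$background_loading_fraction >= 0,
    cfg$background_loading_fraction <= 1,
    cfg$pathology_flip >= 0, cfg$pathology_flip < 1
  )
  structure(cfg, class = "cohort_config")
}

#' Read a cohort configuration from YAML
#'
#' Keys mirror the arguments of [cohort_config()]; unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A `cohort_config` object.
#' @export
read_cohort_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(cohort_config)))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(cohort_config, vals)
}

# Draw the per-gene generative parameters: baselines, loadings, which
# background genes are weakly loaded.  Must run inside a seeded block.
.gene_models <- function(cfg) {
  panel <- panel_definition()
  bg <- sprintf("BG%04d", seq_len(cfg$n_background_genes))
  genes <- c(panel$immunogenicity, control_panel_genes(), bg)
  baseline <- setNames(rnorm(length(genes), cfg$baseline_mean, cfg$baseline_sd),
                       genes)
  loading <- setNames(numeric(length(genes)), genes)
  loading[panel$immunogenicity] <- runif(15L, cfg$panel_loading_range[[1L]],
                                         cfg$panel_loading_range[[2L]])
  n_loaded <- round(cfg$background_loading_fraction * length(bg))
  loaded_bg <- if (n_loaded > 0) sample(bg, n_loaded) else character(0)
  loading[loaded_bg] <- runif(n_loaded, cfg$background_loading_range[[1L]],
                              cfg$background_loading_range[[2L]])
  list(genes = genes, baseline = baseline, loading = loading,
       checkpoint_genes = panel$checkpoint, loaded_background = loaded_bg)
}

# Assemble the linear-scale matrix from gene models, latent values and
# per-sample checkpoint coupling.
.build_matrix <- function(gm, latent, coupling, noise_sd, sample_ids) {
  n_g <- length(gm$genes)
  n_s <- length(latent)
  signal <- outer(gm$loading, latent)
  chk <- gm$genes %in% gm$checkpoint_genes
  signal[chk, ] <- sweep(signal[chk, , drop = FALSE], 2L, coupling, "*")
  logexpr <- gm$baseline + signal +
    matrix(rnorm(n_g * n_s, 0, noise_sd), n_g, n_s)
  m <- 2^logexpr
  dimnames(m) <- list(gm$genes, sample_ids)
  m
}

# Ordinal 0-3 pathology readout: quartile bins of the latent factor with a
# one-level perturbation at probability `flip`.
.pathology_from_latent <- function(latent, flip) {
  qs <- quantile(latent, c(0.25, 0.5, 0.75), names = FALSE)
  score <- findInterval(latent, qs)
  flipped <- runif(length(latent)) < flip
  score[flipped] <- score[flipped] +
    sample(c(-1L, 1L), sum(flipped), replace = TRUE)
  pmin(pmax(score, 0L), 3L)
}

#' Generate a synthetic multi-tissue tumor/normal cohort
#'
#' For each tissue and condition (tumor, normal), `samples_per_group` samples
#' are drawn.  Each sample's latent infiltration L is Gaussian with a
#' condition mean (tumor above normal) plus a per-tissue offset; activation
#' genes track L in both conditions while checkpoint genes track it through
#' the condition-specific coupling, so activation and checkpoint expression
#' are both higher and more tightly coupled in tumors.  The metadata carries
#' a quartile-binned noisy pathology score and a noisy `true_infiltration`
#' readout of L.
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_cohort`: `matrix` (linear-scale
#'   expression), `meta` (data.frame), `truth` (config plus the drawn gene
#'   parameters, tissue offsets and latent values).
#' @export
generate_tissue_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    gm <- .gene_models(config)
    tissues <- sprintf("tissue%02d", seq_len(config$n_tissues))
    offsets <- setNames(rnorm(config$n_tissues, 0, config$tissue_offset_sd),
                        tissues)
    grid <- expand.grid(condition = c("tumor", "normal"), tissue = tissues,
                        stringsAsFactors = FALSE)
    per <- config$samples_per_group
    meta <- data.frame(
      sample_id = sprintf("S%04d", seq_len(nrow(grid) * per)),
      tissue = rep(grid$tissue, each = per),
      condition = rep(grid$condition, each = per),
      arm = "none",
      response = "not-applicable",
      stringsAsFactors = FALSE
    )
    mu <- ifelse(meta$condition == "tumor",
                 config$infiltration_mean_tumor,
                 config$infiltration_mean_normal) + offsets[meta$tissue]
    latent <- rnorm(nrow(meta), mu, config$infiltration_sd)
    coupling <- ifelse(meta$condition == "tumor",
                       config$checkpoint_coupling_tumor,
                       config$checkpoint_coupling_normal)
    m <- .build_matrix(gm, latent, coupling, config$noise_sd, meta$sample_id)
    meta$pathology_score <- .pathology_from_latent(latent, config$pathology_flip)
    meta$true_infiltration <- latent +
      rnorm(nrow(meta), 0, config$infiltration_readout_sd)
    structure(list(
      matrix = m, meta = meta,
      truth = list(config = config, baseline = gm$baseline,
                   loading = gm$loading,
                   loaded_background = gm$loaded_background,
                   tissue_offsets = offsets,
                   latent = setNames(latent, meta$sample_id))
    ), class = "synthetic_cohort")
  })
}

#' Generate a synthetic on-treatment ICB cohort
#'
#' All samples are tumors of a single tissue ("melanoma"), split across the
#' anti-PD-1 and anti-CTLA-4 arms.  Responders (drawn with probability
#' `responder_fraction`, or in fixed numbers when `n_responders` /
#' `n_nonresponders` are given) have their latent infiltration shifted up by
#' `responder_effect`, which raises all 15 panel genes through their
#' loadings; control and unloaded background genes are unaffected by
#' response.  `drop_btla = TRUE` removes the BTLA row, reproducing the
#' 14-gene situation of panel platforms that do not measure it.
#'
#' @param config A [cohort_config()].
#' @param n_responders,n_nonresponders Optional fixed class sizes; when NULL,
#'   `2 * samples_per_group` patients are drawn with Bernoulli response.
#' @param drop_btla Remove the BTLA row from the matrix (default FALSE).
#' @return A `synthetic_cohort` (see [generate_tissue_cohort()]).
#' @export
generate_icb_cohort <- function(config = cohort_config(),
                                n_responders = NULL, n_nonresponders = NULL,
                                drop_btla = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    gm <- .gene_models(config)
    if (is.null(n_responders) != is.null(n_nonresponders)) {
      stop("supply both or neither of n_responders / n_nonresponders",
           call. = FALSE)
    }
    if (is.null(n_responders)) {
      n_total <- 2L * config$samples_per_group
      responder <- runif(n_total) < config$responder_fraction
    } else {
      stopifnot(n_responders >= 1L, n_nonresponders >= 1L)
      n_total <- n_responders + n_nonresponders
      responder <- sample(rep(c(TRUE, FALSE), c(n_responders, n_nonresponders)))
    }
    meta <- data.frame(
      sample_id = sprintf("P%04d", seq_len(n_total)),
      tissue = "melanoma",
      condition = "tumor",
      arm = rep(c("anti-PD-1", "anti-CTLA-4"), length.out = n_total),
      response = ifelse(responder, "responder", "non-responder"),
      stringsAsFactors = FALSE
    )
    latent <- rnorm(n_total, config$infiltration_mean_tumor,
                    config$infiltration_sd) +
      ifelse(responder, config$responder_effect, 0)
    coupling <- rep(config$checkpoint_coupling_tumor, n_total)
    m <- .build_matrix(gm, latent, coupling, config$noise_sd, meta$sample_id)
    if (drop_btla) m <- m[rownames(m) != "BTLA", , drop = FALSE]
    meta$pathology_score <- .pathology_from_latent(latent, config$pathology_flip)
    meta$true_infiltration <- latent +
      rnorm(n_total, 0, config$infiltration_readout_sd)
    structure(list(
      matrix = m, meta = meta,
      truth = list(config = config, baseline = gm$baseline,
                   loading = gm$loading,
                   loaded_background = gm$loaded_background,
                   latent = setNames(latent, meta$sample_id))
    ), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d genes x %d samples (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(unique(x$meta$condition), collapse = "/")))
  invisible(x)
}
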