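#' Simulation configuration for a two-panel mQTL cohort
#'
#' Builds and validates the full parameter set of the synthetic-data
#' generator. Defaults emulate a two-panel epidemiological cohort of older
#' adults: a discovery panel of 581 and a validation panel of 368
#' participants, roughly 18% current / 30% former / 52% never smokers,
#' ~12 years of mortality follow-up, 150 candidate CpG sites with SNPs in
#' linkage-disequilibrium blocks around them, batch effects on methylation,
#' and whole-blood cell-composition mixing over six leukocyte types.
#'
#' @param n_discovery,n_validation Panel sample sizes.
#' @param n_cpgs Number of candidate CpG sites.
#' @param snps_per_cpg SNPs simulated in the cis window of each CpG.
#' @param maf_range Range (low, high) of true minor allele frequencies,
#'   within (0, 0.5].
#' @param ld_block_size Number of adjacent SNPs forming one LD block.
#' @param ld_rho Haplotype copying probability between adjacent SNPs of a
#'   block, in `[0, 1)`; controls realized pairwise genotype R^2 (adjacent
#'   loci correlate at about `ld_rho`, so R^2 of about `ld_rho^2`).
#' @param missing_rate Baseline per-call genotype missingness probability.
#' @param high_missing_fraction Share of SNPs given elevated missingness
#'   (1-3% of calls) so the missingness filter has work to do.
#' @param smoking_effect_range Range of the current-vs-never smoking effect
#'   on the beta-value scale (negative = smoking-induced hypomethylation).
#' @param mqtl_effect_range Range of absolute per-minor-allele mQTL effects
#'   (beta-value units); signs are drawn at random.
#' @param mqtl_fraction Fraction of CpGs given exactly one causal SNP.
#' @param noise_sd Residual standard deviation of beta values.
#' @param n_batches Methylation measurement batches per panel.
#' @param batch_sd Standard deviation of batch random intercepts.
#' @param n_cell_types Number of leukocyte types mixed into whole blood.
#' @param dirichlet_alpha Dirichlet concentration vector (length
#'   `n_cell_types`) for per-sample cell proportions.
#' @param n_ref_cpgs Number of reference CpGs in the deconvolution panel.
#' @param smoking_prevalence Probabilities of (current, former, never)
#'   smoking status; must sum to 1.
#' @param survival_shape,survival_scale Weibull parameters of the latent
#'   survival time (years).
#' @param followup_years Administrative censoring horizon (years).
#' @param seed Integer seed; every stochastic draw of the generator flows
#'   from this one seed.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_discovery = 581L,
                       n_validation = 368L,
                       n_cpgs = 150L,
                       snps_per_cpg = 12L,
                       maf_range = c(0.05, 0.45),
                       ld_block_size = 4L,
                       ld_rho = 0.8,
                       missing_rate = 0.002,
                       high_missing_fraction = 0.08,
                       smoking_effect_range = c(-0.10, -0.02),
                       mqtl_effect_range = c(0.03, 0.12),
                       mqtl_fraction = 0.47,
                       noise_sd = 0.03,
                       n_batches = 8L,
                       batch_sd = 0.01,
                       n_cell_types = 6L,
                       dirichlet_alpha = c(24, 6, 4, 2, 2, 2),
                       n_ref_cpgs = 50L,
                       smoking_prevalence = c(0.18, 0.30, 0.52),
                       survival_shape = 1.5,
                       survival_scale = 55,
                       followup_years = 12.6,
                       seed = 20170817L) {
  cfg <- list(
    n_discovery = as.integer(n_discovery),
    n_validation = as.integer(n_validation),
    n_cpgs = as.integer(n_cpgs),
    snps_per_cpg = as.integer(snps_per_cpg),
    maf_range = as.numeric(maf_range),
    ld_block_size = as.integer(ld_block_size),
    ld_rho = as.numeric(ld_rho),
    missing_rate = as.numeric(missing_rate),
    high_missing_fraction = as.numeric(high_missing_fraction),
    smoking_effect_range = as.numeric(smoking_effect_range),
    mqtl_effect_range = as.numeric(mqtl_effect_range),
    mqtl_fraction = as.numeric(mqtl_fraction),
    noise_sd = as.numeric(noise_sd),
    n_batches = as.integer(n_batches),
    batch_sd = as.numeric(batch_sd),
    n_cell_types = as.integer(n_cell_types),
    dirichlet_alpha = as.numeric(dirichlet_alpha),
    n_ref_cpgs = as.integer(n_ref_cpgs),
    smoking_prevalence = as.numeric(smoking_prevalence),
    survival_shape = as.numeric(survival_shape),
    survival_scale = as.numeric(survival_scale),
    followup_years = as.numeric(followup_years),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg A `sim_config` list.
#' @return `cfg`, invisibly, after checking all invariants.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c("n_discovery", "n_validation", "n_cpgs", "snps_per_cpg",
              "ld_block_size", "n_batches", "n_cell_types", "n_ref_cpgs")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("sim_config: '", f, "' must be a count >= 1", call. = FALSE)
  }
  if (length(cfg$maf_range) != 2L || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || cfg$maf_range[1] > cfg$maf_range[2])
    stop("sim_config: maf_range must be within (0, 0.5] and ordered",
         call. = FALSE)
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1)
    stop("sim_config: ld_rho must be in [0, 1)", call. = FALSE)
  p <- cfg$smoking_prevalence
  if (length(p) != 3L || any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-9)
    stop("sim_config: smoking_prevalence must be 3 probabilities summing to 1",
         call. = FALSE)
  if (cfg$mqtl_fraction < 0 || cfg$mqtl_fraction > 1)
    stop("sim_config: mqtl_fraction must be in [0, 1]", call. = FALSE)
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1 ||
      cfg$high_missing_fraction < 0 || cfg$high_missing_fraction > 1)
    stop("sim_config: missingness parameters must be in [0, 1]",
         call. = FALSE)
  if (length(cfg$dirichlet_alpha) != cfg$n_cell_types ||
      any(cfg$dirichlet_alpha <= 0))
    stop("sim_config: dirichlet_alpha must be a positive vector of length ",
         cfg$n_cell_types, call. = FALSE)
  if (cfg$noise_sd < 0 || cfg$batch_sd < 0)
    stop("sim_config: standard deviations must be non-negative", call. = FALSE)
  if (cfg$survival_shape <= 0 || cfg$survival_scale <= 0 ||
      cfg$followup_years <= 0)
    stop("sim_config: survival parameters must be positive", call. = FALSE)
  invisible(cfg)
}
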