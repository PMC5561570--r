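#' @importFrom stats rnorm runif rbinom rgamma rmultinom sd var cor
NULL

clip01 <- function(x) {
  y <- pmin(1, pmax(0, x))
  if (is.matrix(x)) {
    dim(y) <- dim(x)
    dimnames(y) <- dimnames(x)
  }
  y
}

rdirichlet1 <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Lay out candidate CpGs and their cis SNPs
#'
#' Places `n_cpgs` CpG sites on chromosomes 1-22 with widely separated,
#' non-overlapping cis windows, assigns each a gene label and a
#' reported-frequency count (how often the site has appeared in prior
#' smoking EWASs; candidates require at least 2), and scatters
#' `snps_per_cpg` SNPs within +/-55 kb of each CpG so that a +/-50 kb pairing
#' window drops a few. SNPs are grouped into LD blocks of `ld_block_size`
#' consecutive loci; each block shares one true minor allele frequency drawn
#' from `maf_range`.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer; if given, seeds the generator first.
#' @return A list with data.frames `cpgs` (cpg_id, chrom, pos, gene,
#'   reported_frequency) and `snps` (snp_id, chrom, pos, minor_allele, block,
#'   true_maf, missing_rate).
#' @export
simulate_loci <- function(config, seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  nc <- config$n_cpgs
  m <- config$snps_per_cpg
  chrom <- rep_len(as.character(1:22), nc)
  # 1 Mb spacing keeps +/-50 kb windows disjoint within a chromosome
  idx_on_chrom <- stats::ave(seq_len(nc), chrom, FUN = seq_along)
  cpg_pos <- 1e6L + idx_on_chrom * 1000000L +
    sample.int(100000L, nc, replace = TRUE)
  # reported-frequency counts: mostly weak (2-3), some moderate (4-5), few high
  freq <- sample(2:8, nc, replace = TRUE,
                 prob = c(0.45, 0.28, 0.12, 0.08, 0.04, 0.02, 0.01))
  cpgs <- data.frame(
    cpg_id = sprintf("cg%08d", seq_len(nc)),
    chrom = chrom,
    pos = as.integer(cpg_pos),
    gene = sprintf("GENE%03d", seq_len(nc)),
    reported_frequency = as.integer(freq),
    stringsAsFactors = FALSE
  )

  offs <- matrix(round(runif(nc * m, -55000, 55000)), nrow = nc)
  snp_rows <- vector("list", nc)
  bases <- c("A", "C", "G", "T")
  n_bad <- 0L
  for (j in seq_len(nc)) {
    pos <- sort(as.integer(cpg_pos[j] + offs[j, ]))
    block_local <- (seq_len(m) - 1L) %/% config$ld_block_size + 1L
    snp_rows[[j]] <- data.frame(
      snp_id = sprintf("rs%03d%04d", j, seq_len(m)),
      chrom = chrom[j],
      pos = pos,
      minor_allele = sample(bases, m, replace = TRUE),
      block = sprintf("b%03d_%02d", j, block_local),
      stringsAsFactors = FALSE
    )
  }
  snps <- do.call(rbind, snp_rows)
  blocks <- unique(snps$block)
  block_maf <- runif(length(blocks), config$maf_range[1], config$maf_range[2])
  snps$true_maf <- block_maf[match(snps$block, blocks)]
  bad <- runif(nrow(snps)) < config$high_missing_fraction
  n_bad <- sum(bad)
  snps$missing_rate <- ifelse(bad, runif(nrow(snps), 0.01, 0.03),
                              runif(nrow(snps), 0, config$missing_rate))
  rownames(snps) <- NULL
  list(cpgs = cpgs, snps = snps)
}

#' Simulate genotypes under Hardy-Weinberg equilibrium with LD blocks
#'
#' Draws two haplotypes per sample. Within an LD block, the first locus is a
#' Bernoulli draw at the block's minor allele frequency and each subsequent
#' locus copies the previous locus' allele with probability `ld_rho` (fresh
#' draw otherwise), giving adjacent-locus allele correlation `ld_rho` while
#' every locus remains marginally in HWE at its true MAF. Genotypes are the
#' haplotype sums; calls are then masked at each SNP's missingness rate.
#'
#' @param config A [sim_config()].
#' @param n_samples Number of samples (>= 2).
#' @param seed Optional integer seed.
#' @param loci Optional locus layout from [simulate_loci()]; generated (from
#'   the current RNG stream) when omitted.
#' @return A list of class `"genotype_matrix"`: `G` (integer matrix, samples
#'   x SNPs, values 0/1/2 with `NA` for missing) and `snps` (the locus
#'   annotation including `true_maf`).
#' @export
simulate_genotypes <- function(config, n_samples, seed = NULL, loci = NULL) {
  validate_sim_config(config)
  if (n_samples < 2) stop("n_samples must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(loci)) loci <- simulate_loci(config)
  snps <- loci$snps
  m <- nrow(snps)
  G <- matrix(0L, nrow = n_samples, ncol = m)
  for (blk in unique(snps$block)) {
    idx <- which(snps$block == blk)
    maf <- snps$true_maf[idx[1]]
    h1 <- draw_block_haplotypes(n_samples, length(idx), maf, config$ld_rho)
    h2 <- draw_block_haplotypes(n_samples, length(idx), maf, config$ld_rho)
    G[, idx] <- h1 + h2
  }
  miss <- matrix(runif(n_samples * m), nrow = n_samples) <
    matrix(snps$missing_rate, nrow = n_samples, ncol = m, byrow = TRUE)
  G[miss] <- NA_integer_
  dimnames(G) <- list(sprintf("S%05d", seq_len(n_samples)), snps$snp_id)
  structure(list(G = G, snps = snps), class = "genotype_matrix")
}

draw_block_haplotypes <- function(n, m, maf, rho) {
  h <- matrix(0L, nrow = n, ncol = m)
  h[, 1] <- rbinom(n, 1L, maf)
  if (m > 1) for (j in 2:m) {
    copy <- runif(n) < rho
    h[, j] <- ifelse(copy, h[, j - 1], rbinom(n, 1L, maf))
  }
  h
}

#' Simulate a cohort panel (demographics, smoking, lifestyle, survival)
#'
#' Generates the covariate and phenotype table of one panel: age around 61
#' years, sex, smoking status at the configured prevalences, pack-years and
#' smoking duration for ever smokers, cessation time for former smokers,
#' alcohol/BMI/activity categories, baseline disease prevalences,
#' round-robin batch assignment, Dirichlet cell proportions, and a Weibull
#' survival time depending on age and smoking, administratively censored at
#' `followup_years`.
#'
#' @param config A [sim_config()].
#' @param n_samples Panel size.
#' @param seed Optional integer seed.
#' @param panel Panel label used in sample and batch ids.
#' @return A list: `cohort` (data.frame, one row per sample), `cell_props`
#'   (matrix samples x cell types), and `survival_coefs` (named true
#'   log-hazard coefficients).
#' @export
simulate_cohort <- function(config, n_samples, seed = NULL,
                            panel = c("discovery", "validation")) {
  validate_sim_config(config)
  panel <- match.arg(panel)
  if (!is.null(seed)) set.seed(seed)
  n <- n_samples
  prefix <- if (panel == "discovery") "D" else "V"
  sample_id <- sprintf("%s%05d", prefix, seq_len(n))
  age <- round(pmin(75, pmax(50, rnorm(n, 61, 6.3))), 1)
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.38, 0.62))
  status <- sample(c("current", "former", "never"), n, replace = TRUE,
                   prob = config$smoking_prevalence)
  initiation_age <- ifelse(status == "never", NA_real_,
                           round(pmin(age - 5, pmax(12, rnorm(n, 18, 3))), 1))
  cessation_time <- ifelse(status == "former",
                           round(pmax(1, pmin(age - initiation_age - 1,
                                              rnorm(n, 17, 10))), 1),
                           NA_real_)
  duration <- ifelse(status == "current", age - initiation_age,
              ifelse(status == "former",
                     pmax(1, age - initiation_age - cessation_time),
                     NA_real_))
  duration <- round(duration, 1)
  # intensity in pack-years: current smokers accumulate more than former
  intensity <- ifelse(status == "current", rgamma(n, 4, scale = 8.7),
               ifelse(status == "former", rgamma(n, 2.5, scale = 8.5), 0))
  pack_years <- ifelse(status == "never", 0, round(pmax(0.5, intensity), 1))
  alcohol <- sample(c("abstainer", "low", "intermediate", "high"), n,
                    replace = TRUE, prob = c(0.37, 0.56, 0.05, 0.02))
  bmi_class <- sample(c("normal", "overweight", "obese"), n, replace = TRUE,
                      prob = c(0.27, 0.46, 0.27))
  activity <- sample(c("inactive", "low", "medium_high"), n, replace = TRUE,
                     prob = c(0.20, 0.45, 0.35))
  cvd <- sample(c("yes", "no"), n, replace = TRUE, prob = c(0.15, 0.85))
  diabetes <- sample(c("yes", "no"), n, replace = TRUE, prob = c(0.155, 0.845))
  cancer <- sample(c("yes", "no"), n, replace = TRUE, prob = c(0.058, 0.942))
  batch <- sprintf("%s_batch%02d",
                   prefix, ((seq_len(n) - 1L) %% config$n_batches) + 1L)
  props <- rdirichlet1(n, config$dirichlet_alpha)
  colnames(props) <- sprintf("cell%d", seq_len(config$n_cell_types))
  rownames(props) <- sample_id

  coefs <- c(age = 0.09, current = 0.7, former = 0.25)
  lp <- coefs["age"] * (age - 61) +
    coefs["current"] * (status == "current") +
    coefs["former"] * (status == "former")
  u <- runif(n)
  tdeath <- config$survival_scale * (-log(u) / exp(lp))^(1 / config$survival_shape)
  dead <- ifelse(tdeath <= config$followup_years, "yes", "no")
  followup_time <- round(pmin(tdeath, config$followup_years), 3)

  cohort <- data.frame(
    sample_id = sample_id, panel = panel, age = age, sex = sex,
    smoking_status = status, pack_years = pack_years,
    smoking_duration = duration, initiation_age = initiation_age,
    cessation_time = cessation_time, alcohol = alcohol,
    bmi_class = bmi_class, activity = activity, cvd = cvd,
    diabetes = diabetes, cancer = cancer, batch = batch,
    followup_time = followup_time, dead = dead,
    stringsAsFactors = FALSE
  )
  cohort <- cbind(cohort, as.data.frame(props))
  rownames(cohort) <- NULL
  list(cohort = cohort, cell_props = props, survival_coefs = coefs)
}

#' Simulate a cell-type methylation reference panel
#'
#' Builds an `n_ref_cpgs` x `n_cell_types` matrix of cell-type-specific
#' methylation profiles for the deconvolution reference. Entries are drawn
#' uniformly in `[0.05, 0.95]` independently per cell type, which keeps the
#' columns well separated (identifiable) and the matrix of full column rank.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A list of class `"cell_reference"`: `profiles` (matrix, rows =
#'   reference CpG ids, columns = cell types) .
#' @export
simulate_cell_reference <- function(config, seed = NULL) {
  validate_sim_config(config)
  if (config$n_cell_types < 2)
    stop("n_cell_types must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- config$n_ref_cpgs
  K <- config$n_cell_types
  R <- matrix(runif(m * K, 0.05, 0.95), nrow = m, ncol = K)
  dimnames(R) <- list(sprintf("ref%04d", seq_len(m)),
                      sprintf("cell%d", seq_len(K)))
  structure(list(profiles = R), class = "cell_reference")
}

#' Simulate methylation beta values with planted mQTL and smoking effects
#'
#' For CpG j and sample i the generated beta value is
#' `clip01( a_j G_ij + b_j smoke_i + u_batch(i) + sum_k w_jk p_ik + e_ij )`
#' with `e ~ N(0, noise_sd)`: an additive model on the beta-value scale,
#' clipped to `[0, 1]`. The cell-mixture term `sum_k w_jk p_ik` carries the
#' CpG's baseline level. Each mQTL-bearing CpG has exactly one designated
#' causal SNP (effect `a_j` per minor allele); current smoking shifts the
#' CpG by `b_j` and former smoking by `b_j / 2`. Every generative
#' coefficient is recorded in the returned truth.
#'
#' @param cohort Cohort data.frame from [simulate_cohort()] (needs
#'   `sample_id`, `smoking_status`, `batch`, cell proportion columns).
#' @param genotypes A `genotype_matrix` aligned to the cohort.
#' @param config A [sim_config()].
#' @param cpgs CpG manifest from [simulate_loci()].
#' @param truth Optional truth from a previous panel so both panels share
#'   effect sizes and cell profiles; batch intercepts for this panel's
#'   batches are always drawn fresh.
#' @param seed Optional integer seed.
#' @return A list: `beta` (matrix samples x CpGs) and `truth` (list with
#'   `mqtl_effects` data.frame, `smoking_effects`, `cell_profiles`,
#'   `batch_intercepts`).
#' @export
simulate_methylation <- function(cohort, genotypes, config, cpgs,
                                 truth = NULL, seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  if (!identical(cohort$sample_id, rownames(genotypes$G)))
    stop("sample ids of cohort and genotypes are not aligned", call. = FALSE)
  n <- nrow(cohort)
  nc <- nrow(cpgs)
  K <- config$n_cell_types
  prop_cols <- sprintf("cell%d", seq_len(K))
  P <- as.matrix(cohort[, prop_cols])

  if (is.null(truth)) {
    base <- runif(nc, 0.15, 0.85)
    W <- clip01(matrix(rnorm(nc * K, 0, 0.05), nc, K) + base)
    dimnames(W) <- list(cpgs$cpg_id, prop_cols)
    b <- runif(nc, config$smoking_effect_range[1], config$smoking_effect_range[2])
    names(b) <- cpgs$cpg_id
    n_causal <- round(config$mqtl_fraction * nc)
    causal_cpg <- sort(sample.int(nc, n_causal))
    causal <- data.frame(cpg_id = cpgs$cpg_id[causal_cpg],
                         snp_id = rep(NA_character_, length(causal_cpg)),
                         effect = rep(NA_real_, length(causal_cpg)),
                         stringsAsFactors = FALSE)
    for (r in seq_along(causal_cpg)) {
      j <- causal_cpg[r]
      in_cis <- genotypes$snps$snp_id[
        genotypes$snps$chrom == cpgs$chrom[j] &
          abs(genotypes$snps$pos - cpgs$pos[j]) <= 50000]
      if (length(in_cis) == 0) next
      causal$snp_id[r] <- sample(in_cis, 1)
      causal$effect[r] <- sample(c(-1, 1), 1) *
        runif(1, config$mqtl_effect_range[1], config$mqtl_effect_range[2])
    }
    causal <- causal[!is.na(causal$snp_id), , drop = FALSE]
    truth <- list(mqtl_effects = causal, smoking_effects = b,
                  cell_profiles = W, batch_intercepts = list())
  }

  batches <- unique(cohort$batch)
  u <- rnorm(length(batches), 0, config$batch_sd)
  names(u) <- batches
  truth$batch_intercepts[[cohort$panel[1]]] <- u

  smoke_term <- ifelse(cohort$smoking_status == "current", 1,
                ifelse(cohort$smoking_status == "former", 0.5, 0))
  beta <- P %*% t(truth$cell_profiles)  # n x nc baseline from cell mixing
  beta <- beta + outer(smoke_term, truth$smoking_effects[cpgs$cpg_id])
  beta <- beta + u[cohort$batch]
  ce <- truth$mqtl_effects
  for (r in seq_len(nrow(ce))) {
    g <- genotypes$G[, ce$snp_id[r]]
    g[is.na(g)] <- 0L  # missing calls carry no planted dosage effect
    j <- match(ce$cpg_id[r], cpgs$cpg_id)
    beta[, j] <- beta[, j] + ce$effect[r] * g
  }
  if (config$noise_sd > 0)
    beta <- beta + matrix(rnorm(n * nc, 0, config$noise_sd), n, nc)
  beta <- clip01(beta)
  dimnames(beta) <- list(cohort$sample_id, cpgs$cpg_id)
  list(beta = beta, truth = truth)
}

#' Simulate a complete two-panel mQTL study
#'
#' Draws one locus layout, one set of generative effect sizes and one cell
#' reference, then simulates independent discovery and validation panels
#' (genotypes, cohort, candidate-CpG methylation, and reference-CpG
#' methylation for deconvolution). A single global seed drives every draw,
#' so the same seed reproduces the dataset bit for bit.
#'
#' @param config A [sim_config()].
#' @return A list of class `"mqtl_dataset"`: `cpgs`, `snps`, `reference`
#'   (cell reference), `panels` (named list with `cohort`, `genotypes`,
#'   `beta`, `ref_beta` each), and `truth` (all generative parameters,
#'   including per-sample true cell proportions and survival coefficients).
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  loci <- simulate_loci(config)
  reference <- simulate_cell_reference(config)
  truth <- NULL
  panels <- list()
  cell_props <- list()
  surv_coefs <- NULL
  for (panel in c("discovery", "validation")) {
    n <- if (panel == "discovery") config$n_discovery else config$n_validation
    coh <- simulate_cohort(config, n, panel = panel)
    gen <- simulate_genotypes(config, n, loci = loci)
    rownames(gen$G) <- coh$cohort$sample_id
    met <- simulate_methylation(coh$cohort, gen, config, loci$cpgs,
                                truth = truth)
    truth <- met$truth
    # reference-panel CpGs: cell mixture plus light assay noise
    ref_beta <- clip01(coh$cell_props %*% t(reference$profiles) +
                         matrix(rnorm(n * config$n_ref_cpgs, 0, 0.01),
                                n, config$n_ref_cpgs))
    colnames(ref_beta) <- rownames(reference$profiles)
    panels[[panel]] <- list(cohort = coh$cohort, genotypes = gen,
                            beta = met$beta, ref_beta = ref_beta)
    cell_props[[panel]] <- coh$cell_props
    surv_coefs <- coh$survival_coefs
  }
  truth$maf <- stats::setNames(loci$snps$true_maf, loci$snps$snp_id)
  truth$cell_props <- cell_props
  truth$survival_coefs <- surv_coefs
  truth$reference <- reference$profiles
  structure(list(cpgs = loci$cpgs, snps = loci$snps, reference = reference,
                 panels = panels, truth = truth, config = config),
            class = "mqtl_dataset")
}
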