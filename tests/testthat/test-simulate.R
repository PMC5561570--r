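test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_cpgs = 0), "count")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(smoking_prevalence = c(0.5, 0.5, 0.5)), "summing")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(dirichlet_alpha = c(1, 2)), "dirichlet_alpha")
})

test_that("genotypes are drawn under HWE at the true MAF", {
  cfg <- small_config(maf_range = c(0.5, 0.5), n_cpgs = 1L,
                      snps_per_cpg = 2L, ld_rho = 0,
                      missing_rate = 0, high_missing_fraction = 0)
  g <- simulate_genotypes(cfg, 100000, seed = 21)
  freqs <- table(factor(g$G[, 1], levels = 0:2)) / nrow(g$G)
  expect_equal(as.numeric(freqs), c(0.25, 0.5, 0.25), tolerance = 0.04)

  # allele frequencies converge to truth within 3 binomial SEs at n = 5000
  cfg2 <- small_config(n_cpgs = 4L, snps_per_cpg = 4L,
                       missing_rate = 0, high_missing_fraction = 0)
  g2 <- simulate_genotypes(cfg2, 5000, seed = 22)
  emp <- colMeans(g2$G) / 2
  se <- sqrt(g2$snps$true_maf * (1 - g2$snps$true_maf) / (2 * 5000))
  expect_true(all(abs(emp - g2$snps$true_maf) < 3.5 * se))
})

test_that("ld_rho = 0 gives uncorrelated loci; ld_rho > 0 gives block correlation", {
  cfg0 <- small_config(ld_rho = 0, n_cpgs = 5L, snps_per_cpg = 4L,
                       missing_rate = 0, high_missing_fraction = 0)
  g0 <- simulate_genotypes(cfg0, 5000, seed = 23)
  rs <- c()
  for (blk in unique(g0$snps$block)) {
    idx <- which(g0$snps$block == blk)
    if (length(idx) >= 2)
      rs <- c(rs, cor(g0$G[, idx[1]], g0$G[, idx[2]]))
  }
  expect_lt(abs(mean(rs)), 0.05)

  cfg8 <- small_config(ld_rho = 0.8, n_cpgs = 5L, snps_per_cpg = 4L,
                       missing_rate = 0, high_missing_fraction = 0)
  g8 <- simulate_genotypes(cfg8, 5000, seed = 23)
  rs8 <- c()
  for (blk in unique(g8$snps$block)) {
    idx <- which(g8$snps$block == blk)
    rs8 <- c(rs8, cor(g8$G[, idx[1]], g8$G[, idx[2]]))
  }
  expect_equal(mean(rs8), 0.8, tolerance = 0.05)
})

test_that("generation is bit-identical under the same seed", {
  cfg <- small_config(seed = 99L)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$panels$discovery$genotypes$G, b$panels$discovery$genotypes$G)
  expect_identical(a$panels$validation$beta, b$panels$validation$beta)
  expect_identical(a$truth$mqtl_effects, b$truth$mqtl_effects)
  r1 <- simulate_cell_reference(cfg, seed = 5)
  r2 <- simulate_cell_reference(cfg, seed = 5)
  expect_identical(r1$profiles, r2$profiles)
})

test_that("cohort composition follows the configured prevalences and schema", {
  cfg <- small_config(smoking_prevalence = c(1, 0, 0))
  coh <- simulate_cohort(cfg, 200, seed = 31)$cohort
  expect_true(all(coh$smoking_status == "current"))
  expect_true(all(coh$pack_years > 0))

  cfg2 <- small_config(smoking_prevalence = c(0.18, 0.30, 0.52))
  coh2 <- simulate_cohort(cfg2, 10000, seed = 32)$cohort
  props <- table(coh2$smoking_status)[c("current", "former", "never")] / 10000
  expect_equal(as.numeric(props), c(0.18, 0.30, 0.52), tolerance = 0.02)
  # cessation time present exactly for former smokers
  expect_true(all(is.na(coh2$cessation_time[coh2$smoking_status != "former"])))
  expect_true(all(!is.na(coh2$cessation_time[coh2$smoking_status == "former"])))
  # cell proportions sum to 1
  K <- cfg2$n_cell_types
  expect_equal(rowSums(coh2[, sprintf("cell%d", 1:K)]),
               rep(1, 10000), tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(simulate_genotypes(cfg2, 1), "n_samples")
})

test_that("methylation generator is exactly linear in genotype and smoking when noiseless", {
  cfg <- small_config(noise_sd = 0, n_batches = 1L, batch_sd = 0,
                      missing_rate = 0, high_missing_fraction = 0,
                      mqtl_fraction = 1, mqtl_effect_range = c(0.05, 0.05))
  set.seed(41)
  coh <- simulate_cohort(cfg, 400, panel = "discovery")
  loci <- simulate_loci(cfg)
  gen <- simulate_genotypes(cfg, 400, loci = loci)
  rownames(gen$G) <- coh$cohort$sample_id
  met <- simulate_methylation(coh$cohort, gen, cfg, loci$cpgs)
  tr <- met$truth
  for (r in seq_len(nrow(tr$mqtl_effects))) {
    cpg <- tr$mqtl_effects$cpg_id[r]
    snp <- tr$mqtl_effects$snp_id[r]
    g <- gen$G[, snp]
    nev <- coh$cohort$smoking_status == "never"
    m2 <- mean(met$beta[nev & g == 2, cpg])
    m0 <- mean(met$beta[nev & g == 0, cpg])
    cellpart <- as.matrix(
      coh$cohort[, sprintf("cell%d", 1:cfg$n_cell_types)]) %*%
      tr$cell_profiles[cpg, ]
    sub <- nev & (g == 0 | g == 2)
    unclipped <- all(met$beta[sub, cpg] > 0 & met$beta[sub, cpg] < 1)
    if (any(nev & g == 2) && any(nev & g == 0) && unclipped) {
      d2 <- mean(cellpart[nev & g == 2]) - mean(cellpart[nev & g == 0])
      expect_equal(m2 - m0 - d2, sign(tr$mqtl_effects$effect[r]) * 0.1,
                   tolerance = 1e-10)
    }
  }
})

test_that("noiseless OLS on simulated methylation recovers the planted coefficients", {
  cfg <- small_config(noise_sd = 0, n_batches = 1L, batch_sd = 0,
                      missing_rate = 0, high_missing_fraction = 0,
                      mqtl_fraction = 1)
  set.seed(42)
  coh <- simulate_cohort(cfg, 500, panel = "discovery")
  loci <- simulate_loci(cfg)
  gen <- simulate_genotypes(cfg, 500, loci = loci)
  rownames(gen$G) <- coh$cohort$sample_id
  met <- simulate_methylation(coh$cohort, gen, cfg, loci$cpgs)
  tr <- met$truth
  smoke <- ifelse(coh$cohort$smoking_status == "current", 1,
                  ifelse(coh$cohort$smoking_status == "former", 0.5, 0))
  P <- as.matrix(coh$cohort[, sprintf("cell%d", 1:cfg$n_cell_types)])
  checked <- 0
  for (r in seq_len(nrow(tr$mqtl_effects))) {
    cpg <- tr$mqtl_effects$cpg_id[r]
    snp <- tr$mqtl_effects$snp_id[r]
    y <- met$beta[, cpg]
    if (any(y <= 0) || any(y >= 1)) next  # clipped values break linearity
    f <- stats::lm(y ~ gen$G[, snp] + smoke + P[, -1])
    expect_equal(unname(coef(f)[2]), tr$mqtl_effects$effect[r],
                 tolerance = 1e-8)
    expect_equal(unname(coef(f)[3]), unname(tr$smoking_effects[cpg]),
                 tolerance = 1e-8)
    checked <- checked + 1
  }
  expect_gt(checked, 0)
})

test_that("beta values stay in [0,1] and clipping is rare under the default config", {
  ds <- small_dataset()
  for (p in names(ds$panels)) {
    b <- ds$panels[[p]]$beta
    expect_true(all(b >= 0 & b <= 1))
    expect_lt(mean(b == 0 | b == 1), 0.01)
  }
})

test_that("cell reference has full rank, separated columns and replays by seed", {
  cfg <- small_config(n_cell_types = 2L, dirichlet_alpha = c(5, 5))
  r <- simulate_cell_reference(cfg, seed = 51)
  expect_true(all(r$profiles >= 0 & r$profiles <= 1))
  expect_gt(sqrt(sum((r$profiles[, 1] - r$profiles[, 2])^2)), 0.5)
  cfg6 <- small_config()
  r6 <- simulate_cell_reference(cfg6, seed = 52)
  expect_identical(qr(r6$profiles)$rank, ncol(r6$profiles))
})

test_that("misaligned sample ids are rejected", {
  cfg <- small_config()
  set.seed(61)
  coh <- simulate_cohort(cfg, 50, panel = "discovery")
  loci <- simulate_loci(cfg)
  gen <- simulate_genotypes(cfg, 50, loci = loci)
  rownames(gen$G) <- rev(coh$cohort$sample_id)
  expect_error(simulate_methylation(coh$cohort, gen, cfg, loci$cpgs),
               "aligned")
})
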