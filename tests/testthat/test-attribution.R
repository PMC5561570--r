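test_that("dominant recoding maps counts to carrier status", {
  expect_identical(recode_dominant(c(0L, 1L, 2L, NA)), c(0L, 1L, 1L, NA))
  expect_identical(recode_dominant(rep(0L, 5)), rep(0L, 5))
  set.seed(111)
  maf <- 0.25
  g <- rbinom(20000, 2, maf)
  expect_equal(mean(recode_dominant(g)), 1 - (1 - maf)^2, tolerance = 0.01)
})

test_that("attenuation percentage and direction follow the coefficient-change formula", {
  expect_equal(attenuation_pct(-0.1, -0.1)$pct_change, 0)
  a <- attenuation_pct(-0.10, -0.08)
  expect_equal(a$pct_change, 20)
  expect_identical(a$direction, "attenuated")
  b <- attenuation_pct(-0.10, -0.11)
  expect_equal(b$pct_change, 10)
  expect_identical(b$direction, "strengthened")
  expect_error(attenuation_pct(0, 0.1), "beta1")
})

test_that("frequency and distance classes are pure functions of their inputs", {
  expect_identical(mqtlsmoke:::freq_class(2:10),
                   c("weak", "weak", "moderate", "moderate", "high", "high",
                     "high", "high", "high"))
  expect_identical(mqtlsmoke:::dist_class(c(-9999, 9999, -10000, 10000, 0)),
                   c("<10kb", "<10kb", ">=10kb", ">=10kb", "<10kb"))
})

# builds a pooled current/never dataset with a carrier whose frequency
# differs by smoking group (confounding), noiseless methylation
confounded_data <- function(n = 600, a = 0.06, b = -0.08, seed = 112) {
  set.seed(seed)
  coh <- toy_cohort(n, seed = seed)
  coh$smoking_status <- sample(c("current", "never"), n, TRUE)
  coh$cessation_time <- NA_real_
  smoke <- as.numeric(coh$smoking_status == "current")
  carrier <- rbinom(n, 1, ifelse(smoke == 1, 0.7, 0.3))
  beta <- matrix(0.5 + b * smoke + a * carrier, ncol = 1,
                 dimnames = list(coh$sample_id, "cgT"))
  G <- matrix(as.integer(carrier), ncol = 1,
              dimnames = list(coh$sample_id, "rsT"))
  gm <- structure(list(
    G = G, snps = data.frame(snp_id = "rsT", chrom = "1", pos = 1000L,
                             minor_allele = "A")), class = "genotype_matrix")
  cpgs <- data.frame(cpg_id = "cgT", chrom = "1", pos = 2000L, gene = "T",
                     reported_frequency = 3L)
  mq <- data.frame(cpg_id = "cgT", snp_id = "rsT", distance = -1000L)
  list(coh = coh, beta = beta, gm = gm, cpgs = cpgs, mq = mq,
       smoke = smoke, carrier = carrier, a = a, b = b)
}

test_that("attribution matches the analytic omitted-variable-bias ratio on noiseless data", {
  d <- confounded_data()
  cellc <- sprintf("cell%d", 1:3)
  rec <- run_attribution(d$mq, d$coh, d$beta, d$gm, d$cpgs, cellc)
  # auxiliary regression of carrier on smoking + covariates gives delta;
  # beta1 = b + a*delta, beta2 = b exactly on noiseless data
  X0 <- covariate_design(d$coh, cellc, include_smoking = FALSE)
  delta <- unname(coef(stats::lm(d$carrier ~ d$smoke + X0))[2])
  beta1 <- d$b + d$a * delta
  expect_equal(rec$beta1, beta1, tolerance = 1e-6)
  expect_equal(rec$beta2, d$b, tolerance = 1e-6)
  expect_equal(rec$pct_change, abs(100 * d$a * delta / beta1),
               tolerance = 1e-4)
  expect_identical(rec$direction, "strengthened")  # |beta2| > |beta1| here
})

test_that("zero mQTL effect yields exactly zero percentage change", {
  d <- confounded_data(a = 0)
  rec <- run_attribution(d$mq, d$coh, d$beta, d$gm, d$cpgs,
                         sprintf("cell%d", 1:3))
  expect_equal(rec$pct_change, 0, tolerance = 1e-10)
})

test_that("percentage change is invariant to rescaling the outcome", {
  d <- confounded_data(seed = 113)
  set.seed(113)
  d$beta <- d$beta + matrix(rnorm(nrow(d$beta), 0, 0.01), ncol = 1)
  cellc <- sprintf("cell%d", 1:3)
  r1 <- run_attribution(d$mq, d$coh, d$beta, d$gm, d$cpgs, cellc)
  d2 <- d; d2$beta <- d$beta * 0.37
  r2 <- run_attribution(d2$mq, d2$coh, d2$beta, d2$gm, d2$cpgs, cellc)
  expect_equal(r1$pct_change, r2$pct_change, tolerance = 1e-8)
})

test_that("shuffled carrier labels contribute almost nothing on average", {
  set.seed(114)
  pcts <- replicate(20, {
    d <- confounded_data(n = 2000, a = 0.06, seed = sample.int(1e6, 1))
    d$beta <- d$beta + matrix(rnorm(2000, 0, 0.01), ncol = 1)
    d$gm$G[, 1] <- sample(d$gm$G[, 1])  # break the carrier-outcome link
    run_attribution(d$mq, d$coh, d$beta, d$gm, d$cpgs,
                    sprintf("cell%d", 1:3))$pct_change
  })
  expect_lt(mean(pcts), 1)
})

test_that("class summaries and one-way ANOVA match manual computation", {
  rec <- data.frame(
    cpg_id = sprintf("cg%d", 1:9), snp_id = sprintf("rs%d", 1:9),
    pct_change = c(1, 2, 3, 4, 5, 6, 9, 8, 10),
    frequency_class = rep(c("weak", "moderate", "high"), each = 3),
    distance_class = rep(c("<10kb", ">=10kb"), length.out = 9),
    flagged = FALSE)
  out <- categorize_and_anova(rec)
  grand <- mean(rec$pct_change)
  gm <- tapply(rec$pct_change, rec$frequency_class, mean)
  ssb <- sum(3 * (gm - grand)^2)
  ssw <- sum((rec$pct_change - gm[rec$frequency_class])^2)
  Fman <- (ssb / 2) / (ssw / 6)
  expect_equal(out$anova_F, Fman, tolerance = 1e-10)
  expect_equal(out$anova_p, stats::pf(Fman, 2, 6, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_identical(sort(out$freq_summary$class),
                   c("high", "moderate", "weak"))
  # identical percentages give F = 0
  rec0 <- rec; rec0$pct_change <- 5
  expect_equal(categorize_and_anova(rec0)$anova_F, 0)
  # two classes: F equals the squared two-sample t statistic
  rec2 <- rec[rec$frequency_class != "high", ]
  t2 <- stats::t.test(pct_change ~ frequency_class, data = rec2,
                      var.equal = TRUE)$statistic^2
  expect_equal(categorize_and_anova(rec2)$anova_F, unname(t2),
               tolerance = 1e-10)
  # single class: ANOVA skipped with a message
  rec1 <- rec[rec$frequency_class == "weak", ]
  expect_message(out1 <- categorize_and_anova(rec1), "skipped")
  expect_true(is.na(out1$anova_F))
})

test_that("interaction scan detects a planted pure interaction and respects references", {
  set.seed(115)
  n <- 2000
  coh <- toy_cohort(n, seed = 115)
  coh$smoking_status <- sample(c("current", "never"), n, TRUE)
  coh$cessation_time <- NA_real_
  smoke <- as.numeric(coh$smoking_status == "current")
  g <- rbinom(n, 2, 0.3)
  carrier <- as.numeric(g >= 1)
  y <- 0.5 - 0.05 * smoke + 0.08 * smoke * carrier + rnorm(n, 0, 0.03)
  beta <- matrix(y, ncol = 1, dimnames = list(coh$sample_id, "cgI"))
  gm <- structure(list(
    G = matrix(as.integer(g), ncol = 1, dimnames = list(coh$sample_id, "rsI")),
    snps = data.frame(snp_id = "rsI", chrom = "1", pos = 1L,
                      minor_allele = "A")), class = "genotype_matrix")
  cpgs <- data.frame(cpg_id = "cgI", chrom = "1", pos = 500L, gene = "I",
                     reported_frequency = 4L)
  mq <- data.frame(cpg_id = "cgI", snp_id = "rsI", distance = -499L)
  res <- interaction_scan(mq, coh, beta, gm, cpgs, sprintf("cell%d", 1:3))
  expect_true(res$significant)
  expect_gt(res$int_het_coef, 0.05)
  # reference cells carry no coefficient: only het/hom contrasts appear
  expect_identical(setdiff(c("int_het_coef", "int_hom_coef"),
                           names(res)), character(0))
})

test_that("interaction scan holds its size under the null", {
  set.seed(116)
  n <- 500
  coh <- toy_cohort(n, seed = 116)
  coh$smoking_status <- sample(c("current", "never"), n, TRUE)
  coh$cessation_time <- NA_real_
  m <- 40
  G <- sapply(1:m, function(j) rbinom(n, 2, runif(1, 0.15, 0.4)))
  colnames(G) <- sprintf("rs%02d", 1:m)
  rownames(G) <- coh$sample_id
  gm <- structure(list(
    G = G, snps = data.frame(snp_id = colnames(G), chrom = "1",
                             pos = seq_len(m), minor_allele = "A")),
    class = "genotype_matrix")
  beta <- matrix(rep(0.5 - 0.05 * (coh$smoking_status == "current"), m),
                 ncol = m, dimnames = list(coh$sample_id, sprintf("cg%02d", 1:m)))
  beta <- beta + matrix(rnorm(n * m, 0, 0.03), n, m)
  cpgs <- data.frame(cpg_id = colnames(beta), chrom = "1", pos = seq_len(m),
                     gene = "g", reported_frequency = 3L)
  mq <- data.frame(cpg_id = colnames(beta), snp_id = colnames(G),
                   distance = 1L)
  res <- interaction_scan(mq, coh, beta, gm, cpgs, sprintf("cell%d", 1:3))
  expect_lte(mean(res$significant), 0.05)
})
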