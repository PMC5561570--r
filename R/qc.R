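#' SNP missingness filter
#'
#' Keeps a SNP only when its fraction of missing genotype calls is strictly
#' below `threshold`; a SNP with missingness at or above the threshold (the
#' default excludes at >= 1%) is removed.
#'
#' @param genotypes A `genotype_matrix`.
#' @param threshold Exclusion boundary on the missing fraction, in `[0, 1]`.
#' @return Character vector of surviving SNP ids (column order preserved).
#' @export
missingness_filter <- function(genotypes, threshold = 0.01) {
  stopifnot(threshold >= 0, threshold <= 1)
  miss <- colMeans(is.na(genotypes$G))
  colnames(genotypes$G)[miss < threshold]
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Two-sided exact test of HWE from genotype counts, conditioning on the
#' observed allele counts: the p-value is the sum of the conditional
#' probabilities of all heterozygote counts whose probability does not
#' exceed that of the observed count. Computed in log space with exact
#' factorial terms, so it is stable for large samples. A monomorphic site
#' (one allele absent) returns p = 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (major hom, het, minor hom).
#' @return The exact p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotype call required", call. = FALSE)
  n_a <- 2L * n_aa + n_Aa   # minor allele count
  n_A <- 2L * n_AA + n_Aa
  if (n_a == 0L || n_A == 0L) return(1)
  rare <- min(n_a, n_A)
  # feasible heterozygote counts share the parity of the rare allele count
  het <- seq(rare %% 2L, rare, by = 2L)
  # log P(n_Aa = h | allele counts) up to a common constant:
  #   n! / (n_homR! n_het! n_homC!) * 2^h, homR = (rare - h)/2
  logp <- lgamma(n + 1) - lgamma((rare - het) / 2 + 1) - lgamma(het + 1) -
    lgamma((n - (rare + het) / 2) + 1) + het * log(2)
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  obs <- which(het == n_Aa)
  if (length(obs) != 1L)
    stop("genotype counts inconsistent with allele counts", call. = FALSE)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Minor allele frequency of one genotype column
#'
#' @param g Integer vector of minor-allele counts (0/1/2, `NA` missing).
#' @return `min(f, 1 - f)` where `f` is the counted-allele frequency over
#'   non-missing calls.
#' @export
compute_maf <- function(g) {
  g <- g[!is.na(g)]
  if (length(g) == 0) stop("all genotype calls missing", call. = FALSE)
  f <- sum(g) / (2 * length(g))
  min(f, 1 - f)
}

#' Pairwise linkage disequilibrium R-squared
#'
#' Squared Pearson correlation of minor-allele counts over pairwise-complete
#' samples (composite LD from unphased genotypes).
#'
#' @param g1,g2 Genotype columns (0/1/2, `NA` missing).
#' @return R^2 in `[0, 1]`.
#' @export
ld_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 3)
    stop("need >= 3 pairwise-complete samples for LD", call. = FALSE)
  if (var(g1[ok]) == 0 || var(g2[ok]) == 0)
    stop("LD undefined for a constant genotype column", call. = FALSE)
  cor(g1[ok], g2[ok])^2
}

#' Greedy LD pruning of a candidate SNP set
#'
#' Repeatedly takes the best-ranked SNP still in play and removes every
#' remaining SNP whose R^2 with it is at or above `r2_threshold`; the
#' retained set is mutually below the threshold. Ranking ties are broken by
#' ascending position, then id.
#'
#' @param snp_ids Candidate SNP ids (columns of `genotypes$G`).
#' @param genotypes A `genotype_matrix`.
#' @param r2_threshold Pruning boundary (pairs at or above it collapse).
#' @param score Named numeric ranking score, smaller = stronger (e.g. a
#'   p-value); defaults to ranking by descending MAF when `NULL`.
#' @return Character vector of retained SNP ids.
#' @export
prune_ld <- function(snp_ids, genotypes, r2_threshold = 0.5, score = NULL) {
  if (length(snp_ids) <= 1) return(snp_ids)
  info <- genotypes$snps[match(snp_ids, genotypes$snps$snp_id), ]
  if (is.null(score)) {
    score <- -vapply(snp_ids, function(s) compute_maf(genotypes$G[, s]),
                     numeric(1))
  } else {
    stopifnot(all(snp_ids %in% names(score)))
    score <- score[snp_ids]
  }
  ord <- order(score, info$pos, snp_ids)
  remaining <- snp_ids[ord]
  kept <- character(0)
  while (length(remaining) > 0) {
    best <- remaining[1]
    kept <- c(kept, best)
    remaining <- remaining[-1]
    if (length(remaining) > 0) {
      r2 <- vapply(remaining, function(s)
        ld_r2(genotypes$G[, best], genotypes$G[, s]), numeric(1))
      remaining <- remaining[r2 < r2_threshold]
    }
  }
  kept
}

hwe_from_column <- function(g) {
  g <- g[!is.na(g)]
  n2 <- sum(g == 2L); n1 <- sum(g == 1L); n0 <- sum(g == 0L)
  # orient so the test sees (major hom, het, minor hom); symmetric anyway
  hwe_exact_test(max(n0, n2), n1, min(n0, n2))
}

#' Run the full SNP quality-control cascade for each CpG
#'
#' Applies, in order: missingness (exclude >= `miss`), HWE exact test
#' (exclude p < `hwe_p`), MAF (exclude <= `maf`), then per-CpG greedy LD
#' pruning at R^2 >= `ld_r2` ranked by the marginal association p-value of
#' each SNP with its CpG (simple linear model, no covariates) computed on
#' the ranking panel before pruning. Sample-level filters run once per SNP;
#' LD pruning runs within each CpG's candidate set.
#'
#' @param pairs Pair table from [build_pairs()] (`cpg_id`, `snp_id`).
#' @param genotypes A `genotype_matrix` (panel or pooled panels used for the
#'   QC statistics and pruning LD).
#' @param beta Methylation matrix (samples x CpGs) of the ranking panel.
#' @param miss,hwe_p,maf,ld_r2 Filter thresholds.
#' @param rank `"pvalue"` (marginal association, default) or `"maf"`.
#' @param rank_genotypes `genotype_matrix` aligned with `beta` for the
#'   p-value ranking; defaults to `genotypes`.
#' @return A list of class `"qc_report"`: `pairs` (surviving pair table),
#'   `counts` (SNPs excluded per filter, in application order), and
#'   `surviving` (per-CpG retained SNP ids).
#' @export
run_genotype_qc <- function(pairs, genotypes, beta, miss = 0.01,
                            hwe_p = 1e-4, maf = 0.1, ld_r2 = 0.5,
                            rank = c("pvalue", "maf"),
                            rank_genotypes = genotypes) {
  rank <- match.arg(rank)
  snp_ids <- unique(pairs$snp_id)
  G <- genotypes$G
  n_in <- length(snp_ids)

  keep_miss <- intersect(snp_ids, missingness_filter(genotypes, miss))
  n_miss <- n_in - length(keep_miss)

  hwe_p_vals <- vapply(keep_miss, function(s) hwe_from_column(G[, s]),
                       numeric(1))
  keep_hwe <- keep_miss[hwe_p_vals >= hwe_p]
  n_hwe <- length(keep_miss) - length(keep_hwe)

  mafs <- vapply(keep_hwe, function(s) compute_maf(G[, s]), numeric(1))
  keep_maf <- keep_hwe[mafs > maf]
  n_maf <- length(keep_hwe) - length(keep_maf)

  pairs2 <- pairs[pairs$snp_id %in% keep_maf, , drop = FALSE]
  surviving <- list()
  kept_rows <- logical(nrow(pairs2))
  for (cpg in unique(pairs2$cpg_id)) {
    rows <- which(pairs2$cpg_id == cpg)
    cand <- pairs2$snp_id[rows]
    score <- NULL
    if (rank == "pvalue") {
      y <- beta[, cpg]
      score <- vapply(cand, function(s) {
        g <- rank_genotypes$G[, s]
        ok <- !is.na(g) & !is.na(y)
        if (var(g[ok]) == 0) return(1)
        f <- summary(stats::lm(y[ok] ~ g[ok]))$coefficients
        if (nrow(f) < 2) 1 else f[2, 4]
      }, numeric(1))
    }
    kept <- prune_ld(cand, genotypes, r2_threshold = ld_r2, score = score)
    surviving[[cpg]] <- kept
    kept_rows[rows] <- pairs2$snp_id[rows] %in% kept
  }
  pairs_out <- pairs2[kept_rows, , drop = FALSE]
  rownames(pairs_out) <- NULL
  counts <- c(input_snps = n_in, excluded_missingness = n_miss,
              excluded_hwe = n_hwe, excluded_maf = n_maf,
              input_pairs = nrow(pairs),
              excluded_pairs_ld = nrow(pairs2) - nrow(pairs_out),
              surviving_pairs = nrow(pairs_out))
  structure(list(pairs = pairs_out, counts = counts, surviving = surviving),
            class = "qc_report")
}
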