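#' Dominant recoding of a genotype column
#'
#' Collapses minor-allele counts to carrier status: heterozygotes and minor
#' homozygotes become carriers (1), major homozygotes non-carriers (0);
#' missing calls stay missing.
#'
#' @param g Genotype column (0/1/2, `NA` missing).
#' @return Integer vector of 0/1/`NA`.
#' @export
recode_dominant <- function(g) {
  out <- ifelse(is.na(g), NA_integer_, as.integer(g >= 1L))
  out
}

#' Percentage change of the smoking coefficient due to an mQTL
#'
#' `pct = |100 (beta1 - beta2) / beta1|`, where `beta1` is the smoking
#' coefficient without the mQTL in the model and `beta2` the coefficient
#' with it. The direction is "attenuated" when adjusting for the mQTL
#' shrinks the coefficient in magnitude (`|beta2| < |beta1|`),
#' "strengthened" otherwise.
#'
#' @param beta1,beta2 Smoking (current vs never) coefficients.
#' @return A list: `pct_change` (percent, >= 0) and `direction`.
#' @export
attenuation_pct <- function(beta1, beta2) {
  if (is.na(beta1) || beta1 == 0)
    stop("attenuation undefined for beta1 = 0", call. = FALSE)
  list(pct_change = abs(100 * (beta1 - beta2) / beta1),
       direction = if (abs(beta2) < abs(beta1)) "attenuated" else "strengthened")
}

freq_class <- function(reported_frequency) {
  ifelse(reported_frequency >= 6, "high",
         ifelse(reported_frequency >= 4, "moderate", "weak"))
}

dist_class <- function(distance, breakpoint = 10000) {
  ifelse(abs(distance) < breakpoint, "<10kb", ">=10kb")
}

#' Quantify each validated mQTL's contribution to the smoking effect
#'
#' Restricted to current and never smokers (pooled panels), each validated
#' SNP-CpG pair is fit twice with the fully adjusted batch-random-effect
#' model on the identical sample set: once without the mQTL (smoking
#' coefficient `beta1`) and once adding the carrier indicator (`beta2`).
#' The percentage change `|100 (beta1 - beta2)/beta1|` is the mQTL's
#' contribution. Records where `beta1` is zero or not significant at 0.05
#' are flagged and carry no percentage.
#'
#' @param mqtls Pair table rows flagged `is_mqtl` (needs `cpg_id`, `snp_id`,
#'   `distance`).
#' @param cohort Pooled cohort data.frame (current + never smokers are
#'   selected internally).
#' @param beta Pooled methylation matrix (samples x CpGs).
#' @param genotypes Pooled `genotype_matrix`.
#' @param cpgs CpG manifest (for `reported_frequency`).
#' @param cell_cols Cell-proportion covariate column names.
#' @return Data.frame of attribution records: beta1/beta2 with SEs and
#'   p-values, pct_change, direction, distance_class, frequency_class,
#'   flagged.
#' @export
run_attribution <- function(mqtls, cohort, beta, genotypes, cpgs, cell_cols) {
  if (nrow(mqtls) == 0) stop("empty mQTL set", call. = FALSE)
  sel <- cohort$smoking_status %in% c("current", "never")
  coh <- cohort[sel, , drop = FALSE]
  B <- beta[sel, , drop = FALSE]
  G <- genotypes$G[sel, , drop = FALSE]
  X0 <- covariate_design(coh, cell_cols, include_smoking = FALSE)
  smoke <- as.numeric(coh$smoking_status == "current")
  out <- vector("list", nrow(mqtls))
  for (i in seq_len(nrow(mqtls))) {
    cpg <- mqtls$cpg_id[i]; snp <- mqtls$snp_id[i]
    carrier <- recode_dominant(G[, snp])
    keep <- !is.na(carrier)  # identical sample set for both fits
    X1 <- cbind(smoking_current = smoke, X0)[keep, , drop = FALSE]
    y <- B[keep, cpg]
    bt <- coh$batch[keep]
    f1 <- fit_mixed_lm(y, X1, bt)
    f2 <- fit_mixed_lm(y, cbind(X1, carrier = carrier[keep]), bt)
    i1 <- match("smoking_current", f1$term)
    i2 <- match("smoking_current", f2$term)
    b1 <- f1$coef[i1]; b2 <- f2$coef[i2]
    flagged <- is.na(b1) || b1 == 0 || f1$p[i1] > 0.05
    rec <- data.frame(
      cpg_id = cpg, snp_id = snp,
      beta1 = b1, se1 = f1$se[i1], p1 = f1$p[i1],
      beta2 = b2, se2 = f2$se[i2], p2 = f2$p[i2],
      pct_change = NA_real_, direction = NA_character_,
      distance_class = dist_class(mqtls$distance[i]),
      frequency_class = freq_class(
        cpgs$reported_frequency[match(cpg, cpgs$cpg_id)]),
      n_used = f1$n_used, flagged = flagged,
      stringsAsFactors = FALSE
    )
    if (!flagged) {
      a <- attenuation_pct(b1, b2)
      rec$pct_change <- a$pct_change
      rec$direction <- a$direction
    }
    out[[i]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize attribution percentages by class and test across frequency classes
#'
#' Means and SDs of the percentage change within distance classes (<10 kb vs
#' >= 10 kb) and reported-frequency classes (weak 2-3, moderate 4-5, high
#' >= 6), plus a standard one-way ANOVA of percentage change across
#' frequency classes.
#'
#' @param records Attribution data.frame from [run_attribution()].
#' @return A list: `freq_summary`, `dist_summary` (class, n, mean, sd),
#'   `anova_F`, `anova_p` (`NA` with a message when fewer than 2 non-empty
#'   frequency classes).
#' @export
categorize_and_anova <- function(records) {
  r <- records[!records$flagged & !is.na(records$pct_change), , drop = FALSE]
  summarize <- function(cls) {
    agg <- lapply(split(r$pct_change, cls), function(x)
      c(n = length(x), mean = mean(x), sd = sd(x)))
    out <- data.frame(class = names(agg), do.call(rbind, agg),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  }
  freq_summary <- summarize(r$frequency_class)
  dist_summary <- summarize(r$distance_class)
  if (length(unique(r$frequency_class)) < 2) {
    message("fewer than 2 frequency classes: ANOVA skipped")
    return(list(freq_summary = freq_summary, dist_summary = dist_summary,
                anova_F = NA_real_, anova_p = NA_real_))
  }
  if (stats::var(r$pct_change) == 0) {
    # no variation at all: between-class sum of squares is zero
    return(list(freq_summary = freq_summary, dist_summary = dist_summary,
                anova_F = 0, anova_p = 1))
  }
  a <- stats::anova(stats::lm(pct_change ~ factor(frequency_class), data = r))
  list(freq_summary = freq_summary, dist_summary = dist_summary,
       anova_F = a[1, "F value"], anova_p = a[1, "Pr(>F)"])
}

#' Scan validated mQTLs for SNP-by-smoking interactions
#'
#' Restricted to current and never smokers, fits per pair the fully
#' adjusted batch-random-effect model with 3-level genotype (major
#' homozygote reference), current smoking, and their interaction terms
#' (current x het, current x minor hom). Never-smoking genotype groups and
#' the current x major-homozygote cell are the references and carry no
#' coefficient. The per-pair interaction p-value for the FDR family is the
#' minimum contrast p-value Bonferroni-adjusted for the number of estimable
#' contrasts; BH-FDR is applied across pairs.
#'
#' @inheritParams run_attribution
#' @param alpha FDR significance threshold.
#' @return Data.frame with per-contrast interaction coefficients
#'   (`int_het_*`, `int_hom_*`), the pooled pair p, FDR, and `significant`.
#' @export
interaction_scan <- function(mqtls, cohort, beta, genotypes, cpgs, cell_cols,
                             alpha = 0.05) {
  sel <- cohort$smoking_status %in% c("current", "never")
  coh <- cohort[sel, , drop = FALSE]
  B <- beta[sel, , drop = FALSE]
  G <- genotypes$G[sel, , drop = FALSE]
  X0 <- covariate_design(coh, cell_cols, include_smoking = FALSE)
  smoke <- as.numeric(coh$smoking_status == "current")
  out <- vector("list", nrow(mqtls))
  for (i in seq_len(nrow(mqtls))) {
    cpg <- mqtls$cpg_id[i]; snp <- mqtls$snp_id[i]
    g <- G[, snp]
    het <- as.numeric(g == 1L); hom <- as.numeric(g == 2L)
    D <- cbind(smoking_current = smoke, snp_het = het, snp_hom = hom,
               int_het = smoke * het, int_hom = smoke * hom)
    # drop empty or collinear genotype cells (few minor homozygotes is common)
    keepc <- colSums(D != 0, na.rm = TRUE) > 0
    dropped <- colnames(D)[!keepc]
    D <- D[, keepc, drop = FALSE]
    ok <- stats::complete.cases(cbind(D, X0)) & !is.na(B[, cpg])
    for (cand in intersect(c("int_hom", "snp_hom", "int_het"), colnames(D))) {
      M <- cbind(1, D, X0)[ok, , drop = FALSE]
      if (qr(M)$rank == ncol(M)) break
      dropped <- c(dropped, cand)
      D <- D[, setdiff(colnames(D), cand), drop = FALSE]
    }
    fit <- fit_mixed_lm(B[, cpg], cbind(D, X0), coh$batch)
    getc <- function(nm, what) {
      j <- match(nm, fit$term)
      if (is.na(j)) NA_real_ else fit[[what]][j]
    }
    pint <- c(het = getc("int_het", "p"), hom = getc("int_hom", "p"))
    ncontr <- sum(!is.na(pint))
    pair_p <- if (ncontr == 0) NA_real_ else
      min(1, min(pint, na.rm = TRUE) * ncontr)
    out[[i]] <- data.frame(
      cpg_id = cpg, snp_id = snp,
      int_het_coef = getc("int_het", "coef"),
      int_het_se = getc("int_het", "se"),
      int_het_p = getc("int_het", "p"),
      int_hom_coef = getc("int_hom", "coef"),
      int_hom_se = getc("int_hom", "se"),
      int_hom_p = getc("int_hom", "p"),
      dropped_contrasts = paste(dropped, collapse = ";"),
      pair_p = pair_p, n_used = fit$n_used,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res$fdr <- bh_fdr(res$pair_p)
  res$significant <- !is.na(res$fdr) & res$fdr < alpha
  rownames(res) <- NULL
  res
}
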