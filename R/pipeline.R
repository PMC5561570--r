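#' Pool the genotype matrices of two panels
#'
#' @param a,b `genotype_matrix` objects over the same SNPs.
#' @return A pooled `genotype_matrix`.
#' @export
pool_genotypes <- function(a, b) {
  stopifnot(identical(colnames(a$G), colnames(b$G)))
  structure(list(G = rbind(a$G, b$G), snps = a$snps),
            class = "genotype_matrix")
}

#' Run the complete cis-mQTL analysis pipeline on a dataset
#'
#' Executes, in order: reference-based cell deconvolution (estimated
#' proportions become the model covariates), cis pairing within the window,
#' the SNP QC cascade (missingness, HWE, MAF on pooled panels; LD pruning
#' ranked by discovery-panel marginal association), the two-stage
#' discovery/validation scan, attribution of smoking-coefficient changes
#' with class summaries and ANOVA, the SNP-by-smoking interaction scan, and
#' the smoking-indicator and mortality outcome scans (pooled panels).
#' When `truth` is available in the dataset, planted-mQTL recovery metrics
#' are computed: a planted effect counts as recovered when its CpG
#' validates with the causal SNP itself or a proxy in LD (R^2 >= 0.5).
#'
#' @param dataset An `mqtl_dataset` from [simulate_dataset()] or an
#'   equivalently shaped list built from files.
#' @param window Cis window half-width (bp).
#' @param miss,hwe_p,maf,ld_r2 QC thresholds.
#' @param fdr_alpha FDR threshold for both stages and downstream scans.
#' @param distance_breakpoint Breakpoint (bp) between distance classes.
#' @param downstream Run the post-identification stages (attribution,
#'   interactions, outcome scans); disable for mQTL-discovery-only runs.
#' @param out_dir Optional directory; when given, all stage tables, a
#'   Manhattan-ready table and run metadata are written there.
#' @return A list with every stage's table: `pairs_all`, `dropped_cpgs`,
#'   `qc`, `two_stage`, `mqtls`, `attribution`, `class_summary`,
#'   `interactions`, `smoking_outcomes`, `mortality`, `recovery`,
#'   `cell_estimates`, `manhattan`.
#' @export
run_pipeline <- function(dataset, window = 50000, miss = 0.01, hwe_p = 1e-4,
                         maf = 0.1, ld_r2 = 0.5, fdr_alpha = 0.05,
                         distance_breakpoint = 10000, downstream = TRUE,
                         out_dir = NULL) {
  cpgs <- dataset$cpgs
  panels <- dataset$panels
  K <- ncol(dataset$reference$profiles)
  cell_cols <- sprintf("estcell%d", seq_len(K))

  # 1. deconvolution: estimated proportions become model covariates
  for (p in names(panels)) {
    est <- estimate_proportions(panels[[p]]$ref_beta, dataset$reference)
    props <- est$proportions
    colnames(props) <- cell_cols
    panels[[p]]$cohort <- cbind(panels[[p]]$cohort, as.data.frame(props))
    panels[[p]]$cell_estimates <- props
  }

  # 2. cis pairing
  bp <- build_pairs(cpgs, dataset$snps, window = window)

  # 3. SNP QC on pooled panels, association ranking on discovery
  pooled_gen <- pool_genotypes(panels$discovery$genotypes,
                               panels$validation$genotypes)
  qc <- run_genotype_qc(bp$pairs, pooled_gen, panels$discovery$beta,
                        miss = miss, hwe_p = hwe_p, maf = maf,
                        ld_r2 = ld_r2,
                        rank_genotypes = panels$discovery$genotypes)

  # 4. two-stage discovery/validation scan
  two_stage <- run_two_stage(qc$pairs, panels$discovery, panels$validation,
                             cell_cols, alpha = fdr_alpha)
  mqtls <- two_stage[two_stage$is_mqtl, , drop = FALSE]

  pooled_cohort <- rbind(panels$discovery$cohort, panels$validation$cohort)
  pooled_beta <- rbind(panels$discovery$beta, panels$validation$beta)

  attribution <- NULL; class_summary <- NULL; interactions <- NULL
  smoking_outcomes <- NULL; mortality <- NULL
  if (downstream && nrow(mqtls) > 0) {
    attribution <- run_attribution(mqtls, pooled_cohort, pooled_beta,
                                   pooled_gen, cpgs, cell_cols)
    class_summary <- categorize_and_anova(attribution)
    interactions <- interaction_scan(mqtls, pooled_cohort, pooled_beta,
                                     pooled_gen, cpgs, cell_cols,
                                     alpha = fdr_alpha)
    snp_ids <- unique(mqtls$snp_id)
    smoking_outcomes <- smoking_association_scan(snp_ids, pooled_cohort,
                                                 pooled_gen,
                                                 alpha = fdr_alpha)
    mortality <- cox_mortality_scan(snp_ids, pooled_cohort, pooled_gen,
                                    alpha = fdr_alpha)
  }

  recovery <- NULL
  if (!is.null(dataset$truth))
    recovery <- recovery_metrics(dataset, two_stage, pooled_gen,
                                 ld_proxy = ld_r2)

  manhattan <- two_stage[, c("cpg_id", "snp_id", "chrom", "snp_pos")]
  manhattan$neglog10_p <- -log10(two_stage$valid_p)
  manhattan$fdr <- two_stage$valid_fdr
  manhattan$fdr_line <- fdr_alpha

  out <- list(pairs_all = bp$pairs, dropped_cpgs = bp$dropped_cpgs,
              qc = qc, two_stage = two_stage, mqtls = mqtls,
              attribution = attribution, class_summary = class_summary,
              interactions = interactions,
              smoking_outcomes = smoking_outcomes, mortality = mortality,
              recovery = recovery,
              cell_estimates = lapply(panels, `[[`, "cell_estimates"),
              manhattan = manhattan)

  if (!is.null(out_dir)) {
    tables <- list(pairs_all = bp$pairs,
                   qc_counts = data.frame(filter = names(qc$counts),
                                          n = as.integer(qc$counts)),
                   two_stage = two_stage, mqtls = mqtls,
                   manhattan = manhattan)
    if (!is.null(attribution)) {
      tables$attribution <- attribution
      tables$freq_class_summary <- class_summary$freq_summary
      tables$dist_class_summary <- class_summary$dist_summary
      tables$interactions <- interactions
      tables$smoking_outcomes <- smoking_outcomes
      tables$mortality <- mortality
    }
    write_results(tables, out_dir, config = dataset$config,
                  seed = dataset$config$seed)
  }
  out
}

#' Planted-mQTL recovery metrics against simulation truth
#'
#' A planted causal (CpG, SNP, effect) triple counts as recovered when the
#' CpG has a validated mQTL that is either the causal SNP itself or an LD
#' proxy with R^2 >= `ld_proxy` against it (LD pruning may retain the proxy
#' rather than the causal SNP).
#'
#' @param dataset An `mqtl_dataset` carrying `truth`.
#' @param two_stage Output of [run_two_stage()].
#' @param genotypes Pooled `genotype_matrix` for proxy LD.
#' @param ld_proxy Proxy R^2 threshold.
#' @return Data.frame with one row per planted effect: effect size, MAF,
#'   whether the CpG/SNP survived to testing, and `recovered`.
#' @export
recovery_metrics <- function(dataset, two_stage, genotypes, ld_proxy = 0.5) {
  tr <- dataset$truth$mqtl_effects
  maf <- dataset$truth$maf
  val <- two_stage[two_stage$is_mqtl, , drop = FALSE]
  rows <- lapply(seq_len(nrow(tr)), function(i) {
    cpg <- tr$cpg_id[i]; causal <- tr$snp_id[i]
    hits <- val$snp_id[val$cpg_id == cpg]
    recovered <- FALSE
    if (length(hits) > 0) {
      if (causal %in% hits) recovered <- TRUE
      else recovered <- any(vapply(hits, function(s)
        tryCatch(ld_r2(genotypes$G[, causal], genotypes$G[, s]) >= ld_proxy,
                 error = function(e) FALSE), logical(1)))
    }
    data.frame(cpg_id = cpg, snp_id = causal, effect = tr$effect[i],
               true_maf = unname(maf[causal]),
               tested = cpg %in% two_stage$cpg_id,
               recovered = recovered, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
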