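#!/usr/bin/env Rscript
# Stage 1 — simulate the two-panel cohort.
#
# Generates the discovery (n = 581) and validation (n = 368) panels with
# known genotype-methylation-phenotype structure: 150 candidate CpGs, LD
# blocks of cis SNPs, planted mQTL effects for about half the CpGs,
# smoking-induced hypomethylation, batch effects and leukocyte mixing.
# Writes the raw data tables under results/data/.

source(file.path("analysis", "00_settings.R"))

ds <- simulate_dataset(config)
data_dir <- file.path(results_dir, "data")
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)

write_manifest(ds$cpgs, file.path(data_dir, "cpg_manifest.tsv"))
for (p in names(ds$panels)) {
  write_genotypes_tsv(ds$panels[[p]]$genotypes,
                      file.path(data_dir, paste0("genotypes_", p, ".tsv")))
  write_methylation(ds$panels[[p]]$beta,
                    file.path(data_dir, paste0("methylation_", p, ".tsv")))
  write_methylation(ds$panels[[p]]$ref_beta,
                    file.path(data_dir, paste0("reference_betas_", p, ".tsv")))
  write_cohort(ds$panels[[p]]$cohort,
               file.path(data_dir, paste0("cohort_", p, ".tsv")))
}
utils::write.table(
  data.frame(ref_cpg = rownames(ds$reference$profiles),
             ds$reference$profiles),
  file.path(data_dir, "cell_reference.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

coh <- ds$panels$discovery$cohort
cat(sprintf("discovery panel: %d samples (%.1f%% current smokers), %d batches\n",
            nrow(coh), 100 * mean(coh$smoking_status == "current"),
            length(unique(coh$batch))))
cat(sprintf("validation panel: %d samples\n",
            nrow(ds$panels$validation$cohort)))
cat(sprintf("%d CpGs, %d SNPs, %d planted mQTL effects\n",
            nrow(ds$cpgs), nrow(ds$snps), nrow(ds$truth$mqtl_effects)))
cat(sprintf("deaths: %d (discovery) + %d (validation)\n",
            sum(ds$panels$discovery$cohort$dead == "yes"),
            sum(ds$panels$validation$cohort$dead == "yes")))
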