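#!/usr/bin/env Rscript
# Stage 2 — cis pairing and SNP quality control.
#
# Pairs every SNP with every candidate CpG within +/-50 kb on the same
# chromosome, then applies the QC cascade: missingness >= 1% excluded, HWE
# exact test p < 1e-4 excluded (pooled panels), MAF <= 0.1 excluded, and
# per-CpG greedy LD pruning at R^2 >= 0.5 ranked by discovery-panel
# marginal association.

source(file.path("analysis", "00_settings.R"))

ds <- simulate_dataset(config)
bp <- build_pairs(ds$cpgs, ds$snps, window = 50000)
cat(sprintf("cis window: %d candidate pairs; %d CpG(s) dropped without SNPs\n",
            nrow(bp$pairs), length(bp$dropped_cpgs)))

pooled <- pool_genotypes(ds$panels$discovery$genotypes,
                         ds$panels$validation$genotypes)
qc <- run_genotype_qc(bp$pairs, pooled, ds$panels$discovery$beta,
                      rank_genotypes = ds$panels$discovery$genotypes)
print(qc$counts)

write_results(list(
  pairs_all = bp$pairs,
  pairs_qc = qc$pairs,
  qc_counts = data.frame(filter = names(qc$counts),
                         n = as.integer(qc$counts))),
  results_dir, config = config, seed = config$seed)
cat(sprintf("surviving: %d pairs (%d CpGs, %d SNPs)\n", nrow(qc$pairs),
            length(unique(qc$pairs$cpg_id)),
            length(unique(qc$pairs$snp_id))))
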