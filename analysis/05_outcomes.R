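#!/usr/bin/env Rscript
# Stage 5 — mQTLs versus smoking indicators and all-cause mortality.
#
# Tests every identified mQTL (carrier / non-carrier) against six smoking
# indicators (logistic or linear models, BH-FDR within each indicator) and
# against all-cause mortality (Cox model with Breslow ties, pooled panels).
# The generator plants no genotype-phenotype effects, so a correctly sized
# analysis should find (almost) nothing.

source(file.path("analysis", "00_settings.R"))

mqtls <- utils::read.delim(file.path(results_dir, "mqtls.tsv"))
if (nrow(mqtls) == 0) stop("no mQTLs found by stage 3")
snp_ids <- unique(mqtls$snp_id)

ds <- simulate_dataset(config)
cohort <- rbind(ds$panels$discovery$cohort, ds$panels$validation$cohort)
gm <- pool_genotypes(ds$panels$discovery$genotypes,
                     ds$panels$validation$genotypes)

smk <- smoking_association_scan(snp_ids, cohort, gm)
mort <- cox_mortality_scan(snp_ids, cohort, gm)

write_results(list(smoking_outcomes = smk, mortality = mort),
              results_dir, config = config, seed = config$seed)

cat(sprintf("smoking indicators: %d tests, %d significant at FDR < 0.05\n",
            nrow(smk), sum(smk$significant)))
cat(sprintf("mortality: %d SNPs over %d events, %d significant at FDR < 0.05\n",
            nrow(mort), mort$n_events[1], sum(mort$significant)))
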