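# mqtlsmoke

Cis-mQTL mapping and attribution for smoking-related CpG sites, as a
tested R package plus a numbered analysis workflow.

## What this is for

Blood DNA methylation at certain CpG sites (e.g. in *AHRR*, *F2RL3*) is a
robust biomarker of smoking exposure. Methylation quantitative trait loci
(mQTLs) — SNPs that shift methylation at nearby CpGs — can confound or
distort those signals: if risk-allele frequencies differ between exposure
groups, part of an apparent "smoking effect" is genetics. This package
implements, end to end, a two-panel analysis of that question for
epigenetic epidemiologists:

1. **Simulate** a discovery/validation cohort (581 / 368 participants,
   18/30/52% current/former/never smokers, ~12.6 y follow-up) with known
   genotype–methylation–phenotype structure (`sim_config()`,
   `simulate_dataset()`).
2. **QC** candidate SNPs: missingness ≥ 1% excluded, Hardy–Weinberg exact
   test p < 1e-4 excluded, MAF ≤ 0.1 excluded, per-CpG greedy LD pruning
   at R² ≥ 0.5 (`run_genotype_qc()`, with `hwe_exact_test()`, `ld_r2()`,
   `prune_ld()` as building blocks).
3. **Pair** SNPs and CpGs within ±50 kb on the same chromosome, signed
   distance = SNP position − CpG position (`build_pairs()`).
4. **Deconvolve** leukocyte proportions by constrained projection onto a
   cell-type reference: `argmin ‖m − Rp‖²` s.t. `p ≥ 0, Σp ≤ 1`
   (`estimate_proportions()`).
5. **Identify mQTLs** with the two-stage design: per pair, a linear mixed
   model `β = γ_G·G + Xγ + u_batch + ε` fully adjusted for age, sex,
   smoking, alcohol, BMI, activity, CVD/diabetes/cancer and cell
   proportions; BH-FDR < 0.05 in discovery, survivors refit and BH-FDR
   < 0.05 again in validation (`run_two_stage()`).
6. **Attribute**: for each mQTL, the smoking (current vs never)
   coefficient without (β₁) and with (β₂) the carrier-coded SNP;
   contribution = |100·(β₁−β₂)/β₁|, summarized by distance and
   reported-frequency classes with one-way ANOVA, plus SNP×smoking
   interaction models (`run_attribution()`, `interaction_scan()`).
7. **Outcome scans**: mQTLs vs six smoking indicators (logistic/linear)
   and all-cause mortality (Cox, Breslow ties) (`smoking_association_scan()`,
   `cox_mortality_scan()`).

`run_pipeline()` chains stages 2–7 on a dataset; the numbered scripts
under `analysis/` run the same stages as a narrative workflow writing
tables under `results/`.

## Worked example

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_qc_pairs.R
Rscript analysis/03_mqtl_scan.R
Rscript analysis/04_attribution.R
Rscript analysis/05_outcomes.R
```

prints (default configuration, seed 20170817):

```
discovery panel: 581 samples (19.1% current smokers), 8 batches
validation panel: 368 samples
150 CpGs, 1800 SNPs, 70 planted mQTL effects
deaths: 88 (discovery) + 45 (validation)

cis window: 1632 candidate pairs; 0 CpG(s) dropped without SNPs
surviving: 698 pairs (150 CpGs, 698 SNPs)

tested 698 pairs; 112 passed discovery FDR < 0.05; 108 validated
mQTLs: 108 SNPs across 58 CpGs
planted-effect recovery (tested): 56 / 70 (80.0%)

attribution over 108 pairs (0 flagged): pct change 0.00% - 58.08%
     class  n     mean       sd
1     high  5 1.765453 1.299370
2 moderate 20 4.801201 5.078993
3     weak 83 6.277561 9.008310
ANOVA across frequency classes: F = 0.88, p = 0.4166

smoking indicators: 648 tests, 2 significant at FDR < 0.05
mortality: 108 SNPs over 133 events, 0 significant at FDR < 0.05
```

Reading this: of 1632 cis pairs, QC (mostly LD pruning and the MAF ≤ 0.1
filter) leaves 698; the two-stage design validates 108 mQTLs covering 58
of 150 CpGs — 56 of the 70 planted effects are recovered directly or via
an LD proxy, the misses being small effects (< 0.04 β-units) or rare
alleles. mQTLs move the estimated smoking effect by up to ~58%, and the
weakly smoking-related CpGs are moved the most (class means 6.3% > 4.8% >
1.8%), while genotype–phenotype scans are null by construction — the
generator plants no such effects, and 2/648 significant tests is chance
level.

## Layout

```
R/                 package code (simulation, io, qc, pairing,
                   deconvolution, models, attribution, outcomes, pipeline)
analysis/          numbered workflow scripts (thin drivers over R/)
tests/testthat/    unit, property and acceptance tests
scripts/           acceptance.R
vignettes/         methods vignette (models, assumptions, design choices)
inst/extdata/      small published-table fixtures used by tests
```
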