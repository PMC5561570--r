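---
title: "Methods: two-panel cis-mQTL mapping for smoking-related CpG sites"
author: "mqtlsmoke"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-panel cis-mQTL mapping for smoking-related CpG sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

Smoking leaves reproducible marks on blood DNA methylation: a few hundred
CpG sites (in genes such as *AHRR*, *F2RL3* or *GPR15*) are consistently
hypo- or hypermethylated in current smokers and are used as biomarkers of
current and lifetime exposure. But methylation at a CpG can also be driven
by nearby genetic variants — methylation quantitative trait loci (mQTLs).
If carriers of a minor allele differ systematically in methylation, mQTLs
can masquerade as, inflate, or mask smoking effects, and distort
epigenetic exposure scores.

`mqtlsmoke` implements a complete, testable pipeline for this question on a
two-panel cohort design: identify cis mQTLs (±50 kb) for candidate
smoking-related CpGs with a discovery/validation FDR design, quantify how
much each mQTL changes the estimated smoking effect on its CpG, test
SNP-by-smoking interactions, and scan the mQTLs against smoking phenotypes
and all-cause mortality. Because no individual-level cohort data of this
kind is publicly deposited, the package ships a synthetic-data generator
that emulates the cohort structure; every downstream stage is exercised and
verified against planted ground truth.

## The models

### mQTL identification

For each SNP–CpG pair the methylation β-value (the methylated fraction,
in [0, 1]) is the outcome of a linear mixed model with a random intercept
for the methylation measurement batch:

β = γ₀ + γ_G·G + Xγ + u_batch + ε,  u ~ N(0, σ_b²), ε ~ N(0, σ²)

where G is the minor-allele count (0/1/2) entered as a single additive
predictor, and X holds the full adjustment set: age, sex, smoking status
(current/former/never), alcohol consumption (4 levels), BMI class (3),
physical activity (3), prevalent CVD, diabetes and cancer, and K−1 of the
K estimated leukocyte proportions. Fitting is restricted maximum
likelihood (`lme4::lmer`); the SNP term is tested with a Wald z-test. With
a single batch the model degrades to ordinary least squares with t-tests,
and the result says so.

The two-stage design: all quality-controlled pairs are fit in the
discovery panel and Benjamini–Hochberg FDR is applied across all SNP-term
p-values jointly; pairs with FDR < 0.05 are refit in the validation panel
and BH-FDR is applied over the survivors only. Pairs under 0.05 again are
the mQTLs. The validation-stage FDR family is the survivor set alone — the
narrower reading of a two-stage confirmation design; computing it jointly
with discovery would mix the families.

SNP coding is additive by default. A genotype is fundamentally a 3-level
category, and a categorical coding is available (`snp_coding =
"categorical"`), but a single additive coefficient per pair is what a
per-pair effect table requires and what the dominant-model downstream
stages build on.

### SNP quality control

Filters run in a fixed order and each exclusion is attributed to the first
filter that catches it (the final survivor set is order-invariant; the
attribution is not):

1. **Missingness** — a SNP with ≥ 1% missing calls is excluded (strict
   boundary: exactly 1% is out).
2. **Hardy–Weinberg equilibrium** — exact test p < 1e-4 excludes. The test
   conditions on the observed allele counts and sums the conditional
   probabilities of all heterozygote counts no more probable than the
   observed one; it is computed in log space with exact factorial terms
   and is validated exhaustively against a direct enumeration oracle for
   all configurations up to n = 50. Monomorphic sites return p = 1 by
   convention. HWE uses the pooled panels' calls.
3. **MAF** — minor allele frequency ≤ 0.1 excludes (boundary-inclusive on
   the exclusion side, so MAF = 0.1 exactly is out).
4. **LD pruning** — within each CpG's surviving candidates, greedy
   selection: take the best-ranked SNP, drop all others with composite
   R² ≥ 0.5 against it (squared Pearson correlation of allele counts over
   pairwise-complete samples), repeat. "Best-ranked" defaults to the
   smallest marginal association p-value with the target CpG in the
   discovery panel (simple linear model, no covariates), computed before
   pruning; ties break by position then id. Ranking by MAF is available.
   Pruning is per-CpG — the literal reading of a per-locus workflow — so
   a SNP removed for one CpG may survive for another.

### Cell-type deconvolution

Whole-blood methylation confounds cell composition with everything else,
and smoking shifts leukocyte distributions. Following the reference-based
constrained-projection approach, each sample's β-vector over a panel of
reference CpGs is projected onto the m_ref × K cell-type profile matrix R:

p̂ = argmin ‖m − Rp‖²  subject to  p ≥ 0, Σp ≤ 1.

The quadratic program is solved exactly (dual active-set, `quadprog`); the
contract is the optimum, not the algorithm, and tests verify optimality
against 10⁴ random feasible points and exact recovery of noiseless
mixtures. The inequality Σp ≤ 1 (rather than equality) follows the
original formulation; the residual mass is reported. Downstream models use
K−1 of the K estimated proportions to avoid collinearity with the
intercept — the source analyses do not say which convention they used, so
this package picks K−1 and says so.

### Attribution: how much does an mQTL change the smoking effect?

Restricted to current and never smokers (both panels pooled), each
validated pair is fit twice with the fully adjusted batch-random-effect
model on the identical sample set: without the mQTL (smoking coefficient
β₁) and with the carrier-coded mQTL added (β₂). Carrier coding collapses
heterozygotes and minor homozygotes (minor-homozygote cells are small at
these sample sizes). The contribution is

pct = |100 · (β₁ − β₂) / β₁|,

"attenuated" when |β₂| < |β₁| and "strengthened" otherwise. On noiseless
data this equals the analytic omitted-variable-bias ratio
|100·aδ/(b + aδ)| where a is the carrier effect, b the smoking effect and
δ the coefficient of smoking in the auxiliary regression of carrier status
on smoking and the covariates; tests verify the identity to 1e-6. Records
whose β₁ is zero or not significant at 0.05 are flagged and carry no
percentage. Percentages are summarized by |distance| (< 10 kb vs ≥ 10 kb)
and by the CpG's reported frequency in prior smoking studies (weak 2–3,
moderate 4–5, high ≥ 6), with a standard one-way ANOVA across frequency
classes; when all percentages are identical the F statistic is 0 by
convention.

### Interactions and phenotype scans

The interaction model (current + never smokers) uses 3-level genotype with
the major homozygote as reference plus current-smoking and
smoking-by-genotype terms; never-smoking genotype groups and the
current × major-homozygote cell are references and carry no coefficient.
Cells that are empty or collinear at these sample sizes (typically
current × minor-homozygote) are dropped and recorded. The per-pair p-value
entering the BH-FDR family is the minimum contrast p-value
Bonferroni-adjusted for the number of estimable contrasts — the sources
are silent on how to collapse a multi-contrast interaction, and this is
the conservative choice.

Identified mQTLs (carrier coding) are then tested against six smoking
indicators — ever vs never, current vs never, current vs former (logistic
regression on the indicator-specific subset), pack-years, smoking duration
and age of initiation (linear models among ever smokers) — with BH-FDR
within each indicator family, and against all-cause mortality with a Cox
proportional-hazards model (Breslow ties, panels pooled, BH-FDR across
SNPs). The phenotype models adjust for age, sex, alcohol, BMI class,
activity and baseline CVD/diabetes/cancer. Two deliberate deviations from
a literal reading of the source description: smoking-derived covariates do
not adjust models whose outcome is itself a smoking phenotype (that would
be circular), and the batch random intercept is omitted for phenotype
outcomes (questionnaire phenotypes are not plate-measured). The mortality
model does keep smoking status as a confounder.

## The synthetic cohort

`sim_config()` defaults are the study conditions: discovery n = 581,
validation n = 368; smoking prevalence 18% current / 30% former / 52%
never; ~12.6-year administrative follow-up. Weibull survival (shape 1.5,
scale 55 y) with log-hazards 0.09/y of age, 0.7 for current and 0.25 for
former smoking was calibrated so expected deaths over follow-up match the
cohort description (~15%, 143 of 949). Genotypes: 150 CpGs on chromosomes
1–22 with disjoint windows, 12 SNPs each scattered within ±55 kb (so a few
fall outside the pairing window), LD blocks of 4 SNPs sharing a MAF drawn
from (0.05, 0.45); within a block, haplotypes copy the previous locus with
probability 0.8, giving adjacent-locus correlation ≈ 0.8 (R² ≈ 0.64, so
pruning at 0.5 actually prunes) while each locus stays marginally in HWE.
8% of SNPs get 1–3% call missingness (exercising the ≥ 1% filter); the
rest ~0.2%.

Methylation is generated additively on the β scale and clipped to [0, 1]:

β_ij = Σ_k w_jk p_ik + a_j G_ij + b_j smoke_i + u_batch(i) + ε_ij

with the cell-mixture term carrying the CpG's baseline level (profiles
w_jk ~ baseline + N(0, 0.05²)), one designated causal SNP for 47% of CpGs
(|a_j| ~ U(0.03, 0.12) per allele, random sign; 70/150 CpGs with mQTLs is
the emulated outcome), current-smoking effects b_j ~ U(−0.10, −0.02) with
former smokers at half effect, batch intercepts N(0, 0.01²) over 8 batches
per panel, and noise sd 0.03. Generating directly on the β scale (rather
than logit) matches the analysis model; clipping affects well under 1% of
entries under the defaults and is asserted in tests. The generator does
not model probe chemistry, detection p-values, β-value
heteroscedasticity near the boundaries, or realistic haplotype structure —
so passing tests demonstrate the statistical machinery, not robustness to
array artifacts. Sources of variance the published description does not
quantify (noise sd, batch sd, cell profiles) were set once for reasonable
pipeline power at the cohort's scale.

Effect sizes are shared between panels; batch intercepts are drawn per
panel. A single global seed drives every draw, so a dataset replays bit
for bit. Because LD pruning may keep a high-LD proxy instead of the causal
SNP, recovery bookkeeping counts a planted effect as recovered when the
CpG validates with the causal SNP or any proxy at R² ≥ 0.5 against it.

## Numerical choices and degenerate inputs

- HWE test: log-space enumeration; observed-probability comparison uses a
  1 + 1e-12 relative guard against ties lost to rounding.
- Minor-allele orientation happens within-cohort at load time; frequency
  ties at 0.5 keep file orientation.
- Rank-deficient fixed designs fail loudly, naming the collinear column;
  covariate levels absent from a panel (their dummy is constant) are
  dropped silently, which is the standard epidemiological practice.
- Logistic separation and Cox non-convergence are flagged in the result
  row, never returned silently; constant carrier columns are skipped with
  a note.
- Result TSVs print p-values/FDR in scientific notation (six mantissa
  digits — an FDR of 8.86e-103 survives a round trip) and other reals to
  six significant digits; data matrices round-trip at full precision.

## Problem sizes used by the test suite

Chosen to exercise every property on one CPU in minutes, and stated here
as the package's own scales: the HWE oracle sweep is exhaustive to n = 50;
BH-FDR is checked against the sort-based oracle on 10⁴ random vectors; the
two-stage null calibration uses 200 replicates of a 12-CpG, 48-SNP,
250/160-sample single-batch cohort (the OLS degenerate path — the property
under test is the two-stage FDR, not the mixed model); planted-mQTL
recovery (effect 0.05 β-units, MAF 0.3) uses 40 replicates at the full
581/368 panel sizes with 6 CpGs × 4 SNPs; mixed-model and Cox oracles use
n ≤ 48 instances against direct likelihood maximization.

## Known limitations

- The cis window is fixed at ±50 kb; trans effects are out of scope.
- Imputation, probe-level preprocessing and array normalization are
  upstream of this pipeline and not modeled.
- The attribution statistic compares coefficients, not a formal mediation
  or Mendelian-randomization decomposition.
- β₁/β₂ are estimated on the pooled panels (the sources are ambiguous
  between pooled and validation-only; pooled maximizes the current/never
  subset size and is flagged here).
- Wald z p-values from the mixed model ignore small-sample df corrections;
  at n ≈ 600 per panel the difference is negligible.
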