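---
title: "Effect-pattern epistasis scans: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effect-pattern epistasis scans: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epipattern)
```

## The statistical problem

epipattern implements exhaustive single- and multi-SNP association scans
for unrelated case-control cohorts genotyped on a small candidate panel —
the setting of surfactant-protein (SFTPA1, SFTPA2, SFTPB, SFTPC, SFTPD)
variant studies in interstitial lung disease, where a few hundred subjects
are typed at ~17 biallelic SNPs and the question is which genotype
*combinations*, not just single variants, shift disease risk.

Quantitative genetics decomposes a biallelic locus's effect into an
additive component (half the difference between the homozygote classes), a
dominance component (the heterozygote's deviation from the homozygote
midpoint) and a recessive component. To make these testable in a 2×2
case-control table each component is binarized:

| component | included subjects | exposed group |
|---|---|---|
| `a` (additive) | homozygotes only (dosage 0 or 2) | alt homozygotes |
| `d` (dominant) | all genotyped | heterozygotes |
| `r` (recessive) | all genotyped | alt homozygotes |

A *k*-SNP **effect pattern** assigns one component to each SNP of a tuple
(`dxdxa`, `axd`, ...). A subject is *included* when every component's
inclusion rule holds at its SNP and no tuple genotype is missing, and
*exposed* when all component indicators are simultaneously on — for
example, the exposed group of `dxd` is the double heterozygote AaBb, the
classic epistasis exemplar. The comparison group is the pooled set of all
included, non-exposed subjects.

Two points here were genuinely open and are package decisions:

* **Additive binarization.** The additive contrast is realized as alt
  homozygote vs ref homozygote with heterozygotes excluded — the only
  binarization of the additive effect compatible with a single 2×2 table.
  The orthogonal cis/trans double-homozygote contrast
  ((AABB+aabb) vs (AAbb+aaBB)) is deliberately *not* used, and neither is
  a conditional contrast that fixes the genotype at the partner loci; the
  conjunction rule treats every component symmetrically.
* **Dominant coding.** `d` is the heterozygote-*deviation* indicator
  (dosage == 1), not the carrier coding (dosage ≥ 1), because the
  double-heterozygote exposure group is what makes `dxd` an interaction
  contrast. `dominant_coding = "carrier"` is available for sensitivity
  analysis.

Allele orientation follows the declared REF/ALT of the input file (dbSNP
orientation for rs variants); the package never re-orients by sample
frequency, so odds-ratio directions are stable across cohorts. Subjects
missing a genotype at a tested SNP are dropped from that test only, never
cohort-wide.

## The stratified test

Each exposure is cross-tabulated against case status within sex × smoking
strata (≤ 4 strata; subjects with incomplete covariates are dropped from
stratified tests with a logged count). Association is measured by:

* the **Mantel-Haenszel common odds ratio**
  $\widehat{OR}_{MH} = \sum_i a_i d_i/n_i \,\big/\, \sum_i b_i c_i/n_i$,
  with 95% CI from the Robins-Breslow-Greenland variance of
  $\log \widehat{OR}_{MH}$;
* the **Cochran-Mantel-Haenszel chi-square** (1 df) using the
  hypergeometric mean and variance of the case-exposed cell per stratum.

Numerical conventions:

* With one stratum the CMH statistic equals $\frac{n-1}{n}$ times the
  classical Pearson chi-square — an exact identity that follows from the
  hypergeometric variance, and the behavior of every standard CMH
  implementation.
* The 0.5 **continuity correction** is on by default (`continuity = TRUE`):
  stratum counts in cohorts of a few hundred are small, and the corrected
  statistic tracks the exact conditional reference better in the tails.
  It is deliberately a flag: the corrected test is conservative by
  construction (measured null rejection rate ≈ 0.03 at the template design),
  so *calibration* studies should use `continuity = FALSE`, whose measured
  null rejection rate is 0.05 to within Monte-Carlo error. A continuous
  chi-square tail can approximate the discrete permutation law only to the
  order of the lattice spacing (≈ 0.01 on tables with ~100 subjects);
  agreement beyond that is not attainable by any correction.
* **Zero cells** are not pseudo-counted: $\sum b_i c_i/n_i = 0$ yields an
  infinite OR reported verbatim with an `infinite_or` flag; a test with
  fewer than 5 exposed subjects is computed but flagged `sparse`; strata
  with zero hypergeometric variance contribute nothing, and a fully
  degenerate table yields an `NA` p with a `degenerate` flag rather than
  an error, so exhaustive scans never abort.

A scan of order *k* over *m* SNPs runs every $\binom{m}{k}\,3^k$
tuple-pattern hypothesis (51 / 1,224 / 18,360 for *m* = 17 and
*k* = 1, 2, 3). Benjamini-Hochberg q-values are computed within each scan
order — the orders are reported as separate families, not pooled — and
rows with raw p < `alpha` (default 0.05) are reported, with `q <= fdr`
additionally flagged. The counting core is vectorized (component
inclusion/indicator matrices × a stratum-status design matrix), so a full
order-3 scan of a 278-subject, 17-SNP cohort takes about a second.

## Haplotype analysis

For a SNP pair, the four haplotype frequencies are estimated from unphased
dosages by the standard two-locus EM: every diplotype is phase-certain
except the double heterozygote, whose cis/trans resolutions are
fractionally weighted by the current frequencies each E-step. Convergence
is declared when the largest frequency change drops below `tol` (1e-8) or
after `max_iter` (1,000); with no double heterozygotes the closed-form
gamete-counting solution is returned after one iteration. The
log-likelihood trace is retained and is nondecreasing by construction.

Association uses a **carrier (dominant) contrast**: frequencies are
estimated on the pooled cohort (cases + controls, avoiding case/control
asymmetry in phase assignment), each subject is assigned their most
probable diplotype (cis/trans ties broken toward cis), and carriers of the
candidate haplotype are tested against non-carriers through the same
stratified CMH machinery. Hard assignment keeps the 2×2 counts integral;
it misclassifies a fraction of double heterozygotes proportional to the
minor phase probability, which attenuates estimated carrier effects when
the pair is in weak LD. The surfactant-protein pairs this analysis targets
are tight intragenic pairs in strong LD, where the minor phase is rare and
the attenuation is negligible; the package's recovery checks therefore
simulate strong-LD haplotype structure (frequencies 0.55/0.05/0.10/0.30).
The default pair set is every adjacent SNP pair within a gene, with
`all_pairs = TRUE` as the exhaustive alternative; haplotype labels use the
actual ref/alt nucleotides (e.g. `TG`).

## Cross-disease comparison

Two scans against a shared control group are matched on canonical SNP sets
(identifiers sorted, pattern components permuted in lockstep, so `dxa` on
(s2, s1) equals `axd` on (s1, s2)). Each shared set is classified as
`same_pattern_concordant`, `same_pattern_discordant` (a shared pattern
with odds ratios on opposite sides of 1 — risk in one disease, protective
in the other), or `different_pattern`; sets significant in one disease
only are `unique_a`/`unique_b`. The classification is descriptive — no
formal between-disease heterogeneity test is defined, mirroring how such
comparisons are reported. A single-SNP table
(`single_snp_comparison()`) lists shared and unique SNPs with per-disease
directions, the textual equivalent of a Venn diagram with direction
arrows.

## The cohort simulator

`simulate_cohort()` draws a source population and rejection-samples it to
fixed case/control quotas:

* genotypes per SNP from Hardy-Weinberg proportions at the configured
  alt-allele frequency, or per configured LD pair as two gametes from a
  four-haplotype distribution;
* sex and smoking as independent Bernoulli covariates with their own
  log-odds on disease (confounders of status, never of genotype);
* disease status from a logistic penetrance
  $\text{logit}\,P = \beta_0 + \beta_m\,\text{male} +
  \beta_s\,\text{smoker} + \sum_e \log(OR_e)\,\mathbb{1}[\text{exposed}_e]$,
  where exposure uses exactly the scan's conjunction rule.

Because sex and smoking are independent of exposure, the within-stratum
odds ratio equals the planted conditional OR exactly, so the stratified MH
estimator targets the planted value without a non-collapsibility gap; the
recovery checks confirm mean log-OR bias below 0.01 at n = 2,000/2,000.

`study_template()` encodes the design the package is built around: 17
SNPs across the five surfactant-protein genes (5/4/4/2/2 per gene), 84
cases vs 194 controls, population covariate margins matching the published
control group (64% male, 47% smokers) and covariate log-odds (+0.28 male,
−0.45 smoker) reproducing the case-group shifts. Panel MAFs are not
published for this population; the template spreads them evenly over
0.2–0.4 (typical for these common coding variants) and they are
user-overridable. The baseline logit of −1.5 keeps rejection sampling
efficient; the draw cap (1e7) turns an unattainable quota into an error
suggesting a larger intercept.

What the simulator does **not** emulate: population structure/admixture
(the motivating studies are single-ancestry by design), age (not a
stratification covariate in the analysis), genotyping error, and
missing-data mechanisms other than missing-completely-at-random. Passing
recovery and calibration tests on simulated cohorts therefore validate the
statistical machinery, not robustness to those real-data complications.

## Verification strategy and problem sizes

The test suite checks the machinery against independent references rather
than reproducing any published cohort's numbers (patient-level genotypes
for the motivating studies are not deposited):

* **Oracle equivalence** — 1,000 random stratified table sets (1–4 strata,
  counts 0–200) against a naive scalar implementation of the direct
  formulas, at 1e-10 relative error, plus `stats::mantelhaen.test` and
  `chisq.test` as external references.
* **Permutation reference** — 20 study-scale single-stratum tables
  (expected cells ≥ 5) against a doubled one-sided conditional tail from
  1e5 case-label shuffles. Agreement is limited by the ≈ 0.01 lattice
  floor discussed above.
* **Null calibration** — 1,000 template-design replicates for the
  single-SNP rejection rate (uncorrected statistic, see above) and 150
  replicates of the full order-3 scan for BH false-discovery control;
  within-replicate dependence is handled by using the replicate-level
  empirical standard error.
* **Recovery** — 200 replicates per planted scenario (three-SNP `dxdxa`
  OR 3 and single-SNP dominant OR 0.45 at n = 2,000/2,000; carrier
  haplotype OR 2.4 at n = 600/600 over 500 replicates), checking mean
  log-OR bias (±0.1) and 95% CI coverage (93–97%).

Replicate counts were chosen so Monte-Carlo error is well below each
tolerance band while the whole suite runs in minutes on one CPU.

## Known limitations

* The pooled "all included non-exposed" comparison group mixes reference
  genotype classes; the resulting OR is a contrast against that mixture,
  not against a specific genotype.
* No logistic-regression covariate adjustment (stratification only), no
  HWE-based QC filtering, no imputation, no >2-locus haplotypes, and no
  permutation-based multiplicity control.
* Exhaustive scans on panels much larger than ~20 SNPs grow
  combinatorially; the vectorized core handles tens of thousands of
  hypotheses comfortably but is not designed for genome-wide use.
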