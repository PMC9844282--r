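---
title: "Methods: polygenic score construction and portability evaluation for sleep traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic score construction and portability evaluation for sleep traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A polygenic risk score (PRS) transfers marginal effect estimates from a
large discovery GWAS into an individual-level predictor in a different
("target") cohort. For questionnaire sleep traits — habitual sleep
duration, chronotype (morningness–eveningness), insomnia symptoms — the
scientific question is *portability*: how much trait variance does a score
trained in one European-ancestry population explain in another, and how
informative are the extremes of the score distribution?

`prsport` implements that full analysis path as composable, individually
tested stages, plus a simulator that generates a complete two-cohort
experiment with known ground truth, so every stage is exercised without any
access-restricted cohort data.

# Model and procedure

## Scoring model

The score is the weighted allele-dosage sum
$\mathrm{PRS}_i = \sum_j w_j d_{ij}$, reported by default per allele,
$\mathrm{PRS}_i / (2M)$ over the $M$ contributing variants — the default of
the standard scoring tool, and the scale on which cohort PRS means are
conventionally printed (~1e-3 magnitudes). Missing dosages are mean-imputed
as $2p_j$; an "omit and rescale the denominator" alternative is available
by flag. Weights are marginal per-allele GWAS effects after clumping, not
jointly fitted effects: the method is single-threshold clumping + scoring,
deliberately not an LD-aware shrinkage estimator.

## Summary-statistic QC and harmonization

Records are SNVs on autosomes with alleles in {A,C,G,T}. Filters, with
*strict* inequalities because the inclusion rule is stated as ">":
INFO > 0.8, MAF > 0.01; strand-ambiguous variants (A/T, C/G — undecidable
strand without frequency matching) and multiallelic positions (same
chrom:pos seen more than once; position is the only key summary-stat text
provides) are excluded. Every removed record is attributed to the *first*
failing rule in the fixed order multiallelic → ambiguous → INFO → MAF, so
exclusion counts always partition the removed set and are reproducible.
All-ambiguous exclusion is the plain reading of the protocol; we do not
attempt frequency-based rescue of A/T–C/G variants.

Harmonization aligns each effect to the target's counted allele: identical
orientation keeps $\beta$, swapped alleles negate it, any other allele-set
mismatch drops the variant (counted). Genome builds are assumed identical;
liftover is out of scope, and the assumption is enforced by requiring exact
(chrom, pos, allele-set) matches.

## Target cohort QC

Variant level: autosomes only, INFO ≥ 0.9 — note the *inclusive* boundary,
because here the stated rule is an exclusion ("INFO < 0.9"); the asymmetry
with the summary-stat thresholds is intentional and follows each stated
inequality's direction.

Sample level, two filters:

* **Heterozygosity.** $F_i = (O_{hom,i} - E_{hom,i})/(M_i - E_{hom,i})$
  on hard calls (dosages rounded — F is defined on genotype counts), with
  $E_{hom} = \sum_j (1 - 2p_j(1-p_j))$ over the sample's non-missing sites.
  Samples beyond 3 SD from the mean F are removed; mean and SD are computed
  once on all samples, not iteratively re-centered.
* **Relatedness.** GRM
  $A_{ik} = \frac{1}{M}\sum_j \frac{(x_{ij}-2p_j)(x_{kj}-2p_j)}{2p_j(1-p_j)}$
  with mean-imputed missing dosages and monomorphic variants dropped (with a
  warning) rather than failing the whole matrix. Pruning removes samples
  greedily until no kept pair exceeds 0.125 (~second-degree boundary).
  The reference tool's internal removal order is not documented, so we fix a
  deterministic greedy rule: remove the sample with the most above-cutoff
  partners; break ties by larger mean above-cutoff relatedness, then input
  order. Duplicate samples are just extreme relatedness and need no
  separate detector. Heterozygosity is applied before relatedness by
  default (the source protocol does not state an order; the choice is
  config-overridable).

## Structure covariates

PCA runs on an LD-pruned variant set, standardized by $2p$ and
$\sqrt{2p(1-p)}$, missing values mean-imputed. No pruning parameters are
stated in the source protocol, so the defaults deliberately mirror the
clumping geometry (250 kb, r² 0.1) for internal consistency — a declared
choice, not an inferred one. The pruning algorithm is a greedy
left-to-right scan (keep a variant iff r² ≤ threshold against every kept
variant within the window upstream): unlike literal fixed-step windows this
guarantees the contract — no retained pair within the window span above the
threshold — unconditionally, is order-stable, and always drops the
later-positioned member of a correlated pair. PCA signs are fixed by making
each component's largest-magnitude loading positive, so results are fully
deterministic. PCs are computed once on the post-QC, pre-clumping cohort:
structure covariates are cohort-level, not score-level.

## Clumping

Candidates are the harmonized variants with $p < 5\times10^{-4}$, visited
in ascending p (ties by chromosome then position). Each unassigned
candidate becomes an index; unassigned candidates on the same chromosome
within a ±250 kb *radius* and with $r^2 \ge 0.1$ to the index (measured in
the target cohort itself, which is the LD panel the protocol clumped) are
assigned to it. The member comparison is inclusive (≥) because "threshold"
is stated without strictness and the referenced tool clumps everything at
or above the setting; the p comparison is exclusive ("p < 5e-4"). The
acceptance suite proves this greedy single-pass implementation identical to
a brute-force reference that re-scans all pairs after every promotion, on
100 random LD-structured instances.

## Evaluation

* **Phenotype preparation.** Sleep duration ≤ 3 h or ≥ 16 h is excluded
  (boundary values excluded, "3 h or less / 16 h or more"). Participants
  answering the same question in multiple waves contribute exactly one
  answer, selected by a seeded uniform draw — reproducible, and isolated in
  its own RNG stream so it never perturbs other stages.
* **Dichotomization** (for logistic models): chronotype keeps only the
  "absolutely morning" (1) vs "absolutely evening" (4) extremes; sleep
  keeps ≤ 6 h ("short") vs ≥ 9 h ("long"), boundaries inclusive; insomnia
  severe-vs-none is scale-specific (code 1 vs 3 on the 3-level
  often/sometimes/not-at-all scale; codes 4–5 vs 1 on the 5-level scale).
  Each rule partitions input into cases + controls + excluded.
* **Linear models.** OLS of the trait on PRS + age + sex + PC1..6, and the
  same without PRS; the headline number is the increment
  $\Delta R^2 = R^2_{full} - R^2_{base}$. Published tables are ambiguous
  about full-model vs incremental R², so both are reported. Exact
  collinearity is a named error, not a silent drop.
* **Logistic models.** McFadden pseudo-R² $1 - d_1/d_0$ from the deviances
  of nested maximum-likelihood fits, deviance defined as
  $-2\ell$ (the saturated-model constant cancels in the ratio). A constant
  PRS yields exactly 0; non-convergence (e.g. separation) is flagged in
  the report, never hidden. Insomnia is evaluated with the logistic model
  only, matching how such ordinal symptom scales are reported.
* **Group and tail contrasts.** Welch (unequal-variance) t-tests — the
  source says only "t-test"; Welch is the safer default. The 5% tails use
  nearest-rank quantiles with ties kept (groups may exceed $qn$); tail
  means are raw trait means, not covariate-adjusted, matching how such
  group means are conventionally presented. Under a bivariate-normal model
  with PRS–trait correlation $\rho$ and trait SD $\sigma$, the expected
  top-vs-bottom difference is $2\rho\sigma\,\varphi(z_{1-q})/q$
  (≈ $2\rho\sigma \cdot 2.0627$ at q = 0.05), which the acceptance suite
  verifies by simulation.

# The simulator: what it emulates, and what it does not

`sim_config()` describes a two-cohort world. Genotypes: variants in
50-variant LD blocks; within a block each haplotype is a latent Gaussian
AR(1) (`rho` = 0.8 by default), thresholded at the allele-frequency
quantile, two haplotypes summing to dosage — giving LD that decays with
distance and vanishes across blocks. Blocks sit 1 Mb apart with 5 kb
variant spacing, so physical windows align with LD structure. MAF is
uniform on (0.05, 0.5); INFO ~ Beta(30, 1) (median ≈ 0.98, occasional
low-quality variants), resembling well-imputed common variants.

Phenotypes: `m_causal` variants get standardized effects
$\beta \sim N(0, 1/m)$; noise is scaled so $var(g)/var(y)$ equals the
configured SNP heritability — defaults are the reported sleep-trait values
(chronotype 13.7%, sleep duration 9.8%, insomnia 16.7%). Causal
standardization uses the design MAFs so discovery and target share
identical per-allele true effects. Ordinal questionnaire traits threshold
the same latent liability (chronotype 15/35/35/15%, insomnia 50/35/15%
with severe coded 1 — prevalence choices made once as plausible
questionnaire distributions, stated here, not tuned). Sleep duration is
scaled to mean 7.5 h, SD 1.05 h (≈ 63 min, matching typical self-report
spread). Age and sex are drawn independently of the traits; covariate
adjustment is therefore tested through invariance, not through planted
confounding. The discovery GWAS regresses the *continuous latent* on
dosage for every trait, standing in for the large-scale GWAS that produced
the published weights.

Not emulated: realistic demography and haplotype-copying LD,
genotyping/imputation error (INFO is decorative metadata, not a noise
model), cross-ancestry frequency divergence (beyond a two-subpopulation
PCA fixture in the tests), genotype–covariate correlation. A green
end-to-end test therefore establishes that the pipeline's statistics
behave as designed under an additive LD-blocked world — it does not
certify performance on real cohort data.

All randomness flows from one master seed through labelled per-stage
streams (`stream_seed(seed, label)`), so any stage is reproducible in
isolation and two runs with the same config produce byte-identical
artifacts (verified in the acceptance suite).

# Numerical conventions and degenerate inputs

* Zero-variance dosage vectors have undefined r²; pruning and clumping
  treat them as 0 with a warning.
* GRM and PCA drop monomorphic variants instead of erroring.
* F is undefined when $M_i = E_{hom,i}$; such samples are flagged NA and
  removed by the outlier filter.
* Welch tests degrade gracefully when both groups are constant (equal
  means → p = 1).
* Quantiles for tails are nearest-rank (`ceiling(qn)`-th order statistic),
  ties kept.
* Clumping ties in p are broken by (chrom, pos); pruning drops the
  later-positioned variant; rel-cutoff ties resolve by mean relatedness
  then input order — every tie-break is deterministic and documented.
* Config files are flat JSON (the environment provides no YAML parser);
  round-tripping is lossless (`digits = NA`).

# Design choices made where the design was open

* The chronotype association's direction is reported, not assumed: the 1–4
  scale is evening-coded while the discovery trait is morningness, so the
  PRS coefficient's sign carries that orientation.
* The LD panel for clumping is the post-QC target cohort itself.
* `compute_prs` reports the per-allele average by default (`mode = "sum"`
  available) — consistent with printed cohort score magnitudes.
* The heterozygosity-vs-relatedness filter order (het first) is explicit
  and overridable, since the protocol leaves it unstated.
* Effect sizes are Gaussian across causal variants; the source gives no
  effect-size distribution, so this is a declared modeling choice.

# Known limitations

* Position-only multiallelic detection cannot distinguish true
  multiallelics from build mismatches; both are (correctly) excluded.
* The greedy rel-cutoff removes a small, deterministic — but not provably
  minimal — set of samples; minimality is NP-hard in general and not
  required by the contract (no kept pair above cutoff).
* McFadden pseudo-R² can be marginally negative in theory only for
  non-nested or non-converged fits; the implementation reports a flag
  rather than clipping.
* PCA is full SVD; for cohorts far beyond ~10⁴ samples a truncated/
  randomized solver would be the natural replacement.
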