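---
title: "Methods: sex biases in disease incidence and tissue expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex biases in disease incidence and tissue expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Most autoimmune diseases (AIDs) occur more often in women, most cancers
more often in men. If both phenomena have a common tissue-level basis, the
*incidence rate sex bias* of AIDs and of cancers arising in the same tissue
should co-vary across tissues, and tissue-level molecular covariates —
e.g. the sex bias in mitochondrial gene expression — should track both.
`sexbias` implements the statistical machinery for that style of analysis:
measure estimation from partially reported epidemiological studies,
tissue/country matching, correlation and partial-correlation tests, bulk
expression sex-bias summaries, and preranked gene set enrichment analysis
(GSEA), together with a synthetic-data generator that plants a known signal
so every stage can be verified end to end without external data.

# Incidence measures

For one disease in one population, with `IR` a crude incidence rate
(cases · year⁻¹ per 10⁵ persons; rates on other scales are rescaled on
input),

* IRSB = log2(IR_M / IR_F) — positive means male-biased; zero means no
  bias. A zero rate leaves the measure undefined (`NA`): we never impute
  pseudo-counts, because the ≥ 25-case eligibility floor makes zero cells
  rare and a log ratio at zero has no meaningful value.
* With `SexRatio = population_F / population_M`, missing measures are
  estimable from what a study does report:
  * IRSB ≈ log2(cases_M / cases_F × SexRatio)
  * IR_F ≈ IR_TOTAL × (cases_F / cases_TOTAL) × (1 + 1/SexRatio)
  * IR_M ≈ IR_TOTAL × (cases_M / cases_TOTAL) × (1 + SexRatio)
  * IR_TOTAL = IR_M/(1 + SexRatio) + IR_F × SexRatio/(1 + SexRatio)

These are exact algebraic identities when `SexRatio` is the true one; with
the default `ratio_1_1` variant (sex ratio fixed at 1, adequate because
human background sex ratios sit near 1.0) they are approximations whose
quality `validate_estimators()` measures on the records that report both
the measure and its estimator inputs (Pearson r with a one-sided t-test,
and an OLS fit `actual = β·estimate + α`). Estimates are never chained:
only originally reported quantities feed an estimator, and a reported value
is never overwritten. When a study reports both a direct IRSB and counts
implying a different one, the reported value wins (provenance `given`).

**Curation rules.** Records must be population-based, use clinical
diagnostic criteria, and carry ≥ 25 cases (evaluated only when a total
count is known or derivable — studies reporting only rates have already
passed eligibility at the source); sex-specific tissues are excluded; an
AID must survive in ≥ 3 countries (registry-derived cancers are exempt).
Crude rates are preferred over age-adjusted ones when both are available;
the `age_adjusted` flag propagates to aggregated outputs. Studies spanning
several years contribute one record; registry cancer series arrive as one
record per year and are averaged per (cancer, country).

**Aggregation.** Disease-country points take the arithmetic mean of each
measure over the studies that provide it — different measures of one point
may therefore average over different study subsets, since requiring
complete studies would discard most of the catalogue for no gain in the
per-measure means.

# Pairing and correlation

Within every (tissue, country) cell the full AID × cancer cross product is
formed (two thyroid AIDs and two thyroid cancers in one country give four
pairs); no collapsing to one pair per tissue. Global pairs are built from
per-disease across-country mean IRSBs, *then* matched — not from means of
country-level pairs — so every disease contributes equally regardless of
how many countries report it. Correlations use the t statistic
`r·sqrt((n−2)/(1−r²))`; Spearman's version applies it to average-rank
correlations, the usual small-n approximation (an exact permutation test
would add little at the n ≈ 20–30 of these analyses). Global tests are
two-sided; the per-country scan (countries with ≥ 18 complete pairs) tests
the one-sided positive alternative and corrects across qualifying countries
with Benjamini-Hochberg.

# Expression summaries

From a TPM matrix with per-sample tissue and sex labels:

* GE — per-gene arithmetic mean TPM over a (tissue, sex) cell; summaries
  are mean-then-ratio, not averaged per-sample ratios.
* ESB = log2(GE_M / GE_F), defined only when both means are positive.
* GSA — geometric mean of member-gene GE (computed in log space);
  undefined when any member gene has zero mean expression. An optional
  floor (`eps`, e.g. 0.01 TPM) may be applied and is logged when used;
  it is off by default because silently flooring changes the statistic.
* ASB = log2(GSA_M / GSA_F); when every member ESB is defined this equals
  the arithmetic mean of the member ESBs — an identity the tests assert to
  1e-9.

Sub-tissue sample labels (e.g. brain subregions) can be pooled under one
parent tissue with a tissue map, matching the convention of treating
"brain" as a single unit.

# Per-gene association and GSEA

Each disease contributes one observation pairing its global IRSB with the
ESB of a gene in the disease's tissue of origin; tissues hosting two
diseases contribute two observations with identical ESB. This keeps the
observation unit the disease (matching the point counts of the
corresponding scatter plots); a tissue-collapsed variant (per-tissue mean
IRSB) is available behind `collapse_tissues = TRUE`. Per-gene Spearman
correlations require ≥ 3 observations (configurable). The joint phenotype
is the plain average of the AID and cancer correlations (not
z-transformed, keeping the statistic on the correlation scale).

The preranked GSEA orders genes by these correlations (descending; ties
broken deterministically by gene id; genes with missing correlations are
excluded, not scored as zero) and computes the weighted Kolmogorov-Smirnov
statistic with exponent 1 (the standard weighted form; exponent 0 gives
the classic unweighted walk). The null is gene-label permutation — random
same-size gene sets — because the ranks derive from tissue-level
correlations, so sample permutation is not available. Null distributions
are shared across sets of equal size. NES normalises ES by the mean |null
ES| of matching sign (positive and negative pools separately); nominal p
is one-tailed against the matching-sign pool with the add-one correction;
BH adjustment runs across all tested sets. A tie between the positive and
negative running-sum extreme (possible in the unweighted walk) resolves to
the positive extreme, with a 1e-10 tolerance so the choice cannot flip on
floating-point noise. The permutation inner loop is compiled (Rcpp) and
consumes R's RNG stream, so results are reproducible from a seed.

# Partial correlation

`partial_correlation(x, y, z)` computes
`r_xy.z = (r_xy − r_xz·r_yz)/sqrt((1−r_xz²)(1−r_yz²))` with a two-sided
t-test on n − 3 degrees of freedom; it equals the correlation of the
residuals from the simple regressions of x and y on z, an identity the
tests assert numerically. A control variable collinear with either
argument (|r| within 1e-12 of 1) is flagged degenerate rather than
returning a 0/0 artifact. In the headline use, x and y are the matched
cancer and AID IRSBs and z is the designated gene set's tissue ASB: if the
set carries a genuine common driver, the raw positive pair correlation
attenuates toward zero once its ASB is controlled.

# The synthetic-data generator

`generate_incidence()` emulates a curated study collection. Its defaults
mirror the scale of the real analysis: 17 AIDs + 17 cancers over 12
tissues and 30 countries, a 37-gene planted set over ~2000 background
genes in `generate_expression()`. Per-tissue drivers d_t ~ N(0, 1) enter
each disease's true IRSB as
`IRSB_d = μ_class + τ·(sqrt(ρ)·d_t + sqrt(1−ρ)·ε_d)` with defaults
μ_AID = −1, μ_cancer = 0.5 (the typical female bias of AIDs and male bias
of cancers), τ = 0.6 and mixing weight ρ = 0.5, so the AID and cancer sets
share half their tissue-level variance — the common-factor hypothesis the
pipeline is meant to detect. Case counts are Poisson (the standard
incidence model; the source analysis has no generative model, so this is
the synthetic stand-in) at rates implied by the true IRSB plus
country-level log2 noise (σ = 0.3), with per-country background sex
ratios ~ N(1.04, 0.02) and 10⁶ males per country. Observed rates are then
recomputed from the drawn counts and recorded populations, so every
incidence identity holds exactly and the estimators can be validated as
identities. AID records are masked to the four availability patterns with
probabilities (0.11, 0.56, 0.33, 0) — the observed reporting mix of such
study collections; cancers are registry-style, per-year and fully
reported.

`generate_expression()` plants per-tissue biases
`b = c·d_t + N(0, σ_g)` (defaults c = 1, σ_g = 0.3) on the planted genes,
split ±b/2 between the sexes around a per-gene lognormal baseline
(log2 TPM ~ N(5, 1.5)), with per-sample log2 noise σ = 0.5 and 15 samples
per (tissue, sex). In the noise-free limit the planted per-tissue ESB
equals the driver exactly, and the whole pipeline recovers the planted
couplings; the tests exercise both that limit and the noisy defaults.

What the generator does *not* emulate: age structure (rates are taken as
pre-standardised inputs), reporting-propensity differences between sexes,
correlated masking (availability patterns are independent across records),
secular incidence trends within registry series, and the heavy-tailed,
gene-gene-correlated structure of real bulk RNA-seq. Passing tests
therefore demonstrate the correctness of the estimators and statistics
under a known generative model, not the robustness of the scientific
conclusion to those real-data complications.

# Numerical choices and problem sizes

Tolerances: algebraic identities are asserted to 1e-12 (relative for
rates, absolute for the log2 IRSB, whose natural scale is absolute);
oracle equivalences to 1e-9. Degenerate inputs (constant vectors, zero
rates, empty groups, missing gene ids) raise conditions or return `NA`
per the contracts above rather than propagating infinities. The
end-to-end recovery checks use the default generator configuration with a
collection of the planted set plus 19 random sets and 5 × 10⁴
permutations — enough that the smallest attainable BH-adjusted p
(~m/(1 + n_same-sign)) clears the 10⁻³ significance bar with margin — over
50 seeds; the attenuation check uses 200 seeds of a lighter configuration
(12 countries, 37 planted + 5 background genes) since only the planted
set's ASB and the pair IRSBs matter there. These sizes keep the whole
suite desk-scale while leaving the statistical margins comfortable.

# Known limitations

* The Spearman p-value uses the t approximation throughout; at n < 10 it
  is only approximate (the global analyses operate at n ≥ ~17).
* Availability partitioning treats a present-but-zero count as present;
  the downstream estimator then returns `NA`, so such records contribute
  no estimate.
* `gsea_prerank` shares one permutation null across same-size sets; p-values
  of equal-size sets in one call are therefore not independent across sets
  (NES ordering and BH adjustment are unaffected).
* The CLI wrapper (`inst/scripts/run_pipeline.R`) is a thin convenience
  over the exported stage functions, which remain the primary interface.
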