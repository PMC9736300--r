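# sexbias

Tools for quantifying sex biases in disease incidence and in bulk tissue
gene expression, and for testing whether the two are linked across
tissues.

Most autoimmune diseases (AIDs) are more frequent in women and most
cancers more frequent in men. A natural population-level question is
whether these opposite biases co-vary: across tissues, is the *incidence
rate sex bias* of an AID correlated with that of the cancer arising in the
same tissue, and do tissue-level molecular covariates (such as the sex
bias in mitochondrial gene expression) track both? `sexbias` implements
the full statistical pipeline for this style of analysis:

* **Incidence measures.** For each study record,
  `IRSB = log2(IR_M / IR_F)` (positive = male-biased), with crude rates
  normalised to cases/year per 10⁵ persons. Missing measures are completed
  from partially reported quantities via the estimators
  `IRSB ≈ log2(cases_M/cases_F × SexRatio)`,
  `IR_F ≈ IR_TOTAL × (cases_F/cases_TOTAL) × (1 + 1/SexRatio)`,
  `IR_M ≈ IR_TOTAL × (cases_M/cases_TOTAL) × (1 + SexRatio)` and
  `IR_TOTAL = IR_M/(1+SexRatio) + IR_F·SexRatio/(1+SexRatio)`
  (`SexRatio` = female/male background population; default variant fixes
  it at 1:1). Availability partitioning and estimator validation
  (Pearson r, OLS slope) quantify how well the estimators reproduce
  directly reported values.
* **Curation and aggregation.** Eligibility filtering (population-based,
  clinical criteria, ≥ 25 cases, ≥ 3 countries per AID, sex-specific
  tissues excluded), across-study and across-year arithmetic means to
  disease-country points.
* **Pairing and correlation.** Tissue- and country-matched AID × cancer
  pairs (full cross product per cell), global across-country means,
  Pearson/Spearman t-tests, per-country scans with Benjamini-Hochberg
  correction.
* **Expression sex bias.** Per-tissue, per-sex mean TPM (GE),
  `ESB = log2(GE_M/GE_F)`, gene set activity (geometric mean) and its sex
  bias `ASB = log2(GSA_M/GSA_F)` from GTEx-style wide TSV matrices.
* **Association and GSEA.** Per-gene across-tissue Spearman correlation of
  ESB with disease IRSB (AID, cancer, and their joint average), preranked
  GSEA with a weighted Kolmogorov-Smirnov statistic, gene-label
  permutation null (compiled inner loop), sign-matched NES and BH-adjusted
  p-values; first-order partial correlation
  `r_xy.z = (r_xy − r_xz·r_yz)/√((1−r_xz²)(1−r_yz²))` to control the pair
  correlation for a gene set's ASB.
* **Synthetic data.** Generators that plant a known tissue-level driver in
  both the incidence catalogue and a TPM matrix (Poisson case counts,
  Table-style availability masking, a 37-gene planted set), so every stage
  has a ground-truth recovery test with no downloads.

## Worked example

```r
library(sexbias)

# a synthetic study collection with a planted cross-disease driver
inc <- generate_incidence(seed = 1)
res <- run_incidence_stage(inc)
res$cor_global_pearson
#> pearson correlation: r = 0.2724 (n = 27), two-sided p = 0.1693

# expression matrix whose planted 37-gene set tracks the same driver
expr <- generate_expression(drivers = inc$truth$drivers, seed = 2)
coll <- c(list(MT = expr$truth$planted_genes),
          {set.seed(3); random_gene_sets(rownames(expr$tpm))})
ex <- run_expression_stage(res, expr$tpm, expr$attrs, coll,
                           n_perm = 5000, seed = 4)
head(as.data.frame(ex$gsea$joint)[, 1:6], 2)
#>     pathway size        es      nes    p_nominal      p_adj
#> 1        MT   37 0.9850000 3.554369 0.0003427005 0.00685401
#> 2 nullset10   49 0.3863908 1.483575 0.0294621446 0.29462145
ex$asb_cor_cancer
#> pearson correlation: r = 0.7855 (n = 17), one-sided p = 9.318e-05
ex$partial
#> Partial correlation (n = 27):
#>   r_xy = 0.2724, r_xz = 0.7788, r_yz = 0.5121
#>   r_xy.z = -0.2348, two-sided p = 0.2483 (df = 24)
```

The planted set tops the GSEA ranking of all three phenotypes (here the
joint one: NES 3.55, BH-adjusted p 0.007 at 5000 permutations); its
per-tissue activity sex bias correlates with cancer IRSB (r = 0.79); and
the raw AID-cancer pair correlation (r = 0.27) flips toward zero once the
planted set's ASB is controlled — the signature of a common tissue-level
driver, which is exactly what the generator planted.

Real data enter through `read_incidence()` (study-record TSV),
`read_expression_matrix()` / `read_sample_attributes()` (GTEx-style wide
TSV + sample table) and `read_gmt()`. A thin command-line wrapper with
`simulate` / `incidence` / `expression` / `run-all` subcommands lives in
`inst/scripts/run_pipeline.R`.

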