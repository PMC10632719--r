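# admixclock

Epigenetic clocks — linear combinations of DNA-methylation beta values at
CpG sites — estimate a biological age whose deviation from chronological age
("age acceleration") predicts morbidity and mortality. When two populations
with different genomic histories live side by side, differences in their
acceleration can come from genetics (global or local ancestry, kinship,
inbreeding) or from ecology (place of living, infection). `admixclock` is a
self-contained R implementation of the full analysis chain needed to take
that question apart, aimed at population-epigenetics researchers who have a
CpG×sample beta matrix, clock coefficient files, genotypes and
local-ancestry calls, and want the downstream statistics to be reproducible
and tested.

## What it computes

* **Age acceleration**: for a clock with intercept $\beta_0$ and weights
  $w$, the score $s = \beta_0 + \sum_j w_j b_j$ (optionally through the
  piecewise log-linear age anti-transform), age-adjusted as the OLS residual
  of the estimate on chronological age. EEAA/IEAA variants include or purge
  blood-cell composition.
* **Inter-population tests**: Shapiro–Wilk-gated Welch-t / Wilcoxon per
  estimator, Benjamini–Hochberg q-values (flag at $q<0.1$), Spearman-based
  independence clustering, per-group medians.
* **Genotype QC**: missingness (`mind`/`geno` 0.05), exact Hardy–Weinberg
  test ($p < 7\times10^{-8}$ filter), method-of-moments IBD
  $\hat\pi = P(\mathrm{IBD}{=}2) + P(\mathrm{IBD}{=}1)/2$ with pruning at
  $\hat\pi > 0.25$, strand-ambiguous removal, 50/5/0.2 LD pruning.
* **Ancestry deviation scan**: collapse local-ancestry posteriors
  (argmax > 0.9), per-SNP ancestry frequency $f$, the standardised deviation
  $Z = (f-\mu)/\sigma$ with genome-wide $\mu,\sigma$, two-sided normal
  p-values, regions as same-sign runs of $|Z|>3$; GWAS-catalog discovery
  ($p<0.01$ inside regions) and in-cohort replication by OLS on the
  enriched-allele dosage.
* **Variance attribution**: exact LMG (Lindeman–Merenda–Gold) decomposition
  of linear-model $R^2$ — each predictor's sequential $R^2$ gain averaged
  over all orderings — for the joint and per-population model frames; and
  kinship/inbreeding association via the pairwise delta statistic with a
  label-permutation p-value.
* **Synthetic data**: a first-class generator for the whole study design
  (24+24 cohort, calibrated clock-median shifts, Balding–Nichols panels,
  Markov ancestry tracts with one planted enriched region, mock GWAS
  catalog, planted relatedness), so every stage runs and is tested offline.

## Worked example

```r
library(admixclock)

spec   <- cohort_spec()                      # the 24+24 study design
cohort <- gen_cohort(spec, seed = 1)
clocks <- gen_default_clocks(seed = 2)
betas  <- gen_betas(cohort, clocks, spec, noise_sd = 0.01, seed = 3)
est    <- compute_all(betas, clocks, cohort)

median_discrepancy(est, cohort$population,
                   c("EEAA", "AgeAccelHannum", "AgeAccelPheno", "AgeAccelGrim"))
#>         EEAA AgeAccelHannum AgeAccelPheno AgeAccelGrim
#> groupA  1.25           0.87          1.18         0.50
#> groupB -2.52          -1.76         -2.61        -1.16
```

The indigenous-role group (`groupA`) is epigenetically older on all four
clocks and the admixed-role group younger — the generator's calibration
profile plants exactly those group medians, and the full
betas→clock→residual pipeline recovers them. The gated tests flag all four
planted clocks and leave the unshifted surrogate alone:

```r
compare_all(est, cohort$population)[, c("estimator", "test_used",
                                        "nominal_p", "bh_q", "significant")]
#>        estimator test_used nominal_p    bh_q significant
#> 1           EEAA  wilcoxon   0.00309 0.00386        TRUE
#> 2 AgeAccelHannum  wilcoxon   0.00270 0.00386        TRUE
#> 3  AgeAccelPheno  wilcoxon   0.00309 0.00386        TRUE
#> 4   AgeAccelGrim  wilcoxon   0.00309 0.00386        TRUE
#> 5      DNAmTIMP1         t   0.83189 0.83189       FALSE
```

Which factors carry that variance? The joint LMG model attributes it to
population membership:

```r
lmg(est$AgeAccelHannum,
    cbind(Pop     = as.numeric(cohort$population == "groupA"),
          Female  = as.numeric(cohort$sex == "F"),
          T.cruzi = as.numeric(cohort$infected)))
#> lmg_result: R2 = 0.1836, top = Pop (17.6% of total variance)
#>               Pop Female T.cruzi
#> raw        0.1756 0.0006  0.0073
#> normalised 0.9567 0.0035  0.0398
```

`run_pipeline(pipeline_config(seed = 1, out_dir = "out"))` runs every stage
(QC, scan, discovery/replication, kinship, importance) over a synthetic
genome with a planted ancestry-enriched region and writes per-stage TSV/JSON
reports; identical configs reproduce the reports byte-for-byte.

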