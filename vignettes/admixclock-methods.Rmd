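---
title: "Methods: epigenetic-age differences between co-located populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epigenetic-age differences between co-located populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixclock)
```

## The analysis this package implements

`admixclock` re-implements, as a tested and reusable pipeline, a
population-epigenetics analysis comparing DNA-methylation-based aging
estimators between two populations living in the same area but carrying very
different genomic histories: an indigenous group (role "groupA" throughout)
and an admixed group descended from indigenous/European intermarriage
("groupB"). The pipeline has five analysis stages plus a synthetic-data
module that emulates the study design so every stage is testable without any
external download:

1. **Clock engine** — DNAm age and surrogate estimators from beta matrices,
   age-adjusted into acceleration residuals.
2. **Inter-population testing** — normality-gated t/Wilcoxon tests with
   Benjamini–Hochberg FDR control and Spearman-based independence grouping.
3. **Genotype QC** — missingness, exact Hardy–Weinberg, IBD relatedness,
   strand-ambiguous removal, LD pruning.
4. **Ancestry deviation scan** — local-ancestry collapse, the standardised
   deviation Z-scan, region calling, GWAS-catalog discovery and in-cohort
   replication.
5. **Variance attribution** — exact LMG decomposition of linear-model
   R², plus kinship/inbreeding association via the pairwise delta statistic.

## Clocks and age acceleration

Every estimator handled by the engine is linear in CpG beta values
(methylation fractions in $[0,1]$): a score
$s = \beta_0 + \sum_j w_j b_j$, optionally followed by the piecewise
log-linear age anti-transform used by calculator-style clocks,

$$\mathrm{age}(s) = \begin{cases}
(1+A)\,e^{s}-1 & s \le 0\\
(1+A)\,s + A & s > 0
\end{cases}$$

with adult-age breakpoint $A = 20$ years (continuous, strictly monotone, the
exact inverse of the forward transform). **Age acceleration** is the residual
of the OLS regression of the estimate on chronological age: positive values
mean "epigenetically older than expected". Residual columns have mean zero
and are orthogonal to age by construction — an invariant the tests check to
$10^{-10}$. IEAA additionally residualises on blood-cell fractions (one
simplex column dropped); EEAA takes a standardised weighted average of a
Hannum-type estimate and three age-associated cell measures before
age-adjusting. The EEAA component weights are not prescribed anywhere we
could verify, so equal weights after z-scoring are the default and the
weights are an explicit argument.

Missing clock CpGs are imputed with the cohort mean beta for that CpG
(fallback 0.5 when a CpG is absent everywhere); per-sample clock coverage
below 50% is an error rather than a silent extrapolation.

## Tunable thresholds

| Parameter | Default | Units | Where |
|---|---|---|---|
| `shapiro_alpha` | 0.05 | p | normality gate (t vs Wilcoxon, Pearson vs Kendall) |
| `fdr_q` | 0.1 | q | BH flags in the group comparison |
| `z_threshold` | 3 | SD | ancestry scan region calling |
| `min_snps` | 2 | SNPs | minimum run length for a region |
| `posterior_min` | 0.9 | posterior | local-ancestry collapse (strict `>`) |
| `replication_alpha` | 0.01 | p | catalog discovery and in-cohort replication |
| `mind`, `geno` | 0.05 | fraction | sample/SNP missingness (strict `>` removes) |
| HWE threshold | 7e-08 | p | exact-test filter, applied as printed |
| `pihat_max` | 0.25 | PiHat | relatedness pruning |
| LD pruning | 50 / 5 / 0.2 | SNPs / SNPs / r² | window, step, threshold |

The Shapiro–Wilk alpha is our choice (the analysis convention leaves it
unstated); both the t and Wilcoxon p-values are always reported so the gate
is transparent. The Welch (unequal-variance) t-test is used; the rank-sum
test uses exact enumeration when both groups have $n \le 10$ and the
tie-corrected normal approximation otherwise.

## The ancestry deviation scan

Posterior tables collapse to hard calls by argmax when the posterior
strictly exceeds 0.9, otherwise `UNK`. The per-SNP ancestry frequency
$f$ counts assigned haplotypes only (`UNK` excluded from the denominator;
a switch includes them). The scan statistic is

$$Z = \frac{f - \mu}{\sigma},$$

with $\mu$ and $\sigma$ the genome-wide mean and **sample** standard
deviation ($n-1$) of $f$ over unmasked SNPs — the SD convention is ours, as
only the genome-wide averaging is prescribed. Two-sided p-values come from
the normal reference, $p = 2(1-\Phi(|Z|))$; at the printed anchor
$Z = 3.88$ this gives $1.045\times10^{-4}$, matching the reported
$1.05\times10^{-4}$ to rounding. Regions are maximal runs of $\ge 2$
consecutive SNPs with $|Z|$ above threshold *and the same sign* (a run of
over-representation is not allowed to absorb an adjacent run of
under-representation). Region bounds are 1-based inclusive SNP positions;
the BED exporter converts to 0-based half-open.

Discovery intersects an external GWAS catalog with the called regions
(inclusive bounds, catalog $p < 0.01$); replication re-tests each candidate
by per-SNP OLS of the estimator on the dosage oriented to count the
ancestry-enriched allele, without covariates by default (covariates are an
argument). Allele-set mismatches are dropped, never strand-flipped —
ambiguous A/T and C/G SNPs are already removed upstream.

## LMG variance decomposition

For predictors $1..p$ the LMG share of predictor $k$ is the average over
all $p!$ orderings of its sequential $R^2$ gain, computed here by exact
subset enumeration:

$$\mathrm{LMG}_k = \sum_{S \subseteq \{1..p\}\setminus\{k\}}
\frac{|S|!\,(p-|S|-1)!}{p!}\left[R^2(S\cup\{k\}) - R^2(S)\right].$$

Shares sum to the full-model $R^2$ exactly; the enumeration is capped at
$p \le 15$ (all three model configurations here have $p \le 4$, so $2^p$
OLS fits are trivial). Plain centred $R^2$ is used, matching the statistic's
conventional definition. Numerically negative shares beyond $-10^{-12}$
raise an error; tiny negatives are floored at zero before normalisation.
The three model frames use the stated encodings: joint (`Pop`, `Female`,
`T.cruzi`), indigenous-role only (`Inbreed`, `Paraje`, `Female`,
`T.cruzi`), admixed-role only (`EUR`, `AMR`, `Female`, `T.cruzi`); because
`EUR + AMR` approaches a simplex the admixed frame reports its condition
number. Both raw and normalised shares are emitted, and the "% of total
variance" of the top predictor is its normalised share times the model
$R^2$ (equivalently its raw share).

## Kinship delta

The pairwise delta statistic is the absolute difference of two individuals'
estimator values; under kinship structuring, related pairs should show
smaller deltas. The naive pair-level correlation treats
$\binom{n}{2}$ pairs as independent, which they are not (every individual
appears in $n-1$ pairs). We therefore also report a label-permutation
p-value — permute individuals, recompute all deltas, re-correlate — and
document it as the recommended inference. Whether pairs should span both
populations is not prescribed; the pipeline uses within-group pairs for
this stage.

## What the synthetic-data generator emulates

The generator's defaults are the study design itself: 24 individuals per
group, 12 of each sex, half infected balanced by sex, ages
$\mathcal N(39.2, 12.9^2)$ and $\mathcal N(41.1, 14^2)$ truncated at 18
years (adult cohort; the truncation also keeps the age transform in its
linear branch), 20/24 rural in the indigenous-role group versus 0/24 in
the admixed-role group, and a 0.55 global indigenous-ancestry fraction in
the admixed genome.

**Planted acceleration shifts.** The calibration profile plants the four
reported group medians for the EEAA-, Hannum-, Pheno- and Grim-type clocks:
(1.26, 0.87, 1.19, 0.42) years in the indigenous role and (−2.55, −1.67,
−2.62, −1.16) in the admixed role. Because age adjustment projects the
estimate onto the orthocomplement of $\{1, \mathrm{age}\}$, raw DNAm-age
offsets with those medians would not survive residualisation (the grand
mean, −0.4 years, would be subtracted). The generator therefore constructs
a shift vector that is *exactly orthogonal* to $\{1, \mathrm{age}\}$ while
pinning each group's median: a wide central block of samples sits exactly
at the target (so the noisy sample median averages many near-target values
rather than two order statistics), tail values carry the group mean
offset, and a minimal-norm correction on the tails zeroes the inner
products with 1 and age. At zero noise the downstream residual medians
equal the planted values exactly; at the default noise (0.01 beta units,
giving roughly 0.1–0.3 years of score noise per clock and an acceleration
SD of about 2–3 years) they are recovered well within ±0.3 years.

**Betas.** Each clock is generated invertible: coefficients are drawn
symmetrically and rescaled so that betas in $[0,1]$ represent target ages
10–100 after the transform, and the generator distributes the required
linear-predictor value across the clock's CpGs around 0.5. This makes
clock-engine correctness testable to numerical precision at zero noise.
Background CpGs are Beta(2, 2).

**Admixed genome.** Ancestral allele-frequency panels follow the
Balding–Nichols model at a configurable $F_{ST}$ (no generative model is
prescribed; any controllable-divergence model serves). Per-haplotype
ancestry tracts follow a two-state Markov switch process parameterised per
morgan on a uniform 1 cM/Mb map (default 12 switches/morgan,
1 Mb SNP spacing), matching the window-scale granularity of local-ancestry
callers without implementing phasing. Inside the planted region the AMR
assignment probability is raised by `excess`, and the chain state is
re-equilibrated at the region boundary so the within-region marginal equals
the boosted stationary frequency exactly — without this, tract persistence
would let the genome-wide background leak several SNPs into the region and
make planted-region recovery depend on tract length rather than on the
planted excess. `tract_rate = Inf` gives a tract-free genome (independent
per-SNP draws), which is what the null-calibration tests use: with tracts,
serial correlation between neighbouring SNPs inflates the variance of the
$|Z|>3$ exceedance fraction far beyond the binomial error band that the
calibration check applies, so the binomial band is only valid in the
independent-sites limit. The generator does **not** emulate LD *within*
ancestral panels, chip-specific artifacts, or sequence-level processes —
so passing tests say nothing about those aspects of real data.

**Catalog.** The mock GWAS catalog covers the planted regions; the causal
SNP's enriched allele carries the specified effect (0.29 estimator units
per allele by default, the magnitude convention of the replicated locus),
neighbours decay exponentially with distance, and reported effects add
$\mathcal N(0, se)$ estimation noise so a null catalog passes $p<0.01$ at
the nominal rate. p-values follow the two-sided normal Wald formula.

## Numerical choices and degenerate inputs

- Exact HWE p-values sum the conditional probabilities of heterozygote
  counts no more likely than the observed one (with a $1+10^{-10}$
  relative guard against floating-point ties); monomorphic SNPs return 1.
- PiHat uses the method-of-moments IBD estimator from IBS counts and
  panel frequencies, clipped to the probability simplex; SNPs with
  frequency 0 or 1 (or missing in a pair) are excluded per pair.
- Relatedness pruning removes, per offending pair in decreasing PiHat
  order, the member with higher missingness; ties break to the
  lexicographically later id (which member the original analysis removed
  is unstated, so the rule is ours and deterministic).
- Constant vectors gate as non-normal; constant predictors, constant ages
  and zero ancestry variance are errors, not NaNs.
- All generator randomness flows through a single integer seed with
  deterministic per-stage derivation; identical configs give byte-identical
  reports (wall-clock timings are confined to the log file).

## Problem sizes used by the test-suite and reproduction script

The shipped tests and the reproduction script run at desk scale by design:
cohorts of 24+24; genomes of 400–5000 SNPs over 2–20 chromosomes with 96
haplotypes; 100 seeds for planted-region recovery; 1000 null simulations
for the type-I and replication calibrations; 100 random designs ($p\le5$)
for the LMG-versus-enumeration check. The real study's genome-wide results
(hundreds of thousands of SNPs, published clock coefficient sets, the
undeposited cohort) are out of reach of a self-contained artifact; the
published numbers that *are* internally reproducible — the printed design
counts, the Z-to-p anchor, and the planted clock medians — are the ones the
acceptance checks target.

## Known limitations

- The pair-level kinship-delta correlation ignores pair dependence; use the
  permutation p-value.
- The EEAA definition depends on cell-measure inputs and weights that are
  external to this package; results are only comparable across runs using
  the same convention.
- The LD pruner is greedy and window-local, like the tool it mirrors; it
  does not find a maximum independent set.
- Replication at $n = 24$ has limited power; direction consistency is
  reported separately from significance for exactly this reason.
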