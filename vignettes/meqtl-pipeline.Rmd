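---
title: "Multi-cohort meQTL mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-cohort meQTL mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the models, the parameters that matter, what the synthetic
data generator does and does not emulate, and where open design choices
were settled.

## The discovery model

Methylation at a CpG is measured as a beta-value in [0, 1], the fraction
of methylated signal. Beta-values are heteroscedastic and bounded, so
before association testing each CpG is mapped to normal quantiles by a
rank-based inverse normal transformation (INT),
$y_i = \Phi^{-1}\!\big((r_i - c)/(n - 2c + 1)\big)$, and residualised on
covariates. The INT offset is not canonical; we use the Blom constant
$c = 3/8$ with average ranks for ties, which keeps the transform a
monotone function of ranks and the output mean zero.

The covariates are sex, age, smoking status, blood cell proportions
(supplied as inputs, not estimated here), and the technical factors plate
and chip position. The original analysis fitted a linear mixed model with
the technical factors (and family/zygosity for the twin cohort) as random
intercepts. Our default instead residualises grouping factors as one-hot
categorical fixed effects: this is deterministic, exact, and cheap at
genome scale, and for factors with many well-filled levels the two differ
only by shrinkage of level means. A single-factor random-intercept mode
(method-of-moments variance components, BLUP shrinkage) is available via
`grouping_mode = "random"`; the fixed-effect default is a documented
deviation, not an equivalence claim. A grouping level of size one receives
no shrinkage benefit under the fixed default — its residual is simply
centred within the level.

Each cohort then fits, for every SNP–CpG pair, a simple linear regression
of the residualised methylation on allele dosage, with two-sided t
p-values at $n-2$ degrees of freedom ($n-4$ with the cell-proportion
interaction term). The reference distribution for the per-cohort p is not
dictated by the source analysis; t is the conservative choice at these
sample sizes. Sporadically missing dosages are mean-imputed per SNP
inside the scan only; the stored matrices are never modified. Pairs
within 1 Mbp on the same chromosome (inclusive) are cis, everything else
trans. Candidate retention uses the deliberately liberal thresholds
$P \le 5\times10^{-3}$ (cis) and $P \le 5\times10^{-6}$ (trans): the real
multiplicity control happens after pooling.

## Meta-analysis and permutation FDR

Cohort effects are heterogeneous (different ages, platforms, batch
structures), so candidates are pooled with the DerSimonian–Laird
random-effects estimator — the moment estimator of the between-cohort
variance $\tau^2$, with a normal reference for the pooled p-value. With a
single contributing cohort the pooled record equals the input and
$\tau^2 = 0$.

Significance is calibrated by permutation: each cohort's methylation
sample labels are shuffled — whole families moved between same-size
family slots so twins are never separated, degenerating to a full shuffle
when everyone is a singleton — and the *identical* pipeline (candidate
thresholds, meta-analysis, two-or-more-cohorts same-direction filter) is
re-run B = 20 times. The estimated FDR at threshold $t$ is the mean
number of null pairs at or below $t$ divided by the observed count, and
the selected threshold is the largest grid point with estimated
FDR $\le$ 0.05, evaluated separately for cis and trans. Including the
consistency filter inside the permutation pipeline keeps the null and
observed distributions exchangeable. When no grid point qualifies the
threshold is undefined and flagged rather than silently set to zero.

## Clumping and connectivity

Reported meQTL SNPs are highly redundant through LD. Clumping is greedy:
SNPs are ranked by their number of associated CpGs (ties by best
association p, then position — the tie-break is our addition and is
documented as such), the top unclumped SNP becomes a region
representative, and unclumped SNPs on the same chromosome within
±2 Mbp and $r^2 > 0.1$ (dosage correlation over the pooled samples) are
absorbed. Cis and trans sets are clumped separately, and clumping never
crosses chromosomes. Per-CpG effective counts are distinct clumped
regions; outliers on either side (highly regulated CpGs, key regulatory
regions) are counts strictly above $Q_3 + 3\,\mathrm{IQR}$, with
quartiles computed by linear interpolation (R's type-7 convention — the
flags depend on this, hence it is fixed and stated).

## Enrichment

Annotation tracks are consumed as BED (0-based half-open); points are
1-based, so a position $p$ is inside $[s, e)$ iff $s \le p-1 < e$ —
conversion happens only at that boundary. The 2×2 enrichment test is an
exact Fisher test made two-tailed by point-probability ordering (the sum
of hypergeometric probabilities not exceeding the observed table's), with
the odds ratio under a Haldane–Anscombe +0.5 correction when any cell is
zero and a Woolf logit confidence interval. For SNP enrichments where MAF
and distance-to-CpG are confounders, a matched resampled background is
drawn B = 1000 times — without replacement within each MAF × distance
category, with replacement across categories — and the point estimate and
CI are the mean and 2.5%/97.5% percentiles of the OR distribution. The
default bins are MAF width 0.05 over (0, 0.5] and log-decade distance
bins {0–1k, 1k–10k, 10k–100k, 100k–1M, >1M bp}; bin edges are free
parameters, not estimates. TAD co-membership asks whether both members of
a pair fall inside one common domain interval; cross-chromosome pairs
count as not-same-TAD, and only genuinely overlapping TAD intervals are
merged (adjacent domains stay distinct).

## Twin ACE model

For the twin cohort, the variance of each (residualised, standardised)
CpG is decomposed as $\sigma^2 = a^2 + c^2 + e^2$ with MZ covariance
$a^2 + c^2$ and DZ covariance $a^2/2 + c^2$, by maximising the
bivariate-normal pair likelihood under non-negativity bounds with a
common mean (twins exchangeable within a pair). Two starts are used — the
Falconer plug-in $A = 2(r_{MZ} - r_{DZ})$ and equal thirds — and a fit
failing both is reported as non-converged with missing shares, mirroring
the "critical optimisation failure" exclusion. Shares are
scale-invariant, so inputs are standardised first; the likelihood at the
optimum is verified in tests to dominate the Falconer point. Estimation
error at the study's own 88 MZ + 70 DZ pairs is substantial (mean
absolute share error up to ~0.15 in our recovery grid), which is why the
zero-inflation summary (share of CpGs with $A < 0.01$) and stratified
means are reported rather than per-CpG confidence claims.

## SMR and HEIDI

Co-localisation between meQTLs and eQTL/GWAS signals uses the
summary-based Mendelian randomisation ratio: with the exposure's most
significant SNP as instrument, $b_{xy} = b_{zy}/b_{zx}$ with the
first-order delta variance, $T = b_{xy}^2/\mathrm{var} \sim \chi^2_1$.
The HEIDI test then asks whether alternative SNPs in intermediate LD with
the instrument give the same ratio: differences $d_i$ are standardised
using the delta-method covariance with
$\mathrm{cov}(b_i, b_j) = r_{ij}\,\mathrm{se}_i\,\mathrm{se}_j$, and
$\sum z_i^2$ is referred to a Satterthwaite-matched scaled chi-square on
the eigenvalues of the correlation matrix of the $d_i$. Alternative
instruments are SNPs with exposure $p \le 1.57\times10^{-3}$ and
$0.05 < r^2 < 0.9$ with the instrument, capped at twenty — the p
threshold and LD window follow the reference SMR tool's documented
defaults, since only the cap is stated in the source analysis; all three
are arguments. Strand-ambiguous (A/T, C/G) variants are dropped during
harmonisation, as are variants whose aligned allele frequencies disagree
by more than 0.2.

Design-specific multiplicity: the three eQTL designs use Bonferroni over
their tested pairs; the GWAS design divides by (number of CpGs × seven
phenotype classes); the targeted-trans design tests only SNP–CpG pairs
more than 5 Mbp apart to exclude long-range LD. Co-localisation requires
both $P_{SMR}$ below the design cutoff and $P_{HEIDI} > 0.05$.

## The synthetic-data generator

The generator emulates the study design, not array chemistry. Haplotypes
follow a latent-Gaussian AR(1) threshold scheme: within an LD block,
consecutive latent values have correlation `ld_rho` and an allele is
carried when the latent value falls below the MAF quantile. This model
was chosen because its pairwise dosage correlation has a cheap
Monte-Carlo oracle, which the tests exploit. MZ twins duplicate both
haplotypes; DZ twins re-draw each parental transmission with probability
1/2. Defaults mirror the five-cohort design: sample sizes
394/348/197/83/236 with 88 MZ + 70 DZ pairs inside the first cohort,
smoking prevalence 21.5%, CD4⁺ T-cell proportions ~N(0.199, 0.073²) and
monocytes ~N(0.05, 0.026²) truncated to plausible ranges, plates of 48
samples.

Methylation is built on a latent scale: planted genetic effects plus a
unit-variance ACE component (polygenic term with cross-twin correlation
1/0.5, family-shared term, independent noise, shares set by
`ace_params`) plus covariate and batch effects, pushed through a logistic
link with a per-CpG offset so beta-values stay strictly inside (0, 1).
Planted "true betas" are therefore defined pre-link; after INT and
residualisation the recovered slope is attenuated, so recovery tests are
rank-based and power-based rather than exact. Effect-size distributions
of real meQTLs are unknown; `effect_size_sd` (or the per-effect
`effect_r2` parameterisation, which sizes $\beta$ so the planted latent
variance share is fixed) are free parameters. The generator does not
emulate probe chemistry, detection p-values, population stratification,
or imputation uncertainty beyond an optional dosage-noise flag — passing
tests say nothing about robustness to those.

For summary statistics, a pleiotropy scenario gives every SNP the
marginal effect $r_{j,c}\,\beta_c$ in both studies (one shared causal
variant), while a linkage scenario drives exposure and outcome from two
different causal SNPs in LD; estimation noise is multivariate normal with
covariance $R/n$, independent between studies. Default sample sizes are
2358 (exposure, the pooled meQTL study) and 31,684 (outcome, the blood
eQTL consortium scale).

## Numerical choices and degenerate inputs

* Exact Hardy–Weinberg p-values use conditional enumeration over
  heterozygote counts with a $1 + 10^{-7}$ relative slack when comparing
  point probabilities, the standard guard against ties lost to floating
  point. Dosages are hard-called by rounding for this test only.
* QC order is samples first, then SNP statistics recomputed — the source
  is silent on the order, so it is fixed and documented. All thresholds
  are strict in the stated direction (MAF < 0.01 excluded, missingness
  > 3%/5% excluded).
* Scans stream CpG blocks (`block_size`) to bound memory; output is
  independent of the block size, and this is tested.
* `permutation_fdr` evaluates the ratio on the grid of observed
  p-values; duplicating null sets leaves the curve unchanged.
* HEIDI repairs a non-positive-definite correlation by an eigenvalue
  shift, logged; ratios with a zero outcome effect fall back to the
  delta-method limit variance.
* The pipeline seed fans out deterministically to per-stage child seeds,
  so every randomised stage is reproducible from the one integer and
  reruns are byte-identical (verified on the output manifests).

## Problem sizes used in validation

The bundled validation uses a deliberately desk-scale study: five cohorts
of 150 samples, 300 SNPs in LD blocks of 10 at $\rho = 0.8$, 400 CpGs, 60
planted cis effects at latent $R^2 \approx 0.15$, B = 20 permutations,
ten seeds. At that scale the full two-stage pipeline reports ~120–145 cis
pairs per seed with a realised false-discovery proportion averaging ~3%,
inside the 5% target. ACE recovery runs on 13 (A, C) grid points at
1000+1000 and 88+70 pairs; HEIDI calibration uses 500 replicates per
scenario. These sizes were chosen so the whole suite exercises every
stage in minutes while keeping Monte-Carlo error well below the
tolerances being asserted.

## Known limitations

* The fixed-effect residualisation default is not a mixed model; with
  few, small, or highly unbalanced technical batches the residuals
  differ from BLUP-based ones.
* DerSimonian–Laird τ² is noisy at k ≤ 5 cohorts; no Knapp–Hartung
  adjustment is applied (the reference meta-analysis tool does not
  either).
* HEIDI inherits the known mild anti-conservativeness of
  delta-method-based heterogeneity tests near the null; its rejection
  rate at α = 0.05 sits around 0.07–0.09 under our pleiotropy generator.
* The permutation null preserves genotype LD but destroys
  methylation–covariate structure jointly shuffled with the labels; FDR
  control is demonstrated for the synthetic generator's confounding
  structure, not proven for arbitrary real-data confounding.
* No conditional (multi-SNP) models, no ADE or sex-limitation twin
  models, no reference-panel LD.
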