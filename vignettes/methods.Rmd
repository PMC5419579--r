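---
title: "Methods: summary-statistics association, imputation and fine-mapping in transgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-statistics association, imputation and fine-mapping in transgwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transgwas)
```

# Scope

`transgwas` implements the summary-statistics half of a large
genome-wide association study of quantitative traits in cohorts of more
than one ancestry: every stage that operates on per-variant effect sizes,
standard errors, z-scores and reference-panel LD rather than on raw
genotypes. The package also ships a synthetic two-ancestry data generator
whose role is to give every downstream stage inputs with the statistical
structure it assumes, at desk scale, so that each method can be validated
against an independent oracle (closed forms, enumeration, or
individual-level regression on the same simulated data).

# Trait preparation and variant quality control

Quantitative traits are prepared in the conventional way: the raw trait is
regressed on its covariates (age, age squared, principal components, and
for fat-distribution traits the body-mass index), separately by sex and
case-control stratum, and the residuals are mapped to an exact standard
normal with the rank-based inverse-normal transform. We use the Blom
offset, `qnorm((rank - 3/8) / (n + 1/4))`, with average ranks for ties;
the transform is invariant to any strictly monotone rescaling of the
input, which the test suite asserts directly.

Variant-level filters follow the standard battery for imputed array data:
call rate below 0.95, minor allele count of 6 or fewer, Hardy-Weinberg
exact p below 1e-4, imputation info below 0.3 (minimac-style dosage data)
or 0.4 (IMPUTE-style), and an absolute difference above 0.3 between the
observed effect-allele frequency and the admixture-expected frequency
`0.8 * f_AFR + 0.2 * f_EUR`, the conventional African-American admixture
weighting. The Hardy-Weinberg test is the exact conditional test: all
heterozygote counts compatible with the observed allele counts are
enumerated and the probabilities of tables no more likely than the
observed one are summed. A verdict lists every violated filter, not just
the first, so exclusion logs are complete.

Genomic control estimates the inflation factor as the median association
chi-square divided by 0.4549 (the 1-df chi-square median). Correction
divides the statistics by `max(lambda, 1)`: a deflated scan
(`lambda < 1`) is reported but never inflated, which matches standard
practice. In the pipeline, correction is applied to each study before
meta-analysis and to the combined result afterwards.

# Meta-analysis

Two fixed-effect combinations are provided. The inverse-variance method
weights per-study effects by `1/se^2` and is used whenever betas and
standard errors exist. The sample-size method combines signed z-scores
with weights `sqrt(N)` and is the cross-ancestry scale: the LD-imputed
z-score stream (below) has no betas, so combined-ancestry statistics are
z-based throughout. Two-sided p-values come from the normal; at GWAS
sample sizes the normal/t distinction is far below reporting precision.
Heterogeneity is summarized by Cochran's Q and `I^2 = max(0, (Q-df)/Q)`
on the 0-100 scale; male-female effect differences use the same Q test at
nominal `p < 0.05`. Study inputs with `|beta| >= 10` or `se >= 10`
(artifacts of tiny strata or minor-allele counts) are dropped before
combination, and combined records supported by less than 50% of the
trait's total sample size are dropped after.

# LD-based z-score imputation

Unobserved variants are imputed from observed z-scores and
reference-panel LD. With `Sigma` the haplotype correlation matrix of a
window, the imputed z-score of variant i is the best linear predictor

    z_hat_i = Sigma_{i,obs} (Sigma_{obs,obs} + eps I)^{-1} z_obs

with predicted accuracy
`r2pred_i = Sigma_{i,obs} (Sigma_{obs,obs} + eps I)^{-1} Sigma_{obs,i}`.
We compute `Sigma` as a correlation (not covariance) matrix so `r2pred`
lands in `[0, 1]`, and default the ridge to `eps = 0.1`, the
stabilisation regime published for this estimator family; it also bounds
the amplification of any imputed z-score. Sample sizes are carried over
by the LD weights, `N_i = sum_t |w_{i,t}| N_t / sum_t |w_{i,t}|` with
`w_{i,t}` the LD covariance element between unobserved variant i and
observed variant t. Windows tile the chromosome in non-overlapping 1 Mb
cores with 250 kb buffers on each side; each unobserved variant is
reported from the window whose core contains it. Results below
`r2pred = 0.6` (inclusive threshold: 0.6 itself is kept) are discarded.
Before imputation, records are harmonized against the panel: palindromic
(A/T, C/G) variants are removed regardless of frequency — allele labels
alone cannot resolve their strand — as are allele mismatches; swapped
orientations are sign-flipped.

Calibration is checked empirically: on synthetic cohorts, masked variants
are imputed and the squared correlation between imputed and true z-scores
is compared, bin by bin, against the bin's mean `r2pred`; agreement is
within ±0.1 in every populated bin (acceptance suite).

# Approximate conditional and joint analysis

Marginal effects are taken to the standardized-genotype scale as
`b* = z / sqrt(N)`, where the joint model over a selected set S is
`b_joint = R_S^{-1} b*_S` with `R` the LD correlation matrix from a
reference cohort, and sampling variances
`sigma2_resid * diag(R_S^{-1}) / N_j`, with the residual variance updated
as `sigma_y^2 - b_joint' R_S b_joint` (floored at 5% of the trait
variance). Dosage-scale effects are recovered via `sqrt(2 f (1-f))`,
using each variant's own sample size, so no phenotype-variance input is
needed. The conditional effect of variant i given S is the standard
partial-regression form

    b_i|S = (b*_i - r_iS R_S^{-1} b*_S) / (1 - r_iS R_S^{-1} r_Si)

with variance `sigma2_resid / (N_i (1 - r_iS R_S^{-1} r_Si))`. A variant
whose LD with the conditioning set makes the denominator vanish
(`< 1e-6`) is reported with a zero conditional effect and p = 1: its
signal is fully absorbed. Stepwise selection repeatedly adds the smallest
conditional p-value while it stays below 5e-8, refusing candidates with
`r^2 > 0.9` to any selected variant (the usual collinearity cap for this
analysis family; the selected set is therefore pairwise `r^2 <= 0.9` by
construction), and finally refits the surviving list jointly. On
simulated regions where the analysis cohort doubles as its own LD
reference, the joint and conditional estimates agree with individual-level
multiple regression within two standard errors essentially always
(acceptance suite, 100 regions).

Cross-ancestry signal overlap follows a surrogate-conditioning recipe:
all region variants with `r^2 > 0.8` to an established external-ancestry
lead (external-panel LD) form the surrogate set; these are pruned to
mutually low-LD representatives in the analysis ancestry (`r^2 < 0.3`) to
avoid collinearity; the analysis lead is conditioned on them. Under the
genome-wide rule the lead is independent only when conditioning moves it
little on both scales: `-log10 p` drop below 3 and effect change below
one standard error. Locus-wide signals, being weaker, use the effect-size
criterion alone.

# Fine-mapping

Candidate regions are defined in genetic-map units: the lead variant plus
0.1 cM on each side, converted to base pairs by piecewise-linear
interpolation of the map (the terminal segment's rate extends beyond the
map ends; bounds are clipped to the mapped extent). The generator's
default map is uniform at 1 cM/Mb, so 0.1 cM corresponds to 100 kb in
tests. Under a single causal variant per region, the posterior
probability that variant j drives the association is

    pp_j = exp(z_j^2 / 2) / sum_t exp(z_t^2 / 2)

computed after subtracting the largest exponent, so arbitrarily large
z-scores are handled without overflow. The 99% credible set ranks
variants by posterior probability — ties broken by smaller position, so
output is deterministic — and adds variants until the cumulative mass
strictly exceeds 0.99; with uniform posteriors over 100 variants the set
is all 100, because 0.99 exactly does not qualify. Sets of at most 20
variants are flagged tractable. Cross-ancestry comparison builds one set
per analysis (each ancestry alone plus the sample-size-weighted combined
z-scores — the combined stream is z-based because the imputed ancestry
has no betas) and reports sizes, spans and lead posteriors side by side;
an analysis with no data in a region is reported missing rather than
failing.

# Transferability and power

Loci are assembled greedily: the most significant unassigned variant
below 5e-8 becomes a lead and masks everything within 500 kb on each
side, making each lead the most significant variant of a 1 Mb region;
greedy-by-p is the standard convention where the assembly order is
otherwise unspecified. A lead more than 500 kb from every established
lead is novel. SNP-level transferability asks whether the same
trait-raising allele (after allele alignment, flipping signs for swapped
records) is nominally significant (`p < 0.05`) in the target ancestry;
counts of consistent or significant variants are tested against chance
with the exact one-sided binomial tail, with the null probability chosen
by the caller (0.5 for direction, the nominal level for significance).
Locus-level transferability searches the lead's 0.1 cM region for the
best target-ancestry p-value and compares it to `0.05 / Meff`, where
`Meff` is the Li-Ji effective number of tests from the eigenvalues of the
region's LD correlation matrix:
`Meff = sum_i [I(lambda_i >= 1) + (lambda_i - floor(lambda_i))]`.

Power calculations use the noncentral chi-square: a variant explaining
fraction q of a standardized trait's variance in N samples gives a 1-df
association chi-square with noncentrality `N q` (we omit the `(1-q)`
correction, negligible at the per-variant q of interest, well below
1e-3), and power at level alpha is the upper-tail probability beyond the
central critical value. The same q converts to an SD-unit effect as
`beta = sqrt(q / (2 maf (1-maf)))`, exactly invertible.

# The synthetic-data generator

The generator is first-class, tested code, not a fixture. Its components:

* **Haplotype panels.** A first-order Markov mosaic: site j copies the
  same haplotype's site j-1 allele with probability `rho`, else draws a
  Bernoulli at that site's target frequency (uniform on
  `[maf_low, maf_high]`, default 0.05-0.5). This produces geometrically
  decaying block LD — the structure the downstream linear algebra
  consumes — at a tiny fraction of a coalescent's cost, and is
  analytically controllable: `rho = 0` gives independent sites, `rho = 1`
  makes every site copy site 1. Note the mosaic smooths *realized*
  marginal frequencies toward their neighbours when `rho` is large;
  the drawn target frequencies are kept on the panel (`target_freq`) and
  are the reference point for frequency contracts.
* **Ancestry drift.** Balding-Nichols: each variant's derived target
  frequency is drawn from `Beta(p(1-F)/F, (1-p)(1-F)/F)`, so
  `Var(p' - p) = F p (1-p)` across variants, and haplotypes are
  regenerated with the mosaic around the drifted frequencies. The default
  `F = 0.15` is in the range typical of continental-scale divergence.
* **Cohorts with imputation noise.** Haplotypes are paired with
  replacement into diploids. Imputation is emulated by replacing the hard
  genotype with the posterior mean of the genotype given a
  Gaussian-corrupted signal under the cohort's own `Binomial(2, f)`
  prior; the noise SD is solved per variant (monotone 1-d root find on a
  quadrature evaluation) so the expected info score — dosage variance
  over `2f(1-f)` — hits the requested target. Posterior-mean dosages lie
  in (0, 2) and satisfy `cov(d, g) = Var(d)`, so single-variant
  regression slopes stay unbiased while their sampling variance inflates
  by `1/info`, exactly the behaviour of posterior-mean dosages from a
  real imputation engine. Empirically the info target is met within
  ±0.02 for common variants. Hard genotypes are masked at a configurable
  missing rate to exercise the call-rate filter.
* **Phenotypes.** `y = sum_c sqrt(q_c) x_c_std + C gamma + e`, residual
  variance set to one minus the genetic and covariate shares, so the
  trait has unit variance and each causal variant explains exactly its
  requested fraction `q`. Defaults for q in the pipeline (0.004) sit at
  the upper end of the per-variant adiposity range scaled to desk-size
  cohorts; the conversion utilities handle the published per-variant
  magnitudes (0.0008-0.0018) directly.
* **Association scans.** Closed-form per-variant simple regression on
  dosage (vectorized), two-sided p from the t distribution, stratum-aware,
  with strata under 10 individuals skipped with a warning.

Two properties of the generator matter when interpreting validation
results. First, drawing cohort haplotypes with replacement from a finite
panel creates cryptic relatedness once the cohort is large relative to
the panel; a cohort of N individuals drawn from H haplotypes with
`2N >> H` shows genuine test-statistic inflation (we measured
`lambda ~ 1.09` at `2N/H = 2`). This is a real phenomenon, not an
artifact — related individuals inflate association statistics — so
calibration checks use cohorts small relative to their panels
(`2N/H <= 0.5`), while the pipeline default deliberately retains mild
inflation so the double genomic-control stage has something to correct.
Second, at a given sample size all variants share one phenotype
realization, which couples their test statistics and widens the spread of
the per-scan inflation estimate beyond the independent-variant theory;
the null-calibration check therefore pools chi-squares from several
independently generated cohorts (8 scans of 10,000 variants at N = 2,000)
before taking the median.

What passing these tests does *not* show about real data: the generator
has no recombination-rate heterogeneity, no selection, no demographic
history, unrelated individuals only, and exact single-ancestry panels —
so validation demonstrates correctness of the estimators under their
stated models, not robustness to model violations in real cohorts.

# Numerical choices and problem sizes

Degenerate inputs are handled explicitly: monomorphic variants get zero
LD rows and unit diagonal; an LD block singular even after the ridge is
an error; posterior computations subtract the maximum exponent; credible
ties break by position; the conditional denominator has a collinearity
floor (1e-6); the joint-model residual variance is floored at 5% of the
trait variance; genomic control never deflates. All coordinates are
1-based and intervals closed on both ends, including the 1 Mb locus and
500 kb novelty arithmetic (a variant exactly 500 kb from a lead belongs
to that lead's locus and is not novel).

The validation suite runs at sizes chosen to keep each property estimate
well inside its tolerance while remaining desk-scale: 1,000 single-causal
regions for credible-set coverage (binomial SE ~0.3% at 99% coverage),
100 regions x 3 estimates for the conditional/joint oracle, four LD
strengths x 1,000 variants for imputation calibration, 80,000 pooled null
variants for the inflation factor (pooled-median SE ~0.013), 2,000 null
draws over 100 LD blocks for the locus-wide error rate, and 500
replicates for empirical power (binomial SE ~1.6%).

One empirical finding from the validation suite is worth stating plainly:
under block-mosaic LD the Li-Ji `Meff` underestimates the effective
number of tests, and the locus-wide Bonferroni test at `0.05 / Meff`
shows a family-wise error rate of about 0.05-0.065 rather than 0.05
across the LD range we simulate. This mild anticonservatism is a known
property of eigenvalue-based effective-test estimators under strong
correlation; consumers of locus-wide verdicts should read borderline
calls accordingly.

# The pipeline

`run_pipeline()` chains every stage on a generated two-ancestry study —
panels, drift, cohorts, phenotypes, per-study scans, QC, per-study
genomic control, inverse-variance meta-analysis, post-meta control,
masking and z-score imputation of the external study, sample-size
combination, locus definition, stepwise selection, credible sets, and
transferability — writing one tab-separated artifact per stage plus an
exclusion log in which every dropped record carries a machine-readable
reason tag. Runs are deterministic given the configuration seed; the
test suite asserts byte-identical outputs across repeated runs. The
configuration (`pipeline_config()`) carries every threshold with the
defaults stated above, round-trips through YAML losslessly, and rejects
unknown keys at startup.
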