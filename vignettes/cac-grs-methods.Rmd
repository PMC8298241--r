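---
title: "Methods: genetic risk, statin exposure and rapid CAC progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic risk, statin exposure and rapid CAC progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

HMG-CoA-reductase inhibitors (HMGRIs, statins) lower LDL cholesterol but
also accelerate coronary artery calcification (CAC) and raise the risk of
incident type-2 diabetes. If the diabetogenic and calcifying effects share a
genetic substrate, people with a high polygenic predisposition to diabetes
might calcify disproportionately fast under statin therapy. `cacgrs`
implements the full analysis chain needed to test that hypothesis in a
longitudinal cohort with two CAC measurements roughly five years apart:

1. genotype input and quality control,
2. a weighted diabetes genetic risk score (GRS),
3. classification of CAC progression as slow / expected / rapid against an
   individual percentile-based prediction, and
4. log-linear relative-risk regression with robust variance for the GRS,
   the drug, and their interaction, with Bonferroni control over the
   SNP-by-drug scan.

Because the motivating cohort data are access-restricted, the package ships
a synthetic-cohort generator that reproduces the cohort's marginal
structure with *known* planted effects, so every stage is testable end to
end without any external data.

```{r setup}
library(cacgrs)
```

# The relative-risk model

For a common binary outcome (rapid progression has ~20% prevalence), odds
ratios from logistic regression overstate relative risks. The package
therefore estimates RRs directly by *modified Poisson* regression: a
log-link Poisson working likelihood applied to the binary outcome,
maximized by iteratively reweighted least squares, with the
heteroscedasticity-robust sandwich covariance

$$\widehat{\mathrm{Var}}(\hat\beta) = A^{-1} B A^{-1}, \qquad
  A = X^\top \mathrm{diag}(\hat\mu) X, \qquad
  B = X^\top \mathrm{diag}\big((y-\hat\mu)^2\big) X,$$

which is consistent even though the Poisson variance is misspecified for a
Bernoulli outcome. Wald 95% intervals use $z = 1.959964$. A true
log-binomial family is available via `family = "log-binomial"` (with
step-halving to keep fitted risks below one); it is not the default because
its boundary behavior is fragile exactly where the modified Poisson is
routine.

The three analysis models are

* model 1: `rapid ~ exposure + age + sexF + log(CAC_b + 1)`
* model 2: `rapid ~ hmgri + age + sexF + log(CAC_b + 1)`
* model 3: model 1 + `hmgri` + `exposure:hmgri`

with the exposure either the standardized GRS or a single SNP dosage, and
sex coded F = 1 (recorded in the design so output is auditable). Outcomes
are complete-case; dropped rows are counted in the design object.

Numerical choices: IRLS convergence requires a relative deviance change
below `1e-10` *and* a maximum absolute score below `1e-8`; divergent steps
are halved up to 25 times; rank-deficient designs are rejected with the
collinear columns named. On a saturated binary-exposure design the
estimator reproduces the closed-form crude RR and its sandwich standard
error $\sqrt{1/a - 1/n_1 + 1/c - 1/n_0}$ to numerical precision, which the
test suite asserts at `1e-9`.

```{r crude}
# crude statin effect from a 2x2 table: 70/229 events among users,
# 548/2928 among non-users
y <- c(rep(1, 70), rep(0, 159), rep(1, 548), rep(0, 2380))
x <- c(rep(1, 229), rep(0, 2928))
rr_glm(y ~ x, data.frame(y, x))
```

# The genetic risk score

The score is the weighted average over the panel's $n = 100$ SNPs,
$\mathrm{GRS}_i = \sum_k b_k x_{ik} / n$, with $x_{ik} \in \{0,1,2\}$ the
risk-allele dosage and $b_k$ the published log relative risk. Missing
genotypes are imputed to their expected dosage $2p_k$ under the sample
risk-allele frequency, and the divisor stays the fixed panel size — the two
choices are mutually consistent: a participant with no genotypes at all
scores exactly the population mean $\sum_k 2 p_k b_k / n$. The PLINK-style
alternative (averaging over observed SNPs only) is available via
`divisor = "observed"`. Scores are standardized to mean 0, unit variance
(SD with the $n-1$ denominator; the parameters can be frozen and re-applied
so stratified analyses standardize consistently), and effects are reported
per SD. Per-SD reporting also makes downstream estimates invariant to any
positive rescaling of the weight vector.

The bundled panel (`dm_snp_panel()`) carries the 100 diabetes-associated
SNPs with their risk/other alleles and risk-allele frequencies as reported
for the emulated cohort. The per-SNP weights are *synthetic* — the source
study does not print them — drawn once from plausible diabetes-GWAS effect
sizes (|N(log 1.08, 0.03)|) and rescaled so the panel-implied population
mean score equals the reported 0.0498. The implied between-person SD
(~0.0031) is smaller than the reported 0.005 because the real panel's few
large effects are unknown; standardization absorbs this completely.

# Genotype QC

Samples are filtered before SNPs (the order changes results and is
documented for that reason): samples with more than 5% missing genotypes
are dropped; then SNPs with minor allele frequency below 1%, missingness
above 5%, or an exact Hardy-Weinberg p-value below $10^{-5}$, each
exclusion carrying exactly one primary reason (`missing`, `maf`, `hwe`).
The HWE test is the two-sided conditional exact test (probabilities of
heterozygote counts no more likely than the observed one, under fixed
allele counts), computed by the stable recurrence from the modal
configuration; the suite verifies it against an independent log-gamma
enumeration oracle on every genotype table with up to 50 individuals.
The asymptotic chi-square test was deliberately not used: candidate panels
routinely contain SNPs with small expected cell counts. Minor-allele
frequency always refers to the rarer allele, whichever that is, with
missing dosages excluded from denominators.

Input dialects are VCF (GT field, read via `vcfR`), PLINK text `.ped/.map`,
and a plain dosage TSV. Dosages always count the panel's risk allele;
unambiguous strand flips are applied and logged, while A/T and C/G SNPs,
whose strand cannot be verified, are flagged and dropped unless
`allow_ambiguous = TRUE`. Imputed-probability data can be converted with
`hard_call()`, which returns the modal genotype only when its posterior
reaches 0.8.

# The CAC progression model

CAC is analyzed as $\ln(\mathrm{CAC}+1)$ throughout. Per sex, each
participant receives a baseline percentile as the midrank of their
transformed score within a sliding 10-year age window centered on their own
age (zeros share the bottom mass through midranks). For each percentile on
a grid (default 0.05–0.95 by 0.05) the empirical window quantile — type 5,
the midrank-consistent definition — of overlapping fixed windows (centers
stepped by 5 years) is regressed linearly on the *mean member age* of the
window; using the nominal center would attenuate slopes because edge
windows are one-sided. Evaluation interpolates between grid lines and
enforces monotonicity across percentiles by a cumulative maximum.

The individual prediction carries the participant forward **along their own
percentile line**: $\hat L = \ln(\mathrm{CAC}_b + 1) +
b(p_i)\,\Delta t$, where $b(p_i)$ is the slope interpolated at the
participant's percentile, and $\widehat{\mathrm{CAC}}_{5y} = e^{\hat L}-1$,
floored at zero. Anchoring at the observed baseline value (rather than
re-reading the level off the fitted surface) means a participant exactly on
a fitted line $L(a) = \alpha + \beta a$ is predicted at
$e^{\alpha + \beta(a + \Delta t)} - 1$, and it removes rank-estimation
noise from the *level* of the prediction — only growth-rate mismatch is
classified. Participants whose percentile remains inside the (linearly
extrapolated) zero-mass boundary at the follow-up age are predicted to stay
at zero. Follow-up ages outside the fitted range trigger an extrapolation
warning, not an error.

Classification compares observed and predicted follow-up CAC with an
acceptance band of half-width `band_frac` (default 0.2) times the
**observed** value, centered at the prediction — the literal reading of the
published rule. Because that sentence is ambiguous,
`band_anchor = "predicted"` provides the ±20%-of-predicted alternative.
Equivalently, with anchor "observed" the classes are separated by the two
thresholds $\mathrm{pred}/(1+f)$ and $\mathrm{pred}/(1-f)$: below the band
is slow, inside expected, above rapid. Differences below $10^{-9}$ Agatston
units count as zero so `exp`/`log` round-trips cannot flip a class.

Extreme transitions (baseline ≤ 10 to follow-up > 50; baseline > 20 to
follow-up ≤ 10; otherwise an annualized geometric change of
$(\mathrm{CAC}_{5y}+1)^{1/\Delta t}/(\mathrm{CAC}_b+1)^{1/\Delta t}-1$
above +30% or below −7%) are flagged for review. The geometric rate was
chosen because it is defined at CAC = 0; a linear annualized rate is the
documented alternative. In the source setting such scans were re-read by a
human; flags here never alter values or classes.

# The synthetic cohort generator

`cohort_config()` defaults are the emulated study's conditions: 3157
participants, age 59.0 ± 7.5 truncated to [45, 75] (rejection sampling),
53.1% women, 7.3% statin users, follow-up 5.1 ± 0.3 years floored at 0.5.
Statin use depends on age through a logistic model (slope 0.08/year, so
users are ~3 years older, matching the cohort's 61.9 vs 58.7) whose
intercept is solved numerically so the marginal rate is exact. Genotypes
are drawn in Hardy-Weinberg proportions at the panel's risk-allele
frequencies, with independent entry-level missingness (default 2%).

Baseline CAC is zero-inflated log-normal. The zero probability is logistic
in age and sex (reference: 0.42 for a woman at the mean age; −0.06
logits/year; −0.9 for men), and the location/scale of the non-zero
component are *calibrated per cohort* by solving the marginal quantile
equations so that the realized age/sex mix reproduces the target median
(7.5) and third quartile (98.8) exactly in expectation. The cross-sectional
age slope of mean log(CAC+1) is 0.22/year with a +0.8 male shift —
consistent with the cohort's own aging: its median moved 7.5 → 27.9 over
5.1 years, i.e. $\ln(28.9/8.5)/5.1 \approx 0.24$ per year of rank-preserving
drift. Scores are rounded to 0.1 Agatston units so no sub-resolution
"phantom" lesions appear.

Follow-up CAC is generated by **rank-preserving growth**: the participant
keeps their latent baseline percentile while the age/sex-specific
distribution advances by $\Delta t \cdot g / s$ effective years (growth
rate $g$ = 0.22/year over age slope $s$; with $g = 0$ follow-up equals
baseline exactly), after which a log-scale perturbation
$(\lambda_{\mathrm{hmgri}} h_i + \lambda_{\mathrm{grs}} z_i +
\lambda_{\mathrm{int}} h_i z_i)\,\Delta t/\bar{\Delta t} +
\varepsilon_i$ is applied. The noise SD (default 0.15) is attenuated by
$\mathrm{CAC}_b/(\mathrm{CAC}_b+1)$: small plaques track tightly and vary
in absolute, not relative, terms. With these defaults the mechanistic
pipeline classifies roughly 7/62/32 percent slow/expected/rapid —
in the neighborhood of the emulated cohort's 12.4/68.0/19.6 but not tuned
to it; the classifier sees model error (linear percentile lines vs the
curved truth near the zero boundary) on top of the noise.

Two outcome modes exist because they serve different purposes. The
*mechanistic* mode above exercises the percentile classifier, but the
mapping from a latent log-scale shift to a relative risk on the classified
binary outcome is nonlinear, so planted `true_log_rr` values come out
amplified there. The *reduced-form* mode draws the binary outcome directly
from the log-linear risk model
$P(\mathrm{rapid}_i) = \pi_0 \exp(\mathbf{d}_i^\top \lambda)$ with $\pi_0$
solved so the marginal prevalence is exactly 19.6% — its relative risks are
known exactly and it is the calibration route for the association module
(type-I error, bias, coverage). Default planted effects are the emulated
study's point estimates: RR 1.64 (statin), 1.01 per GRS SD, 1.08
interaction.

All randomness flows from one integer seed through named substreams (one
per generator), so adding a generator never perturbs the draws of another
and identical configurations give byte-identical persisted runs.

What the generator does *not* emulate: linkage disequilibrium between panel
SNPs (the score treats loci as independent, as the scoring equation does),
imputation dosage uncertainty, multi-batch genotyping chips, scanner
changes between visits, and informative dropout. Passing tests therefore
show the machinery is correct under the stated statistical structure, not
that real CAC trajectories follow it.

# Multiple testing and stratification

The interaction scan fits models 1 and 3 for the GRS and every panel SNP
(entered as expected imputed dosages, consistent with the score), reporting
main-effect and interaction RRs per row. The test family is the
interactions: 100 SNPs + 1 GRS = 101 tests, so the Bonferroni level is
$0.05/101 \approx 0.000495$, displayed as 0.0005 (one significant figure)
but compared exactly. Main-effect rows are flagged against the same
threshold, mirroring the single-family treatment in the emulated analysis.
Per-SNP fit failures are recorded and skipped without aborting the scan.
`stratified_analysis()` refits model 1 inside each stratum level (statin
users / non-users in the shipped pipeline), reporting per-stratum failures
(e.g. no events) without losing the other strata.

# Problem sizes used in validation

The suite validates the estimator's calibration by simulation at the study
scale: 2000 reduced-form null cohorts of n = 3157 for the size of the
interaction Wald test (accepted if the rejection rate lies in
[0.035, 0.065]), and 1000 cohorts with a planted statin RR of 1.64 for bias
(within Monte-Carlo error) and 95% CI coverage (accepted in [0.93, 0.97]).
Exactness checks use an independent double-loop oracle for the score, full
enumeration for the HWE test (all tables to n = 50), a constructed
on-the-lines cohort for the classifier, and `glm` + `sandwich::vcovHC` as
an independent route to the same estimator. The bootstrap comparison of the
sandwich SE uses n = 5000 with 400 resamples.

# Known limitations

* The percentile model uses per-percentile *linear* age trends; near the
  zero-mass boundary the true quantile surface is curved, and incident-CAC
  participants (baseline 0, positive follow-up) are classified against a
  zero prediction, inflating the rapid class relative to a method with
  curved reference percentiles.
* The acceptance band anchored at the observed value is very narrow for
  small CAC scores; this is the literal published rule, and the
  `band_anchor` switch is provided precisely because the wording is
  ambiguous.
* Weights in the bundled panel are synthetic; analyses of real cohorts
  must supply a panel with published weights.
* The modified Poisson estimator can fit risks above 1 for extreme
  covariate combinations; this is inherent to the method and the reason
  the log-binomial alternative exists.
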