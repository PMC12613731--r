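---
title: "Regional normative models and centile scores: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional normative models and centile scores: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regionchart)
```

## The problem

Deciding whether a brain MRI shows atrophy beyond what is normal for a
person's age is hard to do by eye. Normative "brain chart" modelling answers
it quantitatively: a reference model, fitted to healthy scans spanning the
lifespan, describes the full conditional distribution of each regional
measurement given age, sex and (for volumes) head size. A patient's scan is
then expressed as a centile — the percentile their measurement would occupy
among healthy peers with the same covariates, scanned under the same
conditions. `regionchart` implements this for 72 regions: the 34
Desikan-Killiany cortical parcels per hemisphere (mean thickness, mm) plus
bilateral hippocampus and amygdala (volume, mm³).

## The distributional model

Each region is modelled independently with a three-parameter generalized
gamma distribution, chosen because it is positive-valued, contains the gamma
(`nu = 1`) and lognormal (`nu -> 0`) as special cases, and lets location,
scale and skewness each depend on covariates. With
$\theta = 1/(\sigma^2\nu^2)$ and $z = (y/\mu)^\nu$:

$$\log f(y) = \log|\nu| + \theta\log\theta + \theta\nu(\log y - \log\mu)
  - \theta z - \log\Gamma(\theta) - \log y,$$

with the lognormal limit substituted below $|\nu| < 10^{-4}$, where the
exact expression cancels catastrophically ($\theta \sim \nu^{-2}$). The CDF
is the regularized incomplete gamma $P(\theta, \theta z)$ (reflected for
$\nu < 0$), so centiles are cheap and exact. Our parameterization maps onto
the Prentice form (`flexsurv::dgengamma`) via $\mu_P = \log\mu$,
$\sigma_P = \sigma$, $Q = \sigma\nu$, which the test suite uses as an
independent cross-check.

Links are log for $\mu$, log for $\sigma$, identity for $\nu$. Each linear
predictor runs over a fractional-polynomial basis in transformed age
$t = \log(\mathrm{age} + c)$ with $c = 0.75$ years, so the model is defined
from birth and age effects are resolved on a log-like scale where early-life
change is fast. Powers come from $\{-2,-1,-0.5,0,0.5,1,2,3\}$ (power 0
meaning $\log t$), at most three terms for $\mu$, two for $\sigma$, and a
constant (optionally one term) for $\nu$. The $\mu$ predictor always carries
a sex indicator; volume regions additionally carry centred $\log$ eTIV in
$\mu$ only — whether head size should also enter the scale predictor is
genuinely open, and we keep the more parsimonious choice. Region-specific
basis flexibility is handled by BIC selection over candidate power sets
(`select_fp_powers()`), with ties broken toward fewer terms and then
lexicographically, so selection is deterministic.

## Batch structure and fitting

Reference data come from many scanner/software batches. Offsets
$\delta\mu_b, \delta\sigma_b$ on the two log links are estimated per batch as
*penalized* fixed effects — a Laplace-style stand-in for integrated random
effects — by maximizing

$$\sum_i \log f(y_i)\;-\;\sum_b \frac{\delta\mu_b^2}{2\tau_\mu^2}
  \;-\;\sum_b \frac{\delta\sigma_b^2}{2\tau_\sigma^2},$$

with the variances updated by the fixed point
$\tau^2 \leftarrow \mathrm{mean}_b(\delta_b^2)$. Because that update
maximizes the joint objective (which includes $-\tfrac{B}{2}\log\tau^2$) for
fixed offsets, the alternation is coordinate ascent and the monitored
objective never decreases; the unit tests assert this on every fit. The
shape $\nu$ is deliberately batch-free in the reference fit — it is weakly
identified per batch — and acquires a study-level offset only in
out-of-sample calibration. With a single batch the offsets are pinned at
zero. As $\tau^2 \to 0$ offsets vanish; as $\tau^2 \to \infty$ they approach
per-batch maximum-likelihood fits (verified against a batch-dummy
parameterization of the same likelihood).

Optimization is quasi-Newton (BFGS) with analytic gradients on all link
scales, three deterministic starts (method-of-moments, near-lognormal, and a
perturbed start; best objective wins), inner relative tolerance $10^{-10}$
with at most 200 iterations, and at most 30 outer fixed-point steps.
Non-converged regions are flagged and excluded downstream, never silently
used.

## Out-of-sample calibration and scoring

A new study is aligned to the frozen reference by maximizing the likelihood
of its cognitively normal controls over a single offset triple
$(\delta\mu, \delta\sigma, \delta\nu)$ per region, started at zero. The
$\delta\nu$ component carries a ridge penalty (default weight 100) because a
skew shift cannot be resolved from typical control counts; with the default
weight it stays near zero unless the controls strongly demand otherwise.
Calibration warns below 100 controls — the scale of control sample that
prior validation work found necessary for stable offsets — and refuses to
run below 10. Centiles are then $100 \times F(y)$ under the offset-adjusted
parameters, clamped to $[0.01, 99.99]$ so downstream rank-based analyses are
unaffected while 0/100 artifacts cannot occur. Scoring demands that the
subjects' batch label match the calibrated study, which prevents the most
dangerous silent error in this workflow (scoring with another scanner's
calibration).

One identifiability point matters for simulation studies: the reference
fit's intercept absorbs the mean of the reference batch offsets, so a new
study's "true" offset is only defined relative to the fitted reference. The
offset-recovery experiments therefore generate their reference without
batch shifts (`generative_truth(offset_sd_mu = 0, offset_sd_sigma = 0)`), which
makes the injected triple the estimand against the true trajectory.

## The synthetic-data generator

Real reference cohorts of this kind are access-controlled, so the package
ships a generator whose defaults define the study conditions used
throughout the tests:

* **Trajectories.** Per-region coefficients are drawn once, deterministically
  from the truth seed: thickness bases 2.2–3.0 mm peaking in infancy and
  declining ~25–30% by age 100; hippocampal (~3.9–4.4 × 10³ mm³) and
  amygdalar (~1.5–1.9 × 10³ mm³) volumes peaking in adolescence; scale
  (CV) ~6% for thickness and ~11% for volumes, increasing slowly with age;
  shape $\nu \in [0.5, 1.5]$. Volumes carry an eTIV coefficient of 0.6–0.9
  on centred log eTIV; thickness has no eTIV term. eTIV itself is lognormal
  and sex-dependent (male meanlog $\log 1.55 \times 10^6$, female
  $\log 1.35 \times 10^6$, sdlog 0.065).
* **Batches.** Per-batch offsets are Gaussian on the links, SD 0.02 on
  $\log\mu$ (≈2% scanner differences) and 0.10 on $\log\sigma$.
* **Ages** are uniform over the configured range rather than matching any
  real age pyramid (unpublished); this covers the curve support evenly,
  which is what trajectory-recovery tests need.
* **Disease patterns.** Log-location shifts, all ≤ 0, restricted to each
  pattern's signature: the AD-like pattern shifts hippocampus/amygdala by
  −0.30 and the signature cortical regions by −0.10; the bvFTD-like pattern
  is frontal-predominant (−0.15) with medial-temporal involvement; the
  semantic-variant pattern is left-predominant temporal; the non-fluent
  pattern touches only left frontal regions (pars triangularis, precentral,
  caudal middle frontal, pars opercularis). Every case's shifts are scaled
  by a per-subject Gamma(4, 4) severity (mean 1, CV 0.5): without this the
  combined discrimination models saturate at AUC 1.0 and comparisons between
  feature sets become vacuous; with it they operate in a realistic regime.
  Cases are sampled older than controls (default +8 years) so that
  propensity matching has real work to do.
* **Clinical linkage.** MMSE is a binomial(30) thinning of a logistic
  severity whose linear predictor rises with the mean signature-region
  latent centile — a modelling choice for testability, not a claim about
  any cohort; controls land near ceiling (~29–30). Regional tau is lognormal
  with a negative loading (−0.5) on the latent centile in temporal and
  amygdalar regions only, generated for the PET-available subset (default
  90%). The Euler index is lognormal with 5% large outliers to give the MAD
  filter something to remove.

The generative family equals the modelling family, so recovery tests are
well-posed; `family = "lognormal"` provides a deliberately misspecified
generator for robustness checks. What passing tests on these data do *not*
show: robustness to real-world heterogeneity the generator lacks —
non-uniform age pyramids, scanner drift within batch, diagnosis noise,
non-generalized-gamma measurement distributions, or spatial correlation
between regions (regions are generated independently given covariates).

## The analysis stack

The cohort-level statistics mirror standard practice and are each checked
against an independent oracle: midrank Spearman correlations with
Benjamini–Hochberg step-up across exactly the analysed family (72 regions
for cognition; 70 for tau, where the hippocampus is excluded because of
off-target tracer binding in the choroid plexus); greedy nearest-neighbour
1:1 propensity matching on age and sex without replacement, cases processed
in descending propensity order, with chi-squared/Mann–Whitney balance
diagnostics; logistic per-ROI and combined discrimination whose AUC is the
midrank Mann–Whitney statistic (equal to brute-force concordant-pair
counting); paired DeLong AUC comparison from midrank placements
(cross-checked against both `pROC::roc.test` and a subject-resampling
bootstrap); Youden-index cut-points from an exhaustive threshold scan with
ties broken at the lowest threshold and case-positivity defined as *low*
centiles; stratified repeated k-fold cross-validation with out-of-fold
probabilities pooled per repeat (fold totals and per-class counts both
balanced to within one; the alternative of averaging per-fold AUCs is
unstated in common practice, and pooling is the lower-variance choice); and
an Euler-index filter keeping subjects at most two *unscaled* median
absolute deviations above the study median. The MAD is unscaled and the
boundary inclusive: a strict rule degenerates to "keep nobody above the
median" whenever the MAD is zero; `strict = TRUE` restores the strict
reading. In the combined ROI models, left and right structures enter as
separate predictors (14 terms), since hemisphere pooling is not obviously
right and separate terms are strictly more general.

## Numerical and interface choices

* JSON model documents store coefficients at 17 significant digits (exact
  double round-trip) with an md5 checksum over the numeric payload printed
  at 15 significant digits; loading verifies schema version and checksum, so
  truncated or hand-edited documents fail loudly.
* All generators and analyses are seeded; the same configuration reproduces
  byte-identical tables, and the pipeline orchestrator writes a manifest of
  file hashes that reruns must reproduce exactly.
* FreeSurfer-style stats parsing locates columns by `ColHeaders` name, never
  position; unknown rows are ignored with a notice, missing catalog rows are
  errors naming the region, and eTIV comes from the
  `EstimatedTotalIntraCranialVol` measure line.
* Degenerate inputs fail early with named fields: non-positive measurements,
  ages outside [0, 100], MMSE outside 0–30, duplicate subjects, constant
  outcomes in correlation, one-class inputs in discrimination.

## Problem sizes used in verification

The shipped verification suite fits the calibration experiment on 20,000
reference subjects across 4 batches and scores 10,000 held-out subjects
(deciles within ±1.5 points of nominal); runs 100-replicate offset recovery
at 25–200 controls; checks the distribution core against a $10^6$-draw
Monte-Carlo CDF (sup-norm < 0.002) and adaptive quadrature (density integral
within $10^{-6}$); and runs the discrimination, correlation-sign and
pattern-separation experiments on studies of 200–500 subjects over a
21-region model fitted to 6,000 reference subjects. These sizes were chosen
so each experiment's Monte-Carlo error is small against its acceptance
margin while the whole suite stays desk-scale.

## Known limitations

Regions are modelled and generated independently, so multivariate structure
across regions (and hence the true sampling distribution of combined-model
statistics) is not emulated. Longitudinal change is out of scope; the models
are cross-sectional. The $\nu$ offset is effectively fixed at zero under the
default ridge. Fractional-polynomial selection explores a finite candidate
list, not the full FP model space. And the generator's clinical linkages
(MMSE, tau) are minimal mechanisms with the right signs and plausible
magnitudes, not calibrated disease models.
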