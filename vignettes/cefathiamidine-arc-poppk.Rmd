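---
title: "Population PK of cefathiamidine in infants with augmented renal clearance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population PK of cefathiamidine in infants with augmented renal clearance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Cefathiamidine is a renally cleared first-generation cephalosporin widely
prescribed to Chinese pediatric patients. Infants with augmented renal
clearance (ARC, estimated glomerular filtration rate at or above 130
mL/min/1.73 m^2) eliminate such drugs faster than average, so standard
doses risk leaving the free drug concentration below the pathogen's MIC
for too much of the dosing interval. `cefapk` implements the full analysis
chain for this problem: a nonlinear mixed-effects (population) PK model of
sparse infant concentration data, covariate screening, uncertainty and
simulation-based validation, and Monte Carlo dosing simulations against
free-time-above-MIC targets. Because the underlying patient-level data are
not publicly deposited, the package ships a synthetic-trial generator that
reproduces the cohort's covariate distributions and sampling sparsity, and
every stage is exercised against it.

## Structural and statistical model

Drug disposition is one-compartment with zero-order (constant-rate)
infusion input and first-order elimination. All profiles are analytic:
a dose infused at rate $R_0$ for duration $D$ contributes
$(R_0/CL)\,(1-e^{-k_e \min(s,D)})\,e^{-k_e \max(0,s-D)}$ at time $s$ after
its start, with $k_e = CL/V$; multiple doses superpose, and the
steady-state profile over one interval $\tau$ is the geometric-series
limit of that superposition (closed form, no long simulated run-in). The
24-h steady-state exposure identity $AUC_{0\text{-}24} = \text{daily
dose}/CL$ is used as an internal consistency check.

Fixed effects follow an allometric-plus-maturation covariate model on the
cohort medians (10.25 kg, 1.25 years):

$$CL = \theta_{CL}\,(WT/10.25)^{0.75}\,(AGE/1.25)^{\theta_{age}},\qquad
  V = \theta_{V}\,(WT/10.25)^{1}$$

with the weight exponents fixed at the standard allometric values 0.75
(clearance) and 1 (volume). Inter-individual variability is lognormal,
$CL_i = CL\,e^{\eta_i}$ with $\eta \sim N(0, \omega^2)$, diagonal across
CL and V. Residual variability is exponential, represented exactly as
additive Gaussian noise on log concentration:
$\log y = \log f + \varepsilon$, $\varepsilon \sim N(0, \sigma^2)$.
Additive and combined (proportional + additive) residual forms are
available as configuration choices for error-model comparison by OFV.

The estimated parameter set shipped as `arc_infant_model()` is
$\theta_{CL} = 2.20$ L/h, $\theta_V = 3.36$ L, $\theta_{age} = 0.662$,
$\omega_{CL} = 0.256$, $\omega_V = 0.224$ (log-scale SDs, i.e. about
25.6%/22.4% CV), $\sigma = 0.226$. Those percentages are mapped to
log-scale SDs by the small-CV approximation $\omega \approx CV$.

## Estimation

`ofv_foce()` computes $-2\log$ of the marginal likelihood by the
conditional (FOCE-I class) approximation: per subject, the 2-d conditional
mode $\hat\eta$ is found by Gauss-Newton iteration with analytic gradients
of the log-profile (gradient tolerance $10^{-8}$, at most 100 iterations,
step halving), and the Laplacian term is accumulated. Two numerical
choices matter here:

* The Laplacian log-determinant uses the exact Hessian of the joint
  log-density at $\hat\eta$, obtained by central finite differences of
  the analytic gradient (step $10^{-4}$), with the Gauss-Newton matrix as
  the search metric and as the fallback when the exact curvature is not
  positive definite (likelihood ridges in very sparse subjects). The pure
  Gauss-Newton determinant drops a term proportional to
  $r\,\partial^2 \log f/\partial \eta^2$, which is not negligible at this
  model's residual magnitude ($\sigma^2 \approx 0.05$); with the exact
  curvature, the OFV agrees with a 64-node adaptive Gauss-Hermite
  quadrature oracle to within 0.1 across a seeded grid of small instances
  (the remaining gap is non-Gaussianity of the integrand, largest for
  subjects with a single observation).
* With the exponential error model handled on the log scale the residual
  variance does not depend on $\eta$, so the FOCE "interaction" is exact
  rather than approximated; for additive/combined errors the
  $\eta$-dependence of the variance is carried through the conditional
  objective and its derivatives.

The outer problem maximizes over log-transformed typical values and
variances (covariate coefficients stay on their natural scale): a
Nelder-Mead search followed by a BFGS polish at relative tolerance
$10^{-6}$, with per-subject warm starts of $\hat\eta$ across objective
evaluations. Standard errors come from the central finite-difference
Hessian of the OFV (relative step $10^{-4}$), transformed to the natural
scale by the delta method; a non-positive-definite Hessian yields an
absent covariance with a warning rather than a fabricated one.

Empirical-Bayes estimates are the conditional modes at the final
estimates; subjects without quantifiable observations sit at the prior
mode $\hat\eta = 0$. Shrinkage is $100(1 - SD(\hat\eta)/\omega)$ per
random effect and $100(1 - SD(\text{IWRES}))$ for the residual, with
IWRES on the scale of the error model. CWRES linearizes the model to
first order about $\hat\eta$ and whitens the residual vector with the
Cholesky factor of the implied marginal covariance.

Observations below the assay lower limit of quantification (0.03 mg/L)
are flagged and excluded from estimation with a warning — the cohort this
emulates had none — rather than entering a censored-likelihood term.

## Covariate selection

`stepwise_select()` screens candidate covariate-parameter pairs (age,
eGFR, sex on CL and V by default; weight is already in the base model
through fixed allometry) with the standard likelihood-ratio thresholds:
forward addition requires an OFV drop strictly greater than 3.84
(chi-square, 1 df, p < 0.05), backward deletion removes any term whose
deletion raises the OFV by at most 6.635 (1 df, p < 0.01). Continuous
covariates enter as power functions of the covariate normalized by a
reference value; sex as a proportional shift. eGFR enters through the
bedside single-constant Schwartz formula
$eGFR = 0.413 \times \text{height(cm)} / \text{Scr(mg/dL)}$ (umol/L
converted by 88.4); the constant is a parameter so age-banded Schwartz
variants can be substituted. A candidate whose fit fails is skipped with
a warning, never aborting the search.

Power at the study's own scale is limited: with 20 infants and ~36
samples, a true age effect of the estimated size is found in some
realizations and missed in others, which is why the selection-calibration
experiments in the test suite run at 100 subjects (where the true effect
is selected in essentially every replicate and a null effect in roughly
the nominal 5-15%).

## Uncertainty and validation

`run_sir()` implements sampling importance resampling around a fit:
4 iterations with M = 5000, 2000, 2000, 1000 proposal samples and
m = 1000, 1000, 1000, 500 resamples (without replacement, importance
weights $\propto e^{-dOFV/2}/q$), the proposal refit to each resample's
mean and covariance on the transformed parameter scale. dOFV is computed
with the same FOCE objective as estimation. Reported medians and 95% CIs
are percentile summaries of the final resample on the natural scale. The
dOFV-distribution diagnostics follow standard practice: the convergence
flag is the Kolmogorov-Smirnov overlap (p > 0.05) of the last two
iterations' resampled dOFV, and the final proposal's dOFV quantiles are
compared against the chi-square reference with df equal to the number of
estimated parameters (a calibrated proposal's dOFV is asymptotically
exactly that chi-square, so the comparison is reported as a
majority-of-quantiles diagnostic rather than folded into the flag). When
a fit carries no covariance, SIR starts from an inflated diagonal
proposal (SD 0.15 on the transformed scale) with a warning.

`compute_npde()` simulates the trial design K = 1000 times (IIV and
residual error), decorrelates each subject's observed and simulated
vectors with the lower-triangular Cholesky factor of the empirical
simulated covariance, and maps the prediction discrepancies
$pd = (\#\{sim < obs\} + 0.5\,\#\text{ties})/K$, clipped to
$[1/2K, 1 - 1/2K]$, through the standard-normal quantile function.
Replicates are drawn from per-subject RNG substreams with one block of
draws per replicate, so runs at increasing K are nested Monte Carlo
samples — the cheap way to verify convergence in K. Reported tests: t-test
of zero mean (a Wilcoxon signed-rank p is also computed and can be
reported instead), a chi-square test of unit variance, Shapiro-Wilk
normality, and a Bonferroni (x3) global p. Two caveats are worth knowing:
linear decorrelation leaves some dependence between observations that
share one $\eta$ through the model's nonlinearity, so with many samples
per subject the variance test is anti-conservative (the self-consistency
calibration therefore uses sparse designs, 1-3 samples per subject); and
the decorrelation step makes npde invariant under common positive
*linear* rescalings of observed and simulated data (tested by jointly
scaling doses and observations, which the dose-linear model passes
exactly), not under arbitrary monotone transforms.

## PTA dosing simulation

`simulate_pta()` draws a virtual population, one $\eta$ pair per subject
(reused across regimens and MICs so regimen contrasts share Monte Carlo
noise), and evaluates the steady-state fraction of the dosing interval
with free concentration above the MIC. The free fraction is fixed at
0.77. The steady-state profile is piecewise mono-exponential, so the up-
and down-crossing times are solved in closed form (logarithms, no root
search); the implementation is validated against a 0.001-h grid oracle.
The pharmacodynamic target is 70% fT>MIC; a regimen is adequate when at
least 70% of subjects attain it. Residual (assay) error is excluded:
PTA concerns true exposure, and residual error is measurement noise.
fT>MIC is evaluated at steady state — the pharmacodynamic convention for
repeated dosing; the first-dose alternative would be slightly more
conservative. All simulated regimens use 0.5-h infusions.

`recommend_regimens()` picks, per MIC, the lowest-burden adequate
regimen with burden ordered by administration frequency first (longest
interval, i.e. fewest infusions per day), then by daily dose. This
ordering reproduces the clinical logic of keeping the prescribed
twice-daily schedule whenever it attains the target and escalating
frequency only when needed; ordering by daily dose first would instead
switch patients to more frequent, lower-dose schedules even when q12h
suffices at low MICs.

## Synthetic cohort and trial generator

`generate_population()` draws weight ~ N(10.33, 1.57^2) kg truncated to
[8.00, 13.00], age ~ N(1.20, 0.43^2) y truncated to [0.35, 1.86], and
serum creatinine ~ N(18, 6^2) umol/L truncated to [10, 26]. Weight and
age are coupled through a shared latent Gaussian factor (latent
correlation 0.6, configurable to 0 for clean recovery experiments) and
mapped to their truncated-normal marginals by the quantile transform, so
the marginals are exact while the realistic weight-age dependence of
infant cohorts is preserved. Note that truncation is asymmetric around
the location parameters: the truncated means are about 10.40 kg and
1.169 y, not 10.33 and 1.20 — distributional checks in the tests compare
against the analytic truncated moments. Height, needed only for the
Schwartz eGFR, follows a piecewise-linear length-for-age curve (about
66 cm at 0.35 y, 75 cm at 1 y, 87 cm at 2 y) with 2 cm Gaussian noise;
creatinine and height are redrawn per subject until eGFR >= 130,
enforcing the ARC inclusion criterion while preserving n. Sex is
balanced and carries no PK effect in the final model.

`simulate_trial()` administers the regimen on each subject's simulated
weight (4 doses by default), draws 1-3 samples per subject (probabilities
0.4/0.4/0.2, mean 1.8, so 20 subjects yield ~36 samples) in post-dose
windows 0.5-2, 2-8 and 8-12 h (weights 0.3/0.4/0.3), and applies the
error model to the predicted concentrations. Samples falling below the
LLOQ are redrawn at a new time, reflecting a cohort in which every
quantified sample was above the LLOQ. The real study's sampling times are
not reported; the window scheme is an assumption and is isolated in
`sampling_design()` so its influence can be probed (a deterministic
`fixed_times` rich design is also available for recovery experiments).

What passing tests on this generator do and do not show: they demonstrate
that the estimation, selection, uncertainty and simulation machinery is
correct and calibrated under the model's own assumptions and the cohort's
covariate envelope. They cannot show that the one-compartment model,
error form or covariate structure are right for real cefathiamidine data,
and the generator deliberately omits real-data features such as dosing
deviations, time-varying covariates, censored concentrations and
model misspecification.

## Problem sizes used in the automated experiments

The test-suite calibration experiments use: a 20-point seeded parameter
grid of 3-subject instances against the quadrature oracle; recovery at
200 subjects x 6 samples summarized over 10 replicate fits (the age
exponent alone carries ~7.6% CV of pure sampling noise at n = 200 — the
binomial floor $\omega^2_{CL}/(n\,\mathrm{var}(\log AGE))$ — so accuracy
is judged on the replicate mean); selection calibration with 20
replicates at 100 subjects per arm; SIR coverage with 20 study-scale
replicates at a reduced schedule (M = 500, 200; m = 100, 50); NPDE
self-consistency with 20 runs of ~500 observations from 250 sparsely
sampled subjects; and PTA at the published n = 1000. These sizes are the
package's choices for sharp yet affordable calibration experiments;
`scripts/acceptance.R` re-runs the dosing simulation itself at full
scale.

## Known limitations

* Diagonal $\Omega$ only; no CL-V correlation (none is reported for this
  model).
* No censored-likelihood (M3) handling of below-LLOQ data.
* No SAEM or importance-sampling estimation; single- (not multi-)
  compartment structures only.
* The PTA covariate approximation: virtual infants are drawn from
  truncated normals rather than resampled from the real cohort's
  covariate vectors, which is the main source of tolerance when
  comparing simulated attainment with the study's printed percentages.
* Cumulative fraction of response is out of scope (no MIC distribution
  data), as are assay chemistry and toxicity/exposure caps.
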