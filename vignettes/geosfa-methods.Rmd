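---
title: "Geoadditive stochastic frontier analysis of hospital quality of care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geoadditive stochastic frontier analysis of hospital quality of care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geosfa)
```

## The model

`geosfa` fits input-oriented production frontiers for hospital care in
which realized quality enters as an input.  For hospital $i$ in year
$t$, the observed log output is

$$
y_{it} = \eta^{(y)}_{it} + v_{it} - u^*_{it}\,\exp\!\big(\eta^{(u)}_{it}\big),
\qquad
v_{it} \sim N(0, \sigma_v^2), \qquad
u^*_{it} \sim N^+(0, \sigma_{u^*}^2).
$$

The output is *risk-adjusted patient volume*: the expected 30-day
stroke deaths of a hospital's patient pool, scaled up by the inverse of
the wave-level average observed mortality rate.  Holding this output
fixed, a hospital is efficient when it produces it with few deaths, few
readmissions and lean staffing — so observed 30-day deaths and
readmissions (the realized *poor* quality) and physician and nurse
full-time equivalents all enter the Cobb–Douglas frontier
$\eta^{(y)}$ as inputs, together with year effects.  Exact-zero quality
counts (no deaths, no readmissions) are retained through the
indicator-plus-floor device: a dummy marks the zero, and the count is
floored at one before logging.  A translog variant adds all squares and
pairwise products of the centered log inputs.

Technical inefficiency follows the *scaling property*: a half-normal
base innovation $u^*_{it}$ is multiplied by $\exp(\eta^{(u)}_{it})$,
where

$$
\eta^{(u)}_{it} = f_{\text{struct}}(d_i) + f_{\text{unstruct}}(d_i)
 + \tau_t + \textstyle\sum_j \delta_j z_{itj}
$$

collects observable determinants (specialization, stroke-unit
certification, market concentration, ownership, teaching status, case
mix, outpatient supply, ...), wave effects, and a geoadditive pair of
district effects: a structured field with an intrinsic Gaussian Markov
random field (ICAR) prior on the contiguity graph — districts are
neighbours when they share a border — and an unstructured iid Gaussian
effect for districts hosting hospitals.  $\eta^{(u)}$ carries no
intercept; its level is identified through the innovation scale
$\sigma_{u^*}$.

One printed form of the scaled inefficiency distribution gives the
variance exponent as $\alpha_{it}$ rather than $\alpha_{it}^2$.  The
package scales the random variable itself, $u_{it} = u^*_{it}
\alpha_{it}$, so the standard deviation is $\sigma_{u^*}\alpha_{it}$ —
the only reading consistent with the scaling-property formulation the
model builds on; the other exponent is treated as a typographical slip.

Technical efficiency is $TE_{it} = \exp(-u_{it}) \in (0, 1]$, with the
half-normal closed form $E[e^{-u}] = 2 e^{\sigma_u^2/2}
\Phi(-\sigma_u)$ available for checks and marginal effects.

## Priors and identification

* Frontier coefficients: flat (the conjugate Gaussian update needs no
  proper prior).
* Inefficiency-scaling coefficients $\delta$: diffuse Gaussian
  $N(0, 100)$ by default.  A fully flat prior leaves the posterior
  improper: a skewed binary covariate can absorb the inefficiency mass
  while $\sigma^2_{u^*}$ escapes to infinity, and chains genuinely
  diverge along that ridge.  `sfa_priors(delta_var = Inf)` restores the
  flat prior for users who want it.
* Variances: inverse-gamma.  $\sigma_v^2$ and the spatial/hospital
  variances use the conventional diffuse $IG(0.001, 0.001)$.  The
  innovation variance $\sigma^2_{u^*}$ uses a weakly informative
  $IG(2, 1)$: on the softly identified ridge between the spread of
  $\eta^{(u)}$ and the innovation scale, the diffuse prior's density
  spike at zero decides the outcome — it collapses $\sigma^2_{u^*}$ and
  inflates every $\delta$ by a common factor.  With $IG(2, 1)$
  simulation recovery is unbiased.  All shapes and scales are
  configurable per parameter.
* ICAR identification: each draw of the structured field is re-centered
  to sum to zero per connected component; the frontier intercept and
  innovation scale absorb the level.  Adjacency is binary and
  unweighted; degree-zero islands keep a structured effect of exactly
  zero.

Internally the covariate design of $\eta^{(u)}$ is centered columnwise.
This changes no slope, but it pins the predictor's level at the sample
mean, so the stored $\sigma^2_{u^*}$ *is* the inefficiency variance at
sample-mean covariates — the evaluation point used for the variance
ratio $\gamma = \sigma_u^2 / (\sigma_v^2 + \sigma_u^2)$ and for all
marginal effects.

## Sampling

`fit_sfa()` runs a partially collapsed Metropolis-within-Gibbs scan.
The latent innovations admit an exact truncated-normal full
conditional, and the $u^*$-integrated (marginal) likelihood of the
composed error is the classic skew-normal density, evaluated stably
through the log-scale Gaussian CDF.  Per iteration:

1. $\delta$, in blocks of at most 8: adaptive random-walk Metropolis on
   the **marginal** likelihood, preconditioned by the Cholesky factor
   of $(Z'Z/n)^{-1}$, with Robbins–Monro scale adaptation towards 0.25
   acceptance during the adaptation window.
2. Structured field: site-wise Metropolis with proposals combining the
   GMRF prior conditional (neighbour mean, precision $d_i/\tau^2$) with
   a finite-difference second-order expansion of the site's marginal
   log-likelihood; then sum-to-zero centering.  Unstructured and
   hospital effects: the same update with an iid prior.
3. $\sigma^2_{u^*}$: log-scale random-walk Metropolis on the marginal
   likelihood.
4. $u^*$: exact inverse-CDF truncated-normal draws (no rejection loop,
   no failure mode at extreme means).
5. Frontier coefficients: conjugate Gaussian draw given the adjusted
   response $y + \alpha u^*$; $\sigma_v^2$ and the spatial variances:
   conjugate inverse-gamma.

Updating $\delta$, the fields and $\sigma^2_{u^*}$ against the marginal
likelihood — with $u^*$ regenerated from its exact conditional before
any step that conditions on it — is what breaks the slow coupling
between the latent innovations and the scaling parameters; the fully
conditional scan mixes catastrophically there.  The kernel's
correctness is checked jointly by a successive-conditional
("getting-it-right") simulation, `successive_conditional_check()`:
alternating data draws and kernel sweeps must return the prior
marginals of $\delta$ and all variances, and does.

The default protocol is 120,000 iterations, 20,000 burn-in, thinning
100 — 1,000 stored draws — with a fixed recorded seed; identical seeds
give bitwise-identical chains.  Convergence is monitored by split-chain
$\widehat R$ and effective sample sizes (warning below 100), plus trace
plots via `autoplot()`.

## Model comparison and post-estimation

DIC ($\bar D + p_D$) and WAIC use the marginal likelihood by default so
that specifications with different latent dimensions (iid hospital
effects, district or coarse-level fields) are compared on the same
footing; the conditional-on-$u$ deviance is available behind a flag. A
data fingerprint guards against comparing fits on different
observations.  The preset family `model1` ... `model9` plus robustness
presets (translog, +0.5 zero-input rescaling, mixed spatial levels)
expresses the whole specification suite purely by configuration.

The post-estimation layer reports technical efficiency (posterior mean
of $e^{-u}$ per hospital-year), $\gamma$, *slack resources* — the
single-input contraction $x_k (1 - e^{-u/\beta_k})$, the amount of
input $k$ removable at unchanged output with all other inputs fixed —
and marginal effects of each determinant on expected TE and on each
slack, evaluated at sample means, with discrete differences for binary
determinants and the closed-form derivative
$\delta_j \sigma_u \, 2 e^{\sigma_u^2/2}[\sigma_u \Phi(-\sigma_u) -
\phi(\sigma_u)]$ for continuous ones (both validated against finite
differences).  The supplementary derivations behind the published slack
and marginal-effect tables are not publicly available; the single-input
contraction is this package's operationalization, consistent with the
verbal definition (how much of an input could be reduced at the same
output) and with the near-total mortality slack the original analysis
reports.  `scenario_savings()` extrapolates a per-hospital effect to a
national total and returns raw, rounded and truncated versions, the two
rounding conventions in which such totals are quoted.

A matching + difference-in-differences check (`run_matching_did()`)
guards the certification effect against self-selection: switchers are
propensity-matched 1:1 without replacement to never-certified hospitals
on first-wave characteristics (logistic propensity model; ties broken
by hospital id after a seeded shuffle), and the frontier is refit on
*all* observations with the certification term replaced by matched-pair
interactions.

## The synthetic-data generator

Real report-card, insurer and certification data are proprietary, so
`simulate_panel()` generates panels with the structure the analysis
assumes and full ground truth.  Defaults emulate the study conditions:
a $21\times 21$ rook lattice (441 districts, a few empty), Poisson(3)
hospitals per district ($\approx$ 1,300 hospitals), five waves
(2006/08/10/12/13) with 15% per-wave dropout, wave-specific zero
fractions of 8–17% for deaths and readmissions (produced by
thresholding the lowest latent counts to zero within each wave),
bivariate log-normal staffing with correlation 0.95, binary
determinants at their published prevalences, Dirichlet within-district
market shares (internally consistent with the realized district
occupancy), an ICAR-distributed structured field
($\tau^2_{\text{struct}} = 0.15$) with a weaker iid field
($\tau^2_{\text{unstruct}} = 0.03$, matching the reported dominance of
the structured component), $\sigma_v^2 = 0.142$, and true effect sizes
taken from the published point estimates so fixtures live in a
realistic regime.  The innovation scale is solved by `uniroot` so the
marginal mean technical efficiency equals 0.73, the published overall
level; expected deaths are constructed as
$\overline{\text{rate}}_t\, e^{y}$ so that the output construction
inverts exactly.  Quality inputs are continuous non-negatives with an
atom at zero (the model treats them as continuous log inputs); a
Poisson option exists.

What the generator does *not* emulate: patient-level risk adjustment
(expected deaths are produced directly), endogenous certification
(certification timing is random — which is precisely what makes the
DID randomization check interpretable), inter-hospital market overlap
beyond district boundaries, and Germany's actual geography.  Passing
recovery tests therefore shows the estimator works when the model is
true at realistic sizes, not that the substantive published estimates
are correct.

## Problem sizes used by the checks

The validation suite runs at deliberately reduced sizes chosen as the
smallest that still exercise every component: recovery fits use 200
hospitals over 5 waves on a 5×5 lattice with chains of 12,000
iterations (2,000 burn-in, thinning 10); interval coverage uses 20
replicates of ~100 hospitals on a 4×4 lattice with 2,500-iteration
chains; the model-selection-direction check uses 10 replicates of ~200
hospitals on a 5×5 lattice (3×3 coarse blocks, matching the real
districts-per-coarse-region ratio) with 2,000-iteration chains; the
getting-it-right check uses 20 observations in 4 districts over 20,000
simulate/update cycles, comparing log-scale variance moments with
batch-means Monte-Carlo errors.  The full-scale default configuration
(~1,300 hospitals, 441 districts, 120k iterations) runs in hours, not
minutes, and is intended for real analyses.

## Numerical choices and edge cases

* Truncated-normal draws by inverse CDF entirely in log-tail space:
  exact for standardized bounds of either sign and extreme magnitude.
* $\log \Phi$ via `pnorm(log.p = TRUE)`, so marginal likelihoods
  survive residuals tens of standard deviations out.
* Zero expected deaths make the log output undefined; such records are
  flagged, kept in the panel, and excluded from fitting with a warning.
* The wave mortality rate is the unweighted mean across hospitals of
  observed mortality rates (matching the published descriptive
  convention); a volume-weighted alternative and a directly supplied
  wave rate are both available.
* Slack is refused for inputs whose posterior-mean elasticity is not
  positive (the contraction is undefined); draws with negative
  elasticity are dropped with a warning, and slack is capped at the
  input level on overflow.
* Centering a binary dummy is allowed but warned about.
* A singular structured-field full conditional (no data information on
  a component's level) is resolved by a $10^{-8}$ ridge before the
  sum-to-zero constraint re-centers the level away.

## Known limitations

* The free truncation mean $\mu^* \neq 0$ exists as a switch but the
  marginal likelihood, DIC/WAIC and the closed-form TE all assume the
  half-normal case; the switch is untested beyond prior sanity.
* Spline effects for metric covariates are out of scope (the supported
  analyses model them linearly).
* Wave effects in $\eta^{(u)}$ are only weakly separated from frontier
  year effects (a level-versus-shape distinction); their posterior
  means are noticeably less precise than the covariate effects.
* With $\sigma_u \approx \sigma_v$ per observation, observation-level
  efficiency estimates shrink strongly towards the covariate
  prediction; hospital-level averages are the reliable ranking unit.
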