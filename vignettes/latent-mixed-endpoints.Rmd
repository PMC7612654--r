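---
title: "Designing trials with mixed-outcome endpoints: methods and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing trials with mixed-outcome endpoints: methods and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentpower)
```

## The latent variable model

Many trials measure several outcomes per patient on different scales — a
continuous disease-activity score, an ordinal clinician grading, a binary
response flag. `latentpower` models the K outcomes of patient *i* in arm
*a* as a latent K-variate normal vector $Y^*_{ai} \sim N_K(\mu_a, \Sigma)$.
Continuous outcomes are observed directly, with design variance
$\sigma_k^2$. Ordinal and binary outcomes are observed only through
threshold crossings: an ordinal outcome with $w+1$ levels has strictly
increasing cut-points $\tau_{k1} < \dots < \tau_{kw}$ and
$Y_{k} = l \iff \tau_{kl} \le Y^*_{k} < \tau_{k(l+1)}$ (with
$\tau_{k0} = -\infty$, $\tau_{k(w+1)} = \infty$); a binary outcome has the
single threshold fixed at 0. For identifiability the latent variances of
discrete components are fixed at 1 (they are not user-settable), ordinal
control-arm means are fixed at 0 with free thresholds, and binary
thresholds are fixed at 0 with free per-arm means. One correlation matrix
$\Gamma$ is shared by both arms; supplying arm-specific matrices is an
error rather than a silent average, because every power formula below uses
a single $\Gamma$ and averaging would hide a modelling decision from the
user. Mixed continuous/discrete correlations are interpreted on the latent
scale (polyserial-type), matching the model in which they appear.

### Orientation of the latent scale

The package orients every discrete outcome so that **response is the upper
tail**: a binary response is $Y = 1 \iff Y^* \ge 0$, so
$\pi = \Phi(\mu^*)$ and $\mu^* = \Phi^{-1}(\pi)$; an ordinal treatment
effect is defined on an upper level set $\{a, \dots, w\}$ (default: the
top level), giving $\pi = \Phi(\mu^* - \tau_{ka})$. With this convention
the latent effect of any discrete outcome is

$$\delta^*_k = \Phi^{-1}(\pi_{Tk}) - \Phi^{-1}(\pi_{Ck}) = \mu^*_{Tk} - \mu^*_{Ck},$$

positive effects always favour treatment, and the simulated control-arm
response rate equals the specified $\pi_{Ck}$ exactly. (The alternative
"response = lowest level" convention makes $\mu^* = \Phi^{-1}(\pi)$ and the
threshold model mutually inconsistent up to a sign; we chose the
self-consistent orientation and document it rather than carrying sign flips
through the code.) Users with "response = low" outcomes recode by a sign
flip; this is deliberate, not auto-detected.

Probabilities of exactly 0 or 1 are rejected, not clipped: the latent
effect is unbounded there and any clipping constant would be an arbitrary
hidden parameter.

## The three endpoints

Write $d_k$ for the standardized effect ($\delta_k/\sigma_k$ continuous,
$\delta^*_k$ discrete), $\kappa = n_C/n_T$, and
$z^\dagger_k = z_\alpha - d_k\sqrt{\kappa n_T/(1+\kappa)}$ for the shifted
critical value of the one-sided outcome-level z test. The centred test
statistics are jointly normal with correlation $\Gamma$, which gives:

* **Co-primary (intersection):** success requires all K tests to reject;
  power $= \Phi_K(-z^\dagger_1, \dots, -z^\dagger_K;\, \Gamma)$. No
  multiplicity adjustment is needed (intersection tests are conservative).
* **Multiple primary (union):** success requires at least one rejection at
  the adjusted level (Bonferroni $\alpha/K$ by default); power is computed
  by inclusion–exclusion over the $2^K - 1$ outcome subsets *and* by the
  complement identity $1 - \Phi_K(z^\dagger; \Gamma)$, and the two routes
  must agree within $10^{-6}$ — a standing internal cross-check of the
  quadrature. Enumeration is refused for $K > 12$; the complement form
  remains available. Holm's step-down has no closed-form power and is
  provided through the simulation functions only.
* **Composite responder:** a patient responds when all components fall at
  or below predefined cuts $\eta_k$ (an `at_least = m` argument relaxes
  this to m-of-K via inclusion–exclusion; the all-of-K default is the
  common case). The arm-level response probability is the normal rectangle
  $p_a = \Phi_K(\eta; \mu^*_a, \Sigma)$, the effect is
  $\delta^* = p_T - p_C$, and the univariate closed forms
  $1-\beta = \Phi(\delta^*/\sqrt{2\sigma^2/n} - z_\alpha)$ and
  $n = \lceil 2\sigma^2(z_{1-\beta}+z_\alpha)^2/\delta^{*2}\rceil$ apply.

Testing is one-sided superiority throughout, default $\alpha = 0.025$ and
target power 0.80; two-sided testing is out of scope.

## Tunable parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.025 | one-sided outcome-level significance level |
| `target_power` | 0.80 | required overall power |
| `adjustment` | `"bonferroni"` | per-test level for union testing (`alpha/K`) |
| `alloc_ratio` | 1 | $\kappa = n_C/n_T$; reports state both arm sizes |
| `thresholds` (ordinal) | uniform quantile cuts | $\tau_j = \Phi^{-1}(j/(w+1))$: equal control-arm category probabilities |
| `response_level` (ordinal) | top level | first level of the upper level set counted as response |
| `eta` (composite) | — | responder cuts, required; on the observed scale for continuous and the latent scale for discrete components |
| `reps` (simulation) | 10 000 | Monte-Carlo SE $\approx$ 0.4 percentage points at 80% power |

## Sample-size search

Power is strictly increasing in n, so the search brackets exponentially
and bisects on the integer lattice. For the co-primary endpoint the start
is the largest single-outcome closed-form size — a certified lower bound,
since joint power cannot exceed any marginal power — so no scan below the
optimum is wasted. Every result carries a minimality certificate: the
achieved power at n and the power at n − 1, which must straddle the
target. The evaluated (n, power) pairs are kept in the result (`tidy()`,
`autoplot()`) for audit.

## Numerical choices

* **MVN probabilities.** All rectangle/orthant probabilities use
  `mvtnorm` with the deterministic Miwa lattice algorithm (2048 grid
  points by default), giving absolute errors near $3\times10^{-8}$ in the
  four-dimensional designs we target — small enough that integer sample
  sizes are reproducible run-to-run, which a randomized quadrature cannot
  guarantee near a power boundary. Bounds of $\pm\infty$ are clamped to
  $\pm 37$ SD (beyond double-precision resolution of the normal CDF). At a
  genuine boundary the published value of a design may sit one patient
  above the certified minimum; the certificate fields make such cases
  visible instead of hiding them.
* **Likelihood evaluation.** In `fit_latent_model()` each patient
  contributes the exact mixed density: the marginal normal density of the
  continuous components times the conditional rectangle probability of
  the observed discrete cell. With one discrete outcome the conditional
  is univariate and fully vectorized; with exactly two, per-patient
  bivariate rectangles are evaluated by a vectorized 40-node
  Gauss–Legendre quadrature over the first conditional coordinate
  (validated against `pmvnorm` to $10^{-12}$); with three or more the
  code falls back to per-patient Miwa calls, which is exact but slow —
  a documented limitation. With no continuous components, identical
  discrete cells are aggregated and weighted by their counts.
* **Parameterization.** Optimization (BFGS) runs on an unconstrained
  scale: log standard deviations, first threshold free with log-gaps,
  `atanh` correlations, plus a barrier if the implied correlation matrix
  loses positive-definiteness. Standard errors come from the numerically
  differentiated observed information on the natural scale; a singular or
  indefinite information matrix falls back to a PSD-projected
  pseudo-inverse with a warning. Starting values are moment-based
  (sample moments, marginal probit transforms, Pearson correlations
  clamped to $\pm 0.7$).
* **Delta method.** The composite variance uses central finite
  differences (relative step $10^{-5}$) of the rectangle-probability risk
  difference with respect to every fitted parameter, then the quadratic
  form with $\widehat{\mathrm{Cov}}(\hat\theta)$; a non-PSD covariance is
  projected to the nearest PSD matrix with a warning, never silently.
  The per-observation scale is recovered as
  $\sigma^2 = \sigma^2_\delta / (1/n_T + 1/n_C)$; unbalanced pilots
  trigger a warning stating the convention because the literature is
  ambiguous about it.
* **Degenerate inputs.** Infeasible designs (no positive effect where one
  is required) raise classed errors naming the offending outcome;
  unobserved discrete levels raise identifiability errors; rows with
  missing values are dropped with a count (within-patient missingness is
  out of scope for this version).

## What the synthetic-trial generator does and does not emulate

`simulate_trial()` draws latent vectors from the specified MVN law —
control means at 0 (or anchored so the control response rate equals a
supplied $\pi_C$), treatment means shifted by the standardized effects —
and thresholds them, returning both observed and latent values. Identical
seeds give byte-identical datasets; a single seeded R stream is used (the
replications are serial, so no substream scheme is needed). Default
simulation sizes: 10 000 replicates (Monte-Carlo SE about 0.4 percentage
points at 80% power), chosen as the desk-scale standard for the empirical
studies reported by the package.

The generator produces exactly the data-generating process the power
formulas assume: multivariate-normal latent traits, a common correlation
matrix, no covariates, no missingness, no measurement error beyond
thresholding. Passing tests therefore demonstrate internal consistency of
the formulas, quadrature and search — they do not certify performance
under model misspecification (non-normal latent traits, arm-dependent
correlations, informative missingness), which a real trial may exhibit.

Empirical testing supports two surfaces. The default `"latent"` surface
applies z tests directly to the latent values with known variances — this
is the surface on which the analytic power formulas live, and empirical
power matches them within Monte-Carlo error. The `"observed"` surface
re-estimates latent means from the thresholded data (closed-form probit
for binary, ordered-probit ML for ordinal, estimated variance for
continuous) as a sensitivity analysis: probit estimation inflates the
standard errors (by roughly $\sqrt{p(1-p)}/\varphi(\Phi^{-1}(p))$ relative
to a known-variance test), so observed-surface power sits visibly below
latent-surface power at the same n. Designs sized on the latent surface
are therefore optimistic for analyses that only use thresholded data; a
joint-model analysis of the real data recovers part of that gap.

Under the global null the latent-surface test statistics are exactly
$N_K(0, \Gamma)$ for every sample size, so `empirical_fwer()` simulates at
the statistic level — this is exact, not an approximation, and makes the
error-rate grids cheap. Note that "at least one Holm rejection" coincides
with "at least one Bonferroni rejection" (Holm's first step *is*
Bonferroni), so their FWERs agree exactly; Holm's advantage appears in the
number of rejections, and in union power it is never worse.

## Design decisions that were genuinely open

* **Printed estimates as inputs.** The packaged lupus fixture
  (`muse_endpoint()`) takes the discrete latent effects as the published
  two-decimal estimates (0.24, 0.40) rather than recomputing
  $\Phi^{-1}(\pi_T)-\Phi^{-1}(\pi_C)$ from the rounded response rates
  (which gives 0.2360 and 0.4059 — the second of which does not even round
  back to the printed 0.40). Design tables are reproducible only with the
  printed values, so the fixture treats them as the authoritative design
  inputs and keeps the probabilities as simulation anchors.
* **Bonferroni as default adjustment** for union testing: it is the
  standard conservative choice, has a closed form on every path, and its
  FWER control holds for any correlation structure. Holm is offered via
  simulation only.
* **FWER under the global null.** All effects exactly 0; least-favourable
  boundary configurations are out of scope.
* **Composite $\sigma^2$ convention.** $\sigma^2$ is user-suppliable
  directly (expert elicitation) or recovered from a pilot fit; both routes
  are explicit because pilot-free composite design is common in practice.
* **Scenario files** (YAML/JSON) reject unknown keys outright, and the
  writers use round-trip-exact number formatting so that load → dump →
  load is the identity — silent config drift is a real failure mode in
  long-running design work.

## Problem sizes used by the shipped studies

The package's own verification studies (test suite and acceptance script)
run at desk scale, chosen once: 10 000 replicates for the headline
empirical-power check; 20 000 statistic-level replicates for error-rate
grids; 200 replicates of a continuous+binary pilot fit at 250 patients per
arm for parameter-recovery coverage (each estimate within 3 reported SEs
in at least 95% of replicates); 4 000 closed-form probit refits for the
delta-method-versus-simulation variance comparison. These sizes give
Monte-Carlo standard errors comfortably below the tolerances they are
checked against.

## Known limitations

* Two arms only; treatment is the only covariate (no covariate-adjusted
  means); no time-to-event components; no more than one correlation
  matrix.
* Fits with three or more discrete outcomes use a slow per-patient
  quadrature loop; five-level ordinal components add many threshold
  parameters for modest precision gain, and collapsing them toward the
  binary component is often a reasonable simplification at design stage.
* Within-patient missing values are dropped, not modelled.
* Group-sequential/adaptive re-estimation, gatekeeping hierarchies,
  weighted Bonferroni and resampling step-downs are out of scope.
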