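---
title: "Modelling momentary stress-affect dynamics and trait moderation with emadsem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling momentary stress-affect dynamics and trait moderation with emadsem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Ecological momentary assessment (EMA) studies prompt participants several
times a day to rate their current perceived stress and negative affect. Two
questions drive the model in this package: how strongly do stress and
negative affect carry over and couple from one moment to the next *within* a
person, and do stable *between*-person traits — here a latent ADHD trait —
moderate those dynamics and, through them, relate to internalising problems
(anxiety/depression)?

`emadsem` implements the full pipeline: a synthetic-data generator that
emulates a two-week smartphone EMA design; conversion of irregular prompts
to an equidistant grid; sum-score and confirmatory factor measurement
models for the trait questionnaires; a Bayesian two-level dynamic
structural equation model (DSEM) estimated by a purpose-built Gibbs
sampler; and reporting utilities (standardised estimates, credible
intervals, indirect effects).

# The model

## Within level

For person $i$ at grid occasion $t$, let $S_{it}$ and $A_{it}$ be the
stress and negative-affect sum scores. Each observation splits into a
stable person mean and a momentary latent deviation,

$$S_{it} = \mu_{S,i} + s_{it}, \qquad A_{it} = \mu_{A,i} + a_{it},$$

and the deviations follow a person-specific bivariate lag-1 process

$$
\begin{aligned}
s_{it} &= \phi_{SS,i}\, s_{i,t-1} + \phi_{AS,i}\, a_{i,t-1} + \varepsilon_{S,it},\\
a_{it} &= \phi_{AA,i}\, a_{i,t-1} + \phi_{SA,i}\, s_{i,t-1} + \varepsilon_{A,it},
\end{aligned}
\qquad \varepsilon_{it} \sim N(0, \Sigma_w).
$$

$\phi_{SS}$ and $\phi_{AA}$ are inertias (autoregressions); $\phi_{SA}$ is
affective stress reactivity (stress at $t-1$ raising affect at $t$);
$\phi_{AS}$ the reverse coupling. $\Sigma_w$ is shared across persons, with
a free off-diagonal by default (configurable to diagonal).

## Between level

The six person-specific quantities
$r_i = (\mu_{S,i}, \mu_{A,i}, \phi_{SS,i}, \phi_{AA,i}, \phi_{AS,i}, \phi_{SA,i})$
are random effects regressed on a latent ADHD factor $\xi_i$ (and, in the
covariate variant, sex, primary-caregiver country of origin, and z-scored
childhood SES):

$$r_{ik} = \nu_k + \gamma_k\, \xi_i + \Gamma_k' c_i + u_{ik}, \qquad
u_{ik} \sim N(0, \tau_k^2) \text{ (mutually independent)}.$$

A latent internalising factor $\eta_i$ is the distal outcome:

$$\eta_i = \beta_0 + \beta' r_i + \beta_{\xi}\, \xi_i + \beta_c' c_i + e_i,
\qquad e_i \sim N(0, \sigma_e^2).$$

$\eta$ is regressed on the *latent* random effects, jointly sampled — no
two-step plug-in of point summaries.

Both factors are measured by ordinal 1-5 questionnaire items treated as
continuous: 9 ADHD items and 14 internalising items, each factor identified
by fixing its first loading to 1, plus one cross-loading: the
"restless inside" ADHD item also loads on internalising (the assignment of
primary vs. cross loading is configurable; the default puts the primary
loading on ADHD).

The random-effect residuals are mutually independent given the predictors:
six random effects with a free 6x6 covariance are weakly identified at a
few hundred persons, and the moderation and mediation questions concern the
regressions, not the residual covariances.

## Indirect effects

The mediation of the ADHD-internalising association through each dynamic
parameter is the within-draw product $\gamma_k \beta_k$ of unstandardised
coefficients, summarised by the posterior median and equal-tailed 2.5/97.5
percentile interval. Products are never formed from interval endpoints or
other posterior summaries. "Significant" throughout means the 95% credible
interval excludes zero; the package computes no p-values.

## Standardisation

Estimates are reported standardised. Within-person coefficients are
standardised per draw and per person using the person's model-implied
stationary within SDs (obtained from the discrete Lyapunov equation at the
person's transition matrix), then averaged over persons; because predictor
and outcome share a stationary SD, the standardised autoregression equals
the raw one, while cross-lagged paths are rescaled by the SD ratio.
Between-level coefficients use the model-implied between SDs, e.g.
$\gamma_k^{std} = \gamma_k \sqrt{\psi_\xi} / \mathrm{sd}(r_k)$ with
$\mathrm{sd}(r_k)^2 = \gamma_k^2 \psi_\xi + \tau_k^2 + \Gamma_k' \Sigma_c \Gamma_k$.
All standardisation happens draw-wise so credible intervals propagate.
Indirect effects are reported unstandardised (standardised versions follow
from the same draws if needed).

# Time gridding

Prompts arrive at quasi-random times, but the lag-1 model needs
approximately equidistant occasions. `build_grid()` bins each answered
prompt into 4-hour slots (`delta = 240` minutes) on a grid anchored at
10:00 of study day 1 — anchoring at a fixed clock time keeps day structure
aligned across persons and makes the overnight gap deterministic. Slots
without a record, including the three overnight slots of every day, become
explicit missing cells that the sampler treats as unknowns.

With four prompts in a 12-hour window and 4-hour bins, two prompts
regularly share a bin. The default collision rule (`"shift"`) moves the
later record one bin forward when that bin is free — usually the empty
late-evening slot — and drops it otherwise (logged); this mirrors how
interval-binning preprocessors in this field behave and, under the default
design (67% compliance), yields the expected pooled missingness of ~54%.
Keeping only the earliest record per bin (`"earliest"`) is available but
discards roughly one record in seven, pushing missingness above 60%.
`"latest"` and `"mean"` complete the deterministic alternatives. A sum
score is missing whenever any constituent item is missing; no proration.

# The synthetic-data generator

`simulate_dataset()` emulates the motivating study design: 262 persons, 14
days, 4 prompts/day drawn by stratified sampling (one uniform draw per
consecutive 3-hour stratum of the 10:00-22:00 window, 30-minute minimum
gap enforced by resampling), and independent Bernoulli(0.67) compliance.
The latent within-person process lives directly on the 4-hour grid; each
answered prompt observes the latent state of the grid slot it is assigned
to (the same deterministic assignment the gridder performs — otherwise two
prompts colliding in one bin would report the identical latent value and
the shifted duplicate would fake a unit-slope transition). Sum scores are
rounded and clamped to their admissible ranges (4-20, 7-35), introducing
the mild floor effects and discretisation noise real scales show; item
responses are emitted by spreading each sum evenly across its items.

Trait items arise from a continuous linear factor model discretised at
fixed thresholds (-1.5, -0.5, 0.5, 1.5 on the standardised propensity
scale). Covariates follow the study margins: 38.5% male, 62.5%
Switzerland-origin caregivers, SES normal with mean 49.09 and SD 17.58
truncated to [16, 88].

Structural generating values are specified on the standardised scale
(matching how such analyses are reported) together with marginal scale
choices the reported tables do not pin down. Those scale choices, fixed at
EMA-realistic values: stationary within-person SD of 2 sum-score points
for both variables with within correlation 0.3; between-person SDs of 1.5
(stress mean), 2.0 (affect mean) and 0.2 (all four dynamic coefficients —
the value at which the posterior SDs of the trait-moderation block in a
study-scale fit match the precision such studies report for those
coefficients, and mid-range for published EMA inertia random-effect SDs);
population means 9 and 12; ADHD factor variance 1; internalising total
variance 1; standardised item loadings about 0.71.
The generator enforces a stationarity guard (spectral radius < 0.95) by
redrawing offending random-effect residuals; the estimator imposes no such
constraint.

What the generator does *not* emulate: time-of-day and weekday structure,
autocorrelated or time-varying compliance, response styles, ordinal
measurement of the momentary items, or floor-censoring beyond the simple
clamp. Passing recovery tests therefore demonstrate correctness of the
estimation machinery under the stated design, not robustness to every
artefact of real EMA data.

# Estimation

All full conditionals are conjugate: latent states at missing slots are
drawn per slot from exact bivariate (or conditional univariate) normals
given their neighbours; person means and transition coefficients from
normal conditionals combining the within likelihood, the between prior and
the internalising equation; regression coefficients and loadings from
normal updates; variances from inverse-gamma updates; $\Sigma_w$ from an
inverse-Wishart update. The first fully observed occasion of each person is
conditioned on (leading and trailing missing slots carry no information
about that person and are trimmed); the exported `sample_latent_states()`
additionally supports stationary-prior imputation of leading gaps.

## Priors

Priors are diffuse but proper: Normal(0, 1e6) on intercepts,
inverse-gamma(0.001, 0.001) on variances, inverse-Wishart(I, 3) on
$\Sigma_w$, and Normal(0, 25) on loadings and regression slopes. The
last choice deserves a note: with essentially flat priors on the ~28 free
loadings and slopes attached to a reference-identified factor, the
conditional width of each coefficient scales like $1/\sqrt{n\psi}$, so the
marginal posterior picks up a large $\psi^{-k/2}$ volume factor and places
substantial mass on a degenerate ridge where the factor variance collapses
and every attached coefficient diverges. Normal(0, 25) is far wider than
any plausible standardised coefficient on these scales, yet bounds that
ridge. All hyperparameters are configurable through the `priors` argument.

## Mixing: interweaving scale moves

Two geometry problems would make plain Gibbs crawl here. First, the factor
scale: only the reference indicator pins the scale of each latent factor,
and single-site updates random-walk along the scale ridge. After each
between-level sweep the sampler therefore proposes a coordinated rescaling
of each factor (scores and variance up; attached loadings and slopes down),
a Metropolis move whose acceptance involves only the reference-indicator
likelihood, the priors and the Jacobian. Second, the classic funnel between
the random-effect residual SDs $\tau_k$ and the person effects: with ~38
observed occasions per person, each person's transition coefficients carry
less information than the between spread, and $\tau^2_k$ can only move
after all 262 person effects move. A non-centered (interweaving) move
rescales every person's deviation from its conditional prior mean jointly
with $\tau_k$, evaluated exactly through per-person sufficient statistics
of the within likelihood. Both moves leave the posterior invariant and cut
the autocorrelation time of the variance parameters by orders of magnitude.

## Convergence and defaults

Two independent chains (overdispersed via chain-specific jitter of SD 0.5
on population locations), a maximum of 50,000 iterations, every 10th draw
recorded, the first half of each chain discarded as burn-in. The potential
scale reduction (PSR) of every population-level parameter is checked on the
second halves at a configurable cadence (default every 1,000 iterations);
when all PSR values first drop below 1.05, the completed iteration count is
doubled before stopping. Runs that exhaust the budget return their draws
with an explicit non-convergence status — never a silent success. A single
seed drives chain seeds and all randomness, including the compiled core
(which uses R's generator), so identical configurations reproduce draws
bit for bit regardless of hardware.

## Degenerate inputs

Persons with fewer than two usable transitions draw their random effects
from the between prior (counted in the fit status). Zero within-chain
variance in a monitored parameter flags the PSR as degenerate rather than
dividing by zero. Non-stationary person transition draws are legal in the
estimator; the per-person standardisation skips persons whose current draw
has spectral radius above 0.999 for that draw.

# The measurement module

`fit_cfa()` fits the two-factor model (with the cross-loading) by
normal-theory maximum likelihood treating items as continuous — the
simplest defensible estimator for 1-5 Likert items, consistent with the
DSEM side. Missing item responses are handled by full-information ML over
the casewise observed-data likelihood, grouped by missingness pattern
(saturated comparison moments come from an EM fit when data are
incomplete). Fit indices use the standard formulas, e.g.
$\mathrm{CFI} = 1 - \max(\chi^2_m - df_m, 0) / \max(\chi^2_b - df_b, \chi^2_m - df_m, 0)$
against the independence baseline; SRMR is computed from standardised
residual covariances on complete data. McDonald's omega includes the factor
variance, $\omega = (\sum\lambda)^2\psi / ((\sum\lambda)^2\psi + \sum\theta)$,
making it invariant to which indicator is the reference.

# Problem sizes and runtimes

The recovery study used throughout (tests and the acceptance script) is
the full design: 262 persons, about 82 grid slots each (~54% missing),
two chains of 20,000 iterations with thinning 5 — 2,000 retained draws
per chain — which completes in about five minutes on one core thanks to
the compiled within-person sweep. Oracle checks (conjugate AR(1)
posterior, Gaussian conditioning of imputed states, PSR on constructed
chains) run in seconds at small sizes chosen so Monte-Carlo error is well
below the tolerances asserted.

A note on what such a recovery run can and cannot show. The population
means, the within-person autoregressive and cross-lagged coefficients,
the ADHD effects on the person means, and the internalising regression
are recovered tightly (errors well under 0.05 on the standardised scale).
The ADHD effects on the *dynamic* random effects are the hardest
estimands in the model: with roughly 38 answered occasions per person,
each person's transition coefficients carry a standard error comparable
to their between-person spread, so the standardised moderation
coefficients carry a combined posterior and dataset-to-dataset
variability of roughly ±0.1 at these conditions. Replicate simulations
land on either side of the generating values by about that much; this is
an identification limit of moderated-dynamics designs at two weeks of
sampling, not a property of the sampler (which recovers the same
quantities essentially exactly when occasions are dense or complete).

# Known limitations

- Lag-1 dynamics with two within-person variables only; no higher lags,
  time-varying covariates, or continuous-time treatment of unequal gaps.
- Items treated as continuous in both measurement models; no ordinal
  (probit/WLSMV-style) estimator.
- Random-effect residuals independent given predictors; residual
  covariances among the six random effects are not estimated.
- The grid-based generative story assigns each prompt the latent state of
  its grid slot; within-bin timing information is deliberately discarded.
- Mediation here is cross-sectional in the between-person sense; the
  generator and model make no claim about longitudinal causal ordering.
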