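---
title: "Modeling circadian activity from hourly GPS telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling circadian activity from hourly GPS telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bearcadian)
```

## The model

The package estimates how the activity of GPS-collared animals — here,
brown bears — varies over the 24-hour day, using the hourly movement rate
(planar distance in km between fixes exactly one hour apart) as an
activity index. The response is the square-root of the rate,

$$y_{tk} = \lambda^*_{tk} + \varepsilon_{tk}, \qquad
  \varepsilon_{tk} \sim N(0, \sigma^2),$$

for observation time $t$ of animal $k$. The square-root transform
stabilizes the strongly right-skewed rates; its cost is that the Gaussian
model admits negative $y$, which a rate cannot produce (see *Degenerate
values* below).

The linear predictor $\lambda^*$ is assembled from a registry of thirteen
nested structures (`model_registry()`), combining:

* **An hour-of-day effect** $\lambda_i$, $i = 1,\dots,24$, a 24-vector
  with the multivariate normal prior $\lambda \sim \mathrm{MN}(0, \Sigma)$
  where
  $$\Sigma_{ii'} = \exp\{-\nu \cdot \min(|i-i'|,\, 24-|i-i'|)\} / \psi .$$
  The distance is *circular*, so hour 24 (midnight) and hour 1 are one
  hour apart and the estimated daily curve closes smoothly on itself —
  a kernel on the clock rather than on the line, which avoids the
  artificial discontinuity at midnight that a non-cyclic formulation
  introduces. $\Sigma$ is circulant, so its eigenvalues are the discrete
  Fourier transform of its first row; the package uses that
  decomposition as a fast inverse and the tests check it against dense
  inversion. Depending on the model, the hour effect is pooled
  ($\lambda_i$), season-specific ($\lambda_{ir}$, four 24-vectors), or
  season-by-sex-specific ($\lambda_{irs}$, eight 24-vectors). All strata
  share one $(\nu, \psi)$ pair: the prior statement is a single scale and
  decay, and giving each stratum its own pair would add hyperparameters
  the hour curves cannot jointly identify at these sample sizes.
* **An individual random effect** $\omega_k \sim N(\alpha, \rho^2)$. The
  global level of the curves is carried by $\alpha$; the $\lambda$
  vectors keep their zero-mean prior, which is what softly identifies
  the split between level and shape.
* **Fixed sex/season terms**: sex and season main effects
  ($\mu_s + \gamma_r$), season only ($\gamma_r$), or their interaction
  ($\xi_{rs}$). Corner constraints are used throughout, with
  female-in-spring as the reference category, so reported coefficients
  are contrasts against that cell.
* **Anthropogenic distance effects**
  $\beta_j \exp(-\varphi_j x_j)$ for distances (km) to roads and
  settlements: either a combined block (any road $x_1$, settlements
  $x_4$) or a split block (primary $x_2$, secondary $x_3$, settlements
  $x_4$), optionally with season-specific $(\beta_{jr}, \varphi_{jr})$.
  The exponential form gives an effect that is largest on the feature
  and vanishes at distance; $3/\varphi$ is the *practical range*, the
  distance at which the effect has decayed to about 5%.

Priors are weakly informative: $N(0, 1000)$ (mean, variance) on
$\alpha$ and all fixed and $\beta$ coefficients; $\mathrm{Ga}(1,1)$ on
the precisions $1/\rho^2$, $1/\sigma^2$ and on $\psi$;
$\nu \sim U(3/24,\, 3)$ so the practical range of the hour covariance
lies between 1 and 24 h (needed to identify $\nu$ at all); and
$\varphi \sim U(3/4,\, 15)$, a practical range between 0.2 and 4 km.
`N(mean, variance)` is the convention everywhere; an engine that
parameterizes by precision would need the translation.

## Sampling

`diel_fit()` runs a Metropolis-within-Gibbs sampler written for exactly
this hierarchy (compiled core, R interface). Update blocks per sweep:

* each hour-effect 24-vector jointly from its Gaussian full conditional
  (precision $\psi C^{-1}(\nu) + \mathrm{diag}(n_{ci})/\sigma^2$);
* $\omega_k$, $\alpha$, each fixed coefficient and each $\beta$ from
  scalar conjugate normals; $1/\sigma^2$, $1/\rho^2$ and $\psi$ from
  conjugate Gammas;
* $\nu$ (log scale) and each $\varphi$ (natural scale) by random-walk
  Metropolis with reflection at their uniform bounds, step sizes adapted
  toward 0.35 acceptance by Robbins–Monro during burn-in only, so the
  post-burn-in kernel is fixed and detailed balance holds for every
  retained draw.

Two extra moves deal with the scale/shape funnels of the hierarchy,
which otherwise make $\psi$ and $\nu$ mix pathologically slowly (the
centered conditionals $\psi \mid \lambda$ and $\nu \mid \lambda$ are
extremely sharp because $\lambda$ carries 24–192 dimensions of
information about them):

* a **non-centered rescaling move** for $\psi$: a log-scale random-walk
  proposal that rescales every $\lambda$ vector by
  $\sqrt{\psi/\psi'}$, holding the whitened effects
  $\sqrt{\psi}\,\lambda$ fixed. In whitened coordinates the MN prior
  cancels and only the Gamma prior, Jacobian and likelihood change enter
  the ratio;
* a **non-centered reshaping move** for $\nu$: the companion proposal
  that maps $\lambda \mapsto L(\nu')L(\nu)^{-1}\lambda$ through the
  Cholesky factors, holding $L^{-1}\lambda$ fixed.

Both are standard interweaving-style fixes; the zero-data prior-recovery
test is what exposes the funnel and validates the fix (every prior
marginal, including $\psi$'s $\mathrm{Ga}(1,1)$ and $\nu$'s uniform, is
recovered by Kolmogorov–Smirnov checks on 2,000 thinned draws).

Weakly identified decays note: when a $\beta_{jr}$ is near zero its
$\varphi_{jr}$ conditional is nearly flat, and a reflected random walk on
a flat target accepts almost always. Near-1 acceptance for such a decay
is ideal mixing, not an adaptation failure; the 0.1–0.6 window is
expected (and tested) only for data-identified decays and for $\nu$.

Initialization is deterministic: location parameters at 0, variances at
1, $\nu$ and $\varphi$ at their prior midpoints. All randomness flows
through R's RNG, so a seed makes chains bit-reproducible. Two chain
protocols ship: the study-faithful default (2 chains, 50,000 burn-in,
20,000 kept with thin 10 → 2,000 draws per chain) and a `"desk"` profile
(burn 2,000 / keep 2,000 / thin 2) for interactive work and simulation
studies. Chains are pooled after burn-in for all reported summaries;
`gelman_rubin()` provides the PSRF across chains.

## Model comparison

`dic(fit)` computes the Deviance Information Criterion
$\mathrm{DIC} = \bar D + p_D$ with
$p_D = \bar D - D(\bar\theta)$, the deviance focused (conditional) on
all sampled parameters including the hour and individual effects — the
observed-data deviance a general Gibbs engine reports for this
hierarchy. $\bar\theta$ takes each parameter's posterior mean on its
sampled scale (the mean of $\sigma^2$, not of $1/\sigma^2$); this is a
documented choice, and with a different focus the absolute DIC shifts
while simulation checks show the *ranking* conclusions are what the
package relies on. `selection_table()` sorts fitted models by DIC with
$\Delta$DIC against the best, alongside each model's formula and its
count of season-interacting terms.

## Result surfaces

All summaries commit to one back-transform convention: curves are built
on the square-root scale *per posterior draw*, floored at zero, squared
to km/h, and only then averaged or quantiled. Squaring a posterior mean
would understate every curve (Jensen), and a property test enforces
that no summary does it. Credibility intervals are equal-tailed
2.5–97.5% quantiles everywhere, through the one shared routine.

* `hourly_curve()` evaluates the population-level predictor ($\alpha$ in
  place of an individual's $\omega_k$) per hour and stratum, with
  anthropogenic terms held at 4 km — effectively their asymptote given
  $\varphi \ge 0.75$. Passing `sex = NULL` averages the two sexes'
  back-transformed rates per draw: the 50:50 sex-ratio population curve.
  Averaging on the km/h scale is the default (a population average of
  rates); a sqrt-scale variant is available by flag. The default curve
  is a "typical-hour" activity index that excludes the residual variance
  $\sigma^2$; `include_noise = TRUE` gives the predictive-mean variant.
* `classify_active_hours()` calls an hour active when its posterior mean
  rate exceeds the across-hours mean of the curve, ties inactive — a
  per-hour threshold rule, which can legitimately produce
  non-contiguous active sets.
* `movement_rate_table()` reports posterior mean ± SD of rates averaged
  over the 24-h, active and inactive hour sets by sex and season
  (SDs are posterior SDs of the hour-set average).
* `anthropogenic_response()` traces the rate along a distance grid for
  one feature and season, other terms at their profile, and flags
  whether the 95% interval of the relevant $\beta$ excludes zero.

## The synthetic generator

Real relocation data of this endangered population are not public, so
the package ships a generator (`simulate_truth()`,
`simulate_records()`, `simulate_landscape()`) that emulates the study
design end to end: 18 collared adults (11 F / 7 M) by default, hourly
fixes across the March – mid-December active period split into the four
dietary seasons, per-hour fix-acquisition probability 0.88 (the middle
of the observed 79–97% range), and isotropic GPS error scaled so the
mean radial displacement is 24.7 m (per-axis sd $24.7/\sqrt{\pi/2}$,
from the Rayleigh mean). Each sampling day schedules 25 slots (00:00
through the closing midnight) so the 23:00→24:00 step is observable; a
movement record requires both endpoint fixes.

Default generating levels place the sqrt-scale predictor around
$\alpha = 0.55$ with hour-effect sd $1/\sqrt{\psi} = 0.125$
($\nu = 0.5$, a 6-h practical range), individual sd 0.1 and residual sd
0.29 — typical hourly rates of roughly 0.15–0.5 km/h, consistent with
the movement rates reported for this population, while keeping the
fraction of Gaussian draws truncated at zero under about 5%. Model 9
truths default to the published-scale season-specific distance
coefficients with decay 6/km (a 500 m practical range). Distance
covariates are log-uniform on 0.02–4 km by default, so inference tests
do not depend on geometry code; with a landscape, each bear walks with
random headings (re-drawn if a step would leave the extent, so the step
length always equals the movement rate) and covariates are the
distances at each step's origin.

What the generator does *not* emulate: home ranges, correlated
headings, autocorrelated behavioral states, habitat selection, or any
dependence of the covariates on behavior. Passing recovery tests
therefore shows the estimator works when its assumptions hold — it says
nothing about robustness to real movement autocorrelation.

**Degenerate values.** The Gaussian model admits $y < 0$ while a
sqrt-rate cannot be; the generator truncates such draws at zero, logs
the truncated fraction, and warns above 5%. This is a deliberate,
visible acknowledgment of a model misspecification the square-root
formulation carries.

## Numerical and design notes

* Hour attribution: a step from $t$ to $t+1$ h carries the hour index,
  season and covariates of its *starting* fix.
* Hour 0 (00:xx) maps to index 24; "mid-December" is fixed at
  December 15 inclusive; timestamps are interpreted in one fixed offset
  (no DST), preserving exact 1-h spacing.
* Outlier screening uses a symmetric speed filter (default 10 km/h,
  generous for bears): a fix is dropped only when the implied speed to
  *both* neighbours exceeds the threshold, so a single fast-but-real
  step never deletes a fix.
* The hourly standardization keeps, per animal-hour, the fix closest to
  the top of the hour (ties to the earlier fix).
* Settlements are represented as centroids, roads as polylines; all
  geometry is planar in meters (no geodesy).
* Corner constraints ($\mu_F = \gamma_{spring} = \xi_{spring,F} = 0$)
  rather than sum-to-zero: they match reference-category reporting.
* The recovery experiment in the acceptance tests (8 bears, ~4,700
  records, 20 replicates, desk profile) generates from the richest
  model at an elevated activity level ($\alpha = 1.15$, residual sd
  0.3). Two effects force this: at lower levels a visible fraction of
  draws is truncated at zero, so the data's residual variance is
  genuinely below $\sigma^2$ and "coverage of $\sigma$" stops being a
  meaningful check of the sampler; and at much smaller $\sigma$ the
  $\mathrm{Ga}(1,1)$ precision prior is no longer weak (it shifts
  $E[\sigma^2]$ by $2/\mathrm{SSR}$, ~3% at $\sigma = 0.12$ versus
  ~0.5% at $\sigma = 0.3$). The elevated level makes the generative
  model exact and the priors data-dominated, which is precisely what a
  sampler-validation experiment needs; other tests keep the realistic
  defaults.
* Test problem sizes (desk profile, ~4,000 MCMC sweeps; studies of
  2–8 bears over 4–32 sampled days) are the package's chosen
  simulation-study scale; the study-faithful chain protocol remains the
  fitting default.

## Limitations

* Movement rate is an activity *proxy*: stationary activities are
  invisible at 1 fix/h, and location error adds a rate floor.
* The level/shape split between $\alpha$, $\xi_{rs}$ and the stratum
  means of $\lambda_{irs}$ is identified only through the priors; the
  identified quantity is their sum (the activity curves), and
  hyperparameters $(\nu, \psi)$ are weakly identified in rich models —
  curves and $\beta$'s are what the recovery tests certify.
* DIC is reported with a conditional focus; rankings, not absolute
  values, are the supported inference.
* No ephemeris: sunrise/sunset markers on plots are user-supplied
  times, never computed.
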