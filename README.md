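# bearcadian

Bayesian hierarchical modeling of circadian activity from hourly GPS
telemetry, built around the movement ecology of brown bears in
human-dominated landscapes. The package is for movement ecologists who
have (or simulate) hourly relocation data and want to estimate *when*
animals are active over the 24-hour day, how that varies by sex and
dietary season, and how activity responds to proximity to roads and
settlements.

## The model

The activity index is the hourly movement rate (planar km between fixes
exactly 1 h apart); its square root is modeled as

```
y_tk = λ*_tk + ε_tk,   ε_tk ~ N(0, σ²)
```

where the predictor combines, depending on the model structure:

* an **hour-of-day effect** `λ_i` (i = 1..24), a 24-vector with prior
  `λ ~ MN(0, Σ)` and the *cyclic* covariance
  `Σ[i,i'] = exp(−ν · min(|i−i'|, 24−|i−i'|)) / ψ`,
  so midnight and 1 AM are neighbours and the daily curve closes on
  itself; optionally stratified by season (`λ_ir`) or season × sex
  (`λ_irs`);
* an **individual random effect** `ω_k ~ N(α, ρ²)`;
* **sex/season fixed effects** `μ_s`, `γ_r` or their interaction `ξ_rs`
  (reference: female in spring);
* **distance-decay anthropogenic effects** `β_j · exp(−φ_j · x_j)` for
  distances to all roads (x1), primary roads (x2), secondary roads (x3)
  and settlements (x4), optionally season-specific (`β_jr, φ_jr`).

Thirteen nested structures form a registry (`model_registry()`) and are
ranked by DIC. Inference is Metropolis-within-Gibbs with a compiled
core: conjugate Gibbs blocks for all Gaussian parameters and the
precisions, adaptive reflected random walks for `ν` and each `φ`, and
non-centered rescaling/reshaping moves that decouple `(ψ, ν)` from the
hour effects. See the methods vignette
(`vignettes/circadian-movement-models.Rmd`) for the full account.

## Worked example

A fully synthetic study (the package ships a generator emulating the
telemetry design: 1 fix/h over the March–mid-December active period,
~88% fix acquisition, 24.7 m mean GPS error), fitted with the richest
model at the light "desk" chain profile:

```r
library(bearcadian)

truth <- simulate_truth(model = 9, n_bears = 8, n_females = 5,
                        study_days = 40, seed = 42)
sim <- simulate_records(truth, seed = 42)
fit <- diel_fit(sim$records, model = 9,
                control = diel_control(profile = "desk", seed = 42))
print(fit)
#> Circadian movement-rate model 9: y = lambda_irs + omega_k + xi_rs + beta_2r*exp(-phi_2r*x2) + beta_3r*exp(-phi_3r*x3) + beta_4r*exp(-phi_4r*x4) + eps
#>   5889 observations, 8 animals; 2 chain(s) x 1000 draws (burn 2000, thin 2)
#>   parameter   mean    sd ci_low ci_high
#> 1     alpha  0.481 0.253  0.014   0.970
#> 2    sigma2  0.082 0.002  0.079   0.085
#> 3        nu  0.142 0.016  0.126   0.184
#> 4       psi 16.455 2.420 12.309  21.742
#> 5      rho2  0.307 0.186  0.114   0.785
```

`alpha` is the population mean of the individual effects on the
sqrt(km/h) scale, `sigma2` the residual variance on that scale (the
generating value here is 0.29² ≈ 0.084), `nu`/`psi` the decay and scale
of the cyclic hour covariance, `rho2` the between-individual variance.
The season-specific distance coefficients recover their generating
values (e.g. spring/primary-road `β` generated at 0.337):

```r
posterior_summary(fit, c("beta_x2_sp", "beta_x3_sp", "beta_x4_sp", "beta_x4_fa"))
#>    parameter       mean         sd     ci_low    ci_high
#> 1 beta_x2_sp  0.3380762 0.02956578  0.2847169  0.3982964
#> 2 beta_x3_sp  0.2448266 0.02651957  0.1949524  0.3006790
#> 3 beta_x4_sp  0.4149831 0.02261561  0.3726844  0.4633250
#> 4 beta_x4_fa -0.1631054 0.02606845 -0.2164167 -0.1157046
```

Result surfaces:

```r
cur <- hourly_curve(fit)                  # 50:50 sex-ratio population curve, km/h
part <- classify_active_hours(cur)        # above/below the 24-h mean rate
part$active
#> 5 6 7 8 9 10 11 16 19 22
round(part$threshold, 3)                  # km/h threshold
#> 0.45
dic(fit)
#> model 9: Dbar = 1965.0, pD = 172.3, DIC = 2137.3
resp <- anthropogenic_response(fit, season = "sp", feature = 2)
attr(resp, "ci_excludes_zero")            # spring primary-road beta
#> TRUE
```

`plot(fit)` draws the hourly curve with its 95% credibility band;
`movement_rate_table(fit)` gives mean ± SD rates by sex × season ×
(24-h / active / inactive); `selection_table(lapply(fits, dic))`
produces the DIC ranking.

A subcommand CLI (`simulate`, `preprocess`, `fit`, `select`,
`summarize`) ships in `inst/cli/bearcadian` over the same functions,
with YAML config support; preprocessing turns raw fix tables
(CSV `animal_id,sex,timestamp,x,y`, meters, ISO-8601) and GeoJSON
road/settlement layers into the observation table via hourly
standardization, symmetric-speed outlier screening, movement rates and
distance covariates.

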