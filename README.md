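# contactRSF

Landscape drivers of direct contact between GPS-tracked animals.

Do animals make contact where they like to be, or somewhere else? A
common shortcut in disease ecology and behavioral ecology treats the
spatial overlap of individual habitat selection as a proxy for where
contacts between animals occur. `contactRSF` implements a framework
that tests this assumption instead of making it: it detects direct
contacts (simultaneous co-location within a GPS-error buffer) from
continuous-time movement-model interpolations of telemetry, fits a
**contact resource selection function** — a used-available logistic
model in which "used" points are the locations where a dyad made
contact and "available" points are the locations the dyad visited
without contact inside their shared range — and compares the
population-level contact-RSF against the aggregated individual-level
RSF of the same animal pairs.

It is aimed at movement and disease ecologists working with collared
populations (the motivating systems are socially structured wild pig
populations, but nothing is species-specific).

## The model

For animal *i*, positions are modeled as an isotropic Gaussian process
per coordinate from the IID / OU / IOU / OUF family, fitted by exact
Kalman-filter maximum likelihood and selected by AIC; the conditional
mean (kriging) discretizes each trajectory to a regular 5-minute grid.
A direct contact is a shared grid timestamp with inter-animal distance
≤ 10 m. Female–female dyads are classified by weekly 50% kernel
core-area overlap (within-group if the tracking-period mean exceeds
0.5, temporarily merged if a season-length run exceeds it, between-group
otherwise); male–male and female–male dyads are assumed between-group.
Between-group pairs with more than 10 contacts enter the analysis.

Both RSFs are used-available logistic regressions

  logit P(used) = β₀ + **β**·**x**,  w(**x**) = exp(**β**·**x**)

with 30 available points per used point: availability is the 95% kernel
home range (individual model) or the dyad's home-range overlap (contact
model, capped at 1:30). Covariates are screened for collinearity
(|r| ≥ 0.6), continuous ones standardized. The model structure is
selected by cumulative-log-likelihood AIC across animals; contact
models inherit the top individual structure. Population coefficients
are Murtaugh-weighted means (individuals: pair multiplicity × sample
size; pairs: contact count) with SE(β̄) = √Σwᵢ²SEᵢ², validated by
fivefold cross-validation of area-adjusted used-point frequency
(Spearman r_s). Because no public telemetry accompanies the method, the
package includes a fully tested synthetic module (landscape stack,
OU movement with resource steering, ground-truth contact log).

## Worked example

The built-in dissociation scenario states a world in which movement
ignores artificial food entirely while contacts, given presence, prefer
food cells with odds ×3 — the situation the framework is designed to
expose:

```r
library(contactRSF)
scn <- scenario_dissociation(seed = 1)   # 4 animals, 2 groups, 14 days
fit <- scenario_fit(scn)
fit$pop_individual
#> <population_rsf: 4 owners>
#>          term    beta     se   ci_lo   ci_hi
#> 1 (Intercept) -3.4090 0.0131 -3.4347 -3.3832
#> 2        food -0.0135 0.0263 -0.0650  0.0380
#> 3 tree_canopy -0.1526 0.0116 -0.1754 -0.1298
fit$pop_contact
#> <population_rsf: 4 owners>
#>          term    beta     se   ci_lo   ci_hi
#> 1 (Intercept) -3.3152 0.0661 -3.4447 -3.1856
#> 2        food  1.2074 0.0953  1.0205  1.3942
#> 3 tree_canopy -0.2086 0.0507 -0.3080 -0.1093
compare_rsf(fit$pop_contact, fit$pop_individual, scn$env, scn$env$dates[1])
#> <comparison_report>
#>    covariate beta_contact beta_individual  difference sign_contact
#>         food    1.2073813     -0.01349098  1.22087223            +
#>  tree_canopy   -0.2086392     -0.15257874 -0.05606046            -
#>  sign_individual sign_agreement
#>                0          FALSE
#>                -           TRUE
#> surface correlation: Spearman 0.511, Pearson -0.068
```

Reading this: the individual-level food coefficient is null
(−0.01, CI covers 0 — the animals do not select for bait), while the
contact-level food coefficient is 1.21 ≈ ln 3 with a CI far from 0,
recovering the simulated ×3 contact odds; the sign-agreement flag marks
food as discordant. Aggregated individual selection would have missed
the contact hotspot entirely.

The full pipeline (simulate → fit CTMMs → interpolate → detect →
classify → filter → individual RSFs → select → contact RSFs → aggregate
→ compare) runs from one seeded configuration and writes every artifact
plus a hash manifest:

```r
cfg <- run_config(out_dir = "run1", seed = 1)
run_pipeline(cfg)
```

or from the command line with
`Rscript inst/cli/contact-rsf.R run --config inst/extdata/example_config.yaml`.
Stages are individually re-runnable; resumed runs are byte-identical to
uninterrupted ones.

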