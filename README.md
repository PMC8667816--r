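# mitoquant

Quantitative analysis for characterising small-molecule inhibitors of the
kinetochore–microtubule interface. The package covers the full measurement
chain used in such a campaign — from triaging a structure-based virtual
screen to single-molecule kinetics and cell-population phenotypes — and
pairs every estimator with a seeded synthetic-data generator so that each
method can be validated by parameter recovery at realistic sample sizes.

It is aimed at chemical biologists and quantitative microscopists who have
score matrices, titrations, kymograph-derived event tables, kinetochore
tracks or live-cell fate annotations in hand and want tested, reproducible
estimates out.

## What it computes

| Module | Method |
|---|---|
| `screen` | Per-scoring-function Z-scores, `z = (s − s̄)/SD`, and consensus hit voting: Z < −3 in ≥ 3 of the functions, after MW ≤ 500 Da / nitro pre-filters |
| `binding` | One-site binding with ligand depletion: `f_b = [(P+L+K_d) − √((P+L+K_d)² − 4PL)]/2L`, fitted to anisotropy titrations for K_d |
| `smkinetics` | Left-truncated exponential MLE for the off-rate k_off (censoring-aware), and weighted MSD line fits, MSD(τ) = 2Dτ + c, for the 1D diffusion constant |
| `ktdyn` | Rapid-movement velocity with the ≥ 10 um/min exclusion, oscillation amplitude as SD of the pole-projected position, inter-kinetochore distance, Welch comparisons |
| `popassay` | Mitotic/death index time courses, per-cell fate fractions and arrest durations, 4PL EC50 fits, Bliss excess-over-additivity |
| `synth` | Seeded generators for all of the above (exponential dwells + Brownian motion, depletion isotherms, oscillating sister pairs, score matrices with planted binders, fate tables, 4PL dose-response) |

## Worked example: does the compound shorten residence on microtubules?

Simulate two single-molecule TIRF experiments at the sample sizes of a
typical campaign (581 control and 483 drug-treated events), extract dwell
times, and fit the off-rates:

```r
library(mitoquant)

ctrl <- gen_tirf_events(k_off = 0.47, n_events = 581, condition = "control", seed = 101)
drug <- gen_tirf_events(k_off = 0.79, n_events = 483, condition = "treated", seed = 102)

fit_c <- fit_koff(dwell_times(ctrl))
fit_d <- fit_koff(dwell_times(drug))
fit_c
#> Single-exponential dwell-time fit
#>   k_off = 0.4877 +/- 0.02045 s^-1 (mean residence 2.05 s)
#>   n = 572 events (3 censored), policy = mle, t_min = 0.1 s
fit_d
#> Single-exponential dwell-time fit
#>   k_off = 0.7907 +/- 0.03671 s^-1 (mean residence 1.26 s)
#>   n = 465 events (1 censored), policy = mle, t_min = 0.1 s

cmp <- compare_koff(fit_c, fit_d)
#> z = 7.21, p = 5.6e-13
```

The fitted rates recover the generating truths (0.47 and 0.79 s^-1) within
their standard errors, and the z-test shows the residence time is
significantly shorter under treatment. The same event tables yield the
diffusion constant from the MSD line:

```r
fit_diffusion(msd(ctrl))
#> Linear MSD fit (1D: slope = 2 D)
#>   D = 0.0142 +/- 0.000148 um^2/s, intercept = 0.0011 um^2
#>   fitted over 5 lags up to 0.5 s
```

(The intercept of ~0.001 um^2 is the localisation-noise floor,
2 × 0.02² um². The SEM-weighted SE understates seed-to-seed scatter
slightly because overlapping-window displacement pairs are correlated;
recovery is unbiased, as the test suite checks over 30 replicates.)

And a binding titration (ligand 5 uM, protein 1–15 uM) gives the
dissociation constant under ligand depletion:

```r
fit_kd(gen_anisotropy(K_d = 2.07, noise_sd = 0.003, seed = 103))
#> One-site binding fit with ligand depletion
#>   K_d     = 2.133 +/- 0.1663 uM
#>   r_free  = 0.04894, r_bound = 0.2521
#>   n = 45 points, RSS = 0.000314, converged = TRUE
```

See `vignette("mitoquant-methods")` for the models, defaults and numerical
choices (including the half-frame dwell correction and why the 4PL bottom
is fixed at zero by default).

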