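---
title: "Models and estimators behind mitoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators behind mitoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoquant)
```

mitoquant implements the quantitative workflow used to characterise a
small-molecule inhibitor of the Ndc80 complex, the outer-kinetochore
assembly that couples chromosomes to spindle microtubules: consensus triage
of a structure-based virtual screen, binding-constant determination by
fluorescence anisotropy, single-molecule TIRF kinetics of the complex on
microtubules, kinetochore-dynamics metrics in live cells, and
cell-population assay summaries. No raw microscopy or plate data are
shipped; instead each assay has a seeded generator that produces tables
with the statistical structure the estimator assumes, so every method is
validated by parameter recovery at realistic sample sizes. This vignette
explains the models, the defaults, and the design decisions.

## Docking-score consensus triage (`prefilter`, `zscore_matrix`, `select_hits`)

A virtual screen docks a vendor library into a target structure and
rescoreses each pose with several scoring functions (six by convention:
the docking engine's native score plus shapegauss, plp, chemgauss3,
chemscore and screenscore). Scales differ across functions, so each column
is standardised to a Z-score, $z = (s - \bar{s}) / \mathrm{SD}(s)$, using
the sample SD ($n-1$; conventional for screen statistics). A compound is
nominated when $z < -3$ — strictly — in at least three functions.

Decisions worth spelling out:

* **Filter, then normalise.** Property filters (molecular weight $\le$ 500
  Da, with the boundary kept because only weights *greater than* 500 are
  excluded; no nitro groups) run before docking in practice, so the scored
  population is the filtered one. The pipeline fixes the order
  `prefilter()` then `zscore_matrix()`; the tests assert that reversing it
  changes column means.
* **Sign convention.** All six functions are treated as "lower = better",
  the convention of exhaustive rigid-docking engines; a `sign_map`
  argument flips any function that scores in the opposite direction.
* **Deterministic ranking.** Screens end with a manual pose inspection
  that cannot be automated; `select_hits()` instead ranks by number of
  passing functions, then by the sum of passing Z-scores, so re-runs are
  reproducible.
* Nitro detection is consumed as a boolean column rather than computed
  from structures, which keeps the package free of a chemistry toolkit
  dependency.

With six independent Gaussian columns the voting rule's false-positive
probability is $P(\ge 3\ \text{of}\ 6\ z < -3) \approx 5\times 10^{-9}$
per compound, which the tests confirm as zero hits in a 10^4-compound
plant-free matrix.

## Anisotropy binding isotherm (`fb`, `fit_kd`)

Fluorescence anisotropy reports the tumbling rate of a fluorescent ligand:
binding to a large protein raises it. With the ligand at 5 uM and protein
titrated over 1–15 uM, free and total ligand differ materially, so the
simple hyperbolic isotherm is wrong and the mass-action quadratic is
required. The bound fraction of ligand is

$$f_b = \frac{(P + L + K_d) - \sqrt{(P + L + K_d)^2 - 4 P L}}{2L},$$

evaluated internally as $2P / (b + \sqrt{b^2 - 4PL})$ with
$b = P + L + K_d$ to avoid catastrophic cancellation at large $K_d$; the
tests verify agreement with an independent free-ligand root-finder to
$10^{-10}$. Observed anisotropy is the linear mix
$r = r_\mathrm{free} + (r_\mathrm{bound} - r_\mathrm{free}) f_b$ — no
intensity (quantum-yield) weighting is applied because no intensity change
on binding is modelled. `fit_kd()` runs bounded Levenberg–Marquardt least
squares over $(K_d, r_\mathrm{free}, r_\mathrm{bound})$ with $K_d \ge 0$
on the natural scale (so the reported SE is in concentration units),
replicates fitted individually, and data-driven starts
($r_\mathrm{free} = \min r$, $r_\mathrm{bound} = \max r$,
$K_d = \mathrm{median}(P)$). A flat titration leaves $K_d$ unidentifiable;
that surfaces as a failed convergence flag or an SE far exceeding the
estimate, never as an exception. `negative_control_check()` encodes the
control-protein logic: no binding when the anisotropy–concentration slope
is indistinguishable from zero at $\alpha = 0.05$ or the fitted span is
strictly below a floor (default 0.02 anisotropy units).

At a ligand concentration of 5 uM and $K_d \approx 2$ uM the titration is
only weakly identifying — the depletion regime flattens the curvature that
separates $K_d$ from the endpoints — which is why noisy-replicate recovery
is validated on the median of many fits (within 15% at measurement noise
0.003) rather than per-fit.

## Single-molecule TIRF kinetics (`dwell_times`, `fit_koff`, `msd`, `fit_diffusion`)

In the TIRF assay, GFP-tagged complexes at picomolar concentration bind
Taxol-stabilised microtubules; each kymograph streak is one binding event
with a residence time and a 1D diffusive excursion along the filament.

**Dwell times.** An event's dwell is `last frame − first frame + one frame
interval`, so a single-frame detection contributes one full frame. Events
shorter than `t_min` (default one frame interval, the detection floor of
0.1 s-scale imaging) are discarded but counted; the generator likewise
keeps sub-frame landings in its ground truth with zero observed frames.

**Off-rate.** The single-exponential fit is performed as a
maximum-likelihood fit of a left-truncated exponential on unbinned dwells.
With censored events dropped the MLE is the closed form
$\hat{k} = 1/(\overline{t} - t_0)$; with `censoring = "mle"` (default)
events that reach the movie end contribute survival terms
$e^{-k (t - t_0)}$ and the score equation is solved numerically. The SE is
$\hat{k}/\sqrt{n_\mathrm{uncensored}}$ from the observed Fisher
information. A binned log-linear histogram fit is included purely as a
cross-check. One numerical subtlety matters at these rates: dwells are
quantised to the frame grid, and for a continuous-exponential likelihood
the effective truncation point of a quantised dwell is half a frame below
the nominal cutoff. When the frame interval is known, `fit_koff()`
therefore uses $t_0 = t_\mathrm{min} - \Delta t/2$. Without this midpoint
correction the estimator carries a $+\mathcal{O}(k^2 \Delta t /2)$ bias
(about +0.01 s^-1 at $k = 0.47$, $\Delta t = 0.1$ s) that is detectable
at the study's sample sizes; with it, 200-replicate recovery at
$n = 581$ and $n = 483$ events is unbiased within Monte-Carlo error.
Conditions are compared with a two-sided Gaussian z-test on the rate
difference.

**Diffusion.** The mean-squared displacement pools squared displacements
over all events and all start frames (overlapping windows), reporting
mean, SEM and pair count per lag. The fit is weighted least squares of
$\mathrm{MSD}(\tau) = 2 D \tau + c$ over the first 5 lags (lag range
capped at 25% of the longest event to keep censoring-induced curvature out
of range; both knobs configurable). The slope-to-$D$ factor is 2 because
motion is parameterised along the filament axis. The intercept absorbs
localisation noise ($c \approx 2\sigma_\mathrm{loc}^2$); the tests verify
that adding 0.02 um noise moves the intercept by that amount and the slope
not at all. A negative slope yields $D = 0$ with a warning flag rather
than a negative constant.

**What the generator emulates — and does not.** Events land uniformly in
time, dwell exponentially, and diffuse with reflecting boundaries at the
filament ends (reflection preserves displacement statistics away from the
ends; the default 15 um filament makes edge effects negligible at
$D \approx 0.02$ um^2/s over the fitted lags). Not modelled:
photobleaching (no correction is applied downstream either), detection
dropouts mid-event, multi-exponential dwell mixtures, and the image-level
noise of real kymographs — recovery tests therefore validate the
estimators, not a spot-tracking pipeline.

## Kinetochore dynamics (`kt_rapid_speeds`, `kt_oscillation`, `kt_distance`)

Sister-kinetochore tracks from cells expressing a fluorescent kinetochore
marker are analysed relative to one spindle pole: the working coordinate
is the scalar distance from the pole, which makes every metric invariant
under rigid motions of the cell (asserted by tests).

* **Rapid velocities.** Per-step speeds $|\Delta d| / \Delta t$ (um/min)
  at 5 s sampling; steps slower than 10 um/min are excluded and the mean
  of the survivors is reported per kinetochore (absent when none survive).
  The rule is idempotent. The per-kinetochore means are then summarised
  per condition. The generator's `drift_speed` models the directed,
  laterally sliding movements these measurements target.
* **Oscillation amplitude.** "Deviation from average position" is
  implemented as the sample SD of the projected position — the paper-style
  quantity names the deviation but not the estimator, and the SD is the
  scale parameter that converges to $A/\sqrt{2}$ for a sinusoid of
  amplitude $A$, giving a closed-form recovery target.
* **Inter-kinetochore distance.** Euclidean sister separation averaged
  over frames where both sisters are visible; frames with one sister
  contribute to amplitude but not distance. Isotropic positional noise
  biases the mean distance upward (a Rice-distribution effect) — the tests
  match this against a Monte-Carlo oracle rather than pretending it away.
* **Condition comparisons** use Welch's t-test (unequal variances
  expected between drug conditions); singleton conditions are summarised
  without a test.

The generator places sisters collinearly with the pole on the spindle
axis, a near-axis approximation that keeps the projected rest distance
exact; real metaphase plates have off-axis pairs for which pole-distance
projection slightly compresses oscillations.

## Population assays (`fate_fractions`, `index_timecourse`, `fit_ec50`, `combination_excess`)

Long-term films are consumed as per-cell event tables (entry into mitosis,
exit, fate); image scoring itself is out of scope. Fate fractions are
percentages over non-censored cells; arrest duration is `exit − entry`
summarised as mean ± sample SD. The mitotic index is instantaneous (in
mitosis at $t$; a cumulative option exists), the death index cumulative,
and both are validated against brute-force interval membership. Arrest
durations are generated as a Gaussian truncated at zero — the source data
report only mean ± SD, and truncation is the minimal positivity fix; it
shaves a few percent off the realised SD at 11.5 ± 5.5 h, which the
recovery tolerances accommodate.

Dose-response curves use the four-parameter logistic
$y = \mathrm{bottom} + (\mathrm{top} - \mathrm{bottom}) /
(1 + (c/\mathrm{EC50})^{h})$, fitted on log10-concentration with
$\log_{10}\mathrm{EC50}$ as the parameter (well conditioned across the
4+ decades of a 1 nM–20 uM series) and the SE delta-method transformed
back. The hill slope and top are free. The lower asymptote is fixed at 0
by default: with seven concentrations ending at 20 uM and EC50s of
5–20 uM, the lower plateau is never observed, and a free bottom makes the
curve unidentifiable — recovery error is then limited by information, not
by the optimiser (it does not improve when started at the truth). A
background-corrected viability signal vanishes at complete kill, which is
exactly the constraint; `fix_bottom = NULL` restores the fully free 4PL
for assays that do reach their floor. Unidentifiable fits (e.g. flat
response) are flagged via the convergence flag, which also trips when
$\log_{10}\mathrm{EC50}$ is determined to worse than ±2 decades.

Combination effects are screened against a Bliss-independence null,
$E = A + B - AB/100$ for indices in percent — chosen because "more than
additive" needs a null, and Bliss is the standard one for probabilistic
endpoints like being in mitosis; a capped plain-additive mode is provided
for comparison, and replicate wells feed a bootstrap interval on the
excess.

## Numerical and testing choices

* Every generator is a pure function of its parameters and an explicit
  seed (`withr::local_seed`, no hidden global state); fixed seed means
  byte-identical tables. Ground truth (censoring flags, plant labels, true
  fates) always travels with the data.
* Recovery tests run at the study's own scales: 581/483 events over 200
  replicate fits for the off-rates, 30 replicates for the diffusion pair,
  200 noisy titrations for $K_d$, 85 pairs for oscillation metrics, 13
  kinetochores for velocities, 75 cells for fates, 50 assays per EC50
  truth. Moment checks (dwell mean, step-displacement variance) use
  $10^5$-sample simulations against 3-SE bands.
* Oracles are kept independent of the code paths they check: exhaustive
  enumeration for the voting rule, free-ligand root-finding for the
  isotherm, closed forms for truncated-exponential MLEs and sinusoid SDs,
  brute-force interval counts for the indices, Monte-Carlo for the Rice
  bias.

## Limitations

The generators are deliberately minimal: single-exponential dwells, pure
Brownian 1D diffusion, sinusoidal oscillations with a shared period,
Gaussian noise everywhere. Passing recovery tests demonstrates that the
estimators are correct and calibrated under these assumptions — not that
real kymographs, titrations or films satisfy them. In particular, no
photobleaching correction exists anywhere in the dwell pipeline, the MSD
fit includes its intercept rather than testing for anomalous diffusion,
and the screen module begins at the score matrix (docking and pose
generation are upstream, out of scope).
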