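---
title: "Methods: interlimb phase, load distribution, and their coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interlimb phase, load distribution, and their coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitphase)
```

This vignette documents the models, the numerical choices, and the design
decisions behind `gaitphase`. It states no empirical result that the test
suite does not itself compute.

## Coordinate conventions

All trajectories follow the left side-view image convention: the horizontal
coordinate `x` increases **rearward**, so a foot drifts up in `x` during
stance (it moves with the belt) and snaps down during swing. Peaks of the
foot trajectory therefore mark **swing onsets** and troughs mark **stance
onsets**; a stride is the half-open interval between consecutive swing
onsets, and the trailing partial stride is truncated at the final swing
onset. The snout-hump angle defines forward as `-x`. Generated recordings
are expressed in surface-parallel coordinates (the cameras tilt with the
rig), so posture angles on synthetic data are computed with `slope = 0`.

## Stride segmentation and interlimb phase

`segment_strides()` detects peaks with two scale-free defaults: the minimum
inter-peak period is half the dominant period found by autocorrelation of the
mean-subtracted trajectory, and the minimum prominence is 20% of the
trajectory range. Both are exposed as arguments; there are no hidden
constants. Constant or near-flat series yield an empty segmentation rather
than an error. A peak at the very first or last sample is undetectable
(there is no flank on one side), so a bout with `n` generated stride periods
typically yields `n - 1` or `n - 2` complete strides.

`relative_phase()` computes the mean-subtracted cross-correlation of the
non-reference against the reference trajectory over **integer** delays in
`[-d/2, d/2]` for a stride of `d` frames, and returns `2π·ℓ*/d` wrapped to
`[-π, π)`. Positive phase means the other limb lags the reference. Ties at
the correlation maximum break deterministically toward the smaller `|lag|`;
there is no sub-frame interpolation, so the estimator is quantized to one
lag, `2π/d` (≈ 0.025 π rad at 400 fps and 0.2 s strides). Windows that leave
the bout are padded with edge values; a zero-variance window flags the
stride as undefined and drops it. Mean subtraction is the default and can be
disabled (`mean_subtract = FALSE`); raw correlation of strictly positive
position signals would be dominated by the DC term, which is why the
mean-subtracted form is the default.

Phases are computed per tracked landmark (two per foot) and a stride is kept
only if the two landmark phases agree within 0.1 π rad on the circle
(`consistency_filter()`); kept pairs are circularly averaged. When the fore
and hind waveforms have different duty factors their shapes differ, and the
cross-correlation argmax acquires a small waveform-shape bias (about 1–2
lags under the default generator settings). This bias is constant within a
condition and cancels exactly in phase *differences*, which is what the
downstream regression and CoS composition consume; the one-lag recovery
tests therefore use matched duty factors.

Hindlimb phase categories use fixed bands: alternating `|φ| ≥ 0.8π`,
synchronized `|φ| ≤ 0.2π`, otherwise asymmetric with the leading side from
the sign.

## Circular statistics

**Kernel density.** `vm_kde()` averages von Mises kernels (default κ = 10 on
a 200-point grid, both chosen as the package defaults for smooth but
resolved phase distributions) and renormalizes by the periodic trapezoid so
the circular integral is 1 to 1e-6.

**Mixtures.** `fit_vm_mixture()` runs EM for 1–4 components from five seeded
restarts (first restart: means spread evenly around the data's mean
direction; later restarts: means sampled from the data). Concentrations come
from the Best–Fisher approximation to the inverse of `A₁(κ) = I₁/I₀` and are
capped at κ = 500 to guard against degenerate clusters; capped fits are
flagged. Model selection minimizes BIC with ties resolved toward fewer
components — an information criterion chosen because EM is not
posterior-based, replacing the posterior-predictive criterion a Bayesian
fitter would use. The EM log-likelihood trace is stored and asserted
non-decreasing in the tests. Unimodality holds when (1) one component is
selected, (2) the dominant component holds ≥ 80% of the weight, or (3) two
components jointly hold ≥ 80% and their means differ by < 0.2 π.

**Circular-linear regression.** `circ_linear_regression()` maximizes the von
Mises likelihood with mean link `μ(x) = μ₀ + 2·atan(βᵀx_c) + offset_group`,
covariates centered internally (the saturation midpoint is absorbed into the
centering) and per-group offsets constrained to sum to zero. This is a
deliberate likelihood-based replacement for a Bayesian projected-normal
mixed model: it preserves the same scientific contract — the direction and
significance of covariate effects on a circular response with per-animal
variation — at desk scale. Optimization is BFGS with analytic gradients;
κ is parameterized on the log scale; the intercept-only, no-group case is
solved in closed form (circular mean and `A₁⁻¹` of the resultant).
Covariates with variance inflation factor above 5 are dropped with a
warning before fitting; a design still rank-deficient afterwards is an error
naming the aliased columns. Intervals come from a case-resampling bootstrap
that resamples groups (mice) with replacement and then strides within each
resampled group (default 500 replicates; percentile intervals); a
coefficient is significant when its interval excludes zero, mirroring an
interval-excludes-zero posterior criterion. An optional two-stage mode
(`circ_regression_by_group()`) fits per mouse and pools slopes, as a
conservative alternative to shared-slope fitting.

Autocorrelation between consecutive strides of a bout is not modeled
explicitly; the cluster bootstrap absorbs within-mouse dependence, and
fitting to random subsamples remains available to the user by subsetting the
stride table before fitting.

## Load analysis

Standstill detection uses rolling 1 s windows and requires the total-load
coefficient of variation below 5% (configurable; the duration threshold of
5 s is the only criterion inherent to the analysis, the CV rule is this
package's operationalization of "standing still"). Weight fractions are
channel means over the longest qualifying window. The CoS index is the exact
fore-minus-hind (and right-minus-left) formula; the cm-valued CoS is the
load-weighted mean of per-trial static foot positions — when no geometry is
available only the dimensionless index is reported. On slopes only the
vertical force component is measurable, so detectable weight is
`cos(θ)·weight` and the offload fraction is `1 − detected/(cos(θ)·weight)`.

Weight-adjusted head height is `(height − 24.5)/(1.25·weight)`, the height
normalized by the weight-scaled maximum comfortable height
`24.5 + 1.25·weight` (mm, g); the identity `value = 1` at the maximum holds
for all weights and is asserted in the tests.

Saturating trends are fit with `y = A − B·e^(−kx)` by Levenberg–Marquardt
least squares, initialized empirically: `A` from the observed maximum, `B`
from `A` minus the `y` at the smallest predictor, `k` as the inverse mean
predictor. A near-constant response returns `A ≈ mean(y)`, `B = 0` and an
unidentifiable (NA) rate with `converged = FALSE`.

## Support patterns and lateralization

The 16 raw limb-contact states are grouped into 8 categories (four-limb,
three-limb, diagonal pair, homologous fore/hind pair, homolateral pair,
single limb, no contact); the raw 16-state fractions are attached for
transparency since the grouping, while natural, is not canonical. Fractions
are computed per reference-limb stride (not fixed time windows). PCA is
centered but not standardized — the fractions share units — with a
correlation-mode alternative left to the user via prior scaling; loading
signs are fixed by forcing each component's largest-magnitude entry
positive, so loading matrices are comparable across runs. Components are
retained until 90% cumulative variance. PC projections are related to
posture covariates by linear mixed models with per-mouse intercepts
(`lmerTest`), falling back to ordinary least squares below three mice.

The lateralization classifier is a linear-kernel support-vector machine
(cost 1; kernel and cost configurable — the margin classifier family is
fixed, its kernel was an open choice and linear is the most interpretable
for 2-D sin/cos features) on sine/cosine phase features, with a 75/25
train/test split stratified by mouse and label and training balanced by
subsampling to equal label counts within each mouse. Stratum iteration is
ordered by content rather than label name so that mirrored relabelings
consume the random stream identically — this makes the
mirror-plus-relabel invariance exact, not just distributional. Significance
uses an add-one permutation estimator, `p = (1 + #{perm ≥ obs})/(1 + n)`,
whose smallest attainable value is `1/(n+1)`.

## The synthetic generator

`cohort_config()` holds every tunable with units. The defaults describe the
study conditions the package targets: 400 fps side-view tracking, 0.2 s
stride periods, duty factors 0.60 (hind) and 0.55 (fore), tracking noise
0.5 mm (between typical train and test tracking errors of a pose network),
2% likelihood dropouts, per-mouse phase offsets with SD 0.05 π rad, and
homolateral concentration κ = 8 (circular SD ≈ 0.12 π, matching the spread
of per-condition phase distributions in head-fixed locomotion).

The covariate link of the generator equals the regression link,
`μ = μ₀ + 2·atan(β_a(angle − 160°) + β_s·slope + β_v(speed − 20))`, so that
parameter recovery is well-posed. Its default coefficients are chosen to
embed one coherent physiology: a quarter-phase (0.25 π rad) synchrony gain
per 0.4 cm posterior CoS shift, composed with linear CoS sensitivities of
−0.027 cm/deg (snout-hump angle) and −0.0096 cm/deg (surface slope). This
gives `β_a = −0.0265` rad/deg and `β_s = −0.0094` rad/deg, with `μ₀ = 0.8π`
at the 160° link midpoint — alternation at hunched postures saturating
toward partial synchrony at upright ones. The speed coefficient is small
(−0.0005 rad per cm/s) so that speed effects stay below 0.1 π across the
speed range, as intended for a paradigm that decouples speed from load.

Head height maps to snout-hump angle curvilinearly,
`180° − 36°·e^{−(h−32)/12}`, approaching the 180° asymptote at high head
positions; because the phase link is linear in angle and the angle is
exponential in height, the implied forelimb load fraction is automatically
of the form `A − B·e^{−kh}` with `k = 1/12 ≈ 0.083` per mm. Load trials add
per-channel Gaussian noise (SD 1% of body weight), a 0.5 ± 0.01 left/right
split, a head-post offload growing to 15% at the highest head position (plus
a decline-driven component), and a 2 s movement lead-in with non-cancelling
channel sway so standstill detection has something to reject.

One global seed expands to per-trial seeds by the documented counter scheme
`seed + 1000·mouse + trial`; per-mouse random offsets are drawn once from
the master seed so all trials of a mouse share one offset. Trajectory trials
draw **one** phase per limb per trial (a constant delay keeps the waveform
continuous); the per-stride phase layer used for regression-recovery
experiments is `simulate_phase_cohort()`, which draws a fresh phase per
stride from the same link. Vertical (y) foot excursion is cosmetic — a swing
arc that segmentation never consumes.

What the generator does **not** emulate: photorealistic appearance,
optogenetic latency dynamics, falls, head-free head pitch, within-trial
phase drift, and autocorrelated stride-to-stride dynamics. Passing tests
therefore demonstrate the correctness of the estimators under the stated
generative assumptions, not robustness to every artifact of real video
tracking.

## Problem sizes in the test suite

The suite validates parameter recovery at the study's scale where that scale
matters and at reduced scale elsewhere: regression interval coverage uses
12 mice × 500 strides over 20 seeded replicates with 100 bootstrap
replicates per fit; the end-to-end CoS composition uses 6 mice × 15
conditions × 25 strides at 400 fps with 100 bootstrap replicates; mixture
recovery uses 2000 draws; null calibration of the classifier uses n = 5000
(chance accuracy) and twenty n = 400 replicates with 99 permutations
(p-value calibration). Orchestration tests run a 2-mouse cohort at 200 fps.
Bootstrap and permutation counts are resampling resolutions, not scientific
parameters; the package defaults are 500 and 1000 respectively.

## Known limitations

- The cross-correlation phase estimator carries a waveform-shape bias when
  limbs differ in duty factor; absolute phases are accurate to ~2 lags,
  phase differences to one lag.
- The ML regression treats per-mouse effects as additive offsets; random
  slopes are available only through the two-stage mode.
- The CoS map assumes the covariate→CoS relation measured during standstill
  transfers to locomotion; the package composes the two fits but cannot test
  that assumption from synthetic data that builds it in.
- TOML support covers the flat dialect the package writes (scalars, flat
  arrays, dotted sections), not the full TOML specification.
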