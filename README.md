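# gaitphase

Quadrupedal interlimb coordination analysis for head-fixed mouse locomotion:
from pose-tracking trajectories and load-cell traces to interlimb phase
distributions, center-of-support biomechanics, circular-statistical models of
phase versus posture, slope and speed, limb-support-pattern decomposition, and
a permutation-tested classifier of phase lateralization.

## The scientific problem

Quadrupeds adjust their gait with speed, but gait also responds to how body
weight is distributed over the legs. On a passive treadmill with the head
fixed at an adjustable height, raising the head (or inclining the surface)
shifts the **anteroposterior center of support (CoS)** — the load-weighted
position of the four feet — toward the hindlimbs. The question this toolkit
addresses is how such load redistribution changes **homolateral phase**: the
timing of a forelimb within the step cycle of the hindlimb on the same body
side, expressed on the circle (0 = synchrony, π = strict alternation).

The pipeline quantifies, per stride of a reference limb:

- **Interlimb phase** `φ = 2π·ℓ*/d`, where `ℓ*` is the argmax lag of the
  mean-subtracted cross-correlation between the two feet's horizontal
  trajectories over delays in `[-d/2, d/2]` for a stride of duration `d`;
  strides whose two per-foot landmarks disagree by more than 0.1 π rad are
  excluded.
- **Circular statistics**: von Mises kernel density estimates (κ = 10, 200
  bins), 1–4 component von Mises mixtures fitted by EM with BIC selection and
  unimodality criteria, and maximum-likelihood circular-linear regression with
  the saturating mean link `μ(x) = μ₀ + 2·atan(βᵀx)` plus per-mouse offsets
  and cluster-bootstrap intervals.
- **Load biomechanics**: per-limb weight fractions over ≥ 5 s standstills,
  `CoS_AP = w_RF + w_LF − (w_RH + w_LH)` (and its load-weighted cm analogue),
  the cos(θ) slope correction of detectable weight, the head-post offload
  fraction, and weight-adjusted head height
  `(height − 24.5) / (1.25 · weight)`.
- **Support patterns**: per-stride time fractions of grouped limb-contact
  states (diagonal, three-limb, …) decomposed by PCA.
- **Lateralization**: a linear support-vector classifier of stimulation side
  from sin/cos phase features with a balanced 75/25 split and a 1000-shuffle
  permutation test.
- **Composition**: covariate→phase regressions composed with covariate→CoS
  maps to express phase shift per centimeter of CoS displacement across trial
  types.

A synthetic cohort generator emulates the recordings (periodic limb
trajectories with configurable stride period, duty factor and phase offsets
drawn from von Mises distributions whose mean follows the covariate link;
load-cell trials whose forelimb fraction decays exponentially with head
height) and stores its ground truth, so every stage is testable by parameter
recovery.

## Worked example

```r
library(gaitphase)

cfg <- cohort_config(n_mice = 4, strides_per_trial = 20, seed = 7)

# one head-height trial: pose series at 400 fps with ground truth
trial <- generate_trajectory_trial(cfg, mouse_index = 1,
                                   covariates = list(head_height = 52, slope = 0, speed = 20),
                                   seed = 7)
posture <- posture_series(trial$recording)
strides <- build_stride_table(trial$recording, posture)
nrow(strides)
#> [1] 18
round(circ_mean(strides$phase_LF) / pi, 3)   # estimated homolateral phase
#> [1] 0.635
round(trial$truth$phases[["LF"]] / pi, 3)    # generator truth
#> [1] 0.602
table(strides$hindlimb_category)
#> alternating
#>          18

# per-stride phase cohort and the posture effect on homolateral phase
d <- simulate_phase_cohort(cfg, n_mice = 4, strides_per_mouse = 300, seed = 7)
fit <- circ_linear_regression(d$phase, d[, "angle", drop = FALSE], d$mouse,
                              n_boot = 200, seed = 7)
print(fit)
#> <circ_reg: n = 1200, kappa = 7.91, mu0 = +2.498 rad (0.80 pi)>
#>          estimate      lower     upper significant
#> angle -0.02594609 -0.0269197 -0.024985        TRUE

# standstill load trial -> center of support
load <- generate_load_trial(cfg, list(head_height = 52, slope = 0), weight = 22, seed = 7)
summ <- summarize_load_trial(load)
round(summ[, c("w_RF", "w_LF", "w_RH", "w_LH", "CoS_AP_index", "CoS_AP_cm")], 3)
#>    w_RF  w_LF w_RH  w_LH CoS_AP_index CoS_AP_cm
#> 1 0.222 0.206  0.3 0.272       -0.144    -0.359
```

The stride table estimates the trial's homolateral phase (0.635 π rad)
within one cross-correlation lag of the generator's true draw (0.602 π rad),
with strictly alternating hindlimbs as configured. The regression recovers a
negative angle coefficient — a more upright posture (larger snout-hump angle)
pulls homolateral coordination from alternation toward synchrony — with a
bootstrap interval excluding zero. At a high head position the CoS sits
behind the body midpoint (−0.36 cm), i.e. hindlimb-biased.

The full chain (simulate → strides → loads → statistics) is also available
as `run_pipeline("all", pipeline_config(...), out_dir)`, which writes tidy
CSV/JSON artifacts plus a reproducibility manifest.

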