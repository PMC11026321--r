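---
title: "Modelling click-position selection for scrolling actions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling click-position selection for scrolling actions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scrollclick)
```

## The task and its geometry

When people scroll by dragging, the first decision is where to click on the
scrollable object. That choice matters because the cursor cannot leave the
screen: a click near the bottom border leaves no room to drag downward, so
a long downward scroll started there needs a release, a return movement, and
a re-click. The package models a vertical number-line task in which a line
of numbered squares moves with the cursor's y coordinate while the button is
held, and the participant must centre a prescribed target number.

All coordinates are in screen-height units with y = 0 at the bottom edge and
y = 1 at the top. A `task_config` fixes the geometry; two presets are built
in. The first has 9 squares of edge 0.2 numbered 1 (top) to 9 (bottom) with
the centre square initially at the screen centre, 0.02-unit release
tolerance, and start squares at three vertical and two horizontal offsets.
The second has 11 squares of edge 0.14 numbered 10-20, 0.014-unit tolerance,
and a single, vertically centred start square per side. The signed
displacement needed to centre target `t` is `(t - centre) * edge`; positive
displacements are upward scrolls, realised by upward drags. With a drag
capacity of `click_y` downward and `1 - click_y` upward, the set of click
positions permitting a one-go scroll is an interval (`one_go_interval()`),
and `scroll_path_cost()` prices any click under a no-unnecessary-movement
drag policy: drag to the border, return to the cheapest viable re-click
point on the line's new on-screen extent, and repeat. Both designs need at
most 0.8 units of displacement, so a one-go click always exists.

Two conventions were genuinely open and are fixed as follows. The whole
strip of the line is clickable, including at the exact screen borders
y = 0 and y = 1. Square spacing in the second preset is the printed 0.14
exactly; the inducer-eccentricity predictor codes used by the mixed model
(0.14, 0.43, 0.71) are used verbatim rather than recomputed from the
spacing, since the two published values are mutually inconsistent at the
third decimal and the predictor coding is the analysis-facing quantity.

## Candidate strategies

Four click-selection models map a trial context to a predicted first click:

* **Minimal path** (`minimal_path_click()`): minimises the Euclidean reach
  from the start square to the strip plus the scroll path cost. The search
  runs on a 0.001 grid (well below any behavioural precision claim)
  augmented by the exact interval endpoints and the start height; ties are
  broken toward the click nearest the start height, then nearest the screen
  centre, which reproduces the "click at your own height when feasible"
  geometry of the optimal solution.
* **Target click** (`target_click()`): the centre of the target's square,
  clamped to the screen — a memory-offloading account.
* **Border buffer** (`edge_buffer_click()`): any one-go position, finishing
  with a rapid movement into the screen border; the point prediction is the
  one-go interval midpoint and the predicted final cursor position is the
  border itself.
* **Two-component heuristic** (`heuristic_click()`): the model of main
  interest, described next.

## The two-component heuristic

The heuristic is described verbally in the source literature; this package
commits to one explicit parametric form. The planned click eccentricity
(absolute distance from the screen centre) on a trial with required
displacement `d` is

```
e* = e0 + k * (|d| - m)          # direction base + amplitude adjustment
e  = (1 - lambda) * e* + lambda * e_prev   # hysteresis blend
y  = 0.5 - sign(d) * e + noise             # upward scrolls -> low clicks
```

where `m` is a running mean of the absolute displacements experienced in
the current block (task context), updated by exponential smoothing,
`m <- (1 - alpha) m + alpha |d|`, and `e_prev` is the previous trial's
realised click eccentricity. Gaussian trial noise is clipped to the screen.

Defaults (all overridable, and treated as free parameters by the recovery
tests): `e0 = 0.25` (half the eccentricity range), `k = 0.5` (a 50-pixel
click shift per 100-pixel amplitude change, the canonical illustration of
partial amplitude adaptation), `lambda = 0.3`, `alpha = 0.1`, and
`noise_sd = 0.07`, matching the between-participant spread of roughly 7% of
screen height reported for condition means. The linear form with a convex
hysteresis blend and exponential-smoothing context is the package's own
formalisation; it is the simplest form with one parameter per postulated
mechanism, and `recover_heuristic_params()` shows all of them are
identifiable from simulated data by ordinary least squares, because the
noisy previous eccentricity is itself the regressor the generative process
uses (no errors-in-variables attenuation). Separate base eccentricities for
up and down scrolls would be a one-line extension but are kept equal: the
empirical asymmetry is small and nothing downstream depends on it.

## The synthetic-data generator

`generate_exp1_design()` and `generate_exp2_design()` enumerate the two
designs exactly: 8 blocks of the full 8 targets x 3 vertical starts x 2
sides factorial (shuffled independently per block), and 3 inducer-
eccentricity block types (randomly ordered per participant, since the
original counterbalancing is unpublished) of 3 subblocks x 32 trials with
every target-side combination exactly four times. `generate_dataset()`
runs every trial through a strategy and a motor model and emits event logs
(click/release, cursor x/y, line offset) in a documented CSV dialect.

The motor model is not part of the studied phenomenon and is deliberately
plain: drag endpoints get Gaussian noise (SD 0.02) truncated at the screen;
if a release leaves the target outside tolerance, the simulator re-clicks —
at the cheapest continuation point when at least 0.1 units remain, near the
screen centre otherwise — until alignment; segment durations are
0.2 s + 1.0 s per unit distance. These constants produce a realistic mix of
substantive and corrective submovements and sub-10-s trials; they are
config-set, not fitted. Between-participant variability is normal jitter on
`e0` (SD 0.05) and `k` (SD 0.1). The context state resets at block
boundaries to the design's mean absolute displacement, so early-block
trials are driven by the direction component alone.

What the generator does *not* emulate: velocity profiles and movement-time
laws, anticipation errors in the x direction, device differences
(mouse vs touchpad), participant-specific strategy switching, and any
dependence of motor noise on movement amplitude. Tests passing on this
generator therefore certify the analysis pipeline and the internal
consistency of the models, not the empirical truth of the heuristic.

## Reduction and statistics

`reduce_trials()` extracts the four dependent variables per trial (initial
vertical click position, final cursor position, submovement count, response
time from target onset, i.e. the start-square release) and applies the
exclusion rule: trial duration from start-square onset above 10 s, strict
inequality, as printed. `classify_submovements()` labels a submovement
corrective when less than 0.1 units (strict) remain to perfect alignment at
its click, substantive otherwise, and flags substantive re-clicks that
repositioned the cursor by less than 0.1 units.

`rm_anova_gg()` implements the fully within-participant factorial ANOVA
from per-participant cell means via orthonormal-contrast projections; each
effect is tested against its effect-by-participant stratum. The
Greenhouse-Geisser epsilon is the usual trace ratio of the contrast-score
covariance, clamped to its `[1/df, 1]` range, and both corrected and
uncorrected p values are reported: when sphericity actually holds — as in
the power generators, which use iid cell noise — the corrected test is
conservative (its estimated epsilon is biased below 1), so calibration
checks read the uncorrected column while all power claims use the corrected
one, matching the published analysis choice. Generalized eta squared uses
all within-participant variance components (participant stratum plus every
error stratum) in the denominator — the standard definition for fully
within designs, which the source names but does not define.
`consecutive_contrasts()` runs paired t tests on adjacent levels of an
ordered factor with `d_z = t / sqrt(n)`, flagging zero-variance
differences as degenerate rather than reporting an unbounded t.

`build_hysteresis_predictors()` codes, per trial: the previous click's
eccentricity centred by 0.25 and sign-flipped for upward scrolls; the
previous absolute click position (centred at 0.5 so every predictor is in
screen-height units); the signed current amplitude; direction as -0.5/+0.5
(down/up); the vertical start offset (first design); the inducer-
eccentricity code (second design). First-of-block trials and trials whose
own or predecessor's duration exceeds 10 s are dropped.
`fit_mixed_model()` fits the model with by-participant random slopes for
all predictors by REML (lme4), falling back from an unstructured to a
diagonal random-effect covariance on singular fits (logged); F tests use
Satterthwaite denominator degrees of freedom (lmerTest), VIFs come from the
correlation of the fixed-design columns after the stated coding, and
marginal/conditional R squared follow the variance-partition formulation
(fixed variance, plus random-effect variance evaluated on the model's own
design rows, over total).

## Power simulations

The first design's power analysis simulates participants who behave exactly
like the minimal-path model plus independent Gaussian noise per cell
(SD 0.20 or 0.40 screen heights, clipped to the screen), one data point per
participant and cell — so individual participants' data are uncorrelated —
and counts significant GG-corrected effects at alpha .05. The second
design's original power analysis drew from each empirical participant's
mean and SD; those moments are not derivable without the raw data, so the
package defines an explicit surrogate, used and stated as such: test-target
trial means symmetric about the screen centre at eccentricity 0.28 (the
geometric click position for the +/-0.28 displacements of the test
targets), trial SD 0.07, and an eccentricity effect growing linearly from
zero at block start to the nominal effect size per adjacent level at block
end, applied at each test trial's sampled serial position within the
block. Both the 2 x 3 interaction ANOVA (on subblock-collapsed means) and
the 2 x 3 x 3 three-way ANOVA are run, since it is unstated whether
subblock entered the original power model.

Problem sizes: the bundled acceptance script uses 600-1000 replicates per
grid point (Monte-Carlo SE below 1.6 percentage points at the reported
powers), and the test suite uses 400-500; the analysis drivers default to
500 across the full sample-size grids. All randomness descends from one
master seed through stage-keyed child seeds (`derive_seed()`), so adding a
stage never perturbs another stage's draws and every run is reproducible
bit for bit.

## Known limitations

* The heuristic's parametric form is one of several consistent with the
  verbal two-component account; conclusions about `lambda` and `alpha` are
  conditional on linearity of the blend and smoothing.
* The motor model's duration constants are placeholders calibrated only to
  keep trial durations realistic; response-time analyses on synthetic data
  reflect geometry, not human chronometry.
* `rm_anova_gg()` requires complete balanced tables and intentionally
  refuses unbalanced input rather than switching to a mixed-model
  approximation.
* The second design's power surrogate replaces per-participant empirical
  moments with common ones; between-participant mean variation cancels
  from within-participant contrasts, but heavy-tailed or skewed individual
  distributions are not represented.
* VIFs are computed after the stated predictor coding (amplitude and
  direction are intentionally correlated; their individual weights should
  not be interpreted, only jointly).
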