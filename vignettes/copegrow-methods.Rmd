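---
title: "Methods: individual growth, moult detection and stressor models in copegrow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual growth, moult detection and stressor models in copegrow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Automated well-plate imaging can follow every individual in a development
experiment at roughly hourly resolution. For a harpacticoid copepod
(*Tigriopus brevicornis*) developing through six naupliar stages (N1–N6),
five copepodite stages (C1–C5) and the adult moult over about two weeks,
this produces, per individual, a few hundred body-length measurements that
are noisy, biased relative to microscope measurements, and irregularly
missing: young benthic stages image well, older stages swim out of focus,
and entire frames are lost to water changes and camera misalignment.

`copegrow` implements the full analysis chain for such data under a
two-by-two stressor design (a toxicant, copper, crossed with predator
cues): per-individual growth smoothing, isochronal prediction, growth
increments and moult detection, and uncertainty-weighted linear models with
AICc-based multimodel inference for stage-transition timing, moult
duration and final size — together with a synthetic-data generator that
emulates the platform's observation process so every step can be exercised
and validated without the original images.

## The synthetic experiment

### Development model

Each individual's development is a sequence of stage durations
$D_s = \mu_s \, c_s(\text{treatment}) \, e^{\gamma + \eta + \varepsilon_s}$,
where $\mu_s$ is the mean duration of stage $s$ (days), $\gamma$ is a
clutch-level and $\eta$ an individual-level normal deviate on the log
scale, and $\varepsilon_s$ is independent per-stage noise. Log-normal
durations guarantee positivity and match the log-scale analysis of
transition times. Stage-entry times are cumulative sums of these
durations; the true length path is a step function over the stage-specific
lengths (0.10 mm at N1 to 0.85 mm at adult by default), scaled by clutch
and individual factors, with a small male surplus (default
$e^{0.04}$) on copepodite and adult lengths.

Copper multiplies the durations of every stage after N2 by a constant
$c$ solved from the configured delay $\delta$ on the log N6$\to$C1
transition time:
$c = (e^{\delta}\sum_{s\le6}\mu_s - \mu_1 - \mu_2)/\sum_{3\le s\le6}\mu_s$.
Because the clutch and individual factors scale both arms identically,
the expected log transition-time difference between copper and control is
$\delta$ exactly (default 0.14, i.e. a 15 % delay). Predator cue alone has
no effect on timing; combined with copper it adds a further delay
(default 0.20 on the log scale) to copepodite-stage durations only, so the
combined treatment diverges late in development. The control naupliar
durations sum to 5.42 days, placing the control mean log transition time
(in days) at 1.69. Clutches also differ in their copper sensitivity of the
moult duration (an interaction SD on the log motion-free time), so some
clutches shorten and others prolong the metamorphosis moult under copper.

### Observation model

One frame is scheduled every 72 minutes for 13 days (260 frames).
A frame is unusable during episodic runs (episodes arrive at 0.6 per day
and last a geometric number of frames, mean 2); an otherwise usable frame
yields a length with a stage-dependent detection probability (0.93 for
nauplii, 0.52 for copepodites, 0.40 for adults — the benthic-to-demersal
shift). Usable lengths are `machine_bias` (default 1.10, machine estimates
run large) times true length times multiplicative noise (CV 5 %).
Recorded ages carry a uniform ±30-minute birth-time error. These defaults
were set so that the aggregate yield matches the platform's printed
figure of roughly 169 usable measurements per analyzable individual; the
per-stage probabilities themselves are not separately reported anywhere
and are declared here, not inferred. Three individuals are lost outright
(handling and a misalignment), leaving 69 of 72 analyzable.

Before the N6$\to$C1 moult the animal falls motionless. The simulator
draws a motionless period from a truncated log-normal on [72, 450]
minutes, lengthened or shortened under copper by the clutch-specific
sensitivity, and marks frames from the start of that period through the
first *usable* frame at or after C1 entry as motion-free — the screening
convention that counts the first picture in which the copepodite is seen
in the same position. Unusable frames immediately preceding the first
copepodite sighting are the "uncertain frames" that later become
observation weights.

Every clutch and every individual draws from its own hash-derived RNG
substream, so adding individuals to a design never perturbs existing
ones, and a configuration plus seed reproduces a dataset byte for byte.

### What the generator does not emulate

No pixel-level image content; no systematic drift in measurement error
with age or stage (real blur worsens as animals swim); no temporal
autocorrelation in detection beyond the episode process; no mortality
during the experiment (individuals are either followed to the end or lost
at the start). Passing recovery tests on these data therefore shows that
the analysis chain is correct and well calibrated under the stated
sampling process, not that it is robust to every pathology of real
imaging data.

## Growth smoothing and increments

Each individual gets its own penalized regression spline of length on
age: cubic B-splines with a second-order difference penalty (`mgcv`,
`bs = "ps"`, `m = c(2, 2)`), basis dimension `k = 40` by default, capped
at one less than the individual's number of usable records. For
one-dimensional smooths this P-spline is the working equivalent of a thin
plate regression spline at far lower setup cost. Smoothness is selected
by REML by default (GCV by flag); REML is the robust modern default and
the choice matters little here. The treatment-level models work on log
length (the hierarchical-GAM intercepts are only plausible on log-mm),
but the increment pipeline runs on the natural mm scale, where increments
are additive and negative values are meaningful; both scales are
selectable.

Isochronal predictions are evaluated on a grid anchored at each
individual's first usable time with exact 72-minute spacing and never
extend past its last usable time — the smoother is never used beyond the
data range. Growth increments are first differences of these predictions,
timestamped at the right endpoint of the interval they complete (an
increment is attributed to the interval it finishes); negatives are
retained. Two invariants hold by construction and are asserted on every
simulated dataset: the increments of an individual sum exactly to its
last-minus-first predicted length, and no prediction time falls outside
its observation window.

`check_fit()` reports, per individual, the effective degrees of freedom
against the basis dimension (flagging `edf/k' > 0.95`, an exhausted
basis), residual SD, residual skewness and excess kurtosis, and the
residual-versus-fitted correlation.

### The noise-free detection regime

On noise-free step data, any criterion-selected penalty smears step edges
— REML treats the steps themselves as roughness to be traded away, and
the resulting ramp can displace an increment peak at the window boundary
by one or two grid steps. The moult-detection fidelity check therefore
runs the smoother in an interpolation regime: basis dimension capped at
the record count and a small fixed penalty (`sp = 0.1`) that leaves the
fitted values essentially at the data while suppressing sub-0.001-mm
numerical ripple between steps. This is a property of fitting noise-free
data, not a special code path: both knobs (`k`, `sp`) are ordinary
arguments of `fit_growth_smoothers()`.

## Moult detection

Moults appear as isolated peaks in the increment series. `detect_peaks()`
calls local maxima by topographic prominence, with three conventions
chosen for this application:

* A peak must rise out of preceding terrain: the first sample of a series
  is never a peak (a series starting mid-decline shows no onset), but a
  rise into the final sample is one (a moult truncated by the window
  end).
* A side of a peak that reaches the series end without meeting higher
  terrain imposes no reference level — the window's cut is not terrain —
  so an end-truncated peak keeps its full prominence from the other side.
* Maxima closer together than `min_separation` (default 12 h; stage
  durations are about a day) are merged keeping the larger, with ties
  broken to the *earlier* maximum: a moult is an onset event.

The default prominence threshold is half the median positive increment of
the series (optionally restricted to the naupliar phase), with an
absolute floor of 0.004 mm. The floor exists because on near-noise-free
data the median positive increment collapses to numerical dust and would
otherwise admit sub-micrometre ripples; 0.004 mm is well below the
smallest true stage increment (about 0.025 mm) and well above machine
epsilon effects. No numeric peak-calling rule is published for this kind
of data; these defaults are declared, and the fidelity check (100 % of
true moults within 72 minutes, zero spurious calls, on 50 noise-free
individuals) is the evidence that they are adequate under the stated
conditions.

The N6$\to$C1 transition itself is not peak-called but screened from the
frame log, as in the manual workflow: the transition time is the first
copepodite-visible frame, the uncertain-frame count is the run of
unusable frames immediately before it, and the moult duration is the run
of motion-free frames ending at (and including) that first sighting,
times the frame interval, censored below at one interval when no
motionless frame was caught. Individuals with no copepodite sighting are
censored and excluded from the transition-time models.

Treatment-averaged increment curves re-bin the individual grids (each
anchored at its own first usable time) onto common 72-minute bins from
birth and average over the individuals present per bin; empty bins are
absent, not zero. A lower averaged peak means more between-individual
spread in transition timing — the property test confirms that raising the
simulated timing SD monotonically lowers the averaged metamorphosis peak.

## Stressor models

All linear-model inference uses the corrected Akaike information
criterion, $\mathrm{AICc} = \mathrm{AIC} + 2k(k+1)/(n-k-1)$ with $k$
counting the residual scale. Candidate sets are exhaustive subsets of the
full fixed-effect structure that respect marginality (no interaction
without its main effects). All models within ΔAICc < 2 of the best are
averaged: each coefficient conditionally, over only the member models
containing it, with Akaike weights renormalized within that subset, and
an unconditional SE that folds in the between-model spread. z- and
p-values use the normal approximation. A brute-force enumeration coded
independently in the test suite reproduces these numbers to 1e-10.

* **Transition time**: log transition time in days (days make the control
  intercept a biologically readable 1.69 ≈ log 5.4 d) on copper, cue and
  clutch with pairwise interactions; a matured-only variant swaps clutch
  for sex.
* **Moult duration**: square-root transformed duration in minutes, with
  the clutch-by-copper interaction estimable.
* **Final size**: log mean length over the experiment's last day — the
  final 1440 minutes before the latest usable record, since individual
  ages differ by the birth-time error and a calendar-day bin would be
  ragged — on copper, cue and clutch, plus sex in the matured-only
  variant.
* **Calibration**: daily machine means regressed on paired manual
  microscope lengths with an individual-level random intercept
  (`lme4`), optionally with treatment fixed effects.

Observation weights reflect transition-time uncertainty. Taken literally,
using the uncertain-frame *count* as the weight would up-weight the least
certain transitions and silently drop the fully certain ones (weight 0).
The default is therefore the inverse mapping $w = 1/(1 + n_\text{uncertain})$,
with the literal mapping available by flag (`weights_mode = "literal"`)
for anyone who wants the face-value convention.

The hierarchical GAMs model log length (or the growth increment) as
parametric clutch, copper and cue offsets plus one smooth age curve per
treatment-by-clutch combination and per-individual factor smooths with a
first-order penalty — a functional random effect with shared smoothing.
Treatment-by-clutch cells with fewer than three individuals are absorbed
into treatment-level smooths. The package defaults to reduced basis
dimensions for these models (`k = 10`, factor-smooth `k = 6` in the
pipeline) so the full 69-individual fit takes seconds; the basis can be
raised to 40 throughout where a longer fit is acceptable, without
changing the model structure. With the default simulator — which contains
*no* direct copper effect on length — the fitted copper coefficient comes
out near −0.12 on log length, emerging entirely from developmental
delay; the cue coefficient stays near zero.

## Numerical conventions and degenerate inputs

Individuals with fewer than six usable records, or whose smoother cannot
be fit, are excluded with a warning, never an error. Windows shorter than
one grid step are skipped. `AICc` is infinite (with a warning) when
$n \le k + 1$, which silently removes over-parameterized candidates.
Constant responses produce perfect fits whose non-intercept estimates are
zero to numerical tolerance. Censoring is always carried in an explicit
status column, never as a sentinel value. Determinism everywhere follows
from one hashed RNG substream per random entity.

## Problem sizes used by the checks

The test suite validates at the study's own scale where the property
demands it: parameter recovery runs 100 simulated experiments of 72
individuals in 9 clutches (95 % CI coverage of the copper delay, the
calibration slope and the male size effect); moult-detection fidelity
uses 50 noise-free individuals; the variability–peak-height property uses
three timing-SD levels with 50 replicates of 8 control individuals over
9 days. Unit tests use 3-clutch, 8-day, 144-minute-interval experiments
for speed. The full suite runs in about three minutes on one core.

## Known limitations

Conditional model averaging inherits the usual post-selection caveats: a
coefficient whose signal is weak may be absent from the member set in
some realizations (the matured-only sex effect is estimable in roughly
four of five simulated experiments at this scale), and conditional
estimates of weak effects are biased away from zero. Moult detection
degrades, as it must, for late copepodite stages in noisy data — moult
cycles desynchronize and measurement error grows with age — which is why
inter-moult intervals beyond the metamorphosis are not modelled here.
The N-to-N moult times are recoverable from increments only; the frame
log identifies the metamorphosis alone, matching what manual screening
can do.
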