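---
title: "Detecting and predicting muscle fatigue from surface EMG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and predicting muscle fatigue from surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgfatigue)
```

## The problem

During a sustained isometric contraction a muscle does not switch abruptly
from fresh to exhausted. Myoelectric manifestations of fatigue accumulate
gradually: the power spectrum of the surface EMG (sEMG) compresses toward
lower frequencies -- its median frequency (MDF) declines -- while signal
amplitude grows as more motor units are recruited to sustain the force.
Detecting the *intermediate* state, here called Transition-to-Fatigue (TF),
is what makes fatigue *prediction* (rather than after-the-fact detection)
possible.

`semgfatigue` implements a complete desk-scale pipeline around that idea:

1. **Kinematic labeling.** Each second of a trial is labeled Non-Fatigue
   (NF), Transition-to-Fatigue (TF) or Fatigue (F) by a six-rule type-1
   fuzzy classifier driven by the elbow-angle goniometer: the held angle and
   its 4-s-block oscillation (standard deviation) are the two antecedents.
2. **Feature extraction.** Five per-second feature streams, headlined by the
   composite `spectro_std` feature: per-second MDF and Welch band power are
   standardized over the trial, subtracted (`z(power) - z(mdf)`, the
   "unified" or 1D spectro stream), and passed through a causal 3-s rolling
   standard deviation.
3. **Pairwise classification.** A Fisher linear discriminant on one feature
   at a time, trained longitudinally (on chronologically earlier seconds)
   and tested on later seconds, for the NF/TF and TF/F pairs.
4. **Evaluation.** Second-denominated confusion matrices with their rates, a
   spread-over-distance cluster separability index, and a per-subject
   percent-correct comparison report with improvement deltas and paired
   t-tests.
5. **Synthetic trials.** A seeded generator of fatiguing-contraction trials
   with ground-truth labels, since no public recording accompanies the
   method; every stage of the package is tested against it.

## The labeling model

Only kinematics label the data: a drop of the held elbow angle and growing
arm oscillation are the accepted mechanical signs of fatigue in healthy
subjects, and they are independent of the sEMG that is later classified --
so the labels are not circular.

The angle input uses three piecewise-linear terms fixed by two boundaries:
angles above 89 degrees are crisply Non-Fatigue, below 86.5 degrees crisply
Fatigue, with linear overlap in between (F trapezoid (0, 0, 86.5, 89); TF
triangle (86.5, 87.75, 89); NF trapezoid (86.5, 89, 180, 180)). The
oscillation input has two terms, Low (0, 0, 0.4, 0.8) and High
(0.4, 0.8, plateau), crossing at 0.6 degrees SD -- the value at which
holding becomes visibly unsteady. Only the 86.5 / 89 / 0.6 boundaries are
anchored by the underlying study; the ramp widths are this package's
parameterization, exposed in the pipeline YAML (`fuzzy.*`) for override.

Inference is by product of the two antecedent memberships; the single rule
with the greatest firing strength decides the label (no weighted blending),
with ties resolved toward the more severe class. Per-sample labels are
reduced to one label per second by majority vote, again with severe-wins
ties. The rule base maps (NF-angle, Low) to NF, (NF-angle, High) to TF,
both TF-angle rules to TF, and both F-angle rules to F.

```{r rules}
classify_sample(91, 0.1)$label   # steady hold at 91 degrees
classify_sample(91, 1.2)$label   # same angle, oscillating: transition
classify_sample(85, 0.3)$label   # angle collapsed: fatigue
```

## The spectro_std feature

Per one-second window the package computes

* **MDF** on the raw periodogram (1 Hz grid at 2 kHz): the first grid
  frequency at which cumulative power reaches half the total. No
  interpolation -- the estimator is deterministic and directly checkable
  against a cumulative-sum oracle. The full-resolution periodogram is used
  here rather than Welch averaging because the median needs a fine grid.
* **Total band power** by Welch's method (256-sample Hamming segments, 50%
  overlap, density scaling), integrated over the grid with the trapezoid
  rule.

Hertz cannot be subtracted from millivolts squared, so "unification by
subtraction" is implemented on per-trial z-scores: `z(power) - z(mdf)`,
which rises as fatigue develops (power up, MDF down). This normalization is
the package's interpretation and is stated prominently wherever the unified
stream appears; sample (n-1) standard deviations are used everywhere in the
package, including here.

The rolling 3-s standard deviation of the unified stream is `spectro_std`.
Its timestamps sit at the *end* of each span, so the value at time t uses
only data up to t + 1 s: the transform is causal, as a predictor must be.

Comparison features -- MDF, band power, Dimitrov's FI2 spectral index
(moments over 8--500 Hz), and the depth-12 db3 wavelet approximation energy
-- are passed through the same 3-s rolling SD so all five streams are
commensurable and share timestamps.

"Scale 12" for the wavelet feature is read as decomposition level 12 of the
*whole trial* (a one-second window cannot support twelve db3 levels); the
level-12 approximation is reconstructed to signal length and its mean square
inside each second is the per-window feature. The DWT itself is a periodized
orthonormal pyramid applied after symmetric padding to a multiple of
2^level; periodization (rather than per-level symmetric extension) keeps the
transform exactly orthonormal and invertible, which the tests verify to
1e-10. The six scaling filters (haar, db2--db4, sym4, sym5) were computed by
spectral factorization of the Daubechies polynomial and satisfy the
orthonormality and vanishing-moment conditions to about 1e-14.

## Classification protocol

Equations-first Fisher LDA: `W` proportional to `Sw^-1 (mu+ - mu-)` with the
pooled within-class covariance and equal priors, bias at the midpoint of the
projected class means, decision by the sign of `W'x + w0` with the midpoint
tie going to the more severe class. Features are classified one at a time
(1-D), mirroring the feature-by-feature comparison design; no fusion.

"Longitudinal" is interpreted as *chronological within trial and class*: the
first `ceil(train_frac * n)` seconds of each class in each trial train the
model, the rest test it, so every training timestamp precedes every test
timestamp of the same trial and class and the model must generalize forward
in time. The split granularity and the 0.5 default fraction are
configuration knobs (`classify.train_frac`), since the original protocol is
under-specified.

## Evaluation conventions

* Confusion cells are counted in seconds with the more severe class of a
  pair as "actual +". Rates follow the printed definitions exactly;
  accuracy, which is reported but never given an equation, uses the
  standard `(a + d) / total`.
* The separability index divides the summed per-cluster SD of
  member-to-centroid distances by the distance between the two centroids.
  This is implemented *as printed* even though it differs from the textbook
  Davies-Bouldin index; `dbi_canonical()` provides the textbook version
  under an unambiguous name.
* In the span sweep (`dbi_window_sweep`), the 1-s entry uses the raw
  unified values: a rolling SD of span 1 is identically zero and would make
  the sweep meaningless.
* Summary tables report 2-dp half-up rounded means and sample SDs.
  Improvement deltas are computed on *unrounded* means and then *truncated*
  to 2 dp for display: that is the only arithmetic that reproduces all four
  published deltas (13.49, 20.58, 5.64, 8.14) from the published
  per-subject tables, so it is taken to be how those numbers were made.
  Significance uses a two-sided paired t-test across subjects; the original
  report does not name its test, and indeed its "p < 0.05" claim for the
  TF/F comparison does not reproduce under a paired t-test (p = 0.099). The
  test used is recorded in the `improvements()` output.

```{r arithmetic}
ref <- read.csv(system.file("extdata", "reference_percent_correct_nf_tf.csv",
                            package = "semgfatigue"), row.names = 1)
s <- summarize_percent_correct(as.matrix(ref))
s$mean_2dp
improvements(s)$per_feature$wavelet_db3$delta_2dp
```

## The synthetic world

No recordings were ever deposited, so the generator emulates the described
phenomenology of an isometric biceps trial held near 90 degrees at 40% MVC:

* **sEMG**: per-second blocks of Gaussian white noise shaped by a 4th-order
  Butterworth band-pass of width 60 Hz re-designed each second around a
  target median frequency; the target holds at `mdf_start` (95 Hz) through
  the NF phase, declines linearly to `mdf_end` (55 Hz) across the TF phase,
  and holds there through F. Block outputs are normalized by the filter's
  expected noise gain, and a linear amplitude ramp reaches `amp_gain` (1.6)
  at the end of the trial. The piecewise-stationary construction keeps the
  spectrum auditable inside every window.
* **Goniometer**: the held angle plus low-pass (5 Hz) oscillation noise
  with SD 0.2 degrees before the TF onset and 1.0 degrees after (straddling
  the 0.6 labeling boundary), white sensor noise (0.05 degrees), and a
  linear drop from 90 to 84 degrees when fatigue sets in.
* **Defaults**: 180-s trials with TF onset at 100 s and F onset at 150 s;
  cohorts of ten subjects with three trials each, subject parameters
  jittered by 10% relative. All randomness flows from one integer seed
  through a counter-based derivation, so trials, cohorts and pipeline runs
  are bit-reproducible.

Two generator constants are deliberate package choices. The **angle decline
duration** (`decline_s`, default 5 s) is not stated anywhere; a decline
stretched over the whole F phase would take the angle through the fuzzy
86.5--89 transition band for 10--17 s and push the detected TF-to-F
change-point far from the true onset, contradicting the labeling-recovery
behavior the pipeline is specified to have, so task failure is modeled as
rapid (a few seconds), which is also how a failed isometric hold looks in
practice. The **amplitude gain profile** ramps over the whole trial because
amplitude growth from progressive recruitment starts well before subjective
fatigue; no published figure quantifies the growth, so 1.6 is a free
parameter, not a measured value.

## What a green test does and does not establish

The generator produces stationary band-limited Gaussian noise with clean
linear ramps. Real sEMG is none of those things: it is bursty,
non-Gaussian, broadband (roughly 20--450 Hz rather than a 60 Hz band), and
its transition phase is marked by abrupt, irregular swings rather than a
smooth ramp. Green synthetic tests therefore establish that the *estimators
and the pipeline plumbing* are correct -- not that the headline feature
separates real fatigue classes at the published rates; those magnitudes are
not reproducible without the original recordings.

Three documented consequences of this gap are visible in the acceptance
battery and are left failing rather than papered over:

1. **spectro_std does not drop in late Fatigue.** Band-power estimation
   noise is multiplicative: for a 60 Hz-wide band and 1-s windows the
   relative SD is about `1/sqrt(B*T)` or 13%, so the absolute noise of
   `z(power)` -- and with it the rolling SD -- is largest where amplitude is
   largest, which in a monotone amplitude ramp is late F. The real-data drop
   after fatigue onset comes from the signal *stabilizing* once the muscle
   has failed, a dynamic the linear-ramp world does not contain.
2. **The separability sweep does not favor longer spans.** In this world
   the TF-phase unified stream ramps cleanly away from the NF level, so the
   raw values separate the classes far better than their 3-point rolling
   SDs, whose sampling noise (about 50% relative) swamps the sweep. The
   published trend depends on real NF/TF streams overlapping in level while
   differing in variability.
3. **NF/TF percent-correct sits near 57%, not above 70%**, for the same
   reason: a 1-D rolling-SD feature under this much estimator noise
   overlaps heavily between classes. The ordering against the comparison
   feature (spectro_std beats the rolling-SD of MDF) does hold.

All three follow analytically from the stated generator (they were predicted
from the `2BT` variance bound before being measured) and would change only
if the generator were made broadband or given burst dynamics -- a
deliberately rejected move, since the synthetic world is a stated input of
the package, not a dial to turn until tests pass.

## Numerical choices

* The 1--500 Hz 5th-order dual-pass (zero-phase) Butterworth filter runs as
  cascaded second-order sections: in direct polynomial form the 1 Hz edge
  at 2 kHz puts poles so close to the unit circle that the filter is
  numerically unstable. Odd-reflection padding plus rest-state (DC-removed)
  initialization suppresses start-up transients; a constant input maps to
  exactly zero output.
* The oscillation signal expands 4-s-block SDs back to sample rate by
  zero-order hold: SD is a block statistic, and interpolating it would
  invent intermediate values.
* Median frequency uses a relative tolerance of 1e-9 on the half-power
  threshold so an exact half split (two equal spectral lines) lands on the
  lower line regardless of floating-point summation order.
* Trailing partial seconds are dropped everywhere (windows are half-open
  `[t, t+1)`), so all per-window streams align by construction; whole
  seconds are the unit of account throughout.
* Degenerate inputs fail loudly: all-zero windows have no median frequency,
  zero-variance streams cannot be standardized, coincident centroids have
  no separability, and single-class datasets cannot train a discriminant.

## Known limitations

* Single-muscle, two-channel recordings only; channel 1 is used for
  features by default (`features.channel`), since no channel-fusion rule is
  published.
* The pipeline is strictly pairwise (NF/TF, TF/F); no three-way confusion
  matrices, no ROC curves, no cross-subject transfer.
* The fuzzy membership ramps between the published boundaries are a
  parameterization, not recovered values.
* The synthetic world's known departures from real sEMG are listed above;
  the published real-data magnitudes (81.58% / 66.59%, separability-index
  levels) are inputs to the report arithmetic, not outputs this package can
  regenerate.
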