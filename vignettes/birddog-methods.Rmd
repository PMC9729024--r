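---
title: "Quantifying bird-dog postural control from 2-D keypoints: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bird-dog postural control from 2-D keypoints: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(birddog)
```

## The measurement problem

In the bird-dog (one-arm-one-leg) balance task a person kneels on all
fours and lifts one arm and the contralateral leg, holding both as level
as possible for up to 60 seconds.  Clinicians conventionally score the
task by how long the posture is held, but most older children and adults
reach the 60-second ceiling, which erases the information the task could
carry.  Markerless pose estimation turns an ordinary video of the task
into per-frame 2-D keypoint trajectories, and from those this package
computes six fine-grained indices: three static postural balance scores
(SPB1–SPB3) that quantify how much the lifted limbs move, and three
antigravity scores (AG1–AG3) that quantify how well the limbs resist
gravity.  The package also provides the statistical machinery used to ask
which indices actually predict a clinician's 7-point rating: ordinary
least squares, backward stepwise selection by AIC, and a comparison of
index models against the conventional duration-only model.

The six task landmarks are the shoulder, elbow and wrist of the lifted
arm and the hip, knee and ankle of the lifted leg.  All pixel-scale
quantities are normalised by the trunk length `t`, the mean shoulder–hip
distance across frames, which removes differences in body size and
camera distance.  By default `t` uses the shoulder–hip pair on the
lifted-arm side (the camera-facing side in a lateral view, which is the
most reliably tracked); `t_mode = "mean_both"` averages both sides when
both are available.  `t` is computed after denoising, because index
computation follows denoising in the pipeline and the two should see the
same coordinates.

## Denoising the keypoint stream

Pose estimators produce two kinds of errors: frames where the estimator
knows it is unsure (low visibility) and sporadic large mislocalisations
(spikes).  The pipeline handles them in a fixed order, independently per
landmark and per coordinate axis:

1. **Visibility threshold.** Keypoints with visibility strictly below
   0.5 are removed.
2. **Exponentially weighted outlier rejection, five passes.** For each
   series the causal exponentially weighted moving average (EMA) and
   standard deviation (EWMSD) are computed with span equal to the video
   FPS (`alpha = 2 / (span + 1)`, the standard span convention in
   time-series tooling); a point is removed when it sits more than one
   EWMSD from the EMA (strict inequality).  Removed points contribute
   neither value nor weight to later passes; a pass that removes nothing
   ends the loop early, with a result identical to running all five.
3. **Linear interpolation.** All removed entries are filled by linear
   interpolation over the frame index; leading or trailing gaps take the
   nearest valid value, since one-sided linear interpolation is
   undefined.

Numerical choices worth knowing:

* The weighting is **causal** (past-only), with weights renormalised over
  the observations actually present.  Centered exponential windows are
  nonstandard and the simplest reading of a "moving" statistic is
  causal.
* The EWMSD is bias-corrected.  Warm-up frames where it is undefined, or
  exactly zero, can never be flagged — a deviation cannot exceed an
  undefined or zero spread.
* The rule is applied to x and y **separately** with a scalar deviation,
  not to the 2-D displacement norm.  A point removed on one axis is a
  removed scalar, not a removed frame; the other axis keeps its
  observation.
* The outlier decision depends only on differences from a weighted mean,
  so denoising commutes exactly with translating all coordinates.

Two properties of the published rule deserve emphasis because they shape
what tests can promise.  First, the one-EWMSD band is **aggressive**: for
a series with an iid Gaussian noise floor, roughly 30% of points sit more
than one standard deviation from the local mean, so each pass removes a
substantial fraction of genuinely noisy (not aberrant) points and the
interpolation step then acts as a smoother.  This is the method as
designed; users who want gentler filtering can raise `sigma_multiplier`.
Second, because of this, denoising is strictly idempotent only when the
second run finds nothing left to flag (for example, when the underlying
motion is constant or smooth after artefact removal); on generically
noisy data a re-run will keep smoothing.  The causal EMA also lags
trending series during its warm-up, so the first couple of windows of a
steep noiseless ramp can be flagged; past the warm-up the deviation
settles below the EWMSD and a ramp is never flagged.

## The six indices

Let `p_i^k` be the position of limb keypoint `k` (1 elbow, 2 wrist,
3 knee, 4 ankle) at frame `i`, `n` the number of frames and `t` the trunk
length.

**SPB1 — mean displacement.**  With
`d_i^k = ||p_{i+1}^k - p_i^k|| / t`, SPB1 is the average of `d` over
frames and keypoints.  It is the per-frame rate of trunk-normalised limb
movement; larger is less stable.

**SPB2 — peak displacement.**  `D_i = sum_k d_i^k`; SPB2 is the maximum
of `D`.  It captures the single worst between-frame movement; by
construction SPB2 is at least 4·SPB1 (a maximum is at least the mean, and
the mean of `D` is four times SPB1).

**SPB3 — excursion area.**  For each keypoint the area of the convex
hull of its visited positions, divided by `t²`, summed over the four
keypoints and divided by `n`.  Collinear or near-static keypoints
contribute zero area.  The `t²` normalisation is a deliberate design
choice: only it makes an area dimensionless and scale-invariant, and
scale invariance of all indices is a requirement here.  Published
per-dataset means exist for conventions that differ in this respect, so
`spb3()` exposes `normalization = c("t2", "t", "none")`; comparisons
across conventions must rescale accordingly.

**AG1 — unsigned droop against the image horizontal.**  Per frame,
`theta1` is the angle between the vector from the shoulder to the
midpoint of elbow and wrist and the horizontal image direction pointing
away from the trunk; `theta2` is the analogue at the hip.  AG1 is the
mean of `theta1 + theta2`.  Its two known weaknesses are intentional
(they motivate AG2/AG3): the angle is unsigned, so raising a limb above
horizontal is penalised just like drooping; and it references the image
horizontal, so it is the one index that is *not* rotation-invariant.
The non-invariance is subtler than it looks: with symmetric arm and leg
droop, a rotation shifts the two limb angles in opposite directions and
their sum is unchanged; it is postures where a rotation carries a limb
across the horizontal (or the limbs droop asymmetrically across 0° or
180°) that expose the dependence, and the tests construct exactly such a
posture.

**AG2/AG3 — trunk-referenced joint angles.**  Per frame, four angles in
[0, 180]°: `phi1` between the trunk line extended through the shoulder
(direction hip→shoulder) and the shoulder→elbow vector, clamped to zero
whenever the elbow is above the shoulder (smaller image y, head-up
orientation); `phi2` the analogue at the hip; `phi3` between the
shoulder→elbow direction extended and the elbow→wrist vector (elbow
flexion); `phi4` the knee analogue.  The clamp applies only to
`phi1`/`phi2` — being above the joint means resisting gravity and should
not be penalised — while flexion is penalised regardless of direction.
With `Phi_i` the per-frame sum, AG2 is its mean and AG3 its maximum, so
AG3 ≥ AG2 always.  This construction makes a perfectly trunk-aligned
extension score exactly zero, and it is the only reading under which the
"zero when above" clamp is coherent.  Because the clamp compares image-y
coordinates, AG2/AG3 are rotation-invariant only while the clamp state
is preserved; the invariance tests rotate drooped postures by angles
small enough not to flip any joint across its reference.

Frames with degenerate geometry (coincident points giving a zero-length
segment) are excluded from the means and maxima with a warning; a report
with more than 10% excluded frames is marked `unreliable`.  Indices are
per-frame quantities at the task's 30 FPS convention; the report records
the FPS so cross-FPS comparisons can be rescaled by the caller.

## Relating indices to clinician ratings

Trial records pair an index report with the mean clinician rating on a
7-point scale.  Predictors (and by default the response) are z-scored
before fitting, since the raw index scales differ by orders of magnitude
and published coefficient magnitudes are only plausible on a standardized
scale; `standardize = FALSE` / `scale_response = FALSE` fit raw scales.
OLS fits report coefficients, standard errors, two-sided t-test p-values,
adjusted R², and AIC under the full Gaussian likelihood with the error
variance counted as a parameter (the `stats::AIC()` convention, which
mainstream statistical software shares).  Backward stepwise selection
starts from all candidates and repeatedly removes the predictor whose
removal most decreases AIC, stopping when no removal helps; ties break
alphabetically for reproducibility, and the removal path is recorded.
`compare_duration_models()` fits the three models of interest — selected
indices plus duration, selected indices alone, duration alone — on
identical records and reports `delta AIC = AIC(duration only) −
AIC(selected + duration)`, positive when the indices add predictive value
beyond the conventional duration score.

One statistical caveat is documented rather than hidden: AIC's fixed
2-point penalty retains a null predictor whenever its |t| exceeds about
1.4 (p ≈ 0.17 at n = 60), so backward-AIC selection keeps each pure-noise
candidate in roughly one replicate in six.  Perfect screening of noise
variables is not a property AIC selection has, and the recovery studies
in the test suite report exactly the rates the procedure achieves.

## The synthetic-data generator

`simulate_trial()` emulates a lateral-view bird-dog trial in image
coordinates (y down): the trunk lies horizontally (shoulder at smaller x,
hip at larger x, 100 px apart by default), the lifted arm extends in −x
from the shoulder (upper arm and forearm 0.6 t each) and the lifted leg
in +x from the hip (thigh and shank 0.8 t each).  `droop_deg` rotates
both limbs below horizontal and `bend_deg` flexes the distal segments
further, so in the noise-free limit AG1 = 2·droop and
AG2 = AG3 = 2·(droop + bend) exactly — closed forms the geometry tests
exploit.  Limb keypoints sway around their nominal positions by a
mean-reverting Gaussian walk (reversion rate 0.1/frame) whose per-frame
step RMS is `sway_amplitude · t`; a sinusoidal option (0.25 Hz circular
path plus 5% noise) exists for closed-form checks.  The shoulder and hip
jitter with 5% of the sway amplitude.  The default
`sway_amplitude = 0.01` was chosen so that post-denoise SPB1 lands at a
few thousandths — the magnitude reported for real adult and child trials;
cohort parameter ranges (0.002–0.02) span quieter and noisier
participants.

Measurement artefacts are generated so that the cleaning rules they are
meant to exercise are unambiguous: visibility is drawn in [0.9, 1.0]
normally and [0.1, 0.4] on dropout frames (cleanly separated by the 0.5
threshold), dropout frames also displace the coordinates (sd 0.3 t) so
thresholding demonstrably matters, and spikes add a fixed-magnitude
offset in a random direction to limb keypoints.  `clean_trajectory`
holds the same sway path without artefacts, giving every trial a ground
truth.

`simulate_cohort()` draws per-trial parameters uniformly from stated
ranges (durations 10–30 s at 30 FPS by default — long enough for stable
indices, small enough that replicated cohort studies run in minutes on a
single core), pushes each trial through the real pipeline (denoise →
indices), and generates the clinician score as
`intercept + sum(beta · z(index)) + noise`, clipped to [1, 7].  The score
is built on the *computed* indices, not latent generator parameters, so
the generating coefficients are exactly the estimands of the regression
and recovery can be judged against them; it is generated on the raw
rating scale (midpoint intercept 4) because a standardized response
could not live on the 1–7 scale.  Coefficient-recovery studies therefore
standardize predictors but not the response.

What the generator does **not** emulate: estimator-specific error
structure (MediaPipe's smoothness and occasional limb swaps),
biomechanical coupling between adjacent joints (keypoints sway
independently), fatigue drift within a trial, rater disagreement, or
failures of pose estimation itself.  Passing tests therefore show the
pipeline computes its definitions correctly and recovers known structure
under realistic noise — not that the indices are valid on any particular
clinical population.

## Video geometry policy

`resize_policy()` documents the contract under which upstream pose
estimation should be run: videos 1000 px tall or more are scaled to one
third, shorter ones to one half, and frames are rotated so the head
points up (the caller states the raw head direction; the returned
rotation is degrees clockwise).  The package never touches pixels —
estimators are run elsewhere and their keypoint output is ingested via
the CSV/JSON dialects with an optional landmark-name mapping.

## Limitations

* All computation is strictly 2-D image geometry; estimator-provided
  depth is ignored.
* The outlier band removes a sizeable share of honest noise (see above);
  indices computed after denoising are smoother than the raw signal, and
  raw-mode scoring (`raw = TRUE`) exists for diagnostics.
* SPB3's normalisation is a convention choice; compare across
  conventions only after rescaling.
* AG1 assumes the camera was held level; AG2/AG3's clamp assumes head-up
  orientation.
* Published per-dataset index means derive from private videos and serve
  only as plausibility ranges for the generator's defaults, not as
  reproduction targets.
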