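---
title: "Methods: gait metrics, robust mixed models and phenotype clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait metrics, robust mixed models and phenotype clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its methods: the measurement
model behind the seven gait metrics, the statistical models, the synthetic
generator used as ground truth, and the numerical and design choices that
were genuinely open.

## The measurement pipeline

### Events

On a treadmill the trunk is roughly stationary while the belt carries the
stance foot rearward, so the lateral malleolus traces a sawtooth in the
fore-aft (X) direction: foot strike is its most anterior point, toe off its
most posterior. `detect_events()` finds candidate extrema from sign changes
of the discrete derivative (plateau-aware), refines each to the extreme
sample, then cleans the sequence with a minimum prominence (default 0.02 m)
and a minimum inter-event interval (default 0.2 s), enforcing
strike/toe-off alternation by keeping the more extreme of two same-type
neighbours. The prominence and refractory defaults are not dictated by the
measurement definition; they were chosen to reject marker jitter while
passing the slowest gait the package targets (0.2 m/s, where the stance
excursion is still an order of magnitude above the prominence threshold),
and both are arguments.

Event *frames* are integers, but support durations ride on fractions of a
frame: a leading double-support interval is only 0.10–0.18 s, so a
half-frame bias at 100 Hz is already a 3–5 % error in the double-support
asymmetry index. The detector therefore also reports sub-sample event
times. Fore-aft extrema of treadmill data are one-sided corners — a line of
slope −belt-speed meeting a locally quadratic swing reversal — so the
corner is located as the vertex of a parabola fitted to the three samples
on the flatter side of the extreme sample; a near-symmetric extremum (the
two one-sided slopes within 10 % of each other) uses the centred
three-point vertex instead. On noiseless synthetic gait this reduces the
mean event-time bias from roughly half a frame to under 0.05 frames, and
the stride table computes all durations from these refined times while
keeping integer frames for windowing.

### Filtering and windows

`lowpass_filter()` applies a zero-phase (forward–backward) Butterworth
low-pass, default 4th order per pass at 6 Hz, the standard conditioning for
gait kinematics; zero-phase filtering preserves event timing. Endpoints use
odd-reflective padding (at least three filter lengths) after subtracting
the segment mean, which makes the DC gain exactly one and suppresses the
zero-state start-up transient. `NA` spans are never interpolated: each
contiguous finite run is filtered independently and missing samples stay
missing. Noiseless synthetic data are analysed unfiltered
(`filter_cutoff = NULL`): filtering exists to attenuate marker noise, and
applying a 6 Hz filter to an ideal sawtooth only rounds the very corners
the events are defined by.

`select_analysis_bin()` returns the whole trial or a centred/final window
(protocols often record long trials but analyse the middle or final thirty
seconds). A stride belongs to the window iff its initiating foot strike
falls inside it, start-inclusive — the boundary rule is a convention the
package fixes, since strides straddle any window edge.

### The seven metrics

All asymmetry indices are `|paretic − nonparetic| / (paretic + nonparetic)`:
bounded in [0, 1], unitless, invariant to which limb is labelled paretic
(for neurotypical participants the right limb fills the "paretic" slot by
convention). Signed alternatives exist in the literature; the absolute
index is the default because group-level summaries of magnitudes stay
positive and limb assignment becomes immaterial.

* **Step length** of a limb at its foot strike is the fore-aft distance
  between the two malleoli at that frame; negative values (step-to
  patterns) are flagged and enter the index by magnitude.
* **Single-limb support** of a limb is the contralateral swing falling
  inside its stance; **double-limb support** (leading) runs from a limb's
  foot strike to the contralateral toe off. Both are averaged across
  unflagged strides before the index is taken.
* **Peak swing knee flexion** uses the three lateral markers: 180° minus
  the interior angle at the femoral epicondyle, so a straight leg reads 0°.
  This planar proxy is what a five-marker lateral set supports; it is not a
  joint-coordinate-system angle.
* **Trailing limb angle** is the angle between the lab vertical and the
  trochanter-to-fifth-metatarsal line at the limb's own toe off, positive
  with the foot posterior — the propulsion-relevant instant. A
  peak-during-terminal-stance variant would be a small extension; the
  evaluation instant is exposed by the design rather than hard-coded deep
  in the computation.
* **Circumduction** is the swing-phase peak lateral malleolus displacement
  relative to that stride's mean stance-phase lateral position, floored at
  zero toward the midline: it is a compensation magnitude, so only lateral
  excursion counts.
* **Hip hiking** is frontal-plane pelvic obliquity — `atan2` of the
  inter-crest height difference over their lateral separation, positive
  when the metric limb's crest is higher — peak during the limb's swing
  minus a reference, floored at zero. The reference posture is genuinely
  open: we use the obliquity at the stride's initiating foot strike
  (double support, both feet grounded, pelvis closest to level). A
  stance-mean reference is available (`reference = "stance_mean"`). An
  instant in mid-contralateral-stance is *not* suitable: with stance
  fractions above one half and the usual half-cycle limb offset it
  coincides with the metric limb's mid-swing, i.e. with the obliquity peak
  itself, and the metric would collapse toward zero.

Missingness propagates but never destroys a record: a trial without iliac
crest markers yields a record with hip hiking `NA` and the other six
metrics present, mirroring how real cohorts lose pelvis markers to
occlusion. The cohort inclusion rule (`apply_inclusion_filter()`) keeps
participants whose slowest speed is strictly above 0.20 m/s and who have a
standing calibration, recording the exclusion reason.

## The synthetic generator

`generate_trial()` is not a biomechanical simulation; it is the *generative
inverse of the metric definitions*, built so that each metric's ground
truth equals a parameter:

* The malleolus fore-aft course is stance retreat at belt speed joined to a
  half-sinusoid-velocity swing, so foot strike and toe off are provably at
  the trajectory extrema and their times are known in closed form.
* On a treadmill at steady state the two step lengths must sum to
  `belt_speed × stride_time`; the constructor enforces this and places the
  per-limb anterior extremes so the step-length definition returns the
  parameters exactly.
* Temporal truth follows from the stance fractions with a half-cycle limb
  offset: single support of one limb is the contralateral swing,
  `(1 − f_contra) T`; leading double support is `(f_contra − 1/2) T`.
* The knee is placed by exact 3-D two-link inverse kinematics between hip
  and ankle. During swing the hip-ankle distance is prescribed to dip to
  the distance implied (law of cosines) by the requested peak flexion at
  mid-swing, so the measured peak equals the parameter. During stance the
  leg rides near-straight (5° floor) with the ankle marker bobbing a few
  centimetres at the stance extremes — a stylized heel-strike/heel-rise,
  adequate for markers but not a sagittal joint-angle model. Swing-phase
  knee flexion below 10° is rejected as unreachable over the near-straight
  boundary configuration.
* The hip's fore-aft position is pinned (fixed-point solve) so the trailing
  limb angle at toe off equals its parameter; pelvic obliquity follows a
  half-sine over each limb's swing with the crest heights derived so the
  measured `atan2` angle is exactly the profile; the swing-phase lateral
  ankle bump is the circumduction parameter.
* Gaussian noise of `noise_sd` is added per axis and frame; markers can be
  dropped (`drop_markers`) to emulate occlusion.

`generate_cohort()` draws participant-level parameters from group profiles
(`group_profile()`): means, between-participant SDs, and linear
speed-slopes relative to each participant's self-selected speed. The
neurotypical profile encodes symmetric gait (asymmetries near zero, knee
flexion ≈ 62° rising ≈ 12°/(m/s), trailing limb angle ≈ 22°, hip hike
≈ 1.6°, circumduction ≈ 8 mm); the stroke profile encodes hemiparesis
(SLA ≈ 0.085, stance-time imbalance, knee ≈ 45° rising only ≈ 4°/(m/s),
TLA ≈ 14°, hip hike ≈ 6.4°, circumduction ≈ 28 mm) — magnitudes chosen to
be clinically plausible for chronic hemiparesis at treadmill speeds of
0.2–1.4 m/s, not calibrated to any particular cohort, since group-level
model coefficients rather than raw distributions are what published work
reports. Speeds form a per-participant ladder (80 %, 100 %, 120 % of
self-selected plus a fastest condition at 145 %). A synthetic
Lower-Extremity Fugl-Meyer score (0–34, integer, clipped) is generated for
stroke participants as a noisy linear map of a latent impairment composite
of the realized deviations, anticorrelated with impairment by
construction — enough to exercise cluster-versus-clinical-score contrasts,
with no claim of clinical realism. Each participant consumes an
independent sub-stream of the master seed, so removing one participant
leaves the others bit-identical.

What the generator does *not* emulate: soft-tissue artefact and
autocorrelated marker noise, stride-to-stride variability within a trial
(each trial is exactly periodic), pelvis translation and rotation beyond
frontal-plane obliquity, foot articulation, double-support force sharing,
and any kinetics. Passing the recovery tests therefore demonstrates that
the pipeline inverts the measurement definitions correctly and tolerates
white marker noise — not that it is robust to every artefact of real
motion capture.

## Statistical models

### Per-metric mixed models

Each metric is modelled as
`y = β0 + β_group·G + β_speed·s̃ + β_int·G·s̃ + b_participant + ε`, with
`G = 1` for stroke (so positive group effects mean "larger in stroke") and
`s̃` the speed centred on the grand mean of the included observations,
making `β_group` the between-group difference at the sample's average
speed. The random intercept absorbs the repeated measures per participant.
The classical path is REML via `lme4` with Satterthwaite denominator
degrees of freedom via `lmerTest`. Rows missing a metric are dropped for
that metric only.

The robust path guards against the heavy-tailed residuals common in gait
metrics. It is an M-type estimator on the mixed-model (Henderson)
equations: residuals and random intercepts are both downweighted on their
respective scales, the weighted equations are iterated to convergence
(relative coefficient change < 1e-8, at most 200 iterations), and an outer
loop re-estimates the variance components by REML under the current
squared weights (squaring bounds a gross outlier's contribution to the
scale estimates; a consistency factor `E[ψ²]` restores the residual scale
under a Gaussian model). Standard errors carry the usual
`E[ψ²]/E[ψ′]²` variance correction. Three deliberate choices:

* **Score function.** The default is the redescending Tukey bisquare
  (c = 4.685): a gross outlier's influence vanishes rather than being
  capped, which is what bounds its coefficient displacement to a small
  fraction of the classical displacement in our validation studies. The
  monotone Huber score (c = 1.345) is available; it is more traditional
  but lets a 10-σ outlier shift its participant's intercept by ≈ c·σ/n_i,
  which cascades into that participant's other residual weights and can
  move slope terms appreciably in designs with few observations per
  participant.
* **Degrees of freedom.** No closed-form Satterthwaite recipe exists for
  the robust path; robust t-statistics reuse the classical fit's
  Satterthwaite degrees of freedom on the same design. This is a
  documented approximation; with the cohort sizes targeted here df ≈ 25–80
  and the approximation is benign.
* **The classical anchor.** With `tuning = Inf` every weight is one and
  the robust path reproduces the classical REML fit exactly (to machine
  precision) — a useful invariant that the implementation preserves by
  keeping the variance components at their (weighted) REML estimates
  rather than switching to a separate robust scale chain.

Internally each metric is fitted on a unit-variance response and the
estimates rescaled afterwards — an exact linear transform that avoids
optimizer scale warnings for metrics measured in metres. If the
random-intercept variance collapses to zero the fit falls back to a
fixed-effects-only robust regression with a warning.

Validation (rerun by `scripts/acceptance.R`): on cohorts of 50
participants × 4 speeds simulated from the model itself with effect sizes
in the regime of hemiparetic step-length asymmetry (β ≈ 0.1/0.08/−0.08/
−0.05, σ_b = σ_e = 0.04), the robust estimator's ±2-SE intervals cover the
true group, speed and interaction coefficients ≥ 93 % of the time, the
type-I error of the group test at α = 0.05 sits inside [0.025, 0.075], and
the mean coefficient displacement caused by a single 10-σ outlier is about
a tenth of the classical fit's displacement. The displacement bound is
asserted on the mean over twenty outlier placements: for any estimator,
ignoring the contaminated observation is equivalent to deleting it, and
the deletion effect of that observation's clean value can occasionally
rival the classical displacement, so a per-instance bound would be
unattainable in principle.

### Phenotype clustering

Per speed condition, participants with any missing metric are excluded
(mirroring per-condition marker loss), the 7 metrics are z-scored with the
sample SD *within that condition* (a joint-scaling sensitivity mode is a
one-line variant since `zscore_scale()` is exposed), and k-means runs in
the full scaled space: Lloyd iterations (via `stats::kmeans`) seeded by
k-means++, best of 25 restarts by total WSS, labels canonicalized by
decreasing cluster size. k is chosen by maximizing the mean silhouette
width over k = 2…8, ties toward the smaller k. The WSS/BSS decomposition
is reported per clustering and satisfies WSS + BSS = TSS to 1e-8 on every
run (an internal identity check). Variable importance retrains a random
forest (500 trees) to predict the cluster labels and reports the raw
permutation mean decrease in out-of-bag accuracy per metric; with
correlated informative metrics the importance is shared, which is
documented behaviour of permutation importance rather than a defect. PCA
(SVD on the scaled, centred table; component signs fixed so the dominant
loading is positive) is used for display only.

Across-condition comparison matches cluster identities by nearest
centroids in scaled space (k-means labels are arbitrary), restricts to the
common participants, and reports switchers and WSS/BSS changes. Clinical
contrasts between the two clusters' stroke members use the two-sided
Mann–Whitney U: exact enumeration when the combined sample is ≤ 20 and
tie-free, otherwise the tie-corrected normal approximation — the cut
matters at the subgroup sizes (≈ 10–17) these analyses see.

Validation: cohorts built from strongly contrasted profiles (measured
standardized group separation ≈ 4.9 pooled SDs — comfortably above the
3-SD study condition, where two Gaussian clusters would still overlap by
≈ 7 % and perfect recovery could not be demanded) give silhouette-chosen
k = 2 and adjusted Rand index 1.0 against the true groups across twenty
seeds; a profile pair whose impairment gap widens with speed yields
BSS(fast) > BSS(self-selected) in every seed. The importance probe —
labels defined by one metric, six pure-noise metrics — ranks the
informative metric first in 20/20 seeds with noise importances within
±0.02 of zero.

## Problem sizes and determinism

The validation suite uses trials of 10–30 strides at 100 Hz, sweeps of 50
parameter draws, 400 simulation replicates for coverage and type-I error,
and 20 seeds for the clustering and importance studies; these sizes give
the binomial margins quoted above while keeping a full run in minutes on a
single core. Every stochastic component takes an explicit seed
(`gait_params(seed=)`, `generate_cohort(seed=)`, `kmeans_fit(seed=)`,
`rf_importance(seed=)`), cohorts use per-participant sub-streams, and a
fixed seed reproduces every table byte-for-byte.

## Known limitations

* The event definition is treadmill-specific; overground data would need a
  belt-frame reconstruction the package deliberately omits.
* The knee angle is a lateral-marker planar proxy; the hip-hiking angle is
  pelvic obliquity, not a hip joint angle.
* C3D files are not read natively; trials arrive as TRC or long CSV (a
  mapping config adapts other labs' axis conventions and marker names).
* The robust estimator's degrees of freedom are borrowed from the
  classical design (see above).
* The generator's periodicity means stride-to-stride variability in real
  data — and its effect on the stride-mean metrics — is untested territory;
  the noise-robustness checks cover white marker noise only.
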