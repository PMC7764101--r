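---
title: "Connectivity-based parcellation of striatum and dopaminergic midbrain: methods"
author: "midparc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-based parcellation of striatum and dopaminergic midbrain: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(midparc)
```

## The method

Connectivity-based parcellation subdivides a gray-matter seed region by
assigning each of its voxels to the remote target it is most strongly
connected to, with connection strength measured by probabilistic streamline
counts. `midparc` implements the two-step variant used to map the
topography of the dopaminergic midbrain (the SNc/VTA complex):

1. **Striatal step.** The striatal seed ROI is parcellated against three
   ipsilateral cortical target groups — limbic, prefrontal and
   sensorimotor — giving three cortico-striatal territories.
2. **Midbrain step.** The three striatal territories from step 1 become the
   target masks for tractography seeded in the midbrain ROI, so midbrain
   voxels inherit the striatal territory labels.

Each step is the same four-stage pipeline:

* **Seed-based tractography** — 5000 streamlines per seed ROI (step size
  1.25 mm, maximum turning angle 30°). Targets act as inclusion masks: a
  streamline that enters a target mask is counted as connecting its seed
  voxel to that target and is immediately terminated; streamlines that
  never reach a target are retained in the tractogram but count for
  nothing. No exclusion masks.
* **Track-density mapping** — for each target, the full path of every
  streamline that reached it is rasterized onto the voxel grid (each
  streamline increments a voxel at most once), and the count image is
  multiplied by the binarized seed ROI. Because streamlines are seeded
  inside the seed ROI, the seed-restricted path density is effectively the
  endpoint distribution; an `endpoints_only` switch rasterizes only the
  terminal points for sensitivity analysis.
* **Normalization** — each target's count map is divided by its mean
  intensity over *all* seed-ROI voxels (zeros included), making maps with
  different streamline yields comparable: proportional maps normalize
  identically, so winner-take-all is invariant to per-target count scaling.
* **Classification** — each seed voxel goes to the normalized map with the
  highest intensity there (`find_the_biggest`-style hard segmentation). A
  voxel where every map is zero is `unclassified`; exact ties go to the
  lowest-index label in the fixed order (limbic, prefrontal, sensorimotor).
  Both conventions are deterministic and are not dictated by the protocol
  we emulate — they are this package's fixed choices.

Group-level **maximum probability maps** count, per label and voxel, the
subjects whose parcellation carries that label there, and threshold at a
fraction of the sample. The threshold count is `ceiling(threshold * n)` —
"at least half" is then exact for both even and odd group sizes (12 of 24,
15 of 30) — with the extra convention that a voxel labeled in no subject is
never included, so threshold 0 yields the union and threshold 1 the
intersection.

## Quantitative layer

* **Streamline density index (SDI).** Per parcel,
  `SDI = 100 * v_parcel / V_seed`, volumes in voxels of the common grid.
  Summed over the three labels plus 100 times the unclassified fraction it
  is exactly 100 for every parcellation (the package exposes the
  unclassified fraction explicitly rather than folding it away; observed
  label sums below 100 are therefore interpretable).
* **Mean FA along streamlines.** 10,000 streamlines are seeded from each
  midbrain parcel and propagated freely (no targets; propagation ends on
  field exhaustion, the angular threshold, or the step bound). FA is
  sampled by trilinear interpolation at every streamline point and averaged
  over all points pooled across streamlines. A per-streamline variant
  (mean of per-streamline means) is available; the two differ when
  streamline lengths vary, and pooled is the default. Nearest-neighbour
  interpolation is available as a switch.
* **Inference.** Each measure (striatal SDI, midbrain SDI, FA) is fitted
  with a full-factorial fixed-effects ANOVA on side × parcel × diagnosis.
  Sums of squares are Type III (sum-to-zero contrasts), the conventional
  choice for the unbalanced 24-vs-30 design and the default of the
  commercial package the protocol names; sequential (Type I) is a switch.
  Partial eta-squared is `SS_effect / (SS_effect + SS_error)`. Post-hoc
  pairwise contrasts use estimated marginal means (unweighted averages of
  cell means), the pooled residual MSE, and Bonferroni adjustment over the
  `choose(k, 2)` pairs. Observations are subject × side × parcel rows
  treated as independent, matching the residual degrees of freedom the
  protocol reports (54 × 2 × 3 − 12 = 312); a repeated-measures variant is
  out of scope.

## The tracker

The orientation model is a discrete per-voxel mixture of up to four
(direction, weight) pairs rather than a spherical-harmonic fiber
orientation distribution: the tracker only ever draws a direction from the
local distribution, and a discrete mixture exercises every part of the
seeding/stepping/termination logic while keeping the phantom's ground
truth exact. For the same reason the propagator is first-order: at each
step one direction is drawn from the voxel mixture restricted to the cone
of 30° around the previous direction (candidates are first sign-flipped
into the hemisphere of the previous direction, since orientation mixtures
are antipodally symmetric). This deliberately simplifies the second-order
integrator used on real FOD data; the scientific content being tested —
the topography of seed-to-target streamline counts — does not depend on
the integrator's order.

Conventions fixed for testability:

* Voxel-center coordinates, 0-based indices, RAS axes; positions in mm are
  `index * voxel_size`; mask membership at a floating-point position is by
  nearest voxel.
* No partial final step: the terminating point is the first regular step
  landing inside a target mask, so consecutive points are always exactly
  one step apart and turning angles never exceed the threshold — both are
  asserted over stored tractograms.
* Seeding is volume-uniform over the continuous extent of the seed-ROI
  voxels, with exactly `n_streamlines` attempts (not redraws until 5000
  successes); the protocol text does not fix either choice, so both are
  explicit knobs.
* The first direction is drawn with no cone constraint and random
  polarity; a streamline that dies within one step is re-attempted once
  with the opposite polarity. Trajectories are invariant to flipping the
  sign of every stored field direction (checked bit-for-bit in the tests).
* All randomness flows through integer seeds; identical inputs and seeds
  give byte-identical tractograms, parcellations and reports.

Streamlines are propagated in lockstep as a batch with vectorized state
updates, which makes pure-R tracking fast enough (a 5000-streamline
tractogram on the 64³ phantom takes well under a second).

## The phantom

Real diffusion data enters the original protocol through preprocessing,
FOD estimation and atlas ROIs — all out of scope here. Instead, a digital
phantom supplies every input with known ground truth:

* Per side, a striatal box split into three equal slabs along z
  (ventro-dorsal), each joined to its own cortical target box by a straight
  bundle along +y; a compact midbrain box split into three medio-lateral
  slabs (medial = limbic, matching the known SNc/VTA arrangement), each
  joined to the x-matched portion of its striatal slab by an oblique
  bundle. Left and right are mirror images by default; an `asymmetry` knob
  shifts the right-side slab boundaries to induce a side effect, since the
  emulated study reports side effects but no mechanism for them.
* A bundle occupies the forward sweep of its origin box along the bundle
  direction, which guarantees a streamline following the bundle from
  anywhere in the origin never exits the orientation field before arrival.
  The three midbrain bundles are kept x-disjoint along their whole length
  — where prisms overlap, streamlines can hop between bundles whose
  directions lie within the 30° cone of each other, which is exactly the
  crossing-fiber confound the `crossing_fraction` knob reintroduces on
  purpose (as a shared secondary direction orthogonal to the locally
  dominant one). `angular_noise_deg` jitters every stored direction with
  the given angular SD. Both default to 0: the default phantom is the
  noise-free condition whose topography the pipeline should recover
  essentially perfectly, and the knobs degrade it monotonically (asserted
  as a trend test).
* The midbrain box is half a slab thick in z so that the z-spread its
  bundles accumulate over the corridor still lands inside the one-slab-high
  striatal landing zones; with a full-height box, edge streamlines
  overshoot into the neighbouring territory and blur the ground truth.
* Cohort FA volumes are `baseline + offset(SZ) + N(0, sd)` per voxel,
  clipped to [0, 1]. Defaults: baseline 0.47 and offset −0.036 (the
  emulated study's group means and difference), noise SD 0.05 (its
  mid-range per-parcel SD). Per-subject seeds derive deterministically
  from one master seed.

What the phantom does *not* emulate: raw DWI signal and acquisition
artifacts, registration error, partial-volume effects, spatially
structured FA (FA is white everywhere up to the global offset), and
anatomical bundle geometry (the protocol's source gives none, so geometry
is parameterized, not anatomical). Passing recovery tests therefore shows
the pipeline is correct and well-calibrated on clean topographies — not
that it is robust to real-data confounds beyond the crossing/noise knobs.

## Study sizes used by the tests and calibration runs

Chosen once as this package's analysis design:

* Topography recovery: 10 phantom instances at 64³, 5000 streamlines per
  seed ROI, both sides — median per-label Dice ≥ 0.9 (striatal) and
  ≥ 0.85 (midbrain).
* Type-I calibration: 200 replicate null cohorts of 8 + 8 subjects on a
  32³ phantom, FA sampled along 500 streamlines per ground-truth midbrain
  territory with shared tracking geometry (one tractogram per parcel,
  every subject's FA volume interpolated along it). Sharing the geometry
  halves nothing scientifically — subject noise fields are independent, so
  the nominal 5% level is unaffected — but removes the dominant cost of
  the replicate loop. The main study, by contrast, tracks from each
  subject's own parcels with per-subject seeds.
* Effect recovery: one full-size cohort (24 + 30), offset −0.036, noise SD
  0.05; the group difference comes back within Monte-Carlo error because
  per-subject sampling error (SD ≈ noise/√points) is an order of magnitude
  below the offset.
* Post-hoc pattern power: 100 replicate cohorts of subject-level records
  with injected midbrain parcel means (25, 27, 41.5) and SD 12. The means
  reproduce the observed post-hoc differences (≈ 16.4 and 14.3 for the two
  sensorimotor contrasts, ≈ 2 for limbic-prefrontal) and the SD sits at
  the upper end of the observed per-cell SDs (7–13); a priori power puts
  the joint pattern — both sensorimotor contrasts significant,
  limbic-prefrontal not — near 93%, comfortably above the 90% check.
  With a much smaller SD the limbic-prefrontal difference itself becomes
  significant and the pattern is unattainable by design.

## Numerical and degenerate-input choices

* An all-zero track-density map normalizes to all-zero and is flagged; it
  can never win a voxel, so a fully disconnected target simply yields no
  parcel (and an empty striatal parcel is dropped from the midbrain step
  with a warning — its midbrain label then cannot occur).
* A saturated ANOVA fit (zero residual variance) reports F = ∞, p = 0 for
  terms with real sums of squares and F = 0, p = 1 for terms whose SS is
  numerical dust (relative threshold 1e-12).
* FA interpolation clamps positions to the grid hull, so the single
  off-grid terminal point of a streamline samples the border value.
* The config hash (md5 of the canonical JSON serialization, excluding the
  output path) is stamped into every text output; outputs from different
  configurations are thereby detectable when mixed.

## Known limitations

* First-order tracking and discrete mixtures understate the angular
  dispersion of real FOD-based tractography; absolute streamline yields
  are not comparable to real-data runs.
* The independence assumption of the three-way ANOVA ignores the
  within-subject correlation of side × parcel rows, exactly as in the
  emulated protocol; a mixed-effects variant would be the principled
  alternative.
* MPMs assume all subjects share one grid (true for the phantom); no
  registration machinery is included.
* `Tractogram` objects hold all points in memory; at the default sizes this
  is tens of MB, but very long free-propagation runs with large `max_steps`
  can grow quickly.
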