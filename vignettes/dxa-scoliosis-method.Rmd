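---
title: "Automated scoliosis identification from total-body DXA scans: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated scoliosis identification from total-body DXA scans: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dxascol)
```

## The problem

Scoliosis — lateral curvature of the spine, conventionally diagnosed at a
Cobb angle of 10° or more on a standing radiograph — cannot be studied at
population scale with radiographs because of the radiation dose. Total-body
DXA scans, routinely collected in large cohorts for body-composition
research, image the spine at a small fraction of that dose, and supine
spinal curvature can be graded from them. Doing this manually takes minutes
per scan and does not scale to cohorts of tens of thousands; `dxascol`
implements an automated pipeline that reads a whole-body DXA-like image and
produces a continuous *suspiciousness score* for scoliosis, a three-class
curvature grade, and a positioning-error score used to exclude scans whose
pose invalidates curvature assessment. Around the pipeline it provides the
full diagnostic-validation toolkit used to evaluate such a screening tool:
cut-off sweeps, hypothetical-population projection of predictive values,
repeat-scan reliability (Cohen's kappa) and association statistics.

Because real cohort images are access-controlled, the package is organised
around a synthetic phantom generator with analytic ground truth; every
stage is validated against quantities that are known exactly by
construction.

## Pipeline stages

1. **Height standardisation** (`standardize_height`). Images are
   isotropically rescaled (bilinear) to a common height, 512 px by default;
   width follows as `round(w * target/h)`, so the aspect ratio — and hence
   every angle in the image — is preserved. No padding is applied.
2. **Heuristic segmentation** (`segment_body`). The subject is expected to
   have a head, a spine, a pelvis and two legs. Foreground is the largest
   connected component above the Otsu threshold. The head is everything
   above the neck (the row-width minimum in the upper body); the crotch is
   the first persistent split of the foreground around the body midline;
   the pelvis is the band between the lower-torso width step and the
   crotch; legs are the two components below the crotch; the spine is the
   per-row maximal-intensity ridge within the central 60 % of the torso,
   grown to the contiguous bright run around it. A row only counts as spine
   if its ridge is at least 0.2 intensity units above the row median —
   without this prominence check, neck and pelvis rows contribute spurious
   midline points. Violated expectations raise errors naming the failed
   expectation rather than returning a partial segmentation.
3. **Mid-spine map** (`compute_midspine_map`). A per-pixel likelihood of
   being the middle of the spine: each spine row gets a Gaussian bump
   (σ = 3 px at the 512-px standard height) centred at the
   intensity-weighted centroid of its spine pixels, zeroed outside a 7-px
   dilation of the spine mask, renormalised so every supported row peaks
   at 1.
4. **Midline and curvature** (`extract_midline`, `measure_curvature`). The
   midline is the row-wise centre of mass of the map, smoothed by a cubic
   smoothing spline. The curvature angle is the *tangent range*
   `max θ − min θ` with `θ(row) = atan(dcol/drow)` along the smoothed
   midline — a supine Cobb analogue measured on the whole curve rather
   than on vertebral end plates. Grades: below 6° `none`, 6–10° (inclusive)
   `mild_6_10`, above 10° `major_gt_10`; 10.0° is graded mild because the
   class scheme names the middle class "6° to 10°" and the top class
   "> 10°".
5. **Scores** (`suspiciousness`, `positioning_error_score`, `binarize`).
   The suspiciousness score is a logistic in the angle
   (`plogis(1.5 * (angle − 6))`): 0.5 at 6° (the smallest graded curve),
   ≈ 0.9975 at 10°, so the operating cut-offs 0.95–0.9995 correspond to
   angle thresholds of roughly 8–11°. The original system's score came
   from a learned classifier whose exact form is not recoverable; the
   logistic stand-in preserves the score's contract — range (0, 1),
   strictly increasing with curve size — which is all the downstream
   machinery uses. Positioning error is the clipped maximum of three
   normalised components: |principal-axis tilt|/10°, |lateral centroid
   offset|/(15 % of width), leg-length asymmetry/0.2. Scans scoring
   strictly above 0.5 are excluded before any diagnostic statistic is
   computed. Binarisation is strict (`score > cutoff`), default cut-off
   0.999.

## The phantom generator

`generate_phantom` renders a supine silhouette from parameterised shapes
(head disc, superellipse torso and pelvis, two leg capsules, a bright
spine band 5 % of the image width wide), at a default 800 × 300 px. The
spine midline's column offset is a smooth bump (`single_C`, piecewise
raised cosine with configurable apex position) or a two-lobed S
(`double_S`, `sin²·cos` form), both with **zero tangent at the spine
ends**: the extreme tangents then lie strictly inside the spine, so the
ground-truth angle is insensitive to a few rows gained or lost at the
segmentation boundaries — with an end-loaded parameterisation such as a
plain sinusoid, trimming two boundary rows visibly biases the recovered
angle. The amplitude is solved numerically (`uniroot` on the exact
tangent-range function) so that the tangent range equals
`curve_angle_deg`; the generator's `true_angle_deg` is therefore analytic,
and re-measuring the noiseless midline with `measure_curvature` recovers
it to well under 0.5°. The spine band is rendered with partial-volume
(soft) edges: with hard binary edges, column quantisation of the band
adds deterministic wiggle to the per-row centroids that the spline
converts into ~1° of spurious tangent range on small curves.

Positioning perturbations are a whole-body rotation about the image
centre (`tilt_deg`), a lateral shift (`lateral_offset_px`) and a
shortened right leg (`leg_asymmetry`). Noise is additive Gaussian with a
signal-dependent scale, `sd = noise_sigma * sqrt(0.25 + I)` — a generic
stand-in for the Poisson–Gaussian character of radiographic noise.
Everything is deterministic given the spec's seed.

`generate_repeat_pair` re-renders the same spine with re-sampled
tilt/offset/asymmetry and fresh noise, emulating repeat scans with
repositioning between visits. `generate_cohort` draws a screening cohort:
prevalence 5.9 % by default (the adolescent population prevalence used
throughout for projections), scoliotic subjects split evenly between the
mild (6–10°) and major (11–28°) classes with uniform angles, normals at
0–5°, routine positioning jitter (tilt SD 1.5°, offset SD 3 px, asymmetry
SD 0.02), and an optional fraction of gross positioning errors (tilt
drawn from ±6–9°, which lands the component score in 0.6–0.9, safely
above the 0.5 exclusion threshold). The half/half mild–major split and
the angle ranges are a package choice — field surveys report most
screened curves near the diagnostic boundary, but no distribution is
published for this setting; the split exercises both sides of every
decision boundary, which is what the validation needs.

### What the phantoms do and do not emulate

They reproduce the *geometry* the pipeline depends on (five-part anatomy,
a bright medial spine band with controlled curvature, pose perturbations)
but none of the photometric complexity of real DXA: no bone-density
variation, ribs, arms, soft-tissue composition gradients, scanner
artefacts, or vertebral-level structure. Passing phantom tests therefore
demonstrates that the *measurement machinery* is correct and stable under
noise and repositioning — not that the heuristics would segment real
scans, which is why the published cohort performance figures are treated
as external inputs (below), never as something these experiments could
reproduce.

## Diagnostic machinery

- `project_population(se, sp, prev, n)` integerises the implied 2 × 2
  table by rounding the diseased count, the true positives and the true
  negatives, deriving complements by subtraction — the table always sums
  to `n` and inverts to its inputs within count-rounding error. This
  rounding convention is validated by reproducing the published worked
  example exactly (tp 510 / fn 80 / tn 9118 / fp 292 at
  sens 86.5 %, spec 96.9 %, prevalence 5.9 %, n = 10,000, giving
  PPV 63.6 %, NPV 99.1 %, predicted prevalence 8.0 %). One published
  column (the 0.99 cut-off) prints an NPV of 99.2 where the arithmetic
  gives 99.3 under every rounding convention we tried; it is flagged as a
  typesetting inconsistency and not targeted.
- `roc_auc` computes the AUC as the midrank Mann–Whitney statistic (ties
  count ½) with a stratified bootstrap percentile CI (2000 resamples,
  seeded; cases and controls resampled separately). The paper-tier
  alternative (DeLong) is not used because the CI method behind the
  published intervals is unstated; the bootstrap makes the choice explicit
  and reproducible. The point estimate is cross-checked in the tests
  against both an exhaustive pairwise oracle and an independent ROC
  library.
- `cohen_kappa` implements unweighted kappa with the large-sample
  standard-error CI and the conventional agreement bands (0.81–1.00
  "almost perfect"). No installed package provides it, so it is
  implemented directly and verified against the hand formula on an
  exhaustive sweep of small 2 × 2 tables.
- `chi2_association` and `unpaired_t_test` wrap `stats::chisq.test`
  (no continuity correction by default) and `stats::t.test` (Welch by
  default); both defaults are stated because the source analyses name
  only the test family.
- `sweep_cutoffs` reports one row per cut-off. AUC is threshold-free, so
  the same score AUC is attached to every row; a cut-off above every
  observed score yields a row with defined sensitivity/specificity and
  `NA` predictive values rather than aborting the sweep.

## Numerical choices

- **Midline smoothing**: smoothing spline with 12 degrees of freedom over
  the ~200 spine rows at standard height. Fewer (8) systematically shrinks
  the tangent range by ~2 %; many more begins to chase per-row noise into
  the derivative. A two-pass robust fit drops points whose residual
  exceeds `max(4·MAD, 2 px)` — single rows where the ridge latches onto a
  bright non-spine pixel otherwise bend the spline tail and can triple a
  small angle.
- **Tangent trimming**: 2 % of rows at each end are excluded from the
  tangent range, so an isolated boundary row cannot set the extreme.
- **Curve counting**: curves are counted as sign-alternating arcs of the
  midline's lateral deviation from its end-to-end chord (|deviation| >
  0.5 px): one for a C, two for an S. Counting sign changes of the
  centred tangent was considered and rejected — it reports two "curves"
  for a plain C bump because the tangent itself is sign-alternating on
  any curve that returns to vertical.
- **Degenerate inputs**: segmentations missing an expected structure,
  midlines under 10 rows, single-class AUC inputs, zero-margin tables and
  both-raters-constant kappa all raise (or flag) typed conditions rather
  than returning numbers.

## Validation experiments (sizes used)

The shipped tests and the acceptance script run, end to end: the
noiseless recovery ladder over injected angles {0, 4, 8, 12, 20, 30}°
(recovered within ±1°, suspiciousness strictly increasing), the same
ladder with default noise and ±2° tilt (within ±3°), Dice ≥ 0.8 of every
segmented part against the generator masks, 200 repeat-scan pairs at low
jitter (tilt SD 2°, offset SD 4 px, asymmetry SD 0.02) for the kappa
reliability simulation, and a 150-subject synthetic screening cohort for
the exclusion-then-evaluation batch path. On the synthetic pairs the
binary calls agree almost everywhere, so kappa sits at the top of the
"almost perfect" band — consistent with, and necessarily cleaner than,
repeat-scan reliability on real images.

## Known limitations

- The segmentation heuristics assume a supine, roughly centred,
  five-structure silhouette; heavily rotated subjects, amputees or scans
  with arms raised will fail (loudly) rather than degrade gracefully.
- The suspiciousness calibration is a documented config choice, not a
  learned quantity; absolute score values are only meaningful relative to
  that calibration, which is why all evaluation is phrased in terms of
  cut-off sweeps rather than score magnitudes.
- The tangent-range angle is measured on the whole midline; it is a
  Cobb *analogue*, and supine DXA curvature is known to under-read
  standing Cobb angles by several degrees. No attempt is made to model
  that offset.
- Axial (torsional) rotation, curve laterality reporting and
  vertebra-level landmarks are out of scope.
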