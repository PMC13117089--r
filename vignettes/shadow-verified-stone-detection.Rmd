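---
title: "Shadow-verified stone detection in B-mode ultrasound: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shadow-verified stone detection in B-mode ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echolith)
```

## The problem and the model

Calcified kidney and gallbladder stones appear on B-mode ultrasound as a
hyperechoic focus — a bright echo from the stone's proximal surface — with a
*posterior acoustic shadow*: a hypoechoic column beneath the stone, produced
because the stone reflects and absorbs most of the incident beam. Purely
intensity-based detectors confuse stones with other bright structures
(vessel walls, fascia, specular reflections); the shadow is the physical
signature that distinguishes a calcification. `echolith` implements an
explainable rule-based pipeline that detects the bright focus *and* verifies
it through its shadow, inside a clinician-drawn rectangular ROI.

The pipeline, run by `detect_stone()`:

1. **Preprocessing.** The ROI is min–max normalized and scaled to
   *scaled intensity units* (SIU, `scale_max = 1000`), then median-filtered
   (3×3, edge-replicated) to suppress speckle impulses.
2. **Candidate generation.** A white top-hat with a disc of radius 5 px
   isolates locally bright structures narrower than the disc. Pixels
   strictly above the 99th percentile of the enhanced ROI form the candidate
   map; 8-connected components below 20 px are dropped; components that
   contain no regional maximum of the enhanced image (broad, ramp-like
   responses) are dropped. For each surviving component we compute area `A`,
   mean SIU intensity `mu`, centroid, bounding box, eccentricity, solidity
   and moment-ellipse axis lengths `L_max`, `L_min`. Candidates are ranked
   by brightness `mu * A` (integrated intensity) and the top `K = 5` kept.
3. **Screening.** *Local contrast*: the candidate-box mean minus the mean of
   a surrounding ring (box expanded 5 px, box excluded, clipped to the
   image); candidates below `tau_lc = 300` SIU are rejected. *Shadow
   region*: axial profiles are taken for 30 rows starting just below the
   candidate box — the centre profile `PC(y)` averages a 5-px band at the
   candidate centroid, the lateral reference `PL(y)` averages bands offset
   ±10 px. The score is
   `mean(PL - PC) + rho * (median(PCe) - median(PCl))` with `rho = 0.5`,
   where `PCe` is the profile up to its steepest decrease and `PCl` the
   segment from there to the steepest subsequent increase. The first term
   measures *selective* attenuation of the centre band relative to adjacent
   tissue; the second rewards the sharp bright-to-dark transition at the
   stone site. Candidates below `tau_sr = 100` SIU are rejected.
4. **Scoring and selection.** Survivors are ranked by
   `0.35*brightness + 0.25*local_contrast + 0.25*shadow_region -
   0.15*shape_penalty`, where the shape penalty
   `0.4*eccentricity + 0.3*max(0, 1 - solidity) +
   0.3*max(0, L_max/L_min - 2)` suppresses line-like, fragmented or
   over-elongated candidates.
5. **Shadow localization.** The shadow onset is the row after the steepest
   decrease of the winner's centre profile; the posterior shadow ROI is the
   winner's column span from the onset down 30 rows (clipped).

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `scale_max` | 1000 | SIU | intensity scale after min–max normalization |
| `se_radius` | 5 | px | top-hat disc; sets the scale of "stone-like" |
| `percentile_q` | 99 | % | candidate threshold (strict `>`; type-7 quantile) |
| `min_area` | 20 | px | suppresses noise blobs |
| `k_max` | 5 | — | candidates passed to screening |
| `ring_margin` | 5 | px | local-contrast ring width |
| `tau_lc` | 300 | SIU | contrast rejection threshold |
| `band_halfwidth` | 2 | px | profile band half-width (width 5) |
| `depth` | 30 | px | axial analysis depth |
| `lateral_offset` | 10 | px | centre-to-reference band gap |
| `rho` | 0.5 | — | weight of the drop-segment median term |
| `tau_sr` | 100 | SIU | shadow rejection threshold |
| `alpha, beta, gamma` | 0.4, 0.3, 0.3 | — | shape-penalty weights |
| `elong_tol` | 2.0 | — | axis-ratio tolerance before penalizing |
| `w_b, w_c, w_s, w_p` | 0.35, 0.25, 0.25, 0.15 | — | composite-score weights |
| `pixel_spacing_mm` | 0.35 | mm/px | pixel-to-mm conversion |

Thresholds are absolute on the SIU scale: shifting all ROI intensities
leaves both screen statistics unchanged (they are differences), while
scaling intensities scales them proportionally — a documented, tested
consequence of the design.

## Design choices where the design was genuinely open

**Intensity scale.** Min–max normalization to [0, 1] is incompatible with
contrast thresholds of 300 and 100, which are clearly intensity-scaled. We
normalize to [0, 1000] SIU so the printed thresholds apply verbatim;
`scale_max` is configurable.

**Brightness.** The ranking feature is written as the juxtaposition "μA";
we read it as the product (integrated intensity — the sum of SIU values
over the region). The quotient reading would penalize larger stones, which
contradicts the retained-candidate behaviour. `brightness_mode = "mean"`
retains the alternative.

**Elongation term.** The penalty's printed third term `max(0, L_max/L_min)`
is never zero, yet the accompanying text demands a penalty "only when
elongation exceeds a predefined tolerance". We implement
`max(0, L_max/L_min - elong_tol)` with `elong_tol = 2` (the printed form is
recovered with `elong_tol = 0`); the term is capped at 10 so a vanishing
minor axis cannot dominate every other feature.

**Score commensurability.** The composite score sums features whose raw
magnitudes differ by orders (brightness ~10^4 SIU·px, contrasts ~10^2–10^3
SIU, penalty ~1). Summing raw values would make the brightness weight the
only one that matters, so each feature is min–max normalized across the
surviving candidates of the image before weighting. Winner selection is
invariant to any common monotone rescaling of a feature, so this preserves
the ranking intent while giving all four weights meaning. With a single
survivor each normalized feature is defined as 1 (penalty 0 if its raw
value is 0). `normalize_scores = FALSE` gives the raw sum.

**Profile segmentation.** `PCe`/`PCl` are located by extreme forward
differences of `PC`: the steepest drop ends `PCe`, the steepest subsequent
rise ends `PCl`. Medians are applied to the segments (a median of a single
value would make the operator pointless). The profile starts at the first
row below the candidate *bounding box*; the centroid-row variant was
considered and rejected because the box is the object the pipeline has
actually delineated. Degenerate cases (no decrease, drop at the last row)
zero the second term with a warning rather than failing.

**Acceptance rule.** The expert annotation protocol records two endpoints
of the stone's long axis, so the accepted region is built from them alone:
a capsule of lateral half-width `0.5 |AB|` with a longitudinal margin of
`0.25 |AB|` beyond each end, boundaries inclusive. It scales with stone
size and uses no information the protocol does not collect. Both factors
are configurable.

**Agreement statistic.** Interobserver agreement uses the two-way
random-effects, absolute-agreement, single-rater ICC — the standard choice
for duplicate continuous annotations — computed from the subject×rater
ANOVA mean squares, with interpretation bands at 0.75 (good) and 0.90
(excellent). Identical observer vectors short-circuit to ICC = 1, since
the mean-squares ratio is 0/0-unstable when the between-subject variance
is also negligible.

**Coordinates.** 1-based (row, col) indices with closed `roi_box`
intervals, the host language's native convention; rows are axial depth
increasing downward, so a shadow lies at larger row indices. Band centres
round half away from zero.

## What the phantom generator emulates — and what it does not

`generate_phantom()` renders: Rayleigh envelope speckle smoothed by a
Gaussian (σ = 1.5 px, giving a speckle cell of a few pixels at 0.35 mm/px)
and rescaled to a mean background of 120; a fixed anechoic pocket (factor
0.12 ellipse) because abdominal ROIs always contain near-anechoic fluid or
vessels — without one the stone's own shadow would set the ROI minimum,
coupling the normalization to shadow strength in a way no clinical frame
exhibits; an elliptical stone (default semi-axes 9×6 px ≈ 6.3×4.2 mm) whose
multiplicative gain decays from 3.5 at the proximal pole to 1.2 at the
distal pole — the textbook appearance of a calculus, whose echo comes from
the proximal surface while its distal half is already inside the shadow;
a graded shadow column beneath the stone (attenuation 0.2/0.45/0.7, length
10/20/40 px, lateral feathering 3/2/1 px for weak/moderate/strong, the weak
grade interrupted by two random 2–3-row gaps); and optional shadow-free
bright line confounders (gain ≈ 2.6–3.0, 2 px thick) that can out-brighten
the stone cap by integrated intensity while staying below the stone's peak,
as fascial reflections do.

The stone-size and surface-gradient choices are not cosmetic: a stone
narrower than the top-hat disc is retained whole by the enhancement, the
candidate box then covers the entire stone, and the axial profile below it
never crosses the bright-to-dark transition that the `rho`-term of the
shadow score is designed to reward. With a clinically sized stone the disc
fits inside the stone interior, the candidate becomes the proximal bright
cap, and the profile traverses the residual bright rows before the shadow —
the geometry the screening stage assumes.

The phantom does **not** emulate fan-beam geometry, time-gain compensation,
log-compression curves, scan-conversion interpolation, anatomy, or motion.
Passing the phantom suite therefore demonstrates that the implementation
realizes the stated rules and that the rules behave as designed under
controlled contrasts — not that the printed clinical accuracies transfer.

All ground truth (stone mask, centroid, axis endpoints, shadow mask) is
derived analytically from the ellipse parameters, never measured from the
rendered image. Frames are quantized to the 16-bit integer grid at
generation so a written TIFF reads back pixel-exact.

## Experimental protocols

**Difficulty study** (`run_difficulty_study()`): paired seeds — the i-th
frame of each grade shares its speckle field and stone geometry, so grades
differ only in the shadow. Candidate generation commutes with the positive
affine map of min–max normalization, so the paired frames yield identical
candidate sets and the comparison isolates the screens. Grades are compared
on acceptance accuracy and on a combined localization error in which a
frame with no accepted candidate is scored at half the ROI diagonal; the
plain mean over accepted frames is also reported, but it is not comparable
across grades because stronger grades accept a superset of frames.

**Ablation study** (`run_ablation_study()`): the four cumulative variants
{B}, {B,C}, {B,C,S}, {B,C,S,P} zero the weights of absent features and
disable the screens of absent features (the penalty has no screen), and are
run on the same frames.

Default problem sizes — 160×160 phantoms, a 120×120 ROI, 20–30 frames per
condition, 50 stone-free frames — were chosen so a full study runs in a few
minutes on one core while keeping binomial noise on a 30-frame accuracy
below ~0.09 SD.

## Numerical conventions and degenerate inputs

Percentiles use linear interpolation over sorted values (type 7);
thresholding is strict (`>`), so a constant enhanced image yields no
candidates. Connectivity is 8-neighbour throughout. Moment ellipses carry
the 1/12 unit-square correction, so one-pixel-thick components keep
`L_min > 0`; solidity divides by the convex-hull area of pixel corners
(exactly 1 for filled rectangles). Brightness ties rank the shallower
candidate first; total-score ties prefer the stronger shadow, then the
shallower candidate. A constant ROI normalizes to all zeros and returns
`no_candidate`; a candidate box spanning the whole image has no ring and is
rejected as `ring_undefined`; a candidate with no rows beneath it is
rejected as `shadow_not_evaluable`; coincident annotation endpoints raise a
validation error. Every command writes files atomically
(write-then-rename) and stamps reports with the configuration hash;
identical config and inputs reproduce outputs byte-for-byte.

## Known limitations

* Strictly vertical shadow tracing; no fan-geometry (polar) profiles.
* Single-stone output per image, by design.
* Min–max normalization ties the absolute thresholds to the ROI's dynamic
  range: a very bright distractor compresses every other contrast. The
  local-contrast screen consequently has a tail near `tau_lc` for frames
  whose shadow or distractor stretches the range — visible as occasional
  strong-grade rejections in the phantom studies.
* The weak-shadow stratum is intentionally marginal under the default
  thresholds: its shadow score hovers around `tau_sr`, which is what makes
  the ablation and difficulty orderings informative.
* DICOM input is not supported; frames are read from PNG or 8/16-bit TIFF.
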