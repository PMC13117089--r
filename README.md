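# echolith

Rule-based detection of kidney and gallbladder stones in B-mode ultrasound,
verified by their posterior acoustic shadow.

## The problem

On B-mode ultrasound a calcified stone is a **hyperechoic focus** — a bright
surface echo — followed by a **posterior acoustic shadow**, the dark column
that forms because the stone reflects and absorbs the beam. Brightness alone
is an unreliable detector: vessel walls, fascial interfaces and specular
reflections mimic stone-like foci. The shadow is the physical signature
that separates a calcification from its mimics, yet most automated
pipelines ignore it.

`echolith` implements an explainable, deterministic pipeline that works
inside a clinician-drawn rectangular ROI:

1. min–max normalization to scaled intensity units (SIU, 0–1000) and 3×3
   median denoising;
2. white top-hat enhancement (disc radius 5 px), 99th-percentile
   thresholding, small-component removal (≥ 20 px), regional-maxima
   gating, and region descriptors (area *A*, mean intensity *μ*, centroid,
   eccentricity, solidity, axis lengths);
3. two screens per candidate: **local contrast**
   `Ī_s − Ī_r ≥ τ_LC = 300` (box mean minus surrounding-ring mean) and
   **shadow region**
   `mean_y(P_L(y) − P_C(y)) + ρ·(median(P_Ce) − median(P_Cl)) ≥ τ_SR = 100`,
   built from axial profiles beneath the candidate (centre band vs
   laterally offset reference bands, ρ = 0.5);
4. a composite score
   `w_B·brightness + w_C·contrast + w_S·shadow − w_P·penalty`
   (weights 0.35/0.25/0.25/0.15; features min–max normalized per image;
   shape penalty `0.4·ecc + 0.3·max(0, 1−solidity) +
   0.3·max(0, L_max/L_min − 2)`);
5. shadow-onset estimation (row after the steepest profile drop) and
   extraction of the posterior shadow ROI beneath the winner.

The package also ships the full evaluation protocol — point-to-axis
localization error `d = |a·x₀ + b·y₀ + c| / √(a² + b²)` against
expert-annotated stone axes, acceptance accuracy, t-based 95% confidence
intervals, two-observer ICC — plus an ablation runner and a seeded
speckle-phantom generator with exact analytic ground truth, so every claim
is testable without clinical data.

## Worked example

```r
library(echolith)

ph  <- generate_phantom(phantom_spec(shadow_grade = "strong", seed = 7))
det <- detect_stone(ph$frame, roi_box(20, 20, 120, 120))
det
#> <stone_detection> phantom_seed7: detected at (x = 80.24, y = 59.07), total score 0.7000
#>   shadow onset row 67; shadow ROI rows 67..96, cols 72..88
```

The true stone centre of this phantom is (80, 60): the detector localized
it to within about one pixel, and the extracted shadow box sits directly
beneath the stone's column span. Scoring the prediction against the
phantom's ground-truth axis annotation:

```r
ev <- evaluate_detections(
  tibble::tibble(image_id = "ph7", status = det$status,
                 stone_x = det$winner$xc, stone_y = det$winner$yc),
  tibble::tibble(image_id = "ph7",
                 xa = ph$truth$axis_a[["x"]], ya = ph$truth$axis_a[["y"]],
                 xb = ph$truth$axis_b[["x"]], yb = ph$truth$axis_b[["y"]],
                 group_label = "ge80"))
ev[, c("image_id", "correct", "d_px", "d_mm")]
#> # A tibble: 1 × 4
#>   image_id correct  d_px  d_mm
#>   <chr>    <lgl>   <dbl> <dbl>
#> 1 ph7      TRUE    0.930 0.325
```

`d_px` is the perpendicular distance from the predicted centroid to the
expert (here: analytic) stone axis; `d_mm` converts it at 0.35 mm/px;
`correct` applies the capsule acceptance rule around the axis.
`autoplot(det)` draws the ROI with the stone cross and shadow box;
`run_ablation_study()` and `run_difficulty_study()` reproduce the
stratified experiment tables. A command-line front end
(`inst/cli/echolith`) exposes `detect`, `evaluate`, `simulate` and
`ablate` over manifest CSV files.

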