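---
title: "Trabecular pattern analysis and fracture-risk statistics: methods and design choices"
author: "trabpat authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trabecular pattern analysis and fracture-risk statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trabpat)
```

## The problem

The trabecular (cancellous) bone pattern visible in the mandible on a
panoramic dental radiograph carries information about skeletal fragility: a
*sparse* pattern — few, poorly mineralized trabeculae with large marrow
spaces — marks a strongly elevated long-term fracture risk in postmenopausal
women, while a *dense* pattern is protective. Clinically the pattern is
judged by an observer against reference images on a three-level ordinal
scale (dense, alternating dense and sparse, sparse). `trabpat` implements
both halves of the analysis around that score:

1. an **image pipeline** that turns a calibrated grayscale region of
   interest (ROI) into quantitative texture features, and
2. the **risk statistics** that relate observer scores, clinical variables,
   and image features to fracture outcome.

Because no radiographs are distributed with the package, a first-class
synthetic-data module generates trabecular-like textures with known ground
truth and score/fracture cohorts with configurable odds, so every stage is
testable end to end.

## The image pipeline

The unit of analysis is a square ROI of 650 × 650 px cut from a radiograph
scanned at 236 px/cm (pixel spacing 10/236 ≈ 0.0424 mm, overridable), i.e.
2.75 cm × 2.75 cm over the premolar/molar region. For the even window side
the crop spans rows `centerRow − 325 … centerRow + 324`; windows must lie
fully inside the image. Pixel coordinates are 1-based (row, column) in R
convention; every image object carries its own pixel spacing so all physical
units are computable without global state.

### Preprocessing

The chain is deliberately minimal and fully deterministic:

* **Brightness and contrast** are measured first, on the *unfiltered* ROI.
  The source material does not define the formulas, so the package declares
  conventions: brightness = arithmetic mean intensity; contrast =
  population standard deviation (divisor *N*). The raw-ROI contrast matters
  beyond quality control — it is one of the predictors retained by the
  combined fracture model.
* A **3 × 3 median filter** removes isolated speckle pixels. Borders use
  edge replication so the grid keeps its size. Note that a 3 × 3 median on
  binary data is a majority filter and is *not* idempotent in general; the
  filter is applied exactly once, before segmentation.
* **Unsharp self-masking** subtracts a heavily blurred copy of the ROI from
  itself, removing the smooth background produced by varying cortex and
  soft-tissue thickness. The blur is a square mean filter (edge
  replication). Its side is not stated by the original description; the
  package default is 101 px ≈ 4.3 mm — several trabecular widths, so the
  texture survives while anatomical gradients are removed. The window must
  be odd, at least 31 px, and smaller than the ROI. A symmetric mean filter
  reproduces any locally linear background exactly, so the residual is
  ~0 on constants and on ramp interiors; for inputs with curvature beyond
  degree 1 a small residual mean remains, which the zero threshold
  tolerates.
* **Segmentation**: a pixel is white (trabecula) iff its residual is ≥ the
  threshold offset, default 0, with ties going to white. Self-masking
  centers the local background at zero, so the sign of the residual is the
  natural separator. No Otsu/adaptive thresholding is offered — the fixed
  chain is the method.

On synthetic textures with a known white-area fraction of 0.5, superimposed
polynomial backgrounds up to 60 gray units and pixel noise up to 10 gray
units, the full chain recovers the true fraction to ±0.05 and agrees with
the ground-truth binary on ≈ 99% of pixels (both properties are asserted in
the test suite and recomputed by `scripts/acceptance.R`).

### Segment morphometry

Segments are connected components of each phase, with the standard
digital-topology duality: 8-connectivity for white, 4-connectivity for
black (otherwise two crossing one-pixel paths of opposite phases would both
be "connected"). Per phase the package reports, in physical units:

* `segment_count` and `number_density` (segments per cm² of ROI);
* `mean_area` — mean pixel count × spacing²;
* `mean_perimeter` — mean count of pixel edges adjacent to the other phase
  *or the image border*, × spacing. The edge-count convention (rather than,
  say, Crofton estimation) was chosen because it has an exact integer
  oracle, which the tests exploit; perimeters are therefore comparable only
  to other edge-count perimeters;
* `mean_width` — per segment, twice the mean Euclidean distance to the
  other phase sampled on the segment's skeleton pixels, × spacing. For a
  band of height *h* this gives exactly *h*. The distance map treats the
  image border as bone, not background.

Segments touching the ROI border are included (no exclusion rule is
applied); `minAreaPx` can drop specks. An empty phase gives zero counts and
means rather than an error.

### Orientation: the LFD profile

The orientation signature is measured in 12 directions (0°, 15°, …, 165°;
0° = horizontal, 90° = vertical, opposite directions identical by
construction). The underlying idea — the *line fraction deviation* — is
that sampling lines running **along** the trabecular grain alternate
between all-trabecula and all-marrow stretches, so the white fraction
varies strongly from line to line, whereas lines **across** the grain
average over many trabeculae and all look alike.

The published description does not fix the statistic, so the package
declares its operationalization precisely:

* parallel digital lines at each angle, spaced one pixel apart in their
  integer intercept, parametrized symmetrically about the image center;
* sample values linearly interpolated between the two pixels each line
  passes between (nearest-pixel rounding would jitter the line and damp the
  variance at intermediate slopes);
* each line is chopped into consecutive segments of exactly 65 samples
  (also the minimum usable line length, so short corner lines drop out),
  with the segment layout centered within the line;
* LFD(θ) = population SD of the per-segment white fractions, scaled by
  √(geometric segment length / ROI side) so that diagonal directions, whose
  sampling steps are geometrically longer and whose fraction variance is
  correspondingly damped, remain comparable to axis-aligned ones.

Fixed-length segments rather than whole lines are the package's key design
choice here: a 650-px ROI offers only ~80 effectively independent whole
lines per direction, and the resulting noise in the across-line SD is large
enough to misrank adjacent 15° bins on a few percent of strongly oriented
textures, even though (as an independent spectral check confirms) the
orientation information is unambiguously present. Chopping into 65-sample
segments multiplies the number of sampling units by ~10 and makes the
orientation peak sharp; on generator textures with anisotropy 4 the profile
argmax recovers the true orientation in 100/100 seeded replicates at the
650-px ROI size (97/100 at 256 px). The construction is exactly invariant
under 180° image rotation, and under 90° rotation of a square image the
profile cyclically shifts by 6 index positions, both to machine precision.

`dominantOrientation` returns the argmax angle, breaking ties toward the
smallest angle (flagged), and returns `NA` for an all-zero profile (uniform
images have no orientation).

### Skeleton statistics

Each phase is thinned to a one-pixel-wide, 8-connected, topology-preserving
skeleton (Guo–Hall two-subiteration thinning; each segment keeps exactly
one skeleton component). On the skeleton:

* an **endpoint** has exactly one skeleton neighbor (8-neighborhood);
* a **node** has three or more;
* **struts** are maximal paths between such terminals (orthogonal step 1,
  diagonal step √2, scaled to mm); a closed loop without terminals counts
  as one strut; isolated single pixels are neither endpoints nor struts.

A consequence of the 8-neighborhood degree rule worth knowing: at a
crossing of two one-pixel lines, the four pixels orthogonally adjacent to
the crossing each see four neighbors (the center, the next arm pixel, and
two diagonal arm pixels), so a "plus" junction is a *cluster of five node
pixels* with twelve short struts, not a single node with four struts. The
counts are exactly reproducible by a brute-force neighbor census, which the
tests assert on toy shapes and random skeletons. The alternative
4-neighborhood reading would collapse the junction to one node but breaks
diagonal skeleton branches entirely, so it was not adopted.

## Risk statistics

* **Contingency table**: fracture outcome × ordinal score (2 × 3). The
  packaged reference table ships as a plain-text fixture whose six cells
  are the unique completion of the published margins (fractured row
  1/35/79, fracture-free row 48/111/30).
* **Odds ratios** use the cross-product with the Wald interval
  exp(ln OR ± z·√(1/a+1/b+1/c+1/d)), z = 1.96 exactly at the 95% level (the
  value conventionally printed, reproducing the published intervals to one
  decimal). Zero cells are rejected unless the 0.5 continuity-correction
  flag is set.
* **Sensitivity/specificity** of a score cutoff follow the direct ratios;
  the published operating point uses sparse as the positive test.
* **Ordinal AUC** is the tie-corrected pairwise concordance over all
  case–control pairs (ties count ½). It equals the trapezoidal ROC area of
  the score used directly as a risk value, and of any monotone model of the
  score — which is why the observer-score model's AUC of 0.800 does not
  depend on how the 3-level score is coded.
* **Cohen's kappa** and **Welch's t** (Satterthwaite df, two-sided) follow
  their textbook definitions; kappa is relabeling-invariant. No
  multiple-testing adjustment is applied across t tests, but a Bonferroni
  view is easy to apply downstream (with four clinical comparisons, a raw
  p ≈ 0.05 is not significant after adjustment).
* **Forward stepwise logistic regression** starts from the intercept-only
  model (prevalence prediction). At each step every remaining candidate is
  added in turn; the candidate with the largest likelihood-ratio
  improvement enters if its LRT p-value is below α = 0.05, and the
  procedure stops otherwise. Pure forward selection — no removal step. The
  entry test is the likelihood-ratio test for transparency and exact
  testability (some legacy software defaults to a score test; with one
  strong ordinal predictor the selected model is the same). The observer
  score enters as a single ordinal numeric (0/1/2). Candidates that
  separate the outcome perfectly are flagged, excluded with a warning, and
  reported; separation is detected both from the glm warning and from
  fitted probabilities numerically at 0/1 (10⁻⁸), since moderate-n fits can
  converge quietly.
* **ROC construction** sweeps thresholds over the unique score values;
  the AUC is trapezoidal and invariant under strictly monotone transforms.

## The synthetic-data module

`generateTexture` builds a seeded correlated Gaussian random field (white
noise convolved, via FFT on the torus, with an anisotropic Gaussian kernel:
σ across the grain = coarseness/2, σ along = anisotropy × that), thresholds
it at the sample quantile giving **exactly** the requested white-area
fraction (the ground-truth binary), and renders gray levels as
128 ± phaseContrast/2 by phase, plus a smooth random second-order polynomial
background of amplitude `gradientAmplitude` (the cortex/soft-tissue
confounder the self-mask must remove) and Gaussian noise. Defaults: side
650 px, area fraction 0.5, coarseness 6 px, isotropic, gradient 40, noise
8, phase contrast 80 — gray-scale magnitudes chosen to resemble a scanned
film radiograph's dynamic range, with the gradient deliberately large
relative to the phase contrast so that global thresholding without
self-masking would fail.

`generateReferencePattern` emulates the three reference patterns: dense
(area fraction 0.55, coarseness 4), sparse (0.30, coarseness 10), and
alternating, which blends the two fields with a row-wise white-fraction
ramp from dense at the top of the ROI (cervical, crown-up) to sparse at the
bottom (apical).

`generateCohort` draws scores from configurable prevalences, fracture
outcomes per score, and Gaussian clinical variables *independent of
outcome* (BMI derived as weight/(height/100)²; means and SDs default to the
published cohort's descriptive statistics). Optional standard-normal image
features add their stated effects to the fracture logit, giving cohorts in
which image features carry signal beyond the score. Defaults reproduce the
published cohort structure: n = 304, prevalences 49/146/109, per-score
fracture probabilities 1/49, 35/146, 79/109 — which imply a sparse-vs-rest
odds ratio of 11.6.

All generators are pure functions of (parameters, seed): one integer seed
expands into fixed substreams (field, background, noise, scores, clinical,
features) so modules stay independently reproducible, and the caller's RNG
state is left untouched.

The record-level expansion of the packaged contingency table
(`table2Cohort`) attaches null clinical variables under a *fixed* seed
(2017), making the expansion a deterministic fixture: the stepwise analysis
on it is exactly reproducible. With four null candidates tested at α = 0.05
there is a ~19% a-priori chance that some null variable would enter for any
given draw; under the fixed fixture the score is selected alone.

### What the generator does and does not emulate

It emulates oriented two-phase texture with controllable density,
coarseness, anisotropy, global intensity gradients, and pixel noise; and
cohorts with an ordinal score whose fracture association matches configured
odds. It does **not** emulate mandibular anatomy (teeth, roots, the
mandibular canal, cortical borders), film/scanner transfer curves, focal
blur, projective distortion of a rotating panoramic beam, or observer
behavior beyond categorical assignment. Passing tests therefore demonstrate
that the algorithms are implemented correctly and recover known truths
under realistic confounding — not that the specific feature values match
what the original software would measure on real radiographs.

## Numerical and testing choices

* Filters use edge replication; segmentation ties go to white; the LFD of a
  uniform image is all zeros; empty phases and empty skeletons give zeros,
  not errors; degenerate (constant) images are valid inputs everywhere.
* Test problem sizes are chosen to keep the default suite fast while
  exercising the full-size path where it matters: oracle comparisons
  (flood fill, windowed median, pairwise concordance, neighbor census) run
  on 7–60 px grids where brute force is exact and cheap; LFD invariances on
  200-px textures; orientation recovery and chain-recovery checks at the
  full 650-px ROI; statistical recovery at n = 5 000–100 000.
* Independent cross-checks: kappa against `e1071::classAgreement`, ROC/AUC
  against `pROC`, Welch p against the t distribution directly; the package
  implementations never delegate to these.

## Known limitations

* The preprocessing formulas (brightness, contrast, blur scale) and the
  LFD operationalization are declared package conventions; the original
  analysis software's exact definitions are not public, so numeric feature
  values are comparable within this package, not across implementations.
  In particular the published image-feature-only AUC (0.603) and combined
  AUC (0.852), and the published observer-agreement kappas, require the
  original radiographs and observers; the package validates the
  corresponding machinery on synthetic stand-ins instead.
* Perimeter is an edge-count (overestimates smooth boundaries by up to
  ~4/π); width assumes elongated segments; node counts at thick junctions
  reflect the junction-cluster convention described above.
* AUC confidence intervals are not computed (the method behind the
  published intervals is unstated).
* No DICOM input, no interactive ROI picking, no survival modelling.
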