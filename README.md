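# trabpat — trabecular pattern texture analysis and fracture-risk statistics

`trabpat` quantifies the mandibular trabecular pattern in fixed-size
regions of interest (ROIs) from panoramic dental radiographs and relates it
to long-term fracture risk in postmenopausal women. It is aimed at
researchers in oral radiology and osteoporosis epidemiology who want a
tested, fully reproducible implementation of the classic
observer-score + texture-analysis workflow — including a synthetic-data
module, so the whole pipeline runs and is validated without any patient
radiographs.

## What it computes

**Image pipeline** (on a 650 × 650 px ROI at 236 px/cm):

1. brightness (mean intensity) and contrast (population SD) of the raw ROI;
2. 3 × 3 median filtering, unsharp self-masking (ROI minus its 101-px box
   blur), and zero-threshold segmentation into white (trabeculae) / black
   (intertrabecular space);
3. per-phase segment morphometry: number density (cm⁻²), mean area (mm²),
   perimeter (mm), and width (mm, via distance transform on the skeleton);
4. the 12-direction LFD orientation profile LFD(θ), θ = 0°, 15°, …, 165° —
   the (length-corrected) standard deviation of white fractions over
   parallel sampling line segments at angle θ, maximal along the trabecular
   grain;
5. skeleton statistics per phase after homotopic thinning: node and
   endpoint counts and mean strut length (endpoint = skeleton pixel with 1
   neighbor, node = pixel with ≥ 3; struts are maximal paths between
   terminals).

**Risk statistics** (on a cohort with a 3-level ordinal observer score —
dense < alternating < sparse — and 0/1 fracture outcome):

- odds ratios with Wald CIs, OR = ad/bc, CI = exp(ln OR ± 1.96·√Σ1/nᵢ);
- sensitivity/specificity of score cutoffs;
- the ordinal ROC AUC as tie-corrected pairwise concordance,
  AUC = P(score_case > score_control) + ½·P(tie);
- Cohen's kappa and Welch t comparisons;
- forward stepwise logistic regression (likelihood-ratio entry test,
  α = 0.05, no removal step) with ROC construction on the fitted
  probabilities.

## Worked example

```r
library(trabpat)

## a synthetic trabecular ROI with known ground truth, grain at 60 degrees
tex <- generateTexture(textureParams(orientation = 60, anisotropy = 3, seed = 11))
fv  <- extractFeatureVector(tex$roi)
fv
#> FeatureVector (30 features)
#>   brightness 127.99, contrast 43.82
#>   white: 99 segments, density 13.1 /cm^2 | black: 97 segments
#>   dominant LFD orientation: 60 deg

## the packaged 304-subject fracture-by-score table
reproduceTable2()
#> Fracture x observer-score contingency table
#>               dense alternating sparse total
#> fractured         1          35     79   115
#> fracture_free    48         111     30   189
#> total            49         146    109   304
#> sparse-vs-rest fracture OR:   11.6 (6.7-20.3)   [published 11.6 (6.7-20.3)]
#> dense-vs-rest fracture-free OR: 38.8            [published 38.8]
#> sparse cutoff sensitivity:    69%             [published 69%]
#> sparse cutoff specificity:    84%             [published 84%]
#> ordinal ROC AUC of the score: 0.800            [published 0.800]

## stepwise fracture model: observer score + null clinical variables
rep <- cohortRiskReport(table2Cohort(), "observer")
rep$model
#> Forward stepwise logistic regression (alpha = 0.05 )
#>   selected: score_ord
#>   coefficients:
#> (Intercept)   score_ord
#>     -3.3940      2.1948
round(rep$auc, 3)
#> [1] 0.8
```

Reading the output: the dominant LFD orientation recovers the generator's
60° grain; in the cohort, a subject with a sparse pattern has 11.6-fold
fracture odds relative to non-sparse patterns, a sparse cutoff flags 69% of
future fracture cases while clearing 84% of the fracture-free, and the
score alone ranks a random future case above a random control 80% of the
time (AUC 0.800). The stepwise model keeps only the score — each step up
the dense → alternating → sparse scale multiplies the fracture odds by
exp(2.19) ≈ 9 — and none of the (null) clinical variables improves it.

## Layout

- `R/` — S4 classes (`GrayROI`, `BinaryROI`, `FeatureVector`,
  `ContingencyTable`, `StepwiseModel`, `ROCResult`, …) and the exported
  pipeline;
- `src/` — Rcpp kernels: connected-component labeling (4/8-connectivity),
  Guo–Hall thinning, exact 3 × 3 median and box filters, strut census;
- `inst/extdata/table2_counts.csv` — the packaged contingency-table
  fixture (plain text, reconstruction documented in its header);
- `inst/scripts/trabpat-cli.R` — thin command-line wrapper
  (`extract`, `cohort`, `simulate`, `reproduce-table2`, `show-config`);
- `vignettes/trabecular-texture-methods.Rmd` — the methods vignette:
  model, conventions, design decisions, and limitations.
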