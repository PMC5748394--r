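#' @useDynLib trabpat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats quantile rnorm runif rbinom glm binomial pchisq qlogis
#'   plogis sd coef fitted predict t.test setNames fft reformulate
#'   complete.cases qnorm
#' @importFrom utils read.csv write.csv head
#' @importFrom tools file_ext
#' @importFrom EBImage distmap
NULL

DEFAULT_PIXEL_SPACING <- 10 / 236 # mm per pixel, 236 px/cm scan resolution
ROI_SIDE <- 650L
LFD_ANGLES <- seq(0L, 165L, by = 15L)

#' Calibrated grayscale radiograph image
#'
#' A 2D grid of gray intensities in \code{[0, 255]} together with the pixel
#' calibration (mm per pixel). Panoramic radiographs digitised at 236 pixels
#' per centimeter have \code{pixelSpacing = 10/236} mm, the package default.
#'
#' @slot pixels numeric matrix of intensities in \code{[0, 255]}
#'   (rows = image rows, 1-based; values may be fractional for 16-bit scans).
#' @slot pixelSpacing mm per pixel, a single positive number.
#' @export
setClass("GrayImage",
  representation(pixels = "matrix", pixelSpacing = "numeric"),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p)) return("pixels must be a numeric matrix")
    if (nrow(p) < 1L || ncol(p) < 1L) return("image must be at least 1 x 1")
    if (!all(is.finite(p))) return("all intensities must be finite")
    if (min(p) < 0 || max(p) > 255) return("intensities must lie in [0, 255]")
    if (length(object@pixelSpacing) != 1L || !is.finite(object@pixelSpacing) ||
        object@pixelSpacing <= 0) return("pixelSpacing must be a single positive number")
    TRUE
  })

#' Square region of interest cut from a radiograph
#'
#' A \linkS4class{GrayImage} restricted to a square window (650 x 650 px by
#' default, 2.75 cm x 2.75 cm at 236 px/cm) — the unit of texture analysis.
#' @export
setClass("GrayROI", contains = "GrayImage",
  validity = function(object) {
    if (nrow(object@pixels) != ncol(object@pixels)) return("ROI must be square")
    TRUE
  })

#' Two-phase (binary) segmented region of interest
#'
#' The result of segmenting a \linkS4class{GrayROI}: \code{TRUE} pixels are
#' white (trabeculae), \code{FALSE} pixels are black (intertrabecular spaces).
#'
#' @slot phase logical matrix, \code{TRUE} = white/trabecula.
#' @slot pixelSpacing mm per pixel inherited from the source ROI.
#' @export
setClass("BinaryROI",
  representation(phase = "matrix", pixelSpacing = "numeric"),
  validity = function(object) {
    if (!is.logical(object@phase)) return("phase must be a logical matrix")
    if (anyNA(object@phase)) return("phase must not contain NA")
    if (length(object@pixelSpacing) != 1L || !is.finite(object@pixelSpacing) ||
        object@pixelSpacing <= 0) return("pixelSpacing must be a single positive number")
    TRUE
  })

#' Preprocessing parameters
#'
#' Parameters of the preprocessing chain: the (fixed) 3x3 median window, the
#' side of the square mean filter used for unsharp self-masking, and the
#' gray-value offset added to the zero segmentation threshold.
#'
#' @slot medianWindow always 3.
#' @slot blurWindow odd integer >= 31, px (default 101 px ~ 4.3 mm).
#' @slot thresholdOffset finite gray-value offset (default 0).
#' @export
setClass("PreprocessParams",
  representation(medianWindow = "integer", blurWindow = "integer",
                 thresholdOffset = "numeric"),
  prototype(medianWindow = 3L, blurWindow = 101L, thresholdOffset = 0),
  validity = function(object) {
    if (object@medianWindow != 3L) return("medianWindow is fixed at 3")
    if (object@blurWindow < 31L || object@blurWindow %% 2L == 0L)
      return("blurWindow must be odd and >= 31")
    if (!is.finite(object@thresholdOffset)) return("thresholdOffset must be finite")
    TRUE
  })

#' Per-ROI bundle of texture features
#'
#' Brightness and contrast of the raw ROI, per-phase segment morphometry,
#' the 12-direction line-fraction-deviation (LFD) profile, and per-phase
#' skeleton strut statistics, as a fixed-schema named numeric vector.
#'
#' @slot values named numeric vector (see \code{\link{featureNames}}).
#' @slot params list of provenance metadata (preprocessing parameters,
#'   pixel spacing).
#' @export
setClass("FeatureVector",
  representation(values = "numeric", params = "list"),
  validity = function(object) {
    miss <- setdiff(featureNames(), names(object@values))
    if (length(miss)) return(paste("missing features:", paste(miss, collapse = ", ")))
    if (anyNA(object@values)) return("feature values must not be NA")
    TRUE
  })

#' Fracture-by-score contingency table
#'
#' Cross-tabulation of fracture outcome (fractured / fracture-free) against
#' the three-level ordinal observer score (dense < alternating < sparse).
#' @slot counts 2 x 3 matrix of non-negative integers with dimnames
#'   \code{list(c("fractured","fracture_free"), c("dense","alternating","sparse"))}.
#' @export
setClass("ContingencyTable",
  representation(counts = "matrix"),
  validity = function(object) {
    ct <- object@counts
    if (!identical(dim(ct), c(2L, 3L))) return("counts must be 2 x 3")
    if (any(ct < 0) || any(ct != round(ct))) return("counts must be non-negative integers")
    if (!identical(rownames(ct), c("fractured", "fracture_free")) ||
        !identical(colnames(ct), c("dense", "alternating", "sparse")))
      return("dimnames must be fractured/fracture_free x dense/alternating/sparse")
    TRUE
  })

#' ROC curve with its area
#'
#' @slot points data.frame with columns \code{fpr}, \code{tpr}, ordered and
#'   monotone non-decreasing in both coordinates.
#' @slot auc trapezoidal area under the points, in \code{[0, 1]}.
#' @export
setClass("ROCResult",
  representation(points = "data.frame", auc = "numeric"),
  validity = function(object) {
    pts <- object@points
    if (!all(c("fpr", "tpr") %in% names(pts))) return("points needs fpr and tpr")
    if (is.unsorted(pts$fpr) || is.unsorted(pts$tpr))
      return("ROC points must be monotone non-decreasing")
    if (object@auc < 0 || object@auc > 1) return("auc must lie in [0, 1]")
    TRUE
  })

#' Forward stepwise logistic regression model
#'
#' @slot variables selected variables in entry order.
#' @slot coefficients intercept and coefficients on the logit scale.
#' @slot steps data.frame of the step history: candidate tried at entry,
#'   likelihood-ratio statistic, df, p-value, entered flag.
#' @slot fitted fitted fracture probabilities, one per record.
#' @slot alpha entry threshold used.
#' @slot excluded candidates dropped for perfect separation, if any.
#' @export
setClass("StepwiseModel",
  representation(variables = "character", coefficients = "numeric",
                 steps = "data.frame", fitted = "numeric", alpha = "numeric",
                 excluded = "character"))

#' Synthetic texture parameters
#'
#' Controls the trabecular-like texture generator: a seeded correlated
#' Gaussian random field is stretched along \code{orientation} by
#' \code{anisotropy}, thresholded at the quantile giving exactly
#' \code{areaFraction} white pixels (the ground truth), then rendered to
#' gray with phase contrast, a smooth polynomial background of amplitude
#' \code{gradientAmplitude} (emulating cortex/soft-tissue thickness), and
#' Gaussian pixel noise.
#'
#' @slot side ROI side in px (default 650).
#' @slot areaFraction target white fraction in (0, 1).
#' @slot orientation degrees in [0, 180).
#' @slot anisotropy >= 1; 1 = isotropic.
#' @slot coarseness correlation length in px (>= 2).
#' @slot gradientAmplitude gray units of the background (default 40).
#' @slot noiseSd gray units of pixel noise (default 8).
#' @slot phaseContrast gray-level separation between phases (default 80).
#' @slot seed integer seed; generation is a pure function of the parameters.
#' @export
setClass("TextureParams",
  representation(side = "integer", areaFraction = "numeric",
                 orientation = "numeric", anisotropy = "numeric",
                 coarseness = "numeric", gradientAmplitude = "numeric",
                 noiseSd = "numeric", phaseContrast = "numeric",
                 seed = "integer"),
  prototype(side = 650L, areaFraction = 0.5, orientation = 0, anisotropy = 1,
            coarseness = 6, gradientAmplitude = 40, noiseSd = 8,
            phaseContrast = 80, seed = 1L),
  validity = function(object) {
    if (object@side < 8L) return("side must be >= 8 px")
    if (object@areaFraction <= 0 || object@areaFraction >= 1)
      return("areaFraction must lie strictly in (0, 1)")
    if (object@orientation < 0 || object@orientation >= 180)
      return("orientation must lie in [0, 180)")
    if (object@anisotropy < 1) return("anisotropy must be >= 1")
    if (object@coarseness < 2) return("coarseness must be >= 2 px")
    if (object@gradientAmplitude < 0 || object@noiseSd < 0 ||
        object@phaseContrast <= 0) return("amplitudes must be non-negative")
    TRUE
  })

#' Synthetic cohort parameters
#'
#' Controls the cohort generator: observer scores are multinomial with
#' \code{scorePrevalence}, fracture is Bernoulli per score with
#' \code{fractureProbByScore}, clinical variables are Gaussian (BMI derived
#' from weight and height), and optional standard-normal image features may
#' carry additional logit effects on fracture. The defaults reproduce the
#' published cohort structure: 304 subjects with score prevalences
#' 49/146/109 and per-score fracture probabilities 1/49, 35/146, 79/109.
#'
#' @slot n number of subjects.
#' @slot scorePrevalence three probabilities summing to 1 (dense,
#'   alternating, sparse).
#' @slot fractureProbByScore three per-score fracture probabilities.
#' @slot clinicalMeans,clinicalSds named (age, weight, height) Gaussian
#'   parameters; BMI is weight / (height/100)^2.
#' @slot featureEffects named per-feature logit effects; empty = no
#'   simulated image features.
#' @slot seed integer seed.
#' @export
setClass("CohortParams",
  representation(n = "integer", scorePrevalence = "numeric",
                 fractureProbByScore = "numeric", clinicalMeans = "numeric",
                 clinicalSds = "numeric", featureEffects = "numeric",
                 seed = "integer"),
  prototype(n = 304L,
            scorePrevalence = c(dense = 49, alternating = 146, sparse = 109) / 304,
            fractureProbByScore = c(dense = 1 / 49, alternating = 35 / 146,
                                    sparse = 79 / 109),
            clinicalMeans = c(age = 54.1, weight = 66.3, height = 163.5),
            clinicalSds = c(age = 4.0, weight = 10.6, height = 5.9),
            featureEffects = numeric(0), seed = 1L),
  validity = function(object) {
    if (object@n < 1L) return("n must be >= 1")
    if (length(object@scorePrevalence) != 3L ||
        abs(sum(object@scorePrevalence) - 1) > 1e-8 ||
        any(object@scorePrevalence < 0))
      return("scorePrevalence must be 3 non-negative probabilities summing to 1")
    if (length(object@fractureProbByScore) != 3L ||
        any(object@fractureProbByScore < 0) || any(object@fractureProbByScore > 1))
      return("fractureProbByScore must be 3 probabilities")
    need <- c("age", "weight", "height")
    if (!all(need %in% names(object@clinicalMeans)) ||
        !all(need %in% names(object@clinicalSds)))
      return("clinicalMeans/clinicalSds must name age, weight, height")
    TRUE
  })
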