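#' Preprocessing parameter constructor
#'
#' @param blurWindow side (px) of the square mean filter used for unsharp
#'   self-masking; odd, >= 31. Default 101 px (~4.3 mm at 236 px/cm, several
#'   trabecular widths).
#' @param thresholdOffset gray-value offset added to the zero segmentation
#'   threshold (default 0).
#' @return a validated \linkS4class{PreprocessParams}.
#' @export
preprocessParams <- function(blurWindow = 101L, thresholdOffset = 0) {
  new("PreprocessParams", medianWindow = 3L,
      blurWindow = as.integer(blurWindow),
      thresholdOffset = as.numeric(thresholdOffset))
}

#' Brightness and contrast of a raw ROI
#'
#' Brightness is the arithmetic mean intensity; contrast is the population
#' standard deviation (divisor N) of the intensities, measured on the
#' unfiltered ROI. The contrast of the unfiltered ROI is one of the
#' predictors retained by the combined fracture-risk model.
#'
#' @param roi a \linkS4class{GrayROI}.
#' @return a single gray-value scalar.
#' @export
measureBrightness <- function(roi) {
  stopifnot(is(roi, "GrayROI"))
  mean(roi@pixels)
}

#' @rdname measureBrightness
#' @export
measureContrast <- function(roi) {
  stopifnot(is(roi, "GrayROI"))
  p <- roi@pixels
  sqrt(mean((p - mean(p))^2))
}

#' 3x3 median filter
#'
#' Replaces every pixel by the median of its 3x3 neighborhood, removing
#' isolated pixels with deviating gray values (film/scanner speckle).
#' Borders are handled by edge replication so the grid keeps its size.
#'
#' @param roi a \linkS4class{GrayROI}.
#' @return the filtered \linkS4class{GrayROI}.
#' @export
medianFilter3x3 <- function(roi) {
  stopifnot(is(roi, "GrayROI"))
  GrayROI(cpp_median3x3(roi@pixels), pixelSpacing = roi@pixelSpacing)
}

#' Unsharp self-masking
#'
#' Subtracts a heavily blurred copy of the ROI (square mean filter of side
#' \code{blurWindow}, edge replication) from the ROI itself, removing
#' large-scale gray-value variation caused by varying cortex and soft-tissue
#' thickness while preserving the fine trabecular texture. The residual is
#' signed; it is returned as a plain matrix because it leaves the
#' \code{[0, 255]} gray range.
#'
#' @param roi a (median-filtered) \linkS4class{GrayROI}.
#' @param params a \linkS4class{PreprocessParams}.
#' @return numeric matrix of signed residuals, same size as the ROI.
#' @export
selfMask <- function(roi, params = preprocessParams()) {
  stopifnot(is(roi, "GrayROI"), is(params, "PreprocessParams"))
  side <- nrow(roi@pixels)
  if (params@blurWindow >= side)
    stop("parameter error: blurWindow (", params@blurWindow,
         ") must be smaller than the ROI side (", side, ")")
  roi@pixels - cpp_box_mean(roi@pixels, params@blurWindow)
}

#' Zero-threshold binary segmentation
#'
#' A pixel is white (trabecula) iff its self-masked residual is greater than
#' or equal to \code{thresholdOffset} (default 0; ties go to white). The
#' self-mask centers the local background at zero, so the sign of the
#' residual separates trabeculae from intertrabecular space.
#'
#' @param residual signed residual matrix from \code{\link{selfMask}}.
#' @param params a \linkS4class{PreprocessParams}.
#' @param pixelSpacing mm per pixel carried to the output.
#' @return a \linkS4class{BinaryROI}.
#' @export
segmentBinary <- function(residual, params = preprocessParams(),
                          pixelSpacing = DEFAULT_PIXEL_SPACING) {
  stopifnot(is.matrix(residual), is(params, "PreprocessParams"))
  BinaryROI(residual >= params@thresholdOffset, pixelSpacing = pixelSpacing)
}

#' Full preprocessing chain
#'
#' Runs the chain 3x3 median filter -> unsharp self-masking -> zero-threshold
#' segmentation on a raw ROI. Deterministic: identical input and parameters
#' give a bit-identical binary image.
#'
#' @param roi a raw \linkS4class{GrayROI}.
#' @param params a \linkS4class{PreprocessParams}.
#' @return a \linkS4class{BinaryROI}.
#' @export
preprocessChain <- function(roi, params = preprocessParams()) {
  filt <- medianFilter3x3(roi)
  res <- selfMask(filt, params)
  segmentBinary(res, params, pixelSpacing = roi@pixelSpacing)
}
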