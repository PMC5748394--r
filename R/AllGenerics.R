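#' Pixel spacing accessor
#'
#' Physical calibration of an image-like object, in mm per pixel.
#' @param object a \linkS4class{GrayImage}, \linkS4class{GrayROI} or
#'   \linkS4class{BinaryROI}.
#' @return a single positive number (mm/px).
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))

#' @rdname pixelSpacing
#' @export
setMethod("pixelSpacing", "GrayImage", function(object) object@pixelSpacing)

#' @rdname pixelSpacing
#' @export
setMethod("pixelSpacing", "BinaryROI", function(object) object@pixelSpacing)

#' @describeIn GrayImage extract the intensity matrix.
#' @param x a \code{GrayImage}.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "GrayImage", function(x, ...) x@pixels)

#' @describeIn BinaryROI extract the logical phase matrix
#'   (\code{TRUE} = white/trabecula).
#' @param x a \code{BinaryROI}.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "BinaryROI", function(x, ...) x@phase)

#' @describeIn GrayImage dimensions of the pixel grid.
#' @export
setMethod("dim", "GrayImage", function(x) dim(x@pixels))

#' @describeIn BinaryROI dimensions of the phase grid.
#' @export
setMethod("dim", "BinaryROI", function(x) dim(x@phase))

setMethod("show", "GrayImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("%s %d x %d px, %.4f mm/px, gray range [%.1f, %.1f]\n",
              class(object), d[1], d[2], object@pixelSpacing,
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "BinaryROI", function(object) {
  d <- dim(object@phase)
  cat(sprintf("BinaryROI %d x %d px, %.4f mm/px, white fraction %.3f\n",
              d[1], d[2], object@pixelSpacing, mean(object@phase)))
})

setMethod("show", "FeatureVector", function(object) {
  v <- object@values
  cat("FeatureVector (", length(v), " features)\n", sep = "")
  cat(sprintf("  brightness %.2f, contrast %.2f\n", v["brightness"], v["contrast"]))
  cat(sprintf("  white: %d segments, density %.1f /cm^2 | black: %d segments\n",
              as.integer(v["white_segment_count"]), v["white_number_density"],
              as.integer(v["black_segment_count"])))
  ang <- dominantOrientation(lfdValues(object))
  cat(sprintf("  dominant LFD orientation: %s\n",
              if (is.na(ang)) "undefined" else paste0(ang, " deg")))
})

setMethod("show", "ContingencyTable", function(object) {
  cat("Fracture x observer-score contingency table\n")
  ct <- object@counts
  m <- cbind(ct, total = rowSums(ct))
  m <- rbind(m, total = colSums(m))
  print(m)
})

setMethod("show", "ROCResult", function(object) {
  cat(sprintf("ROC curve: %d points, AUC = %.3f\n",
              nrow(object@points), object@auc))
})

setMethod("show", "StepwiseModel", function(object) {
  cat("Forward stepwise logistic regression (alpha =", object@alpha, ")\n")
  if (length(object@variables) == 0L) {
    cat("  intercept-only model (no candidate entered)\n")
  } else {
    cat("  selected:", paste(object@variables, collapse = " -> "), "\n")
  }
  cat("  coefficients:\n")
  print(round(object@coefficients, 4))
  if (length(object@excluded))
    cat("  excluded (separation):", paste(object@excluded, collapse = ", "), "\n")
})

#' Feature schema of a FeatureVector
#'
#' The fixed, documented column order used by \code{\link{writeFeatureTable}}:
#' brightness and contrast of the raw ROI, white- then black-phase
#' morphometry, the 12 LFD values \code{lfd_000 ... lfd_165}, then white- and
#' black-phase skeleton statistics.
#' @return character vector of the 30 feature names.
#' @export
featureNames <- function() {
  morpho <- c("segment_count", "number_density", "mean_area",
              "mean_perimeter", "mean_width")
  skel <- c("node_count", "endpoint_count", "mean_strut_length")
  c("brightness", "contrast",
    paste0("white_", morpho), paste0("black_", morpho),
    sprintf("lfd_%03d", LFD_ANGLES),
    paste0("white_", skel), paste0("black_", skel))
}

#' Numeric values of a FeatureVector
#' @param object a \linkS4class{FeatureVector}.
#' @return named numeric vector in \code{\link{featureNames}} order.
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))

#' @rdname featureValues
#' @export
setMethod("featureValues", "FeatureVector",
          function(object) object@values[featureNames()])

#' LFD profile stored in a FeatureVector
#' @param object a \linkS4class{FeatureVector}.
#' @return numeric vector of 12 LFD values named by angle.
#' @export
setGeneric("lfdValues", function(object) standardGeneric("lfdValues"))

#' @rdname lfdValues
#' @export
setMethod("lfdValues", "FeatureVector", function(object) {
  v <- object@values[sprintf("lfd_%03d", LFD_ANGLES)]
  names(v) <- LFD_ANGLES
  v
})

#' Counts of a contingency table
#' @param object a \linkS4class{ContingencyTable}.
#' @return the 2 x 3 integer count matrix.
#' @export
setGeneric("tableCounts", function(object) standardGeneric("tableCounts"))

#' @rdname tableCounts
#' @export
setMethod("tableCounts", "ContingencyTable", function(object) object@counts)

#' ROC accessors
#' @param object a \linkS4class{ROCResult}.
#' @return \code{rocAUC}: the area under the curve; \code{rocPoints}: the
#'   ordered (fpr, tpr) data.frame.
#' @export
setGeneric("rocAUC", function(object) standardGeneric("rocAUC"))

#' @rdname rocAUC
#' @export
setMethod("rocAUC", "ROCResult", function(object) object@auc)

#' @rdname rocAUC
#' @export
setGeneric("rocPoints", function(object) standardGeneric("rocPoints"))

#' @rdname rocAUC
#' @export
setMethod("rocPoints", "ROCResult", function(object) object@points)

#' Stepwise model accessors
#' @param object a \linkS4class{StepwiseModel}.
#' @return \code{selectedVariables}: character vector in entry order;
#'   \code{stepHistory}: data.frame of entry tests.
#' @export
setGeneric("selectedVariables", function(object) standardGeneric("selectedVariables"))

#' @rdname selectedVariables
#' @export
setMethod("selectedVariables", "StepwiseModel", function(object) object@variables)

#' @rdname selectedVariables
#' @export
setGeneric("stepHistory", function(object) standardGeneric("stepHistory"))

#' @rdname selectedVariables
#' @export
setMethod("stepHistory", "StepwiseModel", function(object) object@steps)

#' @describeIn StepwiseModel coefficients on the logit scale.
#' @param object a \code{StepwiseModel}.
#' @export
setMethod("coef", "StepwiseModel", function(object) object@coefficients)

#' @describeIn StepwiseModel fitted fracture probabilities.
#' @export
setMethod("fitted", "StepwiseModel", function(object) object@fitted)
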