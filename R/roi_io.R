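#' Construct a GrayImage or GrayROI from a matrix
#'
#' @param pixels numeric matrix of intensities in \code{[0, 255]}.
#' @param pixelSpacing mm per pixel (default 10/236, i.e. 236 px/cm).
#' @return a validated \linkS4class{GrayImage} / \linkS4class{GrayROI}.
#' @export
GrayImage <- function(pixels, pixelSpacing = DEFAULT_PIXEL_SPACING) {
  new("GrayImage", pixels = pixels, pixelSpacing = pixelSpacing)
}

#' @rdname GrayImage
#' @export
GrayROI <- function(pixels, pixelSpacing = DEFAULT_PIXEL_SPACING) {
  new("GrayROI", pixels = pixels, pixelSpacing = pixelSpacing)
}

#' @rdname GrayImage
#' @param phase logical matrix, \code{TRUE} = white/trabecula.
#' @export
BinaryROI <- function(phase, pixelSpacing = DEFAULT_PIXEL_SPACING) {
  storage.mode(phase) <- "logical"
  new("BinaryROI", phase = phase, pixelSpacing = pixelSpacing)
}

#' Load a grayscale radiograph from PNG or TIFF
#'
#' Reads an 8- or 16-bit single-channel or RGB raster and rescales the
#' intensities to \code{[0, 255]} (16-bit inputs by their full dynamic
#' range, so 65535 maps to 255). RGB inputs are collapsed by the unweighted
#' channel mean; radiographs are gray so the weighting is immaterial.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @param pixelSpacing mm per pixel (default 10/236).
#' @return a \linkS4class{GrayImage}. A zero-variance (constant) image is a
#'   valid degenerate input.
#' @export
loadGrayImage <- function(path, pixelSpacing = DEFAULT_PIXEL_SPACING) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = tryCatch(png::readPNG(path),
                   error = function(e) stop("input error: unreadable PNG: ",
                                            conditionMessage(e))),
    tif = ,
    tiff = tryCatch(tiff::readTIFF(path),
                    error = function(e) stop("input error: unreadable TIFF: ",
                                             conditionMessage(e))),
    stop("input error: unsupported raster format '.", ext,
         "' (PNG/TIFF only)"))
  # readPNG/readTIFF normalise to [0, 1] regardless of bit depth
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    m <- arr[, , 1]
    if (nch >= 3L) m <- (arr[, , 1] + arr[, , 2] + arr[, , 3]) / 3
  } else {
    m <- arr
  }
  GrayImage(m * 255, pixelSpacing = pixelSpacing)
}

#' Write a GrayImage to an 8-bit PNG
#'
#' Intensities are scaled back to \code{[0, 1]}; integer-valued 8-bit data
#' round-trip through \code{\link{loadGrayImage}} bit-exactly.
#' @param image a \linkS4class{GrayImage}.
#' @param path output .png path.
#' @return the path, invisibly.
#' @export
writeGrayImage <- function(image, path) {
  stopifnot(is(image, "GrayImage"))
  png::writePNG(image@pixels / 255, target = path)
  invisible(path)
}

#' Extract a fixed-size square ROI
#'
#' Cuts the analysis window (650 x 650 px by default) centered on a pixel of
#' the source image. For the even default side the crop spans rows
#' \code{centerRow - 325 ... centerRow + 324} (1-based, inclusive), and the
#' same rule in columns.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param centerRow,centerCol 1-based pixel coordinates of the window center.
#' @param side window side in px; 650 unless explicitly overridden.
#' @return a \linkS4class{GrayROI}; the source is unmodified.
#' @export
extractROI <- function(image, centerRow, centerCol, side = ROI_SIDE) {
  stopifnot(is(image, "GrayImage"), side >= 1L)
  d <- dim(image@pixels)
  half <- side %/% 2L
  r0 <- centerRow - half
  r1 <- r0 + side - 1L
  c0 <- centerCol - half
  c1 <- c0 + side - 1L
  if (r0 < 1L) stop("bounds error: window crosses the top edge (first row ",
                    r0, " < 1)")
  if (c0 < 1L) stop("bounds error: window crosses the left edge (first column ",
                    c0, " < 1)")
  if (r1 > d[1]) stop("bounds error: window crosses the bottom edge (last row ",
                      r1, " > ", d[1], ")")
  if (c1 > d[2]) stop("bounds error: window crosses the right edge (last column ",
                      c1, " > ", d[2], ")")
  GrayROI(image@pixels[r0:r1, c0:c1, drop = FALSE],
          pixelSpacing = image@pixelSpacing)
}

SCORE_LEVELS <- c("dense", "alternating", "sparse")

#' Read a cohort CSV
#'
#' Expects header columns \code{id, score, age, weight, height, bmi,
#' fracture} plus optional feature columns. The score is one of
#' dense / alternating / sparse (case-insensitive) and is returned both as a
#' factor and as the ordinal code \code{score_ord} (dense = 0,
#' alternating = 1, sparse = 2). Missing clinical values are kept as
#' \code{NA} and flagged with a warning, never silently dropped.
#'
#' @param path CSV file path (UTF-8, "." decimal separator).
#' @return data.frame of typed cohort records.
#' @export
readCohort <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "score", "age", "weight", "height", "bmi", "fracture")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("parse error: missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$id))
    stop("integrity error: duplicate id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  sc <- tolower(trimws(as.character(df$score)))
  bad <- which(!sc %in% SCORE_LEVELS)
  if (length(bad))
    stop("parse error: unknown score label(s) in row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(df$score[bad]), collapse = ", "),
         " (expected dense/alternating/sparse)")
  df$score <- factor(sc, levels = SCORE_LEVELS)
  df$score_ord <- as.integer(df$score) - 1L
  if (!all(df$fracture %in% c(0, 1)))
    stop("parse error: fracture must be 0 or 1")
  df$fracture <- as.integer(df$fracture)
  clin <- c("age", "weight", "height", "bmi")
  for (v in clin) df[[v]] <- as.numeric(df[[v]])
  nmiss <- sum(is.na(df[clin]))
  if (nmiss > 0)
    warning(nmiss, " missing clinical value(s) kept as NA")
  df
}

#' Write / read a feature table
#'
#' One row per ROI, one column per scalar feature in the fixed
#' \code{\link{featureNames}} order (the LFD profile expands to 12 columns
#' \code{lfd_000 ... lfd_165}). Values round-trip through
#' \code{readFeatureTable} to at least 1e-9.
#'
#' @param records named list of \linkS4class{FeatureVector} objects (names
#'   are ROI ids), or a single FeatureVector.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeFeatureTable <- function(records, path) {
  if (is(records, "FeatureVector")) records <- list(roi_1 = records)
  if (length(records) == 0L)
    stop("input error: empty record list (refusing to write an empty table)")
  if (is.null(names(records)) || any(!nzchar(names(records))))
    names(records) <- paste0("roi_", seq_along(records))
  rows <- lapply(records, function(fv) {
    stopifnot(is(fv, "FeatureVector"))
    as.data.frame(as.list(featureValues(fv)))
  })
  df <- cbind(id = names(records), do.call(rbind, rows))
  rownames(df) <- NULL
  ok <- tryCatch({
    write.csv(df, path, row.names = FALSE)
    TRUE
  }, error = function(e) stop("I/O error writing ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' @rdname writeFeatureTable
#' @return \code{readFeatureTable}: data.frame with an \code{id} column and
#'   the 30 feature columns.
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(featureNames(), names(df))
  if (length(miss)) stop("parse error: missing feature columns: ",
                         paste(miss, collapse = ", "))
  df
}
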