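#' Label the segments of one phase
#'
#' Connected components of the chosen phase. White segments use
#' 8-connectivity and black segments 4-connectivity — the standard
#' digital-topology duality that prevents both phases from being connected
#' across a crossing.
#'
#' @param binary a \linkS4class{BinaryROI}.
#' @param phase \code{"white"} (trabeculae) or \code{"black"}
#'   (intertrabecular spaces).
#' @return list with \code{labels} (integer matrix, 0 = other phase,
#'   1..K = segment id), \code{nSegments}, and \code{phase}.
#' @export
labelSegments <- function(binary, phase = c("white", "black")) {
  stopifnot(is(binary, "BinaryROI"))
  phase <- match.arg(phase)
  mask <- if (phase == "white") binary@phase else !binary@phase
  conn <- if (phase == "white") 8L else 4L
  lab <- cpp_label(mask, conn)
  list(labels = lab, nSegments = max(lab), phase = phase)
}

# per-pixel count of 4-neighbors outside the mask; image border counts as
# outside (a pixel edge on the border is exposed)
.exposedEdges <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  up    <- rbind(rep(FALSE, nc), mask[-nr, , drop = FALSE])
  down  <- rbind(mask[-1, , drop = FALSE], rep(FALSE, nc))
  left  <- cbind(rep(FALSE, nr), mask[, -nc, drop = FALSE])
  right <- cbind(mask[, -1, drop = FALSE], rep(FALSE, nr))
  (!up) + (!down) + (!left) + (!right)
}

#' Segment morphometry of one phase
#'
#' Number density and mean segment area, perimeter, and width of one phase,
#' in physical units:
#' \itemize{
#'   \item \code{mean_area}: mean pixel count x spacing^2 (mm^2);
#'   \item \code{mean_perimeter}: mean count of pixel edges adjacent to the
#'     other phase or to the image border, x spacing (mm);
#'   \item \code{mean_width}: mean over segments of twice the mean Euclidean
#'     distance-to-other-phase sampled on the segment's skeleton pixels,
#'     x spacing (mm);
#'   \item \code{number_density}: segments per cm^2 of ROI.
#' }
#' Segments touching the ROI border are included (no exclusion rule is
#' applied by default); set \code{minAreaPx} to drop specks below a pixel
#' count. An empty phase yields zero counts and zero means.
#'
#' @param binary a \linkS4class{BinaryROI}.
#' @param phase \code{"white"} or \code{"black"}.
#' @param minAreaPx drop segments with fewer pixels than this (default 0 =
#'   keep all).
#' @return named list: \code{phase, segment_count, number_density,
#'   mean_area, mean_perimeter, mean_width}.
#' @export
phaseMorphometry <- function(binary, phase = c("white", "black"),
                             minAreaPx = 0L) {
  phase <- match.arg(phase)
  sp <- binary@pixelSpacing
  lab <- labelSegments(binary, phase)
  K <- lab$nSegments
  d <- dim(binary@phase)
  roiAreaCm2 <- prod(d) * (sp / 10)^2
  empty <- list(phase = phase, segment_count = 0L, number_density = 0,
                mean_area = 0, mean_perimeter = 0, mean_width = 0)
  if (K == 0L) return(empty)

  labv <- lab$labels
  areas <- tabulate(labv, nbins = K)
  keep <- which(areas >= minAreaPx)
  if (length(keep) == 0L) return(empty)

  mask <- labv > 0L
  edges <- .exposedEdges(mask)
  inphase <- labv > 0L
  perims <- as.vector(rowsum(as.numeric(edges[inphase]), labv[inphase]))

  # width: 2 x mean distance-to-other-phase over the segment's skeleton
  skel <- cpp_thin(mask)
  dmap <- EBImage::distmap(matrix(as.numeric(mask), d[1], d[2]))
  dmap <- as.matrix(dmap)
  onsk <- skel & mask
  wsum <- rep(0, K); wcnt <- rep(0, K)
  sl <- labv[onsk]
  agg <- rowsum(cbind(dmap[onsk], 1), sl)
  wsum[as.integer(rownames(agg))] <- agg[, 1]
  wcnt[as.integer(rownames(agg))] <- agg[, 2]
  # a thinned component always keeps >= 1 pixel, so wcnt > 0 for all kept K
  widths <- ifelse(wcnt > 0, 2 * wsum / pmax(wcnt, 1), 0)
  # components with an unbounded distance (no other phase anywhere) get the
  # half-side as a conservative cap
  widths[!is.finite(widths)] <- min(d)

  list(phase = phase,
       segment_count = length(keep),
       number_density = length(keep) / roiAreaCm2,
       mean_area = mean(areas[keep]) * sp^2,
       mean_perimeter = mean(perims[keep]) * sp,
       mean_width = mean(widths[keep]) * sp)
}

# --- LFD line sampling -------------------------------------------------------

# Digital sampling lines at angle theta (degrees, CCW from the column axis;
# 0 = along rows/horizontal, 90 = along columns/vertical). Lines are spaced
# one pixel apart in their integer intercept, and each line is chopped into
# consecutive segments of exactly segLen samples (the trailing partial
# segment is discarded). Cached per (nr, nc, theta, segLen) because the
# 650 x 650 pattern is reused for every ROI.
.lfdCache <- new.env(parent = emptyenv())

.lfdSampling <- function(nr, nc, theta, segLen) {
  key <- paste(nr, nc, theta, segLen, sep = "_")
  hit <- .lfdCache[[key]]
  if (!is.null(hit)) return(hit)
  th <- theta * pi / 180
  mostlyHorizontal <- abs(tan(th)) <= 1 + 1e-12
  idx1L <- list(); idx2L <- list(); wL <- list(); idL <- list()
  lineNo <- 0L; segNo <- 0L
  # samples are linearly interpolated between the two pixels the continuous
  # line passes between, avoiding the rounding jitter that would damp the
  # fraction variance at intermediate slopes
  # lines are parametrized symmetrically about the image center and the
  # segment layout is centered within each line, so the sampling geometry
  # maps onto itself under a 180-degree rotation of the image
  addLine <- function(i1, i2, w) {
    L <- length(i1)
    nSeg <- L %/% segLen
    if (nSeg >= 1L && (L - nSeg * segLen) %% 2L == 1L && segLen %% 2L == 1L)
      nSeg <- nSeg - 1L # keep the leftover even so the layout mirrors exactly
    if (nSeg < 1L) return()
    start <- (L - nSeg * segLen) %/% 2L
    keep <- start + seq_len(nSeg * segLen)
    lineNo <<- lineNo + 1L
    idx1L[[lineNo]] <<- i1[keep]
    idx2L[[lineNo]] <<- i2[keep]
    wL[[lineNo]] <<- w[keep]
    idL[[lineNo]] <<- segNo + rep(seq_len(nSeg), each = segLen)
    segNo <<- segNo + nSeg
  }
  cy <- (nr - 1) / 2
  cx <- (nc - 1) / 2
  snap <- function(v) if (abs(v - round(v)) < 1e-9) round(v) else v
  if (mostlyHorizontal) {
    t <- snap(tan(th)) # exact slopes keep boundary samples mirror-symmetric
    x <- 0:(nc - 1)
    kmax <- ceiling(cy + abs(t) * nc) + 1L
    for (k in seq(-kmax, kmax)) {
      y <- cy + k + t * (x - cx)
      ok <- y >= 0 & y <= nr - 1
      if (sum(ok) < segLen) next
      y0 <- pmin(floor(y[ok]), nr - 2)
      addLine((y0 + 1L) + x[ok] * nr, (y0 + 2L) + x[ok] * nr, y[ok] - y0)
    }
  } else {
    ct <- snap(cos(th) / sin(th))
    y <- 0:(nr - 1)
    kmax <- ceiling(cx + abs(ct) * nr) + 1L
    for (k in seq(-kmax, kmax)) {
      x <- cx + k + ct * (y - cy)
      ok <- x >= 0 & x <= nc - 1
      if (sum(ok) < segLen) next
      x0 <- pmin(floor(x[ok]), nc - 2)
      addLine((y[ok] + 1L) + x0 * nr, (y[ok] + 1L) + (x0 + 1L) * nr, x[ok] - x0)
    }
  }
  step <- if (mostlyHorizontal) sqrt(1 + tan(th)^2) else
    sqrt(1 + (cos(th) / sin(th))^2)
  out <- list(idx1 = unlist(idx1L, use.names = FALSE),
              idx2 = unlist(idx2L, use.names = FALSE),
              w = unlist(wL, use.names = FALSE),
              id = unlist(idL, use.names = FALSE),
              segLen = segLen, step = step, nSegments = segNo)
  .lfdCache[[key]] <- out
  out
}

#' Line-fraction-deviation (LFD) orientation profile
#'
#' For each of the 12 directions 0, 15, ..., 165 degrees, the binary image is
#' sampled along parallel digital lines (one-pixel intercept spacing, values
#' linearly interpolated between the two pixels each line passes between).
#' Each line is chopped into consecutive segments of exactly
#' \code{segmentLength} samples (lines shorter than one segment are
#' excluded), every segment contributes its white-phase fraction, and the
#' LFD value for the direction is the population standard deviation of the
#' per-segment fractions, scaled by the square root of the segment's
#' geometric length relative to the ROI side so that directions whose
#' sampling steps are geometrically longer (diagonals) remain comparable to
#' the axis-aligned ones. Fixed-length segments give many more independent
#' sampling units per direction than whole lines, which sharpens the
#' orientation peak. The profile is maximal along the trabecular grain
#' (segments running along the grain cover all-trabecula or all-marrow
#' stretches, so their fractions vary most) and is identical for opposite
#' directions by construction. An all-white or all-black image has an
#' all-zero profile.
#'
#' @param binary a \linkS4class{BinaryROI}.
#' @param segmentLength sampling-segment length in px (default 65, also the
#'   minimum usable line length; short corner lines are excluded).
#' @return named numeric vector of 12 non-negative values, names
#'   \code{"0" ... "165"}.
#' @export
lfdProfile <- function(binary, segmentLength = 65L) {
  stopifnot(is(binary, "BinaryROI"))
  ph <- binary@phase
  v <- as.numeric(ph)
  refLen <- min(dim(ph))
  out <- vapply(LFD_ANGLES, function(theta) {
    s <- .lfdSampling(nrow(ph), ncol(ph), theta, segmentLength)
    if (s$nSegments < 2L) return(0)
    frac <- as.vector(rowsum(v[s$idx1] * (1 - s$w) + v[s$idx2] * s$w,
                             s$id)) / s$segLen
    w <- s$segLen * s$step / refLen # geometric segment length / ROI side
    sqrt(mean((frac - mean(frac))^2) * w)
  }, numeric(1))
  names(out) <- LFD_ANGLES
  out
}

#' Dominant orientation of an LFD profile
#'
#' The angle with the maximum LFD value; ties are broken toward the smallest
#' angle (flagged via the \code{"tie"} attribute). An all-zero profile has no
#' orientation and returns \code{NA}.
#'
#' @param profile numeric vector of 12 LFD values as returned by
#'   \code{\link{lfdProfile}}.
#' @return the angle in degrees (one of 0, 15, ..., 165), or \code{NA} for an
#'   all-zero profile.
#' @export
dominantOrientation <- function(profile) {
  stopifnot(length(profile) == 12L)
  if (all(profile == 0)) return(NA_integer_)
  i <- which(profile == max(profile))
  ang <- LFD_ANGLES[min(i)]
  if (length(i) > 1L) attr(ang, "tie") <- TRUE
  ang
}

#' Skeletonize one phase
#'
#' Topology-preserving (homotopic) thinning of the chosen phase to a
#' one-pixel-wide, 8-connected skeleton (Guo-Hall algorithm). Each segment
#' keeps exactly one skeleton component.
#'
#' @param binary a \linkS4class{BinaryROI}.
#' @param phase \code{"white"} or \code{"black"}.
#' @return logical skeleton matrix of the same size.
#' @export
skeletonizePhase <- function(binary, phase = c("white", "black")) {
  stopifnot(is(binary, "BinaryROI"))
  phase <- match.arg(phase)
  mask <- if (phase == "white") binary@phase else !binary@phase
  cpp_thin(mask)
}

#' Strut, node and endpoint statistics of a skeleton
#'
#' On a one-pixel skeleton: an endpoint is a skeleton pixel with exactly one
#' skeleton neighbor (8-neighborhood) and a node one with three or more;
#' struts are the maximal skeleton paths between such terminals (a closed
#' loop without terminals counts as one strut). Path length uses step 1 for
#' orthogonal and sqrt(2) for diagonal moves, scaled to mm by the pixel
#' spacing. An empty skeleton yields all zeros.
#'
#' @param skeleton logical matrix (from \code{\link{skeletonizePhase}}).
#' @param pixelSpacing mm per pixel.
#' @return named list: \code{node_count, endpoint_count, strut_count,
#'   mean_strut_length} (mm).
#' @export
strutStatistics <- function(skeleton, pixelSpacing = DEFAULT_PIXEL_SPACING) {
  stopifnot(is.matrix(skeleton))
  storage.mode(skeleton) <- "logical"
  s <- cpp_strut_stats(skeleton)
  meanLen <- if (s$strut_count > 0) s$total_length_px / s$strut_count else 0
  list(node_count = s$node_count,
       endpoint_count = s$endpoint_count,
       strut_count = s$strut_count,
       mean_strut_length = meanLen * pixelSpacing)
}

#' Extract the full feature vector of an ROI
#'
#' Runs the complete texture-analysis chain in its stated order: brightness
#' and contrast on the raw ROI, then 3x3 median filter, unsharp self-masking
#' and binary segmentation, then per-phase segment morphometry, the
#' 12-direction LFD profile, and per-phase skeleton strut statistics.
#' Deterministic: repeated runs on identical input are bit-identical.
#'
#' @param roi a \linkS4class{GrayROI}.
#' @param params a \linkS4class{PreprocessParams}.
#' @param minAreaPx minimum segment size for morphometry (default 0).
#' @param lfdSegmentLength LFD sampling-segment length in px (default 65).
#' @return a \linkS4class{FeatureVector}.
#' @export
extractFeatureVector <- function(roi, params = preprocessParams(),
                                 minAreaPx = 0L, lfdSegmentLength = 65L) {
  stopifnot(is(roi, "GrayROI"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  br <- stage("brightness", measureBrightness(roi))
  ct <- stage("contrast", measureContrast(roi))
  bin <- stage("preprocess", preprocessChain(roi, params))
  mw <- stage("morphometry_white", phaseMorphometry(bin, "white", minAreaPx))
  mb <- stage("morphometry_black", phaseMorphometry(bin, "black", minAreaPx))
  lfd <- stage("lfd", lfdProfile(bin, lfdSegmentLength))
  sw <- stage("struts_white",
              strutStatistics(skeletonizePhase(bin, "white"), bin@pixelSpacing))
  sb <- stage("struts_black",
              strutStatistics(skeletonizePhase(bin, "black"), bin@pixelSpacing))
  morphoVals <- function(m) c(m$segment_count, m$number_density, m$mean_area,
                              m$mean_perimeter, m$mean_width)
  skelVals <- function(s) c(s$node_count, s$endpoint_count, s$mean_strut_length)
  vals <- c(br, ct, morphoVals(mw), morphoVals(mb), unname(lfd),
            skelVals(sw), skelVals(sb))
  names(vals) <- featureNames()
  new("FeatureVector", values = vals,
      params = list(blurWindow = params@blurWindow,
                    thresholdOffset = params@thresholdOffset,
                    minAreaPx = minAreaPx, lfdSegmentLength = lfdSegmentLength,
                    pixelSpacing = roi@pixelSpacing))
}
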