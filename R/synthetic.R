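#' Texture / cohort parameter constructors
#'
#' Validated parameter objects for the synthetic generators; see
#' \linkS4class{TextureParams} and \linkS4class{CohortParams} for the
#' meaning and defaults of every field. All generators are pure functions
#' of their parameters (including the seed): repeated calls are
#' bit-identical.
#'
#' @param side,areaFraction,orientation,anisotropy,coarseness,gradientAmplitude,noiseSd,phaseContrast,seed
#'   see \linkS4class{TextureParams}.
#' @return a validated parameter object.
#' @export
textureParams <- function(side = 650L, areaFraction = 0.5, orientation = 0,
                          anisotropy = 1, coarseness = 6,
                          gradientAmplitude = 40, noiseSd = 8,
                          phaseContrast = 80, seed = 1L) {
  new("TextureParams", side = as.integer(side), areaFraction = areaFraction,
      orientation = orientation, anisotropy = anisotropy,
      coarseness = coarseness, gradientAmplitude = gradientAmplitude,
      noiseSd = noiseSd, phaseContrast = phaseContrast,
      seed = as.integer(seed))
}

#' @rdname textureParams
#' @param n,scorePrevalence,fractureProbByScore,clinicalMeans,clinicalSds,featureEffects
#'   see \linkS4class{CohortParams}.
#' @export
cohortParams <- function(n = 304L,
                         scorePrevalence = c(dense = 49, alternating = 146,
                                             sparse = 109) / 304,
                         fractureProbByScore = c(dense = 1 / 49,
                                                 alternating = 35 / 146,
                                                 sparse = 79 / 109),
                         clinicalMeans = c(age = 54.1, weight = 66.3,
                                           height = 163.5),
                         clinicalSds = c(age = 4.0, weight = 10.6,
                                         height = 5.9),
                         featureEffects = numeric(0), seed = 1L) {
  new("CohortParams", n = as.integer(n), scorePrevalence = scorePrevalence,
      fractureProbByScore = fractureProbByScore,
      clinicalMeans = clinicalMeans, clinicalSds = clinicalSds,
      featureEffects = featureEffects, seed = as.integer(seed))
}

# run expr under a locally seeded RNG, restoring the caller's RNG state.
# One global seed expands to independent substreams via fixed offsets so
# texture, rendering and cohort draws stay independently reproducible.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% 2147483647L, kind = "Mersenne-Twister")
  force(expr)
}

.substream <- function(seed, k) (as.integer(seed) + 77003L * as.integer(k)) %% 2147483647L

# smooth correlated field: seeded white noise convolved (circularly, via
# FFT) with an anisotropic Gaussian kernel elongated along `orientation`
.correlatedField <- function(side, orientation, anisotropy, coarseness, seed) {
  noise <- .withSeed(seed, matrix(rnorm(side * side), side, side))
  d <- ((0:(side - 1)) + side %/% 2) %% side - side %/% 2
  th <- orientation * pi / 180
  # coordinates: rows = y, columns = x; angle CCW from the column axis,
  # matching the LFD line convention (0 = horizontal, 90 = vertical)
  y <- matrix(d, side, side)          # row offsets
  x <- matrix(d, side, side, byrow = TRUE) # column offsets
  sigPerp <- coarseness / 2
  sigAlong <- anisotropy * sigPerp
  u <- x * cos(th) + y * sin(th)   # along the grain
  v <- -x * sin(th) + y * cos(th)  # across the grain
  kern <- exp(-0.5 * ((u / sigAlong)^2 + (v / sigPerp)^2))
  kern <- kern / sum(kern)
  Re(fft(fft(noise) * fft(kern), inverse = TRUE)) / (side * side)
}

# threshold a field so that exactly round(af * n) pixels are white
.thresholdByFraction <- function(field, areaFraction) {
  n <- length(field)
  k <- round(areaFraction * n)
  if (k <= 0L) return(array(FALSE, dim(field)))
  if (k >= n) return(array(TRUE, dim(field)))
  r <- rank(field, ties.method = "first")
  m <- r > (n - k)
  dim(m) <- dim(field)
  m
}

# render a ground-truth binary to gray: phase contrast around mid-gray,
# plus a smooth second-order polynomial background and Gaussian noise
.renderTexture <- function(truth, params, seed) {
  side <- nrow(truth)
  g <- 128 + params@phaseContrast * (truth - 0.5)
  if (params@gradientAmplitude > 0) {
    cx <- seq(-1, 1, length.out = side)
    gx <- matrix(cx, side, side, byrow = TRUE)
    gy <- matrix(cx, side, side)
    coefs <- .withSeed(.substream(seed, 2L), runif(5, -1, 1))
    bg <- coefs[1] * gx + coefs[2] * gy + coefs[3] * gx * gy +
      coefs[4] * (gx^2 - 1 / 3) + coefs[5] * (gy^2 - 1 / 3)
    bg <- bg / max(abs(bg))
    g <- g + params@gradientAmplitude * bg
  }
  if (params@noiseSd > 0)
    g <- g + .withSeed(.substream(seed, 3L),
                       matrix(rnorm(side * side, sd = params@noiseSd), side, side))
  pmin(pmax(g, 0), 255)
}

#' Generate a trabecular-like synthetic texture
#'
#' Builds a seeded correlated Gaussian random field, stretches it along
#' \code{orientation} by \code{anisotropy}, and thresholds it at the
#' quantile that yields exactly \code{areaFraction} white pixels — the
#' ground-truth binary. The gray rendering adds phase contrast, a smooth
#' polynomial background (the cortex/soft-tissue confounder the self-mask
#' must remove) and Gaussian noise.
#'
#' @param params a \linkS4class{TextureParams}.
#' @return list with \code{roi} (\linkS4class{GrayROI}), \code{truth}
#'   (\linkS4class{BinaryROI}) and \code{params}.
#' @export
generateTexture <- function(params = textureParams()) {
  stopifnot(is(params, "TextureParams"))
  validObject(params)
  field <- .correlatedField(params@side, params@orientation,
                            params@anisotropy, params@coarseness,
                            .substream(params@seed, 1L))
  truth <- .thresholdByFraction(field, params@areaFraction)
  gray <- .renderTexture(truth, params, params@seed)
  list(roi = GrayROI(gray), truth = BinaryROI(truth), params = params)
}

#' Generate a dense / sparse / alternating reference pattern
#'
#' Emulates the three reference trabecular patterns used for the observer
#' score: \code{dense} has many trabeculae and small intertrabecular spaces
#' (high white fraction, small correlation length); \code{sparse} has fewer,
#' coarser trabeculae and mostly large spaces; \code{alternating} blends
#' from dense at the top of the ROI (cervical, crown-up orientation) to
#' sparse at the bottom (apical), with the per-row white fraction
#' interpolating between the two.
#'
#' @param kind \code{"dense"}, \code{"sparse"} or \code{"alternating"}.
#' @param seed integer seed.
#' @param side ROI side in px (default 650).
#' @return list with \code{roi}, \code{truth}, \code{kind} (same structure
#'   as \code{\link{generateTexture}}).
#' @export
generateReferencePattern <- function(kind = c("dense", "sparse", "alternating"),
                                     seed = 1L, side = 650L) {
  kind <- match.arg(kind)
  densePar <- textureParams(side = side, areaFraction = 0.55, coarseness = 4,
                            anisotropy = 1.5, orientation = 90, seed = seed)
  sparsePar <- textureParams(side = side, areaFraction = 0.30, coarseness = 10,
                             anisotropy = 1.5, orientation = 90, seed = seed)
  if (kind == "dense") {
    out <- generateTexture(densePar)
  } else if (kind == "sparse") {
    out <- generateTexture(sparsePar)
  } else {
    # blended field with a row-wise white-fraction ramp dense -> sparse
    fDense <- .correlatedField(side, 90, 1.5, 4, .substream(seed, 1L))
    fSparse <- .correlatedField(side, 90, 1.5, 10, .substream(seed, 4L))
    w <- seq(0, 1, length.out = side) # 0 at top (cervical) -> 1 (apical)
    z <- (1 - w) * scale01(fDense) + w * scale01(fSparse)
    afRow <- (1 - w) * 0.55 + w * 0.30
    truth <- matrix(FALSE, side, side)
    for (r in seq_len(side)) {
      k <- round(afRow[r] * side)
      if (k > 0L) truth[r, rank(z[r, ], ties.method = "first") > side - k] <- TRUE
    }
    par <- textureParams(side = side, areaFraction = mean(afRow),
                         coarseness = 7, seed = seed)
    gray <- .renderTexture(truth, par, seed)
    out <- list(roi = GrayROI(gray), truth = BinaryROI(truth), params = par)
  }
  out$kind <- kind
  out
}

scale01 <- function(m) (m - mean(m)) / sd(as.vector(m))

#' Generate a synthetic cohort
#'
#' Draws observer scores from the score prevalences, fracture outcomes per
#' score from the per-score fracture probabilities, Gaussian clinical
#' variables independent of outcome (BMI derived from weight and height),
#' and, when \code{featureEffects} is non-empty, standard-normal image
#' features that add their stated effects to the fracture logit. With the
#' default parameters the cohort is the statistical twin of the published
#' 304-subject table.
#'
#' @param params a \linkS4class{CohortParams}.
#' @return data.frame with columns \code{id, score, score_ord, age, weight,
#'   height, bmi, fracture} and one column per named feature effect.
#' @export
generateCohort <- function(params = cohortParams()) {
  stopifnot(is(params, "CohortParams"))
  validObject(params)
  n <- params@n
  scoreOrd <- .withSeed(.substream(params@seed, 11L),
                        sample(0:2, n, replace = TRUE,
                               prob = params@scorePrevalence))
  cm <- params@clinicalMeans; cs <- params@clinicalSds
  clin <- .withSeed(.substream(params@seed, 12L), {
    age <- rnorm(n, cm["age"], cs["age"])
    weight <- pmax(rnorm(n, cm["weight"], cs["weight"]), 30)
    height <- pmax(rnorm(n, cm["height"], cs["height"]), 120)
    data.frame(age = age, weight = weight, height = height)
  })
  clin$bmi <- clin$weight / (clin$height / 100)^2

  eff <- params@featureEffects
  feats <- NULL
  logit <- qlogis(pmin(pmax(params@fractureProbByScore[scoreOrd + 1L], 1e-12),
                       1 - 1e-12))
  if (length(eff)) {
    feats <- .withSeed(.substream(params@seed, 13L), {
      as.data.frame(setNames(
        lapply(seq_along(eff), function(j) rnorm(n)), names(eff)))
    })
    logit <- logit + as.matrix(feats) %*% eff
  }
  fracture <- .withSeed(.substream(params@seed, 14L),
                        rbinom(n, 1L, plogis(as.numeric(logit))))
  df <- data.frame(id = sprintf("S%04d", seq_len(n)),
                   score = factor(SCORE_LEVELS[scoreOrd + 1L],
                                  levels = SCORE_LEVELS),
                   score_ord = scoreOrd,
                   age = clin$age, weight = clin$weight, height = clin$height,
                   bmi = clin$bmi, fracture = as.integer(fracture))
  if (!is.null(feats)) df <- cbind(df, feats)
  df
}

#' Analytic toy shapes
#'
#' Deterministic binary fixtures with hand-countable morphometry and
#' skeleton statistics, used as exact oracles:
#' \describe{
#'   \item{square}{one \code{size} x \code{size} white square centered in a
#'     black field (area \code{size^2} px).}
#'   \item{band}{full-width horizontal white band of height \code{size} px
#'     (width \code{size} px by the distance-transform convention).}
#'   \item{plus}{two centered \code{size}-px one-pixel lines crossing at the
#'     center: 4 endpoints and, under the 8-neighborhood degree rule, a
#'     five-pixel junction cluster of nodes.}
#'   \item{line}{straight horizontal one-pixel line of \code{size} px:
#'     0 nodes, 2 endpoints, 1 strut.}
#'   \item{stripes}{vertical stripes, \code{size}/2 white then \code{size}/2
#'     black columns: LFD maximal at 90 degrees.}
#' }
#'
#' @param name one of square, band, plus, line, stripes.
#' @param side image side in px.
#' @param size shape size in px (square side, band height, line length,
#'   stripe period; defaults: 10, 10, 9, 20, 20).
#' @param pixelSpacing mm per pixel (default 1 for analytic tests).
#' @return a \linkS4class{BinaryROI}.
#' @export
toyShapes <- function(name, side = 100L, size = NULL, pixelSpacing = 1) {
  m <- matrix(FALSE, side, side)
  ctr <- side %/% 2L
  if (name == "square") {
    if (is.null(size)) size <- 10L
    i <- ctr + seq_len(size) - size %/% 2L
    m[i, i] <- TRUE
  } else if (name == "band") {
    if (is.null(size)) size <- 10L
    m[ctr + seq_len(size) - size %/% 2L, ] <- TRUE
  } else if (name == "plus") {
    if (is.null(size)) size <- 9L
    h <- size %/% 2L
    m[ctr, (ctr - h):(ctr + h)] <- TRUE
    m[(ctr - h):(ctr + h), ctr] <- TRUE
  } else if (name == "line") {
    if (is.null(size)) size <- 20L
    m[ctr, ctr + seq_len(size) - size %/% 2L] <- TRUE
  } else if (name == "stripes") {
    if (is.null(size)) size <- 20L
    half <- size %/% 2L
    white <- ((seq_len(side) - 1L) %% size) < half
    m[, white] <- TRUE
  } else {
    stop("unknown toy shape: ", name,
         " (expected square/band/plus/line/stripes)")
  }
  BinaryROI(m, pixelSpacing = pixelSpacing)
}
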