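#' The packaged fracture-by-score table
#'
#' Cell counts of the 304-subject fracture x observer-score
#' cross-tabulation, shipped as a plain-text fixture
#' (\code{extdata/table2_counts.csv}; the header documents how the six
#' cells follow uniquely from the published margins).
#'
#' @return a \linkS4class{ContingencyTable}.
#' @export
table2Counts <- function() {
  path <- system.file("extdata", "table2_counts.csv", package = "trabpat",
                      mustWork = TRUE)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(df[, SCORE_LEVELS])
  storage.mode(m) <- "integer"
  dimnames(m) <- list(c("fractured", "fracture_free"), SCORE_LEVELS)
  new("ContingencyTable", counts = m)
}

#' Record-level expansion of the packaged table
#'
#' Expands the fracture-by-score counts into one record per subject. With
#' \code{clinical = TRUE} (default), null clinical variables (age, weight,
#' height, BMI independent of outcome, drawn from the cohort's published
#' means and SDs) are attached under a fixed documented seed so the
#' expansion is a reproducible fixture, not a fresh simulation.
#'
#' @param clinical attach simulated null clinical variables.
#' @param seed seed for the clinical draw (default 2017, fixed so the
#'   fixture is deterministic).
#' @return cohort data.frame with columns \code{id, score, score_ord,
#'   fracture} and, when requested, \code{age, weight, height, bmi}.
#' @export
table2Cohort <- function(clinical = TRUE, seed = 2017L) {
  ct <- tableCounts(table2Counts())
  rows <- expand.grid(outcome = rownames(ct), score = colnames(ct),
                      stringsAsFactors = FALSE)
  recs <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    k <- ct[rows$outcome[i], rows$score[i]]
    if (k == 0L) return(NULL)
    data.frame(score = rep(rows$score[i], k),
               fracture = rep(as.integer(rows$outcome[i] == "fractured"), k))
  }))
  recs$score <- factor(recs$score, levels = SCORE_LEVELS)
  recs$score_ord <- as.integer(recs$score) - 1L
  recs <- recs[order(-recs$fracture, recs$score_ord), ]
  recs$id <- sprintf("T%04d", seq_len(nrow(recs)))
  rownames(recs) <- NULL
  if (clinical) {
    n <- nrow(recs)
    clin <- .withSeed(seed, {
      data.frame(age = rnorm(n, 54.1, 4.0),
                 weight = pmax(rnorm(n, 66.3, 10.6), 30),
                 height = pmax(rnorm(n, 163.5, 5.9), 120))
    })
    clin$bmi <- clin$weight / (clin$height / 100)^2
    recs <- cbind(recs, clin)
  }
  recs[, c("id", "score", "score_ord",
           if (clinical) c("age", "weight", "height", "bmi"), "fracture")]
}

#' Reproduce the published observer-score statistics
#'
#' Recomputes, from the packaged fracture-by-score table: the 2x3 table
#' with margins, the sparse-vs-rest fracture odds ratio with its Wald 95%
#' interval, the dense-vs-rest fracture-free odds ratio, sensitivity and
#' specificity of the sparse cutoff, and the ordinal ROC AUC of the score —
#' each printed beside the published value.
#'
#' @return invisibly, a named list of the computed quantities.
#' @export
reproduceTable2 <- function() {
  ct <- table2Counts()
  show(ct)
  orS <- oddsRatioCI(collapseTable(ct, "sparse", "fractured"))
  orD <- oddsRatioCI(collapseTable(ct, "dense", "fracture_free"))
  ss <- sensitivitySpecificity(ct, positive = "sparse")
  auc <- ordinalAUC(ct)
  cat(sprintf("sparse-vs-rest fracture OR:   %.1f (%.1f-%.1f)   [published 11.6 (6.7-20.3)]\n",
              orS["or"], orS["lower"], orS["upper"]))
  cat(sprintf("dense-vs-rest fracture-free OR: %.1f            [published 38.8]\n",
              orD["or"]))
  cat(sprintf("sparse cutoff sensitivity:    %.0f%%             [published 69%%]\n",
              100 * ss["sensitivity"]))
  cat(sprintf("sparse cutoff specificity:    %.0f%%             [published 84%%]\n",
              100 * ss["specificity"]))
  cat(sprintf("ordinal ROC AUC of the score: %.3f            [published 0.800]\n",
              auc))
  invisible(list(table = ct, sparse_or = orS, dense_or = orD,
                 sens_spec = ss, auc = auc))
}

#' Batch feature extraction
#'
#' Runs \code{\link{extractFeatureVector}} over a set of inputs (image file
#' paths or in-memory \linkS4class{GrayROI} objects), writes the feature CSV
#' and a provenance JSON (parameters and package version) alongside, and
#' reports per-input failures without aborting the batch.
#'
#' @param inputs named list/vector of PNG/TIFF paths, or a named list of
#'   \linkS4class{GrayROI} objects.
#' @param outCsv output CSV path.
#' @param params a \linkS4class{PreprocessParams}.
#' @param windows optional list of \code{c(centerRow, centerCol)} per input
#'   for cropping full images; \code{NULL} means inputs are already
#'   ROI-sized.
#' @param pixelSpacing mm per pixel for file inputs.
#' @return invisibly, list with \code{table} (the feature data.frame),
#'   \code{errors} (named character of per-input failures) and \code{ok}
#'   (TRUE when every input succeeded).
#' @export
extractFeaturesBatch <- function(inputs, outCsv, params = preprocessParams(),
                                 windows = NULL,
                                 pixelSpacing = DEFAULT_PIXEL_SPACING) {
  if (is.null(names(inputs)) || any(!nzchar(names(inputs))))
    names(inputs) <- paste0("roi_", seq_along(inputs))
  feats <- list()
  errors <- character(0)
  for (nm in names(inputs)) {
    res <- tryCatch({
      x <- inputs[[nm]]
      roi <- if (is(x, "GrayROI")) {
        x
      } else {
        img <- loadGrayImage(x, pixelSpacing = pixelSpacing)
        if (!is.null(windows[[nm]])) {
          extractROI(img, windows[[nm]][1], windows[[nm]][2])
        } else {
          GrayROI(as.matrix(img), pixelSpacing = pixelSpacing)
        }
      }
      extractFeatureVector(roi, params)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[nm] <- conditionMessage(res)
      message("[extract] ERROR ", nm, ": ", conditionMessage(res))
    } else {
      feats[[nm]] <- res
    }
  }
  if (length(feats) == 0L) stop("no input could be processed")
  writeFeatureTable(feats, outCsv)
  prov <- list(package = "trabpat",
               version = as.character(utils::packageVersion("trabpat")),
               blurWindow = params@blurWindow,
               thresholdOffset = params@thresholdOffset,
               pixelSpacing = pixelSpacing,
               n_inputs = length(inputs), n_failed = length(errors))
  jsonlite::write_json(prov, paste0(outCsv, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(table = readFeatureTable(outCsv), errors = errors,
                 ok = length(errors) == 0L))
}

#' Cohort fracture-risk report
#'
#' Fits forward stepwise logistic regression for one of the three published
#' variable sets — \code{"observer"} (observer score + age, weight, height,
#' BMI), \code{"features"} (image-feature columns), or \code{"combined"} —
#' and builds the ROC curve of the fitted probabilities. Optionally writes
#' the model report as JSON and the ROC points as CSV.
#'
#' @param records cohort data.frame (see \code{\link{readCohort}}).
#' @param set which variable set to fit.
#' @param featureCols character vector naming the image-feature columns
#'   (required for \code{"features"} and \code{"combined"}).
#' @param alpha stepwise entry threshold (default 0.05).
#' @param outJson,rocCsv optional output paths.
#' @return list with \code{model} (\linkS4class{StepwiseModel}), \code{roc}
#'   (\linkS4class{ROCResult}) and \code{auc}.
#' @export
cohortRiskReport <- function(records, set = c("observer", "features",
                                              "combined"),
                             featureCols = NULL, alpha = 0.05,
                             outJson = NULL, rocCsv = NULL) {
  set <- match.arg(set)
  clinical <- intersect(c("age", "weight", "height", "bmi"), names(records))
  observerSet <- c("score_ord", clinical)
  candidates <- switch(set,
    observer = observerSet,
    features = featureCols,
    combined = c(observerSet, featureCols))
  if (set != "observer" && (is.null(featureCols) || length(featureCols) == 0L))
    stop("config error: set '", set, "' needs featureCols")
  miss <- setdiff(candidates, names(records))
  if (length(miss))
    stop("config error: column(s) missing for set '", set, "': ",
         paste(miss, collapse = ", "))
  model <- forwardStepwiseLogistic(records, candidates, alpha = alpha)
  roc <- rocFromScores(fitted(model), records$fracture[
    stats::complete.cases(records[, c("fracture", candidates), drop = FALSE])])
  report <- list(set = set,
                 selected = selectedVariables(model),
                 coefficients = as.list(coef(model)),
                 steps = stepHistory(model),
                 auc = rocAUC(roc))
  if (!is.null(outJson))
    jsonlite::write_json(report, outJson, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  if (!is.null(rocCsv))
    write.csv(rocPoints(roc), rocCsv, row.names = FALSE)
  list(model = model, roc = roc, auc = rocAUC(roc))
}

#' Print the package's tunable defaults
#'
#' @return invisibly, the named list of defaults.
#' @export
showConfig <- function() {
  cfg <- list(pixel_spacing_mm = DEFAULT_PIXEL_SPACING,
              roi_side_px = ROI_SIDE,
              median_window = 3L,
              blur_window_px = 101L,
              threshold_offset = 0,
              lfd_angles_deg = LFD_ANGLES,
              lfd_segment_length_px = 65L,
              min_segment_area_px = 0L,
              stepwise_alpha = 0.05)
  for (nm in names(cfg))
    cat(sprintf("%-26s %s\n", nm, paste(format(cfg[[nm]], digits = 6),
                                        collapse = " ")))
  invisible(cfg)
}
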