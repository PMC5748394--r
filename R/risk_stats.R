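#' Build the fracture-by-score contingency table
#'
#' Cross-tabulates fracture outcome (rows: fractured / fracture-free)
#' against the ordinal observer score (columns: dense / alternating /
#' sparse). Order-invariant in the records.
#'
#' @param records cohort data.frame with columns \code{score} (factor or
#'   label) and \code{fracture} (0/1), as returned by
#'   \code{\link{readCohort}} or \code{\link{generateCohort}}.
#' @return a \linkS4class{ContingencyTable}.
#' @export
buildContingency <- function(records) {
  stopifnot(nrow(records) > 0L)
  sc <- factor(tolower(as.character(records$score)), levels = SCORE_LEVELS)
  fr <- factor(ifelse(records$fracture == 1, "fractured", "fracture_free"),
               levels = c("fractured", "fracture_free"))
  counts <- table(fr, sc)
  m <- matrix(as.integer(counts), 2, 3,
              dimnames = list(c("fractured", "fracture_free"), SCORE_LEVELS))
  new("ContingencyTable", counts = m)
}

#' Collapse a contingency table to 2x2
#'
#' Exposure = membership of the score in \code{positive}; rows keep the
#' outcome. Used to compute, e.g., the sparse-vs-rest fracture odds ratio.
#'
#' @param ct a \linkS4class{ContingencyTable}.
#' @param positive character subset of \code{c("dense","alternating","sparse")}.
#' @param outcome which outcome row is the "event": \code{"fractured"}
#'   (default) or \code{"fracture_free"}.
#' @return 2x2 matrix: rows event/non-event, columns exposed/unexposed.
#' @export
collapseTable <- function(ct, positive,
                          outcome = c("fractured", "fracture_free")) {
  stopifnot(is(ct, "ContingencyTable"))
  outcome <- match.arg(outcome)
  stopifnot(length(positive) >= 1L, all(positive %in% SCORE_LEVELS),
            length(positive) < 3L)
  cnt <- ct@counts
  if (outcome == "fracture_free") cnt <- cnt[2:1, , drop = FALSE]
  expo <- colnames(cnt) %in% positive
  m <- cbind(exposed = rowSums(cnt[, expo, drop = FALSE]),
             unexposed = rowSums(cnt[, !expo, drop = FALSE]))
  rownames(m) <- c("event", "no_event")
  m
}

#' Odds ratio with Wald confidence interval
#'
#' Cross-product odds ratio of a 2x2 table with the Wald interval
#' \code{exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))}. Zero cells are
#' rejected by default; set \code{correction = TRUE} to add the conventional
#' 0.5 to every cell.
#'
#' @param tab 2x2 numeric matrix: rows event/no-event, columns
#'   exposed/unexposed.
#' @param level confidence level (default 0.95; z = 1.96 exactly for 95%, as
#'   conventionally printed).
#' @param correction add 0.5 to all cells (Haldane-Anscombe) when a cell is
#'   zero.
#' @return named numeric: \code{or, lower, upper}.
#' @export
oddsRatioCI <- function(tab, level = 0.95, correction = FALSE) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  if (any(tab == 0) && !correction)
    stop("zero cell in 2x2 table; re-run with correction = TRUE to apply ",
         "the 0.5 continuity correction")
  if (correction) tab <- tab + 0.5
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- if (abs(level - 0.95) < 1e-12) 1.96 else stats::qnorm(1 - (1 - level) / 2)
  c(or = or, lower = exp(log(or) - z * se), upper = exp(log(or) + z * se))
}

#' Sensitivity and specificity of a score cutoff
#'
#' Treating membership of the score in \code{positive} as a positive test:
#' sensitivity = fractured subjects with a positive score / all fractured;
#' specificity = fracture-free subjects with a negative score / all
#' fracture-free.
#'
#' @param ct a \linkS4class{ContingencyTable}.
#' @param positive non-empty subset of the score levels (default
#'   \code{"sparse"}, the published cutoff; the full set is the degenerate
#'   all-positive cutoff with sensitivity 1 and specificity 0).
#' @return named numeric: \code{sensitivity, specificity} (proportions);
#'   \code{NA} for an empty outcome row.
#' @export
sensitivitySpecificity <- function(ct, positive = "sparse") {
  stopifnot(is(ct, "ContingencyTable"), length(positive) >= 1L,
            all(positive %in% SCORE_LEVELS))
  cnt <- ct@counts
  pos <- colnames(cnt) %in% positive
  nFrac <- sum(cnt["fractured", ])
  nFree <- sum(cnt["fracture_free", ])
  sens <- if (nFrac == 0) NA_real_ else sum(cnt["fractured", pos]) / nFrac
  spec <- if (nFree == 0) NA_real_ else sum(cnt["fracture_free", !pos]) / nFree
  c(sensitivity = sens, specificity = spec)
}

#' Ordinal AUC of the observer score
#'
#' Tie-corrected pairwise concordance: over all fractured x fracture-free
#' subject pairs, a pair scores 1 when the fractured subject has the higher
#' ordinal score (dense < alternating < sparse), 0.5 when tied; the AUC is
#' the total divided by the number of pairs. This equals the ROC area of any
#' model with the score as sole monotone predictor.
#'
#' @param ct a \linkS4class{ContingencyTable}.
#' @return the AUC, or \code{NA} if an outcome row is empty.
#' @export
ordinalAUC <- function(ct) {
  stopifnot(is(ct, "ContingencyTable"))
  f <- as.numeric(ct@counts["fractured", ])     # ordered dense < alt < sparse
  g <- as.numeric(ct@counts["fracture_free", ])
  nF <- sum(f); nG <- sum(g)
  if (nF == 0 || nG == 0) return(NA_real_)
  conc <- 0
  for (i in 2:3) conc <- conc + f[i] * sum(g[seq_len(i - 1L)])
  ties <- sum(f * g)
  (conc + 0.5 * ties) / (nF * nG)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between two categorical raters:
#' \code{(observed agreement - chance agreement) / (1 - chance agreement)},
#' with chance agreement from the marginal label distributions. Invariant
#' under relabeling of the categories.
#'
#' @param x,y label vectors of equal length over the same category set.
#' @return kappa, or \code{NA} when chance agreement is 1 (degenerate
#'   marginals).
#' @export
cohensKappa <- function(x, y) {
  if (length(x) != length(y)) stop("rating vectors must have equal length")
  lev <- sort(unique(c(as.character(x), as.character(y))))
  x <- factor(as.character(x), levels = lev)
  y <- factor(as.character(y), levels = lev)
  n <- length(x)
  tab <- table(x, y) / n
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (abs(1 - pe) < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Welch two-sample t comparison
#'
#' Welch's t statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value, for comparing fractured with fracture-free subjects
#' on a clinical variable. Requires n >= 2 per group and a nonzero variance
#' in at least one group.
#'
#' @param groupA,groupB numeric vectors.
#' @return named numeric: \code{t, df, p}.
#' @export
welchT <- function(groupA, groupB) {
  groupA <- groupA[!is.na(groupA)]; groupB <- groupB[!is.na(groupB)]
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 observations")
  if (sd(groupA) == 0 && sd(groupB) == 0) {
    if (mean(groupA) == mean(groupB))
      return(c(t = 0, df = length(groupA) + length(groupB) - 2, p = 1))
    stop("degenerate variance: both groups are constant but differ")
  }
  tt <- t.test(groupA, groupB, var.equal = FALSE)
  c(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' ROC curve from continuous risk scores
#'
#' Threshold sweep over the unique score values (predicted positive when the
#' score is >= the threshold), giving the ordered (FPR, TPR) points from
#' (0,0) to (1,1), with the trapezoidal AUC. The AUC is invariant under any
#' strictly monotone transform of the scores and equals the tie-corrected
#' pairwise concordance.
#'
#' @param scores per-record risk values.
#' @param outcomes 0/1 outcomes of the same length.
#' @return a \linkS4class{ROCResult}, or \code{NA} if only one outcome class
#'   is present.
#' @export
rocFromScores <- function(scores, outcomes) {
  stopifnot(length(scores) == length(outcomes))
  ok <- !is.na(scores) & !is.na(outcomes)
  scores <- scores[ok]; outcomes <- as.integer(outcomes[ok])
  nP <- sum(outcomes == 1L); nN <- sum(outcomes == 0L)
  if (nP == 0L || nN == 0L) return(NA)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & outcomes == 1L) / nP,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & outcomes == 0L) / nN,
                numeric(1))
  fpr <- c(0, fpr); tpr <- c(0, tpr)
  if (fpr[length(fpr)] != 1 || tpr[length(tpr)] != 1) {
    fpr <- c(fpr, 1); tpr <- c(tpr, 1)
  }
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  new("ROCResult", points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Forward stepwise logistic regression
#'
#' Starts from the intercept-only model (prediction by prevalence). At each
#' step every remaining candidate is added in turn to the current model; the
#' candidate with the largest likelihood-ratio improvement enters if its LRT
#' p-value is below \code{alpha}, and the procedure stops otherwise (pure
#' forward selection, no removal step). The observer score enters as a
#' single ordinal numeric (0/1/2); with one 3-level predictor the fitted
#' probabilities are monotone in the score, so the ROC/AUC is identical
#' under ordinal or dummy coding.
#'
#' Candidates on which the fit separates perfectly (fitted probabilities
#' numerically 0 or 1) are flagged, excluded with a warning, and reported in
#' the \code{excluded} slot.
#'
#' @param records cohort data.frame containing \code{fracture} and the
#'   candidate columns.
#' @param candidates character vector of candidate variable names.
#' @param alpha entry threshold on the LRT p-value (default 0.05).
#' @return a \linkS4class{StepwiseModel}.
#' @export
forwardStepwiseLogistic <- function(records, candidates, alpha = 0.05) {
  stopifnot(is.data.frame(records), "fracture" %in% names(records))
  if (length(unique(records$fracture)) < 2L)
    stop("both outcome classes must be present")
  miss <- setdiff(candidates, names(records))
  if (length(miss)) stop("candidate(s) not in records: ",
                         paste(miss, collapse = ", "))
  stopifnot(alpha > 0, alpha <= 1)

  dat <- records[, c("fracture", candidates), drop = FALSE]
  cc <- stats::complete.cases(dat)
  if (!all(cc)) {
    warning(sum(!cc), " record(s) with missing candidate values dropped")
    dat <- dat[cc, , drop = FALSE]
  }

  fitGlm <- function(vars) {
    fml <- if (length(vars) == 0L) fracture ~ 1 else
      stats::reformulate(vars, response = "fracture")
    sep <- FALSE
    fit <- withCallingHandlers(
      glm(fml, family = binomial(), data = dat,
          control = list(maxit = 100)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8))
      sep <- TRUE
    if (!fit$converged)
      stop("no convergence for model ", deparse(fml),
           " after ", fit$iter, " IRLS iterations")
    list(fit = fit, separated = sep)
  }

  selected <- character(0)
  excluded <- character(0)
  remaining <- candidates
  cur <- fitGlm(selected)$fit
  steps <- data.frame(variable = character(0), lr = numeric(0),
                      df = numeric(0), p = numeric(0), entered = logical(0))

  repeat {
    remaining <- setdiff(remaining, excluded)
    if (length(remaining) == 0L) break
    trials <- lapply(remaining, function(v) {
      res <- fitGlm(c(selected, v))
      if (res$separated) return(list(sep = TRUE))
      lr <- cur$deviance - res$fit$deviance
      df <- cur$df.residual - res$fit$df.residual
      list(sep = FALSE, fit = res$fit, lr = lr, df = df,
           p = pchisq(lr, df = max(df, 1L), lower.tail = FALSE))
    })
    names(trials) <- remaining
    seps <- names(trials)[vapply(trials, function(x) isTRUE(x$sep), logical(1))]
    if (length(seps)) {
      warning("candidate(s) excluded for perfect separation: ",
              paste(seps, collapse = ", "))
      excluded <- c(excluded, seps)
      trials <- trials[setdiff(names(trials), seps)]
      if (length(trials) == 0L) break
    }
    lrs <- vapply(trials, `[[`, numeric(1), "lr")
    best <- names(trials)[which.max(lrs)]
    bt <- trials[[best]]
    enter <- bt$p < alpha
    steps <- rbind(steps, data.frame(variable = best, lr = bt$lr, df = bt$df,
                                     p = bt$p, entered = enter))
    if (!enter) break
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    cur <- bt$fit
  }

  new("StepwiseModel",
      variables = selected,
      coefficients = coef(cur),
      steps = steps,
      fitted = unname(fitted(cur)),
      alpha = alpha,
      excluded = excluded)
}
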