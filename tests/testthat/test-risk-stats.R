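table2Fixture <- function() table2Counts()

test_that("the contingency table is built correctly and is order-invariant", {
  coh <- table2Cohort(clinical = FALSE)
  ct <- buildContingency(coh)
  expect_identical(tableCounts(ct),
                   matrix(c(1L, 48L, 35L, 111L, 79L, 30L), 2, 3,
                          dimnames = list(c("fractured", "fracture_free"),
                                          c("dense", "alternating", "sparse"))))
  set.seed(1)
  perm <- coh[sample(nrow(coh)), ]
  expect_identical(tableCounts(buildContingency(perm)), tableCounts(ct))

  one <- data.frame(score = "sparse", fracture = 1)
  ct1 <- tableCounts(buildContingency(one))
  expect_identical(sum(ct1), 1L)
  expect_identical(ct1["fractured", "sparse"], 1L)
})

test_that("odds ratios use the cross-product with the Wald interval", {
  expect_equal(unname(oddsRatioCI(matrix(c(1, 1, 1, 1), 2, 2))["or"]), 1)

  set.seed(5)
  for (i in 1:10) {
    tab <- matrix(sample(5:50, 4), 2, 2)
    got <- oddsRatioCI(tab)
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    expect_equal(unname(got["or"]), a * d / (b * c), tolerance = 1e-12)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    expect_equal(unname(got["lower"]), exp(log(a * d / (b * c)) - 1.96 * se),
                 tolerance = 1e-12)
    # transposing exposure maps OR -> 1/OR and swaps reciprocal CI ends
    flipped <- oddsRatioCI(tab[, 2:1])
    expect_equal(unname(flipped["or"]), 1 / unname(got["or"]), tolerance = 1e-12)
    expect_equal(unname(flipped["lower"]), 1 / unname(got["upper"]),
                 tolerance = 1e-12)
  }

  ztab <- matrix(c(0, 5, 3, 7), 2, 2)
  expect_error(oddsRatioCI(ztab), "correction = TRUE")
  corr <- oddsRatioCI(ztab, correction = TRUE)
  expect_equal(unname(corr["or"]), (0.5 * 7.5) / (3.5 * 5.5), tolerance = 1e-12)
})

test_that("sensitivity and specificity follow the direct ratios", {
  ct <- table2Fixture()
  ss <- sensitivitySpecificity(ct, positive = "sparse")
  expect_equal(unname(ss["sensitivity"]), 79 / 115, tolerance = 1e-12)
  expect_equal(unname(ss["specificity"]), 159 / 189, tolerance = 1e-12)

  all3 <- sensitivitySpecificity(ct, positive = c("dense", "alternating", "sparse"))
  expect_equal(unname(all3["sensitivity"]), 1)
  expect_equal(unname(all3["specificity"]), 0)

  set.seed(9)
  for (i in 1:10) {
    m <- matrix(sample(1:40, 6, replace = TRUE), 2, 3,
                dimnames = list(c("fractured", "fracture_free"),
                                c("dense", "alternating", "sparse")))
    ct2 <- new("ContingencyTable", counts = m)
    pos <- sample(c("dense", "alternating", "sparse"), sample(1:2, 1))
    got <- sensitivitySpecificity(ct2, pos)
    expect_equal(unname(got["sensitivity"]),
                 sum(m[1, pos]) / sum(m[1, ]), tolerance = 1e-12)
    expect_equal(unname(got["specificity"]),
                 sum(m[2, setdiff(colnames(m), pos)]) / sum(m[2, ]),
                 tolerance = 1e-12)
  }
})

test_that("the ordinal AUC equals brute-force pairwise concordance", {
  perfect <- new("ContingencyTable",
                 counts = matrix(c(0L, 40L, 0L, 0L, 25L, 0L), 2, 3,
                                 dimnames = list(c("fractured", "fracture_free"),
                                                 c("dense", "alternating", "sparse"))))
  expect_equal(ordinalAUC(perfect), 1)

  set.seed(17)
  for (i in 1:50) {
    m <- matrix(sample(0:30, 6, replace = TRUE), 2, 3,
                dimnames = list(c("fractured", "fracture_free"),
                                c("dense", "alternating", "sparse")))
    if (sum(m[1, ]) == 0 || sum(m[2, ]) == 0) next
    ct <- new("ContingencyTable", counts = m)
    ex <- expandTable(m)
    expect_equal(ordinalAUC(ct), oraclePairAUC(ex$scores, ex$outcomes),
                 tolerance = 1e-12)
    # and equals the ROC area of the score used directly as a risk value
    roc <- rocFromScores(ex$scores, ex$outcomes)
    expect_equal(ordinalAUC(ct), rocAUC(roc), tolerance = 1e-12)
  }
})

test_that("Cohen's kappa matches its definition and is relabeling-invariant", {
  x <- c("a", "b", "c", "a", "b")
  expect_equal(cohensKappa(x, x), 1)

  # independence: all four cells of a 2x2 confusion equal
  x2 <- rep(c("p", "p", "q", "q"), 10)
  y2 <- rep(c("p", "q", "p", "q"), 10)
  expect_equal(cohensKappa(x2, y2), 0)

  set.seed(23)
  for (i in 1:10) {
    a <- sample(letters[1:3], 60, replace = TRUE)
    b <- sample(letters[1:3], 60, replace = TRUE)
    tab <- table(factor(a, levels = letters[1:3]),
                 factor(b, levels = letters[1:3]))
    expect_equal(cohensKappa(a, b),
                 e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
    relab <- c(a = "z", b = "y", c = "x")
    expect_equal(cohensKappa(relab[a], relab[b]), cohensKappa(a, b),
                 tolerance = 1e-12)
  }
  expect_error(cohensKappa(1:3, 1:4), "equal length")
})

test_that("the Welch t comparison gives the textbook statistic and p-value", {
  g <- c(1, 2, 3, 4)
  out <- welchT(g, g)
  expect_equal(unname(out["t"]), 0)
  expect_equal(unname(out["p"]), 1)

  hand <- welchT(c(0, 2), c(1, 3))
  expect_equal(unname(hand["t"]), -1 / sqrt(2), tolerance = 1e-12)

  set.seed(29)
  a <- rnorm(15); b <- rnorm(20, 0.5)
  got <- welchT(a, b)
  expect_equal(unname(got["p"]),
               2 * stats::pt(-abs(got["t"]), df = got["df"]),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(welchT(c(1, 1), c(1, 1, 1)), NA) # equal constants: t = 0
  expect_error(welchT(c(1, 1), c(2, 2)), "degenerate")
})

test_that("ROC construction is exact, monotone-invariant, and agrees with pROC", {
  y <- c(0, 1, 0, 1, 1)
  expect_equal(rocAUC(rocFromScores(y, y)), 1)
  expect_equal(rocAUC(rocFromScores(rep(2, 5), y)), 0.5)
  expect_true(is.na(suppressWarnings(rocFromScores(1:4, rep(1, 4))[1])))

  set.seed(31)
  for (i in 1:10) {
    sc <- round(rnorm(40), 1) # ties included
    out <- rbinom(40, 1, plogis(sc))
    if (length(unique(out)) < 2) next
    roc <- rocFromScores(sc, out)
    expect_equal(rocAUC(roc), oraclePairAUC(sc, out), tolerance = 1e-12)
    expect_equal(rocAUC(rocFromScores(exp(sc), out)), rocAUC(roc),
                 tolerance = 1e-12)
    pr <- pROC::roc(out, sc, quiet = TRUE, direction = "<")
    expect_equal(rocAUC(roc), as.numeric(pROC::auc(pr)), tolerance = 1e-9)
    pts <- rocPoints(roc)
    expect_false(is.unsorted(pts$fpr))
    expect_false(is.unsorted(pts$tpr))
  }
})

test_that("forward stepwise selects a strong true effect first and respects alpha", {
  # one true logit effect beta = 2 on X1 among four pure-noise candidates
  set.seed(7)
  n <- 1000
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("X", 1:5)))
  y <- rbinom(n, 1, plogis(2 * X[, 1]))
  dat <- data.frame(fracture = y, X)
  m <- forwardStepwiseLogistic(dat, paste0("X", 1:5))
  expect_identical(selectedVariables(m)[1], "X1")

  # alpha = 1 admits every candidate; alpha ~ 0 admits none
  mAll <- forwardStepwiseLogistic(dat, paste0("X", 1:5), alpha = 1)
  expect_setequal(selectedVariables(mAll), paste0("X", 1:5))
  mNone <- forwardStepwiseLogistic(dat, paste0("X", 1:5), alpha = 1e-300)
  expect_identical(selectedVariables(mNone), character(0))
  expect_equal(unname(coef(mNone)["(Intercept)"]), qlogis(mean(y)),
               tolerance = 1e-6)
})

test_that("stepwise false entries on null cohorts stay below the empirical bound", {
  entries <- 0L
  reps <- 200
  for (s in seq_len(reps)) {
    set.seed(11 + s)
    n <- 1000
    X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("N", 1:5)))
    y <- rbinom(n, 1, 0.3)
    m <- forwardStepwiseLogistic(data.frame(fracture = y, X), paste0("N", 1:5))
    if (length(selectedVariables(m)) > 0L) entries <- entries + 1L
  }
  expect_lte(entries / reps, 0.25)
})

test_that("perfectly separating candidates are excluded with a warning", {
  set.seed(37)
  n <- 80
  y <- rbinom(n, 1, 0.5)
  sepvar <- y * 2 - 1 # perfectly separates
  noise <- rnorm(n)
  dat <- data.frame(fracture = y, sep = sepvar, noise = noise)
  expect_warning(m <- forwardStepwiseLogistic(dat, c("sep", "noise")),
                 "separation")
  expect_true("sep" %in% m@excluded)
  expect_false("sep" %in% selectedVariables(m))
})
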