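test_that("PNG round-trips are bit-exact for 8-bit gray images", {
  set.seed(42)
  m <- matrix(sample(0:255, 60 * 80, replace = TRUE), 60, 80)
  f <- withr::local_tempfile(fileext = ".png")
  writeGrayImage(GrayImage(m), f)
  img <- loadGrayImage(f)
  expect_identical(dim(img), c(60L, 80L))
  expect_equal(as.matrix(img), m, ignore_attr = TRUE)

  # constant image is a valid degenerate input
  f2 <- withr::local_tempfile(fileext = ".png")
  writeGrayImage(GrayImage(matrix(100, 10, 10)), f2)
  expect_true(all(as.matrix(loadGrayImage(f2)) == 100))
})

test_that("16-bit TIFF is scaled by full dynamic range and RGB collapses by channel mean", {
  f <- withr::local_tempfile(fileext = ".tif")
  m <- matrix(c(0, 1, 1, 0), 2, 2) # writeTIFF scales [0,1] to 0/65535
  tiff::writeTIFF(m, f, bits.per.sample = 16)
  img <- loadGrayImage(f)
  expect_setequal(as.vector(as.matrix(img)), c(0, 255))

  fp <- withr::local_tempfile(fileext = ".png")
  arr <- array(0, c(4, 4, 3))
  arr[, , 1] <- 30 / 255; arr[, , 2] <- 60 / 255; arr[, , 3] <- 90 / 255
  png::writePNG(arr, fp)
  expect_equal(as.vector(as.matrix(loadGrayImage(fp))), rep(60, 16),
               tolerance = 1e-6)
})

test_that("unreadable or unsupported files raise input errors", {
  expect_error(loadGrayImage("does/not/exist.png"), "not found")
  f <- withr::local_tempfile(fileext = ".png")
  writeLines("not a png", f)
  expect_error(loadGrayImage(f), "unreadable")
  f2 <- withr::local_tempfile(fileext = ".bmp")
  writeLines("x", f2)
  expect_error(loadGrayImage(f2), "unsupported")
})

test_that("extractROI crops the documented window and leaves the source intact", {
  set.seed(7)
  m <- matrix(runif(200 * 300, 0, 255), 200, 300)
  img <- GrayImage(m)
  roi <- extractROI(img, 100, 150, side = 50)
  # even side: rows centerRow-25 ... centerRow+24
  expect_equal(as.matrix(roi), m[75:124, 125:174], ignore_attr = TRUE)
  expect_equal(as.matrix(img), m, ignore_attr = TRUE)
  expect_identical(pixelSpacing(roi), pixelSpacing(img))

  # exact-size image: crop equals the whole image, and cropping is idempotent
  sq <- GrayImage(m[1:50, 1:50])
  whole <- extractROI(sq, 26, 26, side = 50)
  expect_equal(as.matrix(whole), m[1:50, 1:50], ignore_attr = TRUE)
  again <- extractROI(GrayImage(as.matrix(whole)), 26, 26, side = 50)
  expect_identical(as.matrix(again), as.matrix(whole))
})

test_that("out-of-bounds windows name the violated edge", {
  img <- GrayImage(matrix(0, 700, 700))
  expect_error(extractROI(img, 10, 350), "top")
  expect_error(extractROI(img, 695, 350), "bottom")
  expect_error(extractROI(img, 350, 10), "left")
  expect_error(extractROI(img, 350, 695), "right")
})

test_that("readCohort types records, is case-insensitive, and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,score,age,weight,height,bmi,fracture",
               "a,dense,54,60,160,23.4,0",
               "b,Alternating,55,65,165,23.9,1",
               "c,SPARSE,56,70,170,24.2,1"), f)
  df <- readCohort(f)
  expect_identical(df$score_ord, c(0L, 1L, 2L))
  expect_identical(levels(df$score), c("dense", "alternating", "sparse"))
  expect_identical(df$fracture, c(0L, 1L, 1L))

  writeLines(c("id,score,age,weight,height,bmi,fracture",
               "a,dense,54,60,160,23.4,0",
               "b,medium,55,65,165,23.9,1"), f)
  expect_error(readCohort(f), "row\\(s\\) 2.*medium")

  writeLines(c("id,score,age,weight,height,bmi,fracture",
               "a,dense,54,60,160,23.4,0",
               "a,sparse,55,65,165,23.9,1"), f)
  expect_error(readCohort(f), "duplicate id")

  writeLines(c("id,score,age,weight,height,bmi,fracture",
               "a,dense,,60,160,23.4,0"), f)
  expect_warning(df2 <- readCohort(f), "missing clinical")
  expect_true(is.na(df2$age[1]))
})

test_that("feature tables have the fixed schema and round-trip to 1e-9", {
  tex <- generateTexture(textureParams(side = 120, seed = 5, coarseness = 4))
  fv <- extractFeatureVector(tex$roi)
  f <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(list(alpha = fv), f)
  df <- readFeatureTable(f)
  expect_identical(nrow(df), 1L)
  expect_identical(names(df), c("id", featureNames()))
  expect_equal(unlist(df[1, featureNames()]), featureValues(fv),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(writeFeatureTable(list(), f), "empty record list")
})
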