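test_that("segment labeling respects the 8/4 connectivity duality and matches flood fill", {
  sq <- toyShapes("square", side = 40, size = 10)
  expect_identical(labelSegments(sq, "white")$nSegments, 1L)
  expect_identical(labelSegments(sq, "black")$nSegments, 1L)

  # two diagonally touching white pixels: one white segment (8-connectivity),
  # but the same pixels as black phase in a white field split in two (4-conn)
  m <- matrix(FALSE, 10, 10); m[4, 4] <- TRUE; m[5, 5] <- TRUE
  expect_identical(labelSegments(BinaryROI(m, 1), "white")$nSegments, 1L)
  expect_identical(labelSegments(BinaryROI(!m, 1), "black")$nSegments, 2L)

  for (s in 1:6) {
    blobs <- randomBlobs(48, seed = s)
    bin <- BinaryROI(blobs, 1)
    for (ph in c("white", "black")) {
      mask <- if (ph == "white") blobs else !blobs
      conn <- if (ph == "white") 8 else 4
      got <- labelSegments(bin, ph)
      ref <- oracleLabels(mask, conn)
      expect_identical(got$nSegments, max(ref))
      # same partition (labels may be permuted): compare canonical form
      expect_identical(as.vector(table(got$labels[mask])),
                       as.vector(table(ref[mask])))
      # pixels share a label iff the oracle agrees, via label-of-label map
      expect_true(all(tapply(ref[mask], got$labels[mask],
                             function(v) length(unique(v)) == 1L)))
    }
  }
})

test_that("morphometry is exact on analytic shapes", {
  sq <- toyShapes("square", side = 60, size = 10, pixelSpacing = 1)
  mw <- phaseMorphometry(sq, "white")
  expect_identical(mw$segment_count, 1L)
  expect_equal(mw$mean_area, 100)      # mm^2 at 1 mm/px
  expect_equal(mw$mean_perimeter, 40)  # 4 x 10 exposed edges

  band <- toyShapes("band", side = 80, size = 10, pixelSpacing = 1)
  mb <- phaseMorphometry(band, "white")
  expect_equal(mb$mean_width, 10, tolerance = 1e-9)

  # mean area over K disjoint identical squares does not depend on K
  m1 <- matrix(FALSE, 60, 60); m1[5:14, 5:14] <- TRUE
  m3 <- m1; m3[5:14, 25:34] <- TRUE; m3[30:39, 40:49] <- TRUE
  a1 <- phaseMorphometry(BinaryROI(m1, 1), "white")$mean_area
  a3 <- phaseMorphometry(BinaryROI(m3, 1), "white")$mean_area
  expect_equal(a1, a3)

  # number density: 1 segment in a 60 x 60 mm ROI = 36 cm^2
  expect_equal(mw$number_density, 1 / 36, tolerance = 1e-12)
})

test_that("morphometry matches flood-fill / edge-count / distance oracles on random blobs", {
  for (s in 1:20) {
    blobs <- randomBlobs(48, seed = 100 + s)
    bin <- BinaryROI(blobs, 1)
    got <- phaseMorphometry(bin, "white")
    ref <- oracleLabels(blobs, 8)
    ap <- oracleAreaPerim(ref)
    expect_identical(got$segment_count, max(ref))
    expect_equal(got$mean_area, mean(ap$area), tolerance = 1e-9)
    expect_equal(got$mean_perimeter, mean(ap$perim), tolerance = 1e-9)
    expect_equal(got$number_density, max(ref) / (48 * 48 * 0.01),
                 tolerance = 1e-9)
    # width: 2 x mean oracle distance over each segment's skeleton pixels
    if (sum(!blobs) > 0) {
      dref <- oracleDistmap(blobs)
      skel <- skeletonizePhase(bin, "white")
      labs <- labelSegments(bin, "white")$labels
      wid <- tapply(dref[skel], labs[skel], mean) * 2
      expect_equal(got$mean_width, mean(wid), tolerance = 1e-9)
    }
    # conservation: white + black pixel counts fill the grid
    expect_identical(sum(blobs) + sum(!blobs), 48L * 48L)
  }
})

test_that("the LFD profile is zero on uniform images and peaks across stripes", {
  allw <- BinaryROI(matrix(TRUE, 100, 100), 1)
  expect_identical(unname(lfdProfile(allw)), rep(0, 12))
  allb <- BinaryROI(matrix(FALSE, 100, 100), 1)
  expect_identical(unname(lfdProfile(allb)), rep(0, 12))

  stripes <- toyShapes("stripes", side = 140, size = 20)
  p <- lfdProfile(stripes)
  expect_identical(dominantOrientation(p), 90L)
  expect_lt(p["0"], 0.05)
  expect_true(all(p >= 0))
})

test_that("the LFD profile is invariant under 180-degree rotation and shifts under 90-degree rotation", {
  for (s in 1:20) {
    tex <- generateTexture(textureParams(side = 200, seed = 400 + s,
                                         orientation = (s * 37) %% 180,
                                         anisotropy = 1 + s %% 4,
                                         coarseness = 4 + s %% 5))
    ph <- as.matrix(tex$truth)
    p0 <- lfdProfile(BinaryROI(ph, 1))
    p180 <- lfdProfile(BinaryROI(rot180(ph), 1))
    expect_lt(max(abs(p0 - p180)), 1e-3)
    # rotating the image by 90 degrees cycles the angle index by 6 positions
    p90 <- lfdProfile(BinaryROI(rot90cw(ph), 1))
    shifted <- p0[c(7:12, 1:6)]
    expect_lt(max(abs(p90 - shifted)), 0.02)
  }
})

test_that("dominant orientation handles ties and undefined profiles and recovers generator truth", {
  p <- setNames(rep(0.1, 12), seq(0, 165, 15)); p["60"] <- 0.5
  expect_identical(dominantOrientation(p), 60L)

  flat <- setNames(rep(0.2, 12), seq(0, 165, 15))
  d <- dominantOrientation(flat)
  expect_identical(as.integer(d), 0L)
  expect_true(isTRUE(attr(d, "tie")))

  expect_true(is.na(dominantOrientation(setNames(rep(0, 12), seq(0, 165, 15)))))

  tex <- generateTexture(textureParams(side = 256, orientation = 60,
                                       anisotropy = 4, seed = 21))
  expect_identical(dominantOrientation(lfdProfile(tex$truth)), 60L)
})

test_that("skeletonization thins bars to one-pixel lines and preserves topology", {
  bar <- matrix(FALSE, 30, 30); bar[14:16, 5:25] <- TRUE
  sk <- skeletonizePhase(BinaryROI(bar, 1), "white")
  expect_true(all(colSums(sk[, 6:24]) == 1)) # 1 px wide along the bar
  expect_identical(max(oracleLabels(sk, 8)), 1L)

  # solid disk: skeleton stays a single component
  rr <- outer(1:41, rep(1, 41)); cc <- t(rr)
  disk <- (rr - 21)^2 + (cc - 21)^2 <= 15^2
  skd <- skeletonizePhase(BinaryROI(disk, 1), "white")
  expect_identical(max(oracleLabels(skd, 8)), 1L)

  for (s in 1:8) {
    blobs <- randomBlobs(40, seed = 200 + s)
    skb <- skeletonizePhase(BinaryROI(blobs, 1), "white")
    expect_identical(max(oracleLabels(skb, 8)), max(oracleLabels(blobs, 8)))
  }
})

test_that("strut statistics are exact on hand-countable shapes", {
  # plus sign under the 8-neighborhood degree rule: the center has four
  # skeleton neighbors and each pixel orthogonally adjacent to it sees the
  # center, the next arm pixel and two diagonal arm pixels, so the junction
  # is a cluster of five node pixels; the struts are the four outer arms
  # (3 steps each), the four center spokes (1 step) and the four diagonals
  # (sqrt(2)) between adjacent arm pixels
  plus <- toyShapes("plus", side = 21, size = 9, pixelSpacing = 1)
  s <- strutStatistics(as.matrix(plus), pixelSpacing = 1)
  expect_identical(s$node_count, 5L)
  expect_identical(s$endpoint_count, 4L)
  expect_identical(s$strut_count, 12L)
  expect_equal(s$mean_strut_length, (4 * 3 + 4 * 1 + 4 * sqrt(2)) / 12)

  line <- toyShapes("line", side = 40, size = 20, pixelSpacing = 1)
  s2 <- strutStatistics(as.matrix(line), pixelSpacing = 1)
  expect_identical(s2$node_count, 0L)
  expect_identical(s2$endpoint_count, 2L)
  expect_identical(s2$strut_count, 1L)
  expect_equal(s2$mean_strut_length, 19) # 20 pixels = 19 unit steps

  empty <- strutStatistics(matrix(FALSE, 10, 10), pixelSpacing = 1)
  expect_identical(empty$node_count, 0L)
  expect_identical(empty$endpoint_count, 0L)
  expect_equal(empty$mean_strut_length, 0)
})

test_that("node and endpoint counts equal a brute-force neighbor census on random skeletons", {
  for (s in 1:20) {
    blobs <- randomBlobs(60, nBlobs = 8, seed = 300 + s)
    skel <- skeletonizePhase(BinaryROI(blobs, 1), "white")
    got <- strutStatistics(skel, pixelSpacing = 1)
    ref <- oracleSkeletonCensus(skel)
    expect_identical(got$node_count, ref$nodes)
    expect_identical(got$endpoint_count, ref$endpoints)
  }
})

test_that("the full feature chain handles degenerate input and separates dense from sparse", {
  const <- GrayROI(matrix(120, 150, 150), 1)
  fv <- extractFeatureVector(const)
  v <- featureValues(fv)
  expect_equal(unname(v["brightness"]), 120)
  expect_equal(unname(v["contrast"]), 0)
  expect_equal(unname(v["white_segment_count"]), 1) # all-zero residual -> all white
  expect_equal(unname(v["black_segment_count"]), 0)
  expect_true(all(lfdValues(fv) == 0))

  dense <- generateReferencePattern("dense", seed = 31, side = 300)
  sparse <- generateReferencePattern("sparse", seed = 31, side = 300)
  fd <- phaseMorphometry(dense$truth, "white")
  fs <- phaseMorphometry(sparse$truth, "white")
  bd <- phaseMorphometry(dense$truth, "black")
  bs <- phaseMorphometry(sparse$truth, "black")
  expect_gt(fd$number_density, fs$number_density)
  expect_lt(bd$mean_area, bs$mean_area)

  tex <- generateTexture(textureParams(side = 150, seed = 8))
  f1 <- extractFeatureVector(tex$roi)
  f2 <- extractFeatureVector(tex$roi)
  expect_identical(featureValues(f1), featureValues(f2))
})
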