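intr1000 <- CameraIntrinsics(fw = 1000, fh = 1000, cx = 0, cy = 0)

test_that("extractDepth takes the median of valid counts in the central sub-box", {
  intr <- CameraIntrinsics()
  expect_equal(extractDepth(matrix(1000, 40, 40),
                            boundingBoxes(20, 20, 10, 10), intr), 1000)
  # central 50% sub-box of a 2x2 box at (5.5, 5.5) is exactly rows/cols 5:6
  m <- matrix(0, 10, 10)
  m[5:6, 5:6] <- c(0, 800, 0, 1200)
  expect_equal(extractDepth(m, boundingBoxes(5.5, 5.5, 2, 2), intr), 1000)
  # zeros are invalid everywhere
  expect_true(is.na(extractDepth(matrix(0, 10, 10),
                                 boundingBoxes(5, 5, 4, 4), intr)))
  # depth scale multiplies counts
  intr2 <- CameraIntrinsics(depthScale = 2.5)
  expect_equal(extractDepth(matrix(100, 10, 10),
                            boundingBoxes(5, 5, 4, 4), intr2), 250)
})

test_that("pixelToMetric applies pinhole similar triangles", {
  wh <- pixelToMetric(boundingBoxes(0, 0, 100, 120), 1000, intr1000)
  expect_equal(unname(wh), c(100, 120))
  # z = fw makes pixels numerically equal millimetres
  expect_equal(pixelToMetric(boundingBoxes(0, 0, 37, 37), 1000,
                             intr1000)[["wreal"]], 37)
  # degenerate box: metric width vanishes with pixel width
  expect_equal(pixelToMetric(boundingBoxes(0, 0, 1e-9, 1e-9), 1000,
                             intr1000)[["wreal"]], 1e-9)
  expect_error(pixelToMetric(boundingBoxes(0, 0, 10, 10), 0, intr1000),
               "invalid depth")
  expect_error(pixelToMetric(boundingBoxes(0, 0, 10, 10), -5, intr1000),
               "invalid depth")
})

test_that("estimateDiameter mean and literal modes behave as documented", {
  expect_equal(estimateDiameter(60, 60), 60)
  expect_equal(estimateDiameter(50, 70), 60)
  # literal mode re-multiplies by z/(fw+fh)
  expect_equal(estimateDiameter(50, 50, z = 500, intr = intr1000,
                                mode = "literal"), 25)
  expect_equal(estimateDiameter(50, 50, mode = "mean"), 50)
  # the two modes agree exactly when z = (fw + fh)/2 and disagree otherwise
  expect_equal(estimateDiameter(40, 60, z = 1000, intr = intr1000,
                                mode = "literal"),
               estimateDiameter(40, 60, mode = "mean"))
  expect_false(isTRUE(all.equal(
    estimateDiameter(40, 60, z = 900, intr = intr1000, mode = "literal"),
    estimateDiameter(40, 60, mode = "mean"))))
})

test_that("backprojectCenter inverts the pinhole projection", {
  intr <- CameraIntrinsics(fw = 700, fh = 700, cx = 320, cy = 240)
  expect_equal(unname(backprojectCenter(boundingBoxes(320, 240, 10, 10),
                                        1234, intr)), c(0, 0, 1234))
  intrU <- CameraIntrinsics(fw = 500, fh = 500, cx = 100, cy = 100)
  ctr <- backprojectCenter(boundingBoxes(100 + 500, 100, 10, 10), 1000, intrU)
  expect_equal(ctr[["X"]], 1000)
  # homogeneity: doubling z doubles X and Y
  c1 <- backprojectCenter(boundingBoxes(400, 300, 10, 10), 1000, intr)
  c2 <- backprojectCenter(boundingBoxes(400, 300, 10, 10), 2000, intr)
  expect_equal(2 * c1[["X"]], c2[["X"]])
  expect_equal(2 * c1[["Y"]], c2[["Y"]])
  expect_error(backprojectCenter(boundingBoxes(1, 1, 1, 1), 0, intr))
})

test_that("sphereVolume and ellipticity correction match closed forms", {
  expect_equal(sphereVolume(0), 0)
  expect_equal(sphereVolume(20), 4188.79, tolerance = 0.01 / 4188.79)
  expect_equal(sphereVolume(60), 113097.34, tolerance = 0.01 / 113097.34)
  expect_error(sphereVolume(-1), "non-negative")
  expect_equal(applyEllipticity(1234.5, 0.9), 1111.05)
  expect_equal(applyEllipticity(4188.79, 0.9), 3769.91,
               tolerance = 0.01 / 3769.91)
  expect_warning(v <- applyEllipticity(100, 0.5), "0.85-0.95")
  expect_equal(v, 50)
  expect_error(applyEllipticity(100, 0), "k must be > 0")
})

test_that("a projected sphere round-trips to its true diameter", {
  set.seed(11)
  for (i in 1:200) {
    D <- runif(1, 10, 120)
    z <- runif(1, 400, 4000)
    intr <- CameraIntrinsics(fw = runif(1, 300, 2000),
                             fh = runif(1, 300, 2000),
                             cx = 320, cy = 240)
    bx <- boundingBoxes(320, 240, D * intr@fw / z, D * intr@fh / z)
    wh <- pixelToMetric(bx, z, intr)
    expect_equal(estimateDiameter(wh[["wreal"]], wh[["hreal"]]), D,
                 tolerance = 1e-12)
  }
})

test_that("metric width grows with pixel width and depth; volume with diameter", {
  intr <- CameraIntrinsics(fw = 700, fh = 700)
  w <- sapply(c(10, 20, 40, 80), function(wp)
    pixelToMetric(boundingBoxes(0, 0, wp, 10), 1000, intr)[["wreal"]])
  expect_true(all(diff(w) > 0))
  wz <- sapply(c(500, 1000, 2000), function(z)
    pixelToMetric(boundingBoxes(0, 0, 30, 10), z, intr)[["wreal"]])
  expect_true(all(diff(wz) > 0))
  expect_true(all(diff(sphereVolume(c(10, 30, 50, 90))) > 0))
})

test_that("measureFruits flags boxes without valid depth instead of failing", {
  intr <- CameraIntrinsics()
  depth <- matrix(0, 50, 50)
  depth[1:25, ] <- 1500
  boxes <- boundingBoxes(c(25, 25), c(10, 40), c(10, 10), c(10, 10))
  m <- measureFruits(boxes, depth, intr)
  expect_true(m$valid[1])
  expect_false(m$valid[2])
  expect_true(is.na(m$dreal[2]))
  expect_equal(m$z[1], 1500)
  expect_equal(m$volume[1], 0.9 * m$volume_raw[1])
})
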