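prof <- cultivarProfile()

test_that("dominantHue finds the modal 1-degree hue bin", {
  expect_equal(dominantHue(patchHSV(10)), 10)
  # 70/30 mixture keeps the majority hue
  arr <- patchHSV(10, nr = 20, nc = 20)
  minority <- patchHSV(90, nr = 20, nc = 20)
  pick <- matrix(FALSE, 20, 20); pick[1:6, ] <- TRUE  # 30% of pixels
  for (ch in 1:3) {
    pl <- arr[, , ch]; pl[pick] <- minority[, , ch][pick]
    arr[, , ch] <- pl
  }
  expect_equal(dominantHue(arr, mask = matrix(TRUE, 20, 20)), 10)
  # fully desaturated region has no qualifying pixel
  expect_true(is.na(dominantHue(patchHSV(10, s = 0.05))))
  # dark region fails the value cutoff
  expect_true(is.na(dominantHue(patchHSV(10, v = 0.1))))
})

test_that("colorScore reproduces the piecewise hue model", {
  expect_equal(as.numeric(colorScore(10, prof)), 1.0)
  expect_equal(as.numeric(colorScore(340, prof)), 1.0)
  expect_equal(as.numeric(colorScore(30, prof)), 0.65)   # 0.5 + 0.015*10
  expect_equal(as.numeric(colorScore(75, prof)), 0.45)   # 0.2 + 0.01*25
  s45 <- colorScore(45, prof)
  expect_equal(as.numeric(s45), 0)
  expect_true(attr(s45, "fallback"))
  expect_false(any(attr(colorScore(c(10, 30, 75), prof), "fallback")))
  expect_error(colorScore(361, prof), "0, 360")
  expect_error(colorScore(-1, prof), "0, 360")
  # branch 2 decreasing in H, branch 3 increasing in H
  h2 <- seq(20, 39.9, by = 0.5)
  expect_true(all(diff(as.numeric(colorScore(h2, prof))) < 0))
  h3 <- seq(50, 99.9, by = 0.5)
  expect_true(all(diff(as.numeric(colorScore(h3, prof))) > 0))
})

test_that("sizeScore reproduces the piecewise diameter model", {
  expect_equal(sizeScore(25, prof), 0.15)    # 0.3 * 25/50
  expect_equal(sizeScore(60, prof), 0.65)    # 0.3 + 0.7 * 10/20
  expect_equal(sizeScore(77.5, prof), 0.90)  # 1 - 0.2 * 7.5/15
  expect_error(sizeScore(-1, prof), "non-negative")
  expect_error(cultivarProfile(dUnripe = 70, dRipe = 70, dOverripe = 85))
  expect_error(cultivarProfile(dRipe = 70, dOverripe = 70))
})

test_that("sizeScore is continuous at both thresholds for random profiles", {
  set.seed(4)
  for (i in 1:25) {
    dU <- runif(1, 20, 60); dR <- dU + runif(1, 5, 40)
    dO <- dR + runif(1, 5, 40)
    p <- cultivarProfile(dUnripe = dU, dRipe = dR, dOverripe = dO)
    eps <- 1e-9
    expect_equal(sizeScore(dU - eps, p), sizeScore(dU, p), tolerance = 1e-6)
    expect_equal(sizeScore(dR + eps, p), sizeScore(dR, p), tolerance = 1e-6)
    # non-decreasing up to dRipe, non-increasing beyond
    gl <- sizeScore(seq(0, dR, length.out = 60), p)
    expect_true(all(diff(gl) >= -1e-12))
    gr <- sizeScore(seq(dR, dO * 3, length.out = 60), p)
    expect_true(all(diff(gr) <= 1e-12))
  }
})

test_that("aspectRatio and shapeScore follow the deviation model", {
  expect_equal(aspectRatio(60, 60), 1.0)
  expect_equal(aspectRatio(70, 50), 1.4)
  expect_equal(aspectRatio(50, 70), 0.714, tolerance = 0.001 / 0.714)
  expect_error(aspectRatio(50, 0), "hreal")
  expect_equal(shapeScore(1.0, prof), 1.0)
  expect_equal(shapeScore(1.2, prof), 0.96)
  expect_equal(shapeScore(1.5, prof), 0.64)
  expect_equal(shapeScore(2.0, prof), 0.28)
  expect_error(shapeScore(0, prof))
  # only |r - 1| matters: equal deviations on both sides score equally
  for (d in c(0.1, 0.25, 0.45, 0.8))
    expect_equal(shapeScore(1 + d, prof), shapeScore(1 - d, prof),
                 info = paste("deviation", d))
})

test_that("contourCircularity separates discs from elongated shapes", {
  n <- 121
  disc <- outer(1:n, 1:n, function(i, j) (i - 61)^2 + (j - 61)^2 <= 50^2)
  expect_gte(contourCircularity(disc), 0.9)
  rect <- matrix(FALSE, 120, 30); rect[11:110, 11:20] <- TRUE
  expect_equal(contourCircularity(rect), 0.26, tolerance = 0.05 / 0.26)
  expect_true(is.na(contourCircularity(matrix(FALSE, 10, 10))))
})

test_that("fuseScores is the convex combination of component scores", {
  expect_equal(fuseScores(1, 1, 1, prof), 1.0)
  expect_equal(fuseScores(0, 0, 0, prof), 0.0)
  expect_equal(fuseScores(0.65, 0.65, 0.96, prof), 0.712)
  expect_error(fuseScores(1.2, 0.5, 0.5, prof), "0, 1")
  # weights not summing to one are rejected at profile construction
  expect_error(cultivarProfile(wc = 0.5, wd = 0.5, ws = 0.2), "sum to 1")
})

test_that("classifyRipeness partitions [0,1] with the stated boundaries", {
  expect_equal(classifyRipeness(0.39), "immature")
  expect_equal(classifyRipeness(0.40), "ripe")
  expect_equal(classifyRipeness(0.70), "ripe")
  expect_equal(classifyRipeness(0.71), "overripe")
  expect_error(classifyRipeness(0.5, lo = 0.7, hi = 0.4), "lo < hi")
  # every score on a fine grid receives exactly one valid label
  grid <- seq(0, 1, by = 0.001)
  lab <- classifyRipeness(grid)
  expect_true(all(lab %in% c("immature", "ripe", "overripe")))
  expect_equal(lab, ifelse(grid < 0.4, "immature",
                           ifelse(grid <= 0.7, "ripe", "overripe")))
})

test_that("all scores stay in [0,1] over random valid inputs", {
  set.seed(9)
  H <- runif(500, 0, 360)
  d <- runif(500, 0, 200)
  r <- runif(500, 0.05, 5)
  sc <- as.numeric(colorScore(H, prof))
  ss <- sizeScore(d, prof)
  ssh <- shapeScore(r, prof)
  fused <- fuseScores(sc, ss, ssh, prof)
  for (v in list(sc, ss, ssh, fused)) {
    expect_true(all(v >= 0))
    expect_true(all(v <= 1))
  }
})
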