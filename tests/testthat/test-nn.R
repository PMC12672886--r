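test_that("elsaClamp restricts the negative-branch slope to [0.01, 0.99]", {
  expect_equal(elsaClamp(0.5), 0.5)
  expect_equal(elsaClamp(5), 0.99)
  expect_equal(elsaClamp(-3), 0.01)
  expect_error(elsaClamp(NaN), "finite")
})

test_that("elsaAttention weights depend only on the sign of the input", {
  expect_equal(elsaAttention(-1, alpha = 0.5, beta = 0), 0.5)
  expect_equal(elsaAttention(2, alpha = 0.5, beta = 0), 0.5)
  expect_equal(elsaAttention(0, alpha = 0.2, beta = 0), 0.5)  # v >= 0 branch
  expect_equal(elsaAttention(-7, alpha = 5, beta = 3), 0.99)
})

test_that("arelu shrinks negatives and amplifies non-negatives", {
  expect_equal(arelu(0, 0.5, 0), 0)
  expect_equal(arelu(2, 0.5, 0), 3)            # (1 + 0.5) * 2
  expect_equal(arelu(-1, 5, 0), -0.99)         # clamp then product
  # positive homogeneity on each half-line
  set.seed(3)
  x <- runif(50, -10, 10); t <- runif(50, 0.1, 8)
  expect_equal(arelu(t * x, 0.3, 1.2), t * arelu(x, 0.3, 1.2))
  # |output| <= |input| for negatives, >= for non-negatives
  xn <- -runif(100, 0, 5); xp <- runif(100, 0, 5)
  expect_true(all(abs(arelu(xn, 2, -1)) <= abs(xn)))
  expect_true(all(arelu(xp, 2, -1) >= xp))
  # array shapes are preserved
  a <- array(rnorm(24), c(2, 3, 4))
  expect_equal(dim(arelu(a, 0.5, 0)), c(2, 3, 4))
})

test_that("analytic AReLU partials match central finite differences", {
  expect_equal(areluGradients(2, 0.5, 0)$dbeta, 0.5)  # 2 * 0.25
  expect_equal(areluGradients(-1, 5, 0)$dalpha, 0)    # clamp saturated
  set.seed(17)
  h <- 1e-5
  x <- runif(1000, -10, 10)
  x <- x[abs(x) > 1e-3]
  alpha <- runif(1, 0.05, 0.95)
  beta <- runif(1, -2, 2)
  g <- areluGradients(x, alpha, beta)
  fdx <- (arelu(x + h, alpha, beta) - arelu(x - h, alpha, beta)) / (2 * h)
  fda <- (arelu(x, alpha + h, beta) - arelu(x, alpha - h, beta)) / (2 * h)
  fdb <- (arelu(x, alpha, beta + h) - arelu(x, alpha, beta - h)) / (2 * h)
  # x = 0 aside (excluded) the branch never changes inside the stencil
  ok <- abs(x) > h
  relerr <- function(a, b) abs(a - b) / pmax(1e-8, abs(b))
  expect_lt(max(relerr(g$dx[ok], fdx[ok])), 1e-5)
  expect_lt(max(relerr(g$dalpha[ok], fda[ok])), 1e-5)
  expect_lt(max(relerr(g$dbeta[ok], fdb[ok])), 1e-5)
})

test_that("gradient descent recovers AReLU slopes from activation pairs", {
  set.seed(8)
  x <- runif(400, -4, 4)
  y <- arelu(x, alpha = 0.3, beta = 0.8)
  fit <- fitArelu(x, y, alpha0 = 0.6, beta0 = -0.5)
  expect_equal(fit$alpha, 0.3, tolerance = 0.02)
  expect_equal(fit$beta, 0.8, tolerance = 0.05)
  expect_lt(fit$mse, 1e-4)
})

test_that("boxIoU matches hand-computed overlaps", {
  expect_equal(boxIoU(box(0, 0, 2, 2), box(0, 0, 2, 2)), 1)
  expect_equal(boxIoU(box(0, 0, 2, 2), box(10, 10, 2, 2)), 0)
  expect_equal(boxIoU(box(0, 0, 2, 2), box(1, 0, 2, 2)), 1 / 3)
  expect_error(box(0, 0, -1, 2), "extents")
})

test_that("eiouLoss matches hand computation and its invariances", {
  expect_equal(eiouLoss(box(3, -2, 4, 5), box(3, -2, 4, 5)), 0)
  # worked pair: wc = 3, hc = 2 -> 2/3 + 1/13
  expect_equal(eiouLoss(box(0, 0, 2, 2), box(1, 0, 2, 2)),
               2 / 3 + 1 / 13, tolerance = 1e-4 / 0.7436)
  set.seed(12)
  for (i in 1:30) {
    p <- box(runif(1, -5, 5), runif(1, -5, 5), runif(1, 0.5, 5), runif(1, 0.5, 5))
    g <- box(runif(1, -5, 5), runif(1, -5, 5), runif(1, 0.5, 5), runif(1, 0.5, 5))
    L <- eiouLoss(p, g)
    expect_gte(L, 0)
    # joint translation invariance
    tr <- runif(2, -10, 10)
    pt <- box(p[["cx"]] + tr[1], p[["cy"]] + tr[2], p[["w"]], p[["h"]])
    gt <- box(g[["cx"]] + tr[1], g[["cy"]] + tr[2], g[["w"]], g[["h"]])
    expect_equal(eiouLoss(pt, gt), L)
    # joint uniform scale invariance
    s <- runif(1, 0.2, 5)
    ps <- box(s * p[["cx"]], s * p[["cy"]], s * p[["w"]], s * p[["h"]])
    gs <- box(s * g[["cx"]], s * g[["cy"]], s * g[["w"]], s * g[["h"]])
    expect_equal(eiouLoss(ps, gs), L)
  }
  # zero loss only for identical boxes
  expect_gt(eiouLoss(box(0, 0, 2, 2), box(0, 0, 2, 2.0001)), 0)
})

test_that("focalEiouLoss reweights by IoU^gamma", {
  p <- box(0, 0, 2, 2); g <- box(1, 0, 2, 2)
  expect_equal(focalEiouLoss(p, g, gamma = 0), eiouLoss(p, g))
  expect_equal(focalEiouLoss(p, g, gamma = 0.5),
               sqrt(1 / 3) * (2 / 3 + 1 / 13), tolerance = 1e-4 / 0.4293)
  expect_equal(focalEiouLoss(box(0, 0, 2, 2), box(10, 10, 2, 2), 0.5), 0)
  expect_error(focalEiouLoss(p, g, gamma = -1), "gamma")
  # the focal weight grows with IoU: slide the prediction toward the truth
  # (stopping short of coincidence, where the EIoU denominator vanishes)
  shifts <- seq(1.9, 1.1, by = -0.2)
  ious <- sapply(shifts, function(s) boxIoU(box(s, 0, 2, 2), g))
  wts <- sapply(shifts, function(s)
    focalEiouLoss(box(s, 0, 2, 2), g, 0.5) / eiouLoss(box(s, 0, 2, 2), g))
  expect_true(all(diff(ious) > 0))
  expect_true(all(diff(wts) > 0))
})

test_that("ghostFeatures equals the naive convolution oracle", {
  # scalar composition: 1x1 input, kernel 2, ghost kernel 3 -> maps 2x, 6x
  prim <- array(2, c(1, 1, 1, 1))
  cheap <- array(3, c(1, 1, 1, 1))
  sp <- ghostSpec(prim, cheap)
  X <- array(5, c(1, 1, 1))
  Y <- ghostFeatures(X, sp)
  expect_equal(as.numeric(Y), c(10, 30))
  # s = 1 returns the intrinsic maps untouched
  set.seed(6)
  prim2 <- array(rnorm(3 * 3 * 4 * 2), c(3, 3, 4, 2))
  sp1 <- ghostSpec(prim2)
  X2 <- array(rnorm(4 * 8 * 8), c(4, 8, 8))
  expect_equal(ghostFeatures(X2, sp1), naiveConv(X2, prim2),
               tolerance = 1e-10)
  # full composition against the triple-loop oracle
  cheap2 <- array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2))
  sp2 <- ghostSpec(prim2, cheap2)
  expect_equal(max(abs(ghostFeatures(X2, sp2) - naiveGhost(X2, sp2))), 0,
               tolerance = 1e-6)
  expect_error(ghostFeatures(array(0, c(3, 8, 8)), sp2), "channel")
})

test_that("ghost composition needs fewer parameters than dense convolution", {
  set.seed(10)
  for (s in 2:4) {
    m <- sample(2:6, 1)
    C <- sample(2:8, 1)
    prim <- array(rnorm(3 * 3 * C * m), c(3, 3, C, m))
    cheap <- array(rnorm(3 * 3 * m * (s - 1)), c(3, 3, m, s - 1))
    pc <- ghostParamCount(ghostSpec(prim, cheap))
    expect_lt(pc[["ghost"]], pc[["dense"]])
  }
})
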