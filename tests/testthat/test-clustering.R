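test_that("euclid3 is the 3D Euclidean distance and is symmetric", {
  expect_equal(euclid3(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclid3(c(0, 0, 0), c(3, 4, 0)), 5)
  p <- c(1.5, -2, 7); q <- c(-3, 0.5, 2)
  expect_equal(euclid3(p, q), euclid3(q, p))
})

test_that("dbscanLabels handles the elementary reachability cases", {
  expect_equal(dbscanLabels(matrix(c(0, 0, 0), 1), eps = 10), 1L)
  expect_equal(dbscanLabels(matrix(numeric(0), 0, 3), eps = 10), integer(0))
  two <- rbind(c(0, 0, 0), c(0.9 * 50, 0, 0))
  expect_equal(dbscanLabels(two, eps = 50), c(1L, 1L))
  # two 5-point blobs separated by 10*eps form exactly two clusters equal
  # to the eps-graph connected components
  set.seed(2)
  blob <- function(ctr) sweep(matrix(runif(15, -20, 20), 5), 2, ctr, `+`)
  pts <- rbind(blob(c(0, 0, 0)), blob(c(1000, 0, 0)))
  lab <- dbscanLabels(pts, eps = 100)
  expect_equal(length(unique(lab)), 2L)
  expect_equal(canonicalPartition(lab),
               canonicalPartition(epsGraphComponents(pts, 100)))
  expect_error(dbscanLabels(two, eps = 0), "eps")
  expect_error(dbscanLabels(two, eps = 10, minSamples = 0), "minSamples")
})

test_that("with minSamples = 1 labels equal eps-graph connected components", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    pts <- matrix(runif(n * 3, 0, 1000), n)
    eps <- runif(1, 50, 400)
    lab <- dbscanLabels(pts, eps = eps)
    expect_true(all(lab > 0))  # no noise when every point is core
    expect_equal(canonicalPartition(lab),
                 canonicalPartition(epsGraphComponents(pts, eps)))
  }
})

test_that("noise arises only for minSamples > 1 and is reported distinctly", {
  pts <- rbind(c(0, 0, 0), c(10, 0, 0), c(5, 5, 0), c(5000, 0, 0))
  lab <- dbscanLabels(pts, eps = 20, minSamples = 2L)
  expect_equal(lab, c(1L, 1L, 1L, 0L))
  sm <- summarizeClusters(lab, data.frame(id = 1:4, volume = rep(1, 4)))
  expect_equal(attr(sm, "noise"), 4L)
  expect_equal(sm$n_fruits, 3L)
  # same scene with minSamples = 1: the isolated fruit is its own plant
  expect_equal(sort(unique(dbscanLabels(pts, eps = 20))), c(1L, 2L))
})

test_that("cluster partitions are invariant under input reordering", {
  set.seed(33)
  pts <- matrix(runif(90, 0, 800), 30)
  eps <- 150
  base <- dbscanLabels(pts, eps = eps)
  for (i in 1:5) {
    perm <- sample(nrow(pts))
    lab <- dbscanLabels(pts[perm, ], eps = eps)
    # member sets must agree after undoing the permutation
    expect_equal(canonicalPartition(lab[order(perm)]),
                 canonicalPartition(base))
  }
})

test_that("enlarging eps never increases the non-noise cluster count", {
  set.seed(5)
  pts <- matrix(runif(120, 0, 1500), 40)
  ks <- sapply(c(50, 100, 200, 400, 800, 1600), function(e)
    length(setdiff(unique(dbscanLabels(pts, eps = e)), 0L)))
  expect_true(all(diff(ks) <= 0))
})

test_that("summarizeClusters sums member volumes and orders plants", {
  lab <- c(1L, 1L, 1L)
  sm <- summarizeClusters(lab, data.frame(id = 1:3, volume = rep(4189, 3)))
  expect_equal(sm$total_volume, 12567, tolerance = 1 / 12567)
  expect_equal(sm$n_fruits, 3L)
  # all-noise input gives an empty table and a full noise list
  smn <- summarizeClusters(c(0L, 0L), data.frame(id = 1:2, volume = 1:2))
  expect_equal(nrow(smn), 0L)
  expect_equal(attr(smn, "noise"), 1:2)
  sm2 <- summarizeClusters(c(2L, 1L, 2L),
                           data.frame(id = 1:3, volume = c(1, 2, 4)))
  expect_equal(sm2$plant_id, c(1L, 2L))
  expect_equal(sm2$total_volume, c(2, 5))
})

test_that("plantYield scales total volume by the density parameter", {
  expect_equal(plantYield(0, 1e-4), 0)
  expect_equal(plantYield(2 * 4188.79, 2.4e-4), 2.011,
               tolerance = 0.001 / 2.011)
  expect_equal(plantYield(1000, 2 * 3e-4), 2 * plantYield(1000, 3e-4))
  expect_error(plantYield(1000, 0), "omega")
})

test_that("well-separated synthetic blobs are recovered with ARI 1", {
  g <- generateClusterPoints(3, 5, intraSpread = 50, interSpacing = 1000,
                             seed = 7)
  lab <- dbscanLabels(g$points, eps = 300)
  expect_equal(mclust::adjustedRandIndex(lab, g$labels), 1.0)
})
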