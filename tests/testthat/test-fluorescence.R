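test_that("otsuThreshold matches the exhaustive intra-class-variance oracle", {
  # perfectly bimodal: threshold strictly between the two values
  x <- matrix(c(rep(10, 8), rep(200, 8)), 4)
  t <- otsuThreshold(x)
  expect_gt(t, 10)
  expect_lt(t, 200)
  expect_equal(t, 105)
  # 4-pixel image: same partition as exhaustive search
  x4 <- c(0, 0, 100, 100)
  expect_identical(x4 > otsuThreshold(x4), x4 > oracleOtsu(x4))
  # random small integer images: threshold equals the brute-force argmin
  set.seed(101)
  for (i in 1:20) {
    v <- sample(0:40, 60, replace = TRUE,
                prob = runif(41, 0.1, 1)^sample(1:4, 1))
    expect_identical(v > otsuThreshold(v), v > oracleOtsu(v))
    expect_equal(intraClassVariance(v, otsuThreshold(v)),
                 intraClassVariance(v, oracleOtsu(v)), tolerance = 1e-9)
  }
  expect_error(otsuThreshold(matrix(7, 3, 3)), "degenerate histogram")
})

test_that("segmentNuclei finds disjoint bright disks and ignores noise-only images", {
  # 12 disjoint bright disks, noiseless
  blue <- matrix(100, 200, 200)
  centres <- expand.grid(cx = c(30, 80, 130, 180), cy = c(40, 100, 160))
  for (i in seq_len(nrow(centres)))
    blue <- paintDisk(blue, centres$cx[i], centres$cy[i], 6, 3000)
  nuc <- segmentNuclei(blue)
  expect_equal(nObjects(nuc), 12)
  # structureless noise: empty set, not an error
  set.seed(202)
  noise <- matrix(pmax(0, round(rnorm(200 * 200, 100, 10))), 200)
  expect_equal(nObjects(segmentNuclei(noise)), 0)
  # generator ground truth: centroids within 1 px
  g <- generateFov(nCells = 15, trueTransfectedFraction = 0.2,
                   noiseSd = 5, seed = 7)
  nuc2 <- segmentNuclei(g$fov)
  expect_equal(nObjects(nuc2), 15)
  truth <- g$truth@cells
  for (i in seq_len(nObjects(nuc2))) {
    d <- sqrt((truth$x - nuc2@objects$cx[i])^2 +
                (truth$y - nuc2@objects$cy[i])^2)
    expect_lt(min(d), 1)
  }
})

test_that("segmentCellBoundaries yields one nucleus-superset object per cell", {
  g <- generateFov(nCells = 12, trueTransfectedFraction = 1,
                   noiseSd = 5, seed = 9)
  nuc <- segmentNuclei(g$fov)
  cells <- segmentCellBoundaries(g$fov, nuc)
  expect_equal(nObjects(cells), nObjects(nuc))
  for (i in seq_len(nObjects(nuc))) {
    cl <- cells@objects$label[cells@objects$seedLabel == i]
    expect_length(cl, 1)
    expect_true(all(cells@labels[nuc@labels == i] == cl))
    expect_gte(cells@objects$area[cells@objects$label == cl],
               nuc@objects$area[i])
  }
})

test_that("all-zero green degenerates cell boundaries to the nuclei", {
  blue <- matrix(100, 120, 120)
  for (c in c(30, 60, 90)) blue <- paintDisk(blue, c, c, 6, 3000)
  fov <- FieldOfViewImages(blue, blue * 0, blue * 0)
  nuc <- segmentNuclei(fov)
  cells <- segmentCellBoundaries(fov, nuc)
  expect_equal(nObjects(cells), nObjects(nuc))
  expect_identical(cells@labels, nuc@labels)
})

test_that("touching cells are split by nuclei-seeded propagation", {
  blue <- matrix(100, 80, 80)
  green <- matrix(100, 80, 80)
  for (cy in c(30, 48)) {                 # cytoplasm disks overlap
    green <- paintDisk(green, 40, cy, 14, 600)
    blue <- paintDisk(blue, 40, cy, 6, 3000)
  }
  fov <- FieldOfViewImages(blue, green, matrix(100, 80, 80))
  cells <- segmentCellBoundaries(fov)
  expect_equal(nObjects(cells), 2)
})

test_that("positivity criterion is inclusive and monotone in n", {
  # worked boundary cases
  expect_true(classifyPositive(manualObjectSet(10, 5, 1), "green", 3)[[1]])
  expect_false(classifyPositive(manualObjectSet(7.9, 5, 1), "green", 3)[[1]])
  expect_true(classifyPositive(manualObjectSet(5, 5, 1), "green", 0)[[1]])
  # n = 3 positives are a subset of n = 2 positives
  set.seed(33)
  for (i in 1:10) {
    os <- manualObjectSet(rnorm(25, 8, 3), bgMean = 5, bgSd = 1)
    p3 <- classifyPositive(os, "green", 3)
    p2 <- classifyPositive(os, "green", 2)
    expect_true(all(!p3 | p2))
  }
  # empty background is refused
  os0 <- manualObjectSet(10, 5, 1, nPixels = 1)
  expect_error(classifyPositive(os0, "green"), "background")
})

test_that("criterion decisions are invariant under affine intensity rescaling", {
  set.seed(44)
  for (i in 1:10) {
    m <- rnorm(20, 8, 3)
    a <- runif(1, 0.2, 5)
    b <- runif(1, -2, 20)
    p1 <- classifyPositive(manualObjectSet(m, 5, 1), "red", 3)
    p2 <- classifyPositive(manualObjectSet(a * m + b, a * 5 + b, a * 1),
                           "red", 3)
    expect_identical(p1, p2)
  }
  # end to end: rescaling the green channel leaves quantification unchanged
  g <- generateFov(nCells = 20, trueTransfectedFraction = 0.25,
                   trueApoptoticFraction = 0.1, noiseSd = 8, seed = 5)
  q1 <- quantifyFov(g$fov)
  fov2 <- g$fov
  fov2@green <- 2 * fov2@green + 50
  q2 <- quantifyFov(fov2)
  expect_equal(q1@nTransfected, q2@nTransfected)
  expect_equal(q1@nCells, q2@nCells)
})

test_that("quantifyFov recovers ground-truth fractions on synthetic fields of view", {
  # noiseless: exact recovery
  g <- generateFov(nCells = 40, trueTransfectedFraction = 0.05,
                   trueApoptoticFraction = 0.1, noiseSd = 0, seed = 21)
  q <- quantifyFov(g$fov)
  expect_equal(q@nCells, 40)
  expect_equal(q@transfectedFraction, 0.05)
  expect_equal(q@apoptoticFraction, 0.1)
  # all-negative: zero fractions
  g0 <- generateFov(nCells = 20, trueTransfectedFraction = 0,
                    trueApoptoticFraction = 0, noiseSd = 10, seed = 22)
  q0 <- quantifyFov(g0$fov)
  expect_equal(q0@transfectedFraction, 0)
  expect_equal(q0@apoptoticFraction, 0)
  # moderate noise, several seeds: small absolute error
  errs <- vapply(1:8, function(s) {
    gi <- generateFov(nCells = 50, trueTransfectedFraction = 0.06,
                      noiseSd = 10, seed = 100 + s)
    abs(quantifyFov(gi$fov)@transfectedFraction - 0.06)
  }, numeric(1))
  expect_lt(mean(errs), 0.01)
})

test_that("an empty field of view reports missing fractions, not zero", {
  blue <- matrix(100, 50, 50)
  blue[c(120, 800, 2100)] <- 4000    # isolated specks below minObjectArea
  fov <- FieldOfViewImages(blue, matrix(100, 50, 50), matrix(100, 50, 50))
  q <- quantifyFov(fov)
  expect_equal(q@nCells, 0)
  expect_true(is.na(q@transfectedFraction))
  expect_true(is.na(q@apoptoticFraction))
})

test_that("replicateAverage is the unweighted mean of per-FOV fractions", {
  mkq <- function(tf, af = 0, n = 50)
    new("FovQuantification", nCells = n, nTransfected = round(tf * n),
        nApoptotic = round(af * n), transfectedFraction = tf,
        apoptoticFraction = af)
  expect_equal(replicateAverage(list(mkq(0.04), mkq(0.06)))$transfectedFraction,
               0.05)
  expect_equal(replicateAverage(list(mkq(0.07)))$transfectedFraction, 0.07)
  # 25 fields of view vs brute-force mean
  set.seed(55)
  tf <- round(runif(25), 2)
  qs <- lapply(tf, mkq)
  expect_equal(replicateAverage(qs)$transfectedFraction, mean(tf))
  # empty FOVs are excluded, not averaged as zero
  empty <- new("FovQuantification", nCells = 0, nTransfected = 0,
               nApoptotic = 0, transfectedFraction = NA_real_,
               apoptoticFraction = NA_real_)
  expect_equal(replicateAverage(list(mkq(0.1), empty))$nFov, 1)
  expect_error(replicateAverage(list(empty)), "empty")
})
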