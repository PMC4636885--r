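test_that("heterogeneity is the population sd of masked pressures", {
  # constant map: zero variance
  s <- PlanarScan(10, (-2:2) * 0.7, (-2:2) * 0.7, matrix(3, 5, 5))
  expect_equal(heterogeneity(s), 0)
  # mask covering exactly two points with pressures 1 and 3
  s2 <- PlanarScan(10, c(-0.5, 0.5), 0, matrix(c(1, 3), 2, 1))
  expect_equal(heterogeneity(s2, maskRadius = 1), 1.0)
  # simulated piston slice vs explicit enumeration oracle
  tx <- PistonTransducer()
  scan <- fieldOnPlane(tx, 14, halfWidth = 5.25, spacing = 0.7)
  g <- expand.grid(x = scan@x, y = scan@y)
  inside <- g$x^2 + g$y^2 <= 5.25^2
  expect_equal(heterogeneity(scan, 5.25),
               popSd(as.vector(scan@pressure)[inside]))
  # scaling behaviour: std(c P) = c std(P)
  scan2 <- scan
  scan2@pressure <- scan@pressure * 3.7
  expect_equal(heterogeneity(scan2, 5.25), 3.7 * heterogeneity(scan, 5.25))
  expect_error(heterogeneity(scan, maskRadius = 0.01), "degenerate mask")
})

test_that("optimalDistance takes the heterogeneity argmin with smaller-z ties", {
  mk <- function(z, p) PlanarScan(z, c(-0.5, 0.5), 0, matrix(p, 2, 1))
  # sds: 1, 0.5, 2 -> unique minimum at the middle z
  scans <- list(mk(10, c(1, 3)), mk(11, c(1, 2)), mk(12, c(1, 5)))
  plan <- optimalDistance(scans, maskRadius = 1)
  expect_equal(plan@optimalZ, 11)
  expect_equal(plan@heterogeneityAtOptimum, 0.5)
  expect_equal(plan@curve@heterogeneity, c(1, 0.5, 2))
  # tie between z = 10 and z = 12 -> smaller z, independent of list order
  scansTie <- list(mk(12, c(1, 3)), mk(10, c(1, 3)), mk(11, c(1, 5)))
  expect_equal(optimalDistance(scansTie, maskRadius = 1)@optimalZ, 10)
  expect_error(optimalDistance(list(), 1), "non-empty")
  expect_error(optimalDistance(scans[1], 1), "at least 2")
})

test_that("optimalDistance agrees with exhaustive search on piston slices and is scale-invariant", {
  tx <- PistonTransducer()
  zs <- seq(13, 17, by = 0.5)
  scans <- lapply(zs, fieldOnPlane, tx = tx, halfWidth = 5.25,
                  spacing = 0.7, elementSize = wavelength(tx) / 10)
  plan <- optimalDistance(scans, maskRadius = 5.25)
  # brute force over the same slices
  het <- vapply(scans, heterogeneity, numeric(1), maskRadius = 5.25)
  expect_equal(plan@optimalZ, zs[which.min(het)])
  # multiplying all slices by one constant changes nothing
  scaled <- lapply(scans, function(s) { s@pressure <- s@pressure * 42; s })
  expect_equal(optimalDistance(scaled, maskRadius = 5.25)@optimalZ,
               plan@optimalZ)
})

test_that("calibrationPoint picks the grid point nearest the target relative intensity", {
  # map containing an exact 90 % relative-intensity point
  p <- matrix(0.1, 5, 5)
  p[3, 3] <- 1
  p[2, 3] <- sqrt(0.9)
  s <- PlanarScan(16, (-2:2) * 0.7, (-2:2) * 0.7, p)
  cp <- calibrationPoint(s)
  expect_equal(cp[["value"]], 0.9)
  expect_equal(unname(cp[c("x", "y")]), c(-0.7, 0))
  # uniform map: all at 1.0, radial tie-break picks the centre
  su <- PlanarScan(16, (-2:2) * 0.7, (-2:2) * 0.7, matrix(2, 5, 5))
  cpu <- calibrationPoint(su)
  expect_equal(unname(cpu[c("x", "y")]), c(0, 0))
  # simulated optimal-plane scan vs exhaustive search
  tx <- PistonTransducer()
  scan <- fieldOnPlane(tx, 16, 5.25, 0.7, elementSize = wavelength(tx) / 10)
  cps <- calibrationPoint(scan)
  rel <- (scan@pressure / max(scan@pressure))^2
  expect_equal(abs(cps[["value"]] - 0.9), min(abs(rel - 0.9)))
  expect_error(calibrationPoint(PlanarScan(16, 0:1, 0:1, matrix(0, 2, 2))),
               "degenerate")
})

test_that("crosstalkDb follows the intensity-ratio definition in dB", {
  # offset 0 includes the maximum: self-ratio, 0 dB
  p <- matrix(0.01, 7, 7)
  p[4, 4] <- 2
  p[1, 4] <- 1                       # r = 2.1 mm, intensity ratio 1/4
  s <- PlanarScan(16, (-3:3) * 0.7, (-3:3) * 0.7, p)
  expect_equal(crosstalkDb(s, 0), 0)
  expect_equal(crosstalkDb(s, 2.0), 10 * log10(0.25), tolerance = 1e-9)
  expect_error(crosstalkDb(s, 50), "outside")
})

test_that("simulated piston cross-talk is nonpositive and decays with offset", {
  tx <- PistonTransducer()
  wide <- fieldOnPlane(tx, 16, halfWidth = 12, spacing = 0.7,
                       elementSize = wavelength(tx) / 10)
  offs <- seq(0, 11, by = 1)
  db <- vapply(offs, crosstalkDb, numeric(1), scan = wide)
  expect_true(all(db <= 0))
  # beyond the -6 dB contour the envelope is non-increasing
  beyond <- db[db < -6]
  expect_true(all(diff(beyond) <= 1e-9))
  ct <- crosstalkContours(wide)
  expect_true(all(c(-6, -18) %in% ct$level))
})

test_that("planTreatment chains distance, calibration and cross-talk", {
  tx <- PistonTransducer()
  zs <- seq(14, 17, by = 1)
  scans <- lapply(zs, fieldOnPlane, tx = tx, halfWidth = 5.25,
                  spacing = 0.7, elementSize = wavelength(tx) / 10)
  wide <- fieldOnPlane(tx, 15, halfWidth = 12, spacing = 0.7,
                       elementSize = wavelength(tx) / 10)
  plan <- planTreatment(scans, wideScan = wide, lateralOffset = 10)
  expect_true(plan@optimalZ %in% zs)
  expect_length(plan@calibration, 3)
  expect_true(plan@calibration[["value"]] >= 0 &&
                plan@calibration[["value"]] <= 1)
  expect_lt(plan@crosstalkDb, 0)
})
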