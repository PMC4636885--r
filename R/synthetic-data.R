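# Seeded generators for every input the pipeline needs: noisy planar
# scans (in-silico hydrophone scanning), three-channel micrographs with
# ground truth, detachment dot images, and replicate response tables
# with the group structure of the validation study. Every generator is a
# pure function of its parameters and seed; the caller's RNG state is
# left untouched.

#' Generate a set of noisy planar scans
#'
#' Simulates [fieldOnPlane()] at each requested axial distance and adds
#' zero-mean Gaussian measurement noise (truncated at zero, since
#' pressure amplitudes are nonnegative).
#'
#' @param tx a [PistonTransducer-class].
#' @param zList axial distances in mm.
#' @param halfWidth,spacing scan geometry in mm (defaults match the
#'   10.5-mm characterization scans at 0.7-mm pitch).
#' @param noiseSd standard deviation of the additive noise, relative
#'   pressure units (0 = noiseless, bit-identical to [fieldOnPlane()]).
#' @param seed RNG seed (NULL leaves the RNG alone).
#' @param elementSize see [radialPressure()].
#' @return list of [PlanarScan-class] objects in `zList` order.
#' @export
generateScanSet <- function(tx, zList, halfWidth = 5.25, spacing = 0.7,
                            noiseSd = 0, seed = NULL,
                            elementSize = wavelength(tx) / 20) {
  stopifnot(is(tx, "PistonTransducer"), noiseSd >= 0)
  .withSeed(seed, {
    lapply(zList, function(z) {
      scan <- fieldOnPlane(tx, z, halfWidth, spacing,
                           elementSize = elementSize)
      if (noiseSd > 0) {
        p <- scan@pressure + rnorm(length(scan@pressure), 0, noiseSd)
        scan@pressure <- pmax(p, 0)
      }
      scan
    })
  })
}

# disk rasterization helper: TRUE inside the disk of radius r at (cx, cy)
.diskMask <- function(nr, nc, cx, cy, r) {
  ri <- matrix(seq_len(nr), nr, nc)
  ci <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (ri - cx)^2 + (ci - cy)^2 <= r^2
}

#' Generate a synthetic field of view with ground truth
#'
#' Emulates a three-channel micrograph of adherent cells: nuclei are
#' bright disks in blue; transfected cells carry a reporter offset in
#' green over both cytoplasm and nucleus; apoptotic cells carry a
#' marker offset in red over the nucleus. The medium outside cells
#' fluoresces at `backgroundMean` in every channel (unbound dye /
#' autofluorescence) while unstained cell interiors are dark, so
#' negative objects fall below the background-referenced criterion and
#' positive ones exceed it. Gaussian noise of sd `noiseSd` is added
#' everywhere and values are clipped to the 12-bit range. Cells are
#' placed by rejection sampling with non-overlapping cytoplasm disks.
#'
#' Positive flags are assigned deterministically: the first
#' `round(fraction * nCells)` cells of a seeded shuffle, so requested
#' fractions are recovered exactly whenever `fraction * nCells` is
#' integral.
#'
#' @param nCells number of cells to place.
#' @param trueTransfectedFraction,trueApoptoticFraction requested
#'   positive fractions.
#' @param width,height image size in px.
#' @param nucleusRadius,cytoRadius cell geometry in px.
#' @param backgroundMean,noiseSd background level and noise sd, counts.
#' @param nucleusOffset blue offset of nuclei above zero, counts.
#' @param signalOffset green/red offset of positive structures, counts.
#' @param seed RNG seed.
#' @param maxAttempts rejection-sampling budget; exceeding it raises a
#'   capacity error.
#' @return list with `fov` (a [FieldOfViewImages-class]) and `truth`
#'   (a [FovGroundTruth-class]).
#' @examples
#' g <- generateFov(nCells = 20, trueTransfectedFraction = 0.1, seed = 1)
#' sum(g$truth@cells$transfected)  # 2
#' @export
generateFov <- function(nCells = 80, trueTransfectedFraction = 0.05,
                        trueApoptoticFraction = 0.05, width = 320,
                        height = 320, nucleusRadius = 6, cytoRadius = 11,
                        backgroundMean = 100, noiseSd = 10,
                        nucleusOffset = 2900, signalOffset = 600,
                        seed = NULL, maxAttempts = 1e4) {
  stopifnot(nCells >= 0, trueTransfectedFraction >= 0,
            trueTransfectedFraction <= 1, trueApoptoticFraction >= 0,
            trueApoptoticFraction <= 1, nucleusRadius < cytoRadius)
  .withSeed(seed, {
    nr <- height; nc <- width
    margin <- cytoRadius + 1
    xs <- numeric(0); ys <- numeric(0)
    attempts <- 0L
    while (length(xs) < nCells) {
      attempts <- attempts + 1L
      if (attempts > maxAttempts)
        stop(sprintf(
          "capacity error: could not place %d non-overlapping cells in %d attempts",
          nCells, as.integer(maxAttempts)))
      x <- runif(1, margin, nr - margin)
      y <- runif(1, margin, nc - margin)
      if (length(xs) == 0 ||
          all((xs - x)^2 + (ys - y)^2 > (2 * cytoRadius)^2)) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
    }
    nT <- round(trueTransfectedFraction * nCells)
    nA <- round(trueApoptoticFraction * nCells)
    transfected <- apoptotic <- rep(FALSE, nCells)
    if (nCells > 0) {
      ord <- sample.int(nCells)
      transfected[ord[seq_len(nT)]] <- TRUE
      # apoptosis flags use an independent shuffle
      ord2 <- sample.int(nCells)
      apoptotic[ord2[seq_len(nA)]] <- TRUE
    }
    blue <- matrix(backgroundMean, nr, nc)
    green <- matrix(backgroundMean, nr, nc)
    red <- matrix(backgroundMean, nr, nc)
    for (i in seq_len(nCells)) {
      cyto <- .diskMask(nr, nc, xs[i], ys[i], cytoRadius)
      nuc <- .diskMask(nr, nc, xs[i], ys[i], nucleusRadius)
      # unstained cell interiors are dark against the fluorescing medium
      green[cyto] <- if (transfected[i]) signalOffset else 0
      red[cyto] <- 0
      if (apoptotic[i]) red[nuc] <- signalOffset
      blue[nuc] <- backgroundMean + nucleusOffset
    }
    clip <- function(m) {
      if (noiseSd > 0) m <- m + rnorm(length(m), 0, noiseSd)
      matrix(pmin(pmax(round(m), 0), 4095), nr, nc)
    }
    fov <- FieldOfViewImages(blue = clip(blue), green = clip(green),
                             red = clip(red), bitDepth = 12)
    truth <- new("FovGroundTruth",
      cells = data.frame(x = xs, y = ys, nucleusRadius = nucleusRadius,
                         cytoRadius = cytoRadius,
                         transfected = transfected, apoptotic = apoptotic),
      params = list(nCells = nCells,
                    trueTransfectedFraction = trueTransfectedFraction,
                    trueApoptoticFraction = trueApoptoticFraction,
                    width = width, height = height,
                    backgroundMean = backgroundMean, noiseSd = noiseSd,
                    nucleusOffset = nucleusOffset,
                    signalOffset = signalOffset, seed = seed))
    list(fov = fov, truth = truth)
  })
}

#' Generate before/after detachment dot images
#'
#' Places `kBefore` non-touching 3 x 3 dots at random positions; the
#' after image keeps `round((1 - lossFraction) * kBefore)` of them (a
#' seeded subset at unchanged positions). Feeding the pair through
#' [countMarkers()] and [cellLoss()] returns `-100 * lossFraction`
#' whenever the counts are integral.
#'
#' @param kBefore number of dots before treatment.
#' @param lossFraction fraction of dots removed, in `[0, 1]`.
#' @param width,height image size in px.
#' @param seed RNG seed.
#' @return list with `before` and `after` binary matrices.
#' @export
generateDotImages <- function(kBefore, lossFraction, width = 256,
                              height = 256, seed = NULL) {
  stopifnot(kBefore >= 0, lossFraction >= 0, lossFraction <= 1)
  .withSeed(seed, {
    nr <- height; nc <- width
    xs <- ys <- numeric(0)
    attempts <- 0L
    while (length(xs) < kBefore) {
      attempts <- attempts + 1L
      if (attempts > 1e5)
        stop("capacity error: could not place the requested dots")
      x <- sample(2:(nr - 1), 1)
      y <- sample(2:(nc - 1), 1)
      # dots are 3x3; centres at Chebyshev distance > 3 never touch
      if (length(xs) == 0 || all(pmax(abs(xs - x), abs(ys - y)) > 3)) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
    }
    draw <- function(keep) {
      img <- matrix(0, nr, nc)
      for (i in keep)
        img[(xs[i] - 1):(xs[i] + 1), (ys[i] - 1):(ys[i] + 1)] <- 1
      img
    }
    kAfter <- round((1 - lossFraction) * kBefore)
    kept <- if (kBefore > 0) sample.int(kBefore)[seq_len(kAfter)] else integer(0)
    list(before = draw(seq_len(kBefore)), after = draw(kept))
  })
}

#' Group specification presets
#'
#' Per-cell means and standard deviations of the three response
#' variables of the validation study (3 treatments x 3 temperatures,
#' n = 3 replicates): transfection efficiency (%), relative cell-count
#' change (%; negative = loss), apoptotic-cell ratio (%).
#'
#' @param which `"transfection"`, `"cell_loss"` or `"apoptosis"`.
#' @return data.frame with columns `treatment`, `temperature`, `mean`,
#'   `sd`.
#' @export
groupSpecPreset <- function(which = c("transfection", "cell_loss",
                                      "apoptosis")) {
  which <- match.arg(which)
  base <- expand.grid(temperature = .TEMPERATURES,
                      treatment = .TREATMENTS,
                      stringsAsFactors = FALSE)[, c("treatment", "temperature")]
  vals <- switch(which,
    transfection = list(
      mean = c(5.4, 5.8, 5.3,   0.66, 1.1, 0.57,  0.50, 0.73, 1.3),
      sd   = c(0.92, 1.3, 1.1,  0.38, 0.46, 0.26, 0.22, 0.24, 0.53)),
    cell_loss = list(
      mean = c(-31, -32, -34,   -6.7, -9.1, -18,  -5.6, -2.8, -2.2),
      sd   = c(3.4, 13, 17,     7.9, 8.3, 5.9,    7.4, 7.9, 12.2)),
    apoptosis = list(
      mean = c(0.34, 0.22, 0.41, 0.31, 0.22, 0.23, 0.18, 0.32, 0.21),
      sd   = c(0.15, 0.08, 0.2,  0.25, 0.10, 0.11, 0.17, 0.08, 0.10)))
  data.frame(base, mean = vals$mean, sd = vals$sd)
}

#' Generate a replicate response table
#'
#' Draws `nReplicates` independent Normal(mean, sd) values per
#' (treatment, temperature) cell of a group specification — the minimal
#' distributional assumption consistent with mean +- s.d. reporting and
#' ANOVA use.
#'
#' @param spec data.frame with columns `treatment`, `temperature`,
#'   `mean`, `sd` (see [groupSpecPreset()]); 9 cells expected.
#' @param nReplicates replicates per cell (default 3).
#' @param seed RNG seed.
#' @return replicate table (see [asReplicateTable()]).
#' @examples
#' tab <- generateExperiment(groupSpecPreset("transfection"), seed = 7)
#' head(tab)
#' @export
generateExperiment <- function(spec, nReplicates = 3, seed = NULL) {
  need <- c("treatment", "temperature", "mean", "sd")
  if (!is.data.frame(spec) || !all(need %in% names(spec)))
    stop("'spec' must have columns treatment, temperature, mean, sd")
  if (any(spec$sd < 0)) stop("sd must be >= 0")
  .withSeed(seed, {
    rows <- lapply(seq_len(nrow(spec)), function(i) {
      data.frame(treatment = spec$treatment[i],
                 temperature = spec$temperature[i],
                 replicate = seq_len(nReplicates),
                 response = rnorm(nReplicates, spec$mean[i], spec$sd[i]))
    })
    asReplicateTable(do.call(rbind, rows))
  })
}
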