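# Segmentation and positivity scoring of three-channel fluorescence
# micrographs.
#
# Nuclei come from the blue (DAPI) channel by global Otsu thresholding
# and 8-connected component labelling; cell boundaries come from the
# pixelwise maximum of the min-max-normalized blue and green channels,
# split between touching cells by nuclei-seeded propagation so that each
# cell object contains exactly one nucleus. An object is positive in a
# channel iff its mean intensity satisfies the inclusive criterion
#   Ibar_obj >= Ibar_bg + n * sigma_bg   (n = 3 by default),
# with the background statistics taken over all pixels not occupied by
# any object. The criterion is invariant under affine rescaling
# I -> a*I + b (a > 0) of the channel, and the positive set shrinks as n
# grows.

#' Otsu threshold of an intensity raster
#'
#' Global histogram threshold minimizing the weighted intra-class
#' variance (equivalently maximizing the between-class variance).
#' Deterministic: among tied optima the smallest cut is taken. The
#' returned value is the midpoint between the two intensity levels
#' spanning the optimal cut, so foreground is `raster > threshold`.
#'
#' @param raster numeric matrix (or vector) with at least two distinct
#'   values.
#' @return threshold value.
#' @examples
#' otsuThreshold(matrix(c(10, 10, 200, 200), 2))  # 105
#' @export
otsuThreshold <- function(raster) {
  v <- as.vector(raster)
  if (any(!is.finite(v))) stop("raster must be finite")
  tab <- table(v)
  u <- as.numeric(names(tab))
  cnt <- as.numeric(tab)
  m <- length(u)
  if (m < 2L)
    stop("degenerate histogram: raster has fewer than 2 distinct values")
  n <- sum(cnt)
  w0 <- cumsum(cnt) / n            # class-0 weight after cut i
  s <- cumsum(cnt * u) / n         # partial first moment
  muT <- s[m]
  i <- seq_len(m - 1L)
  sigmaB <- (muT * w0[i] - s[i])^2 / (w0[i] * (1 - w0[i]))
  best <- which.max(sigmaB)        # first maximum: smallest cut on ties
  (u[best] + u[best + 1L]) / 2
}

# 8-connected component labelling of a logical mask by iterative
# neighbourhood min-propagation; labels renumbered 1..N in raster order.
.label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  M <- matrix(Inf, nr, nc)
  fg <- which(mask)
  if (length(fg) == 0) return(matrix(0L, nr, nc))
  M[fg] <- seq_along(fg)
  repeat {
    P <- matrix(Inf, nr + 2L, nc + 2L)
    P[2:(nr + 1L), 2:(nc + 1L)] <- M
    N <- P[1:nr, 1:nc]
    for (di in 0:2) for (dj in 0:2) {
      if (di == 0 && dj == 0) next
      N <- pmin(N, P[(1:nr) + di, (1:nc) + dj])
    }
    changed <- N[fg] < M[fg]
    if (!any(changed)) break
    M[fg] <- N[fg]
  }
  lab <- matrix(0L, nr, nc)
  lab[fg] <- match(M[fg], sort(unique(M[fg])))
  lab
}

.minMaxNorm <- function(m) {
  rng <- range(m)
  if (diff(rng) == 0) return(m * 0)
  (m - rng[1]) / diff(rng)
}

# per-object areas, centroids and mean channel intensities, plus
# background statistics over label-0 pixels. `seedLabel` records, for
# cell-boundary objects, the nucleus label that seeded each object.
.makeObjectSet <- function(labels, fov, kind, minObjectArea,
                           seedLabels = NULL) {
  fg <- which(labels > 0)
  lab <- labels[fg]
  n <- if (length(fg)) max(lab) else 0L
  if (n > 0) {
    area <- tabulate(lab, nbins = n)
    ri <- ((fg - 1L) %% nrow(labels)) + 1L
    ci <- ((fg - 1L) %/% nrow(labels)) + 1L
    objects <- data.frame(
      label = seq_len(n),
      seedLabel = if (is.null(seedLabels)) seq_len(n) else seedLabels,
      area = area,
      cx = as.vector(rowsum(as.numeric(ri), lab)) / area,
      cy = as.vector(rowsum(as.numeric(ci), lab)) / area,
      meanBlue = as.vector(rowsum(fov@blue[fg], lab)) / area,
      meanGreen = as.vector(rowsum(fov@green[fg], lab)) / area,
      meanRed = as.vector(rowsum(fov@red[fg], lab)) / area)
  } else {
    objects <- data.frame(label = integer(0), seedLabel = integer(0),
                          area = numeric(0), cx = numeric(0),
                          cy = numeric(0), meanBlue = numeric(0),
                          meanGreen = numeric(0), meanRed = numeric(0))
  }
  bgPix <- labels == 0
  background <- do.call(rbind, lapply(c("blue", "green", "red"), function(ch) {
    v <- slot(fov, ch)[bgPix]
    data.frame(channel = ch,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v)) .popSd(v) else NA_real_,
               nPixels = length(v))
  }))
  new("ObjectSet", labels = labels, kind = kind, objects = objects,
      background = background, minObjectArea = minObjectArea)
}

.asFov <- function(x) {
  if (is(x, "FieldOfViewImages")) return(x)
  if (is.matrix(x)) {
    bits <- max(12, ceiling(log2(max(x) + 1)))
    return(FieldOfViewImages(blue = x, green = x * 0, red = x * 0,
                             bitDepth = bits))
  }
  stop("expected a FieldOfViewImages or a matrix")
}

# drop objects below the area filter (and optionally a contrast filter)
# from a raw label matrix; returns the relabelled matrix plus the kept
# original labels in increasing order.
.filterLabels <- function(labels, keep) {
  out <- matrix(0L, nrow(labels), ncol(labels))
  if (length(keep)) {
    fg <- which(labels > 0 & matrix(labels %in% keep, nrow(labels)))
    out[fg] <- match(labels[fg], keep)
  }
  out
}

#' Segment nuclei from the blue channel
#'
#' Otsu-thresholds the blue (DAPI) channel, labels the foreground with
#' 8-connected components, removes components smaller than
#' `minObjectArea`, and (when `minContrastSigma > 0`) removes candidate
#' objects whose mean blue intensity does not exceed the below-threshold
#' background by `minContrastSigma` standard deviations — the same
#' inclusive background-referenced criterion used for positivity
#' scoring, here acting as a sanity filter so that structureless noise
#' yields an empty object set rather than spurious "nuclei".
#'
#' @param x a [FieldOfViewImages-class] (or a bare matrix treated as the
#'   blue channel).
#' @param minObjectArea minimum object area in px (default 30).
#' @param minContrastSigma contrast filter in background standard
#'   deviations (default 3; 0 disables).
#' @return an [ObjectSet-class] of kind `"nuclei"` (possibly empty).
#' @export
segmentNuclei <- function(x, minObjectArea = 30, minContrastSigma = 3) {
  fov <- .asFov(x)
  blue <- fov@blue
  thr <- otsuThreshold(blue)
  mask <- blue > thr
  raw <- .label8(mask)
  n <- max(raw)
  keep <- integer(0)
  if (n > 0) {
    area <- tabulate(raw[raw > 0], nbins = n)
    keep <- which(area >= minObjectArea)
    if (length(keep) && minContrastSigma > 0) {
      bg <- blue[!mask]
      if (length(bg) >= 2) {
        lim <- mean(bg) + minContrastSigma * .popSd(bg)
        objMean <- as.vector(rowsum(blue[raw > 0], raw[raw > 0])) /
          tabulate(raw[raw > 0], nbins = n)
        keep <- keep[objMean[keep] >= lim]
      }
    }
  }
  labels <- .filterLabels(raw, keep)
  .makeObjectSet(labels, fov, "nuclei", minObjectArea)
}

#' Segment cell boundaries from the blue and green channels
#'
#' The combined image is the pixelwise maximum of the
#' min-max-normalized blue and green channels (so cells without
#' reporter signal remain visible through their nuclei). It is
#' Otsu-thresholded and the resulting mask is split between touching
#' cells by propagation seeded at the nuclei, yielding one cell object
#' per nucleus; each cell object is a superset of its nucleus. Objects
#' below `minObjectArea` are dropped.
#'
#' @param x a [FieldOfViewImages-class].
#' @param nuclei an [ObjectSet-class] of kind `"nuclei"`; segmented from
#'   `x` when `NULL`.
#' @param minObjectArea minimum object area in px.
#' @return an [ObjectSet-class] of kind `"cell_boundary"`; its
#'   `objects$seedLabel` column records the seeding nucleus label. Empty
#'   when there are no nuclei.
#' @export
segmentCellBoundaries <- function(x, nuclei = NULL, minObjectArea = 30) {
  fov <- .asFov(x)
  if (is.null(nuclei)) nuclei <- segmentNuclei(fov, minObjectArea)
  stopifnot(is(nuclei, "ObjectSet"), nuclei@kind == "nuclei")
  if (nObjects(nuclei) == 0)
    return(.makeObjectSet(matrix(0L, nrow(fov@blue), ncol(fov@blue)),
                          fov, "cell_boundary", minObjectArea))
  combined <- pmax(.minMaxNorm(fov@blue), .minMaxNorm(fov@green))
  thr <- otsuThreshold(combined)
  mask <- combined > thr | nuclei@labels > 0  # seeds always inside mask
  prop <- EBImage::propagate(combined, nuclei@labels, mask = mask)
  raw <- matrix(as.integer(round(prop)), nrow(mask))
  n <- max(raw)
  area <- tabulate(raw[raw > 0], nbins = n)
  keep <- which(area >= minObjectArea)
  labels <- .filterLabels(raw, keep)
  .makeObjectSet(labels, fov, "cell_boundary", minObjectArea,
                 seedLabels = keep)
}

#' Background-referenced positivity of objects
#'
#' Applies the inclusive criterion
#' `Ibar_obj >= Ibar_bg + n * sigma_bg` to each object's mean intensity
#' in the stated channel, with background statistics over all
#' non-object pixels of that channel. Decisions are invariant under a
#' common affine rescaling of the whole channel, and the positive set at
#' a larger `n` is a subset of the positive set at a smaller `n`.
#'
#' @param objects an [ObjectSet-class].
#' @param channel `"green"` (transfection) or `"red"` (apoptosis).
#' @param n standard-deviation multiplier (default 3).
#' @return named logical vector, one entry per object (names are
#'   labels).
#' @export
classifyPositive <- function(objects, channel = c("green", "red"), n = 3) {
  stopifnot(is(objects, "ObjectSet"))
  channel <- match.arg(channel)
  bg <- objects@background[objects@background$channel == channel, ]
  if (bg$nPixels < 2)
    stop("undefined background: fewer than 2 background pixels")
  lim <- bg$mean + n * bg$sd
  col <- if (channel == "green") "meanGreen" else "meanRed"
  stats::setNames(objects@objects[[col]] >= lim,
                  as.character(objects@objects$label))
}

#' Quantify one field of view
#'
#' Segments nuclei and cell-boundary objects, counts cells
#' (cell-boundary objects), scores transfection on the cell objects
#' against the green channel and apoptosis on the corresponding nuclei
#' against the red channel, and reports fractions relative to the cell
#' count. With zero cells, fractions are `NA` (missing), not 0.
#'
#' @param fov a [FieldOfViewImages-class].
#' @param n standard-deviation multiplier of the positivity criterion.
#' @param minObjectArea minimum object area in px.
#' @param minContrastSigma see [segmentNuclei()].
#' @return a [FovQuantification-class].
#' @export
quantifyFov <- function(fov, n = 3, minObjectArea = 30,
                        minContrastSigma = 3) {
  stopifnot(is(fov, "FieldOfViewImages"))
  nuclei <- segmentNuclei(fov, minObjectArea, minContrastSigma)
  cells <- segmentCellBoundaries(fov, nuclei, minObjectArea)
  nCells <- nObjects(cells)
  if (nCells == 0)
    return(new("FovQuantification", nCells = 0, nTransfected = 0,
               nApoptotic = 0, transfectedFraction = NA_real_,
               apoptoticFraction = NA_real_))
  transfected <- classifyPositive(cells, "green", n)
  apoptoticAll <- classifyPositive(nuclei, "red", n)
  # score apoptosis only on nuclei that seeded a surviving cell object
  apoptotic <- apoptoticAll[as.character(cells@objects$seedLabel)]
  new("FovQuantification",
      nCells = nCells,
      nTransfected = sum(transfected),
      nApoptotic = sum(apoptotic),
      transfectedFraction = sum(transfected) / nCells,
      apoptoticFraction = sum(apoptotic) / nCells)
}

#' Average field-of-view fractions within a replicate
#'
#' Unweighted mean of the per-FOV positive fractions (not pooled
#' counts), excluding fields of view with zero cells.
#'
#' @param fovResults list of [FovQuantification-class] objects.
#' @return data.frame with one row: `nFov` (contributing fields of
#'   view), `transfectedFraction`, `apoptoticFraction`.
#' @export
replicateAverage <- function(fovResults) {
  if (!is.list(fovResults) || length(fovResults) == 0)
    stop("'fovResults' must be a non-empty list")
  ok <- vapply(fovResults, function(q) q@nCells > 0, logical(1))
  if (!any(ok)) stop("all fields of view are empty (no cells)")
  kept <- fovResults[ok]
  data.frame(
    nFov = length(kept),
    transfectedFraction =
      mean(vapply(kept, function(q) q@transfectedFraction, numeric(1))),
    apoptoticFraction =
      mean(vapply(kept, function(q) q@apoptoticFraction, numeric(1))))
}
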