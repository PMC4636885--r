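# Near-field treatment-plane selection and array cross-talk analysis.
#
# The device operates in the piston near field, where the lateral
# pressure distribution varies strongly with axial distance. The
# characterization pipeline quantifies each slice's "heterogeneity" as
# the (population) standard deviation of the pressure within a circular
# mask centred on the acoustic axis, picks the axial distance minimizing
# it, selects a ~90 % relative-intensity point on the optimal plane for
# electrical power calibration, and checks that the field leaking to a
# neighbouring transducer's treatment area is acceptably low.

#' Field heterogeneity of a planar scan
#'
#' Population standard deviation of the pressure over grid points inside
#' the circular mask `x^2 + y^2 <= maskRadius^2` centred on the acoustic
#' axis. A descriptive statistic over a fixed grid, hence the population
#' (divide-by-N) form. Scales linearly with the pressure: a global
#' rescaling of the field rescales the heterogeneity by the same factor.
#'
#' @param scan a [PlanarScan-class].
#' @param maskRadius mask radius in mm. Default: the half-extent of the
#'   scan (the circle inscribed in the scanned square, 5.25 mm for the
#'   10.5-mm characterization scans).
#' @return a nonnegative scalar, relative pressure units.
#' @export
heterogeneity <- function(scan, maskRadius = max(scan@x)) {
  stopifnot(is(scan, "PlanarScan"))
  maskRadius <- .scalarNum(maskRadius, "maskRadius")
  g <- expand.grid(x = scan@x, y = scan@y)
  inside <- g$x^2 + g$y^2 <= maskRadius^2 + 1e-12
  if (sum(inside) < 2L)
    stop("degenerate mask: fewer than 2 grid points inside maskRadius")
  .popSd(as.vector(scan@pressure)[inside])
}

#' Optimal treatment distance
#'
#' Computes the heterogeneity of every slice and returns the axial
#' distance at which it is minimal (ties broken toward the smaller z),
#' together with the full heterogeneity curve for audit and plotting.
#' The choice is invariant under a common positive rescaling of all
#' slices.
#'
#' @param scans list of [PlanarScan-class] objects at distinct z.
#' @param maskRadius mask radius in mm (default: inscribed circle of the
#'   first scan).
#' @return a [TreatmentPlan-class] with `optimalZ`,
#'   `heterogeneityAtOptimum` and `curve` filled in (calibration and
#'   cross-talk left unset; see [planTreatment()]).
#' @export
optimalDistance <- function(scans, maskRadius = max(scans[[1]]@x)) {
  if (!is.list(scans) || length(scans) == 0)
    stop("'scans' must be a non-empty list of PlanarScan objects")
  if (length(scans) < 2L) stop("need at least 2 slices")
  z <- vapply(scans, function(s) s@z, numeric(1))
  if (anyDuplicated(z)) stop("slice z values must be distinct")
  o <- order(z)
  z <- z[o]
  het <- vapply(scans[o], heterogeneity, numeric(1), maskRadius = maskRadius)
  i <- which.min(het)  # which.min takes the first minimum: smaller z on ties
  curve <- new("HeterogeneityCurve", z = z, heterogeneity = het,
               maskRadius = maskRadius)
  new("TreatmentPlan", optimalZ = z[i], heterogeneityAtOptimum = het[i],
      curve = curve, calibration = numeric(0), crosstalkDb = NA_real_)
}

#' Calibration point of given relative intensity
#'
#' Grid point of the scan whose relative intensity
#' `(pressure / max pressure)^2` is closest to the target (0.9 by
#' default: the ~90 % point used to set the electrical drive power).
#' Ties are broken by smaller radial distance from the axis, then
#' smaller x, then smaller y.
#'
#' @param scan a [PlanarScan-class] with a positive maximum.
#' @param targetRelIntensity target relative intensity in (0, 1].
#' @return named numeric `c(x, y, value)`, `value` being the achieved
#'   relative intensity.
#' @export
calibrationPoint <- function(scan, targetRelIntensity = 0.9) {
  stopifnot(is(scan, "PlanarScan"))
  rel <- relativeIntensity(scan)  # errors on all-zero scans
  g <- expand.grid(x = scan@x, y = scan@y)
  d <- abs(as.vector(rel) - targetRelIntensity)
  r <- sqrt(g$x^2 + g$y^2)
  i <- order(d, r, g$x, g$y)[1L]
  c(x = g$x[i], y = g$y[i], value = as.vector(rel)[i])
}

#' Cross-talk level at a lateral offset
#'
#' Intensity leaking past a given radial distance, in decibels relative
#' to the plane maximum: `10 log10(I(offset) / I_max)` with
#' `I = pressure^2` and `I(offset)` the maximum intensity among grid
#' points at radial distance >= `lateralOffset` from the axis. For a
#' 26-mm housing pitch and a 20-mm crystal, the edge of the neighbouring
#' crystal sits 16 mm off axis.
#'
#' @param scan a [PlanarScan-class] (use a wide scan, e.g. 40 x 40 mm).
#' @param lateralOffset radial distance in mm; must lie inside the scan
#'   extent.
#' @return dB value <= 0.
#' @seealso [crosstalkContours()] for the -6/-18 dB reporting contours.
#' @export
crosstalkDb <- function(scan, lateralOffset) {
  stopifnot(is(scan, "PlanarScan"))
  lateralOffset <- .scalarNum(lateralOffset, "lateralOffset",
                              positive = FALSE)
  if (lateralOffset < 0) stop("'lateralOffset' must be >= 0")
  g <- expand.grid(x = scan@x, y = scan@y)
  r <- sqrt(g$x^2 + g$y^2)
  if (lateralOffset > max(r))
    stop("'lateralOffset' lies outside the scan extent")
  I <- as.vector(scan@pressure)^2
  iMax <- max(I)
  if (iMax == 0) stop("degenerate scan: all pressures are zero")
  10 * log10(max(I[r >= lateralOffset]) / iMax)
}

#' Intensity contours of a planar scan in dB
#'
#' Contour polygons of the relative intensity map expressed in dB
#' (`10 log10(I / I_max)`), by default at the -6 and -18 dB levels used
#' for cross-talk reporting.
#'
#' @param scan a [PlanarScan-class].
#' @param levelsDb contour levels in dB (negative).
#' @return data.frame with columns `level`, `polygon` (index within a
#'   level) and `x`, `y` (mm).
#' @export
crosstalkContours <- function(scan, levelsDb = c(-6, -18)) {
  stopifnot(is(scan, "PlanarScan"))
  rel <- relativeIntensity(scan)
  db <- 10 * log10(pmax(rel, 1e-300))
  cl <- contourLines(scan@x, scan@y, db, levels = levelsDb)
  if (length(cl) == 0)
    return(data.frame(level = numeric(0), polygon = integer(0),
                      x = numeric(0), y = numeric(0)))
  out <- lapply(seq_along(cl), function(i)
    data.frame(level = cl[[i]]$level, polygon = i,
               x = cl[[i]]$x, y = cl[[i]]$y))
  do.call(rbind, out)
}

#' Full treatment plan for one transducer
#'
#' Convenience wrapper chaining [optimalDistance()],
#' [calibrationPoint()] on the optimal slice, and optionally
#' [crosstalkDb()] on a supplied wide scan.
#'
#' @param scans list of [PlanarScan-class] slices over z.
#' @param maskRadius heterogeneity mask radius in mm.
#' @param targetRelIntensity calibration target (default 0.9).
#' @param wideScan optional wide [PlanarScan-class] at the optimal plane
#'   for cross-talk evaluation.
#' @param lateralOffset radial offset in mm for the cross-talk figure
#'   (default 16: 26-mm housing pitch minus the 10-mm crystal radius).
#' @return a [TreatmentPlan-class].
#' @export
planTreatment <- function(scans, maskRadius = max(scans[[1]]@x),
                          targetRelIntensity = 0.9, wideScan = NULL,
                          lateralOffset = 16) {
  plan <- optimalDistance(scans, maskRadius = maskRadius)
  zs <- vapply(scans, function(s) s@z, numeric(1))
  best <- scans[[which(zs == plan@optimalZ)[1L]]]
  plan@calibration <- calibrationPoint(best, targetRelIntensity)
  if (!is.null(wideScan))
    plan@crosstalkDb <- crosstalkDb(wideScan, lateralOffset)
  validObject(plan)
  plan
}
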