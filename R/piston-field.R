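# Continuous-wave field of a flat circular piston.
#
# The field is the Rayleigh integral over the source surface,
#   p(r, z) ~ |(k / 2 pi) * int_disc exp(i k R) / R dS|,
# with uniform piston velocity and R the source-to-field-point distance.
# On the axis the integral has the classical closed form
#   p(0, z) = 2 |sin( (k/2) (sqrt(z^2 + a^2) - z) )|,
# which fixes the normalization of the quadrature. The model is
# continuous-wave, lossless and free-field: the culture chamber membrane
# is minimally reflective and an absorber sits in the far field, so
# reflections and standing waves are ignored by design.

#' On-axis pressure amplitude of a circular piston
#'
#' Closed-form relative pressure amplitude on the acoustic axis,
#' `2 |sin((k/2) (sqrt(z^2 + a^2) - z))| * amplitudeScale` with
#' `k = 2 pi / lambda` and `a` the crystal radius. Axial nulls occur
#' where the edge-to-centre path difference is a whole number of
#' wavelengths; the last axial maximum sits at `z = a^2/lambda -
#' lambda/4`, the near/far-field transition of the ideal piston.
#'
#' @param tx a [PistonTransducer-class].
#' @param z axial distance(s) in mm, all > 0.
#' @return relative pressure amplitude(s), same length as `z`.
#' @examples
#' tx <- PistonTransducer()
#' onAxisPressure(tx, 20)
#' lam <- wavelength(tx)
#' onAxisPressure(tx, 10^2 / lam - lam / 4)  # last axial maximum: 2
#' @export
onAxisPressure <- function(tx, z) {
  stopifnot(is(tx, "PistonTransducer"))
  if (!is.numeric(z) || length(z) == 0 || any(!is.finite(z)) || any(z <= 0))
    stop("'z' must be positive and finite")
  lam <- wavelength(tx)
  k <- 2 * pi / lam
  a <- tx@radius
  2 * abs(sin((k / 2) * (sqrt(z^2 + a^2) - z))) * tx@amplitudeScale
}

# Discretize the piston surface into concentric rings of roughly square
# elements of side <= elementSize; returns x, y (mm) and area weights w.
.pistonElements <- function(tx, elementSize) {
  a <- tx@radius
  nr <- ceiling(a / elementSize)
  dr <- a / nr
  rho <- (seq_len(nr) - 0.5) * dr
  parts <- lapply(rho, function(r) {
    nphi <- max(8L, ceiling(2 * pi * r / elementSize))
    phi <- (seq_len(nphi) - 0.5) * (2 * pi / nphi)
    cbind(x = r * cos(phi), y = r * sin(phi), w = r * dr * (2 * pi / nphi))
  })
  do.call(rbind, parts)
}

.checkElementSize <- function(tx, elementSize) {
  lam <- wavelength(tx)
  if (!is.numeric(elementSize) || length(elementSize) != 1L ||
      !is.finite(elementSize) || elementSize <= 0)
    stop("'elementSize' must be a single positive number")
  if (elementSize > lam / 5)
    stop(sprintf(
      "surface discretization too coarse: elementSize = %.4g mm exceeds lambda/5 = %.4g mm",
      elementSize, lam / 5))
  elementSize
}

#' Radial pressure profile on a plane
#'
#' Rayleigh quadrature of the piston field at radial distances `r` from
#' the acoustic axis on the plane at distance `z` (the field of a
#' circular piston is radially symmetric). Normalized so that
#' `radialPressure(tx, z, 0)` agrees with [onAxisPressure()].
#'
#' @param tx a [PistonTransducer-class].
#' @param z axial distance in mm, > 0.
#' @param r radial distance(s) in mm, >= 0.
#' @param elementSize side of the surface quadrature elements in mm;
#'   must not exceed lambda/5. Default lambda/20.
#' @return relative pressure amplitude(s), same length as `r`.
#' @export
radialPressure <- function(tx, z, r, elementSize = wavelength(tx) / 20) {
  stopifnot(is(tx, "PistonTransducer"))
  z <- .scalarNum(z, "z")
  if (!is.numeric(r) || any(!is.finite(r)) || any(r < 0))
    stop("'r' must be nonnegative and finite")
  .checkElementSize(tx, elementSize)
  src <- .pistonElements(tx, elementSize)
  k <- 2 * pi / wavelength(tx)
  sx <- src[, "x"]; sy <- src[, "y"]; w <- src[, "w"]
  scale <- k / (2 * pi) * tx@amplitudeScale
  vapply(r, function(ri) {
    R <- sqrt(z^2 + (ri - sx)^2 + sy^2)
    scale * Mod(sum(w * exp(1i * k * R) / R))
  }, numeric(1))
}

#' Simulate a planar hydrophone scan
#'
#' Evaluates the piston field on a centred regular grid at axial
#' distance `z`, the in-silico counterpart of one planar hydrophone
#' scan. The grid is symmetric about the axis (coordinates
#' `(-n:n) * spacing` with `n = floor(halfWidth / spacing)`), so the map
#' inherits the x/-x and y/-y mirror symmetry of the source.
#'
#' @param tx a [PistonTransducer-class].
#' @param z axial distance in mm, > 0.
#' @param halfWidth half-extent of the scan in mm (>= spacing).
#' @param spacing grid pitch in mm (0.7 in the characterization
#'   protocol, below lambda/2 at 1 MHz).
#' @param elementSize see [radialPressure()].
#' @return a [PlanarScan-class].
#' @examples
#' tx <- PistonTransducer()
#' scan <- fieldOnPlane(tx, z = 16, halfWidth = 5.25, spacing = 0.7)
#' scan
#' @export
fieldOnPlane <- function(tx, z, halfWidth, spacing,
                         elementSize = wavelength(tx) / 20) {
  stopifnot(is(tx, "PistonTransducer"))
  z <- .scalarNum(z, "z")
  spacing <- .scalarNum(spacing, "spacing")
  halfWidth <- .scalarNum(halfWidth, "halfWidth")
  if (halfWidth < spacing) stop("'halfWidth' must be >= 'spacing'")
  n <- floor(halfWidth / spacing + 1e-9)
  coords <- (-n:n) * spacing
  g <- expand.grid(x = coords, y = coords)
  r <- sqrt(g$x^2 + g$y^2)
  key <- round(r, 9)
  ur <- sort(unique(key))
  pu <- radialPressure(tx, z, ur, elementSize = elementSize)
  p <- pu[match(key, ur)]
  PlanarScan(z = z, x = coords, y = coords,
             pressure = matrix(p, nrow = length(coords)),
             provenance = "simulated")
}

#' On-axis intensity sweep
#'
#' Relative acoustic intensity (pressure squared) down the centre of the
#' acoustic axis from `zMin` to `zMax` in steps of `dz` (the last point
#' is step-bounded: `seq(zMin, zMax, by = dz)`). The characterization
#' protocol sweeps 8-13 mm at 0.1 mm and 13-70 mm at 0.7 mm; run two
#' sweeps to reproduce it.
#'
#' @param tx a [PistonTransducer-class].
#' @param zMin,zMax axial range in mm, `0 < zMin < zMax`.
#' @param dz step in mm, > 0.
#' @return an [AxialProfile-class].
#' @export
axialSweep <- function(tx, zMin, zMax, dz) {
  stopifnot(is(tx, "PistonTransducer"))
  zMin <- .scalarNum(zMin, "zMin")
  zMax <- .scalarNum(zMax, "zMax")
  dz <- .scalarNum(dz, "dz")
  if (zMin >= zMax) stop("'zMin' must be < 'zMax'")
  z <- seq(zMin, zMax, by = dz)
  new("AxialProfile", z = z, intensity = onAxisPressure(tx, z)^2)
}
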