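#' Wavelength of a transducer in its medium
#'
#' @param object a [PistonTransducer-class].
#' @return wavelength in mm.
#' @export
setGeneric("wavelength", function(object) standardGeneric("wavelength"))

#' @rdname wavelength
#' @export
setMethod("wavelength", "PistonTransducer", function(object) {
  1e3 * object@soundSpeed / object@frequency
})

#' Relative intensity map of a planar scan
#'
#' `(pressure / max(pressure))^2`, in `[0, 1]`.
#'
#' @param object a [PlanarScan-class].
#' @return matrix of relative intensities.
#' @export
setGeneric("relativeIntensity",
           function(object) standardGeneric("relativeIntensity"))

#' @rdname relativeIntensity
#' @export
setMethod("relativeIntensity", "PlanarScan", function(object) {
  pmax <- max(object@pressure)
  if (pmax == 0) stop("degenerate scan: all pressures are zero")
  (object@pressure / pmax)^2
})

#' Number of objects in an ObjectSet
#'
#' @param object an [ObjectSet-class].
#' @return integer count.
#' @export
setGeneric("nObjects", function(object) standardGeneric("nObjects"))

#' @rdname nObjects
#' @export
setMethod("nObjects", "ObjectSet", function(object) nrow(object@objects))

setMethod("show", "PistonTransducer", function(object) {
  cat(sprintf(
    "PistonTransducer: radius %.3g mm, %.3g MHz, c = %g m/s (lambda = %.4g mm)\n",
    object@radius, object@frequency / 1e6, object@soundSpeed,
    wavelength(object)))
})

setMethod("show", "PlanarScan", function(object) {
  cat(sprintf(
    "PlanarScan (%s): z = %g mm, %d x %d grid, spacing %.3g mm, max pressure %.4g\n",
    object@provenance, object@z, length(object@x), length(object@y),
    if (length(object@x) > 1) diff(object@x)[1] else NA_real_,
    max(object@pressure)))
})

setMethod("show", "AxialProfile", function(object) {
  cat(sprintf("AxialProfile: %d points, z in [%g, %g] mm\n",
              length(object@z), min(object@z), max(object@z)))
})

setMethod("show", "TreatmentPlan", function(object) {
  cat(sprintf("TreatmentPlan: optimal z = %g mm (heterogeneity %.4g)\n",
              object@optimalZ, object@heterogeneityAtOptimum))
  if (length(object@calibration) == 3L)
    cat(sprintf("  calibration point: (%.2f, %.2f) mm at %.3f relative intensity\n",
                object@calibration[["x"]], object@calibration[["y"]],
                object@calibration[["value"]]))
  if (!is.na(object@crosstalkDb))
    cat(sprintf("  cross-talk at neighbour: %.2f dB\n", object@crosstalkDb))
})

setMethod("show", "ExposureProtocol", function(object) {
  cat(sprintf(
    "ExposureProtocol (%s): %.3g MHz, %.2g MPa PNP, %g cycles / %g us (duty %.3g %%, PRF %.3g kHz)\n",
    object@scheme, object@frequency / 1e6, object@peakNegativePressure,
    object@cyclesPerBurst, object@burstPeriod, dutyCycle(object),
    pulseRepetitionFrequency(object) / 1e3))
  cat(sprintf("  %g s/site x %d sites, %g s switch, %g s equalization -> %.3g min submerged\n",
              object@exposureDuration, as.integer(object@nSites),
              object@switchInterval, object@equalizationTime,
              submersionTime(object)))
})

setMethod("show", "ObjectSet", function(object) {
  cat(sprintf("ObjectSet (%s): %d objects, %d x %d raster, min area %g px\n",
              object@kind, nObjects(object), nrow(object@labels),
              ncol(object@labels), object@minObjectArea))
})

setMethod("show", "FovQuantification", function(object) {
  cat(sprintf(
    "FovQuantification: %d cells, %d transfected (%s), %d apoptotic (%s)\n",
    object@nCells, object@nTransfected,
    ifelse(is.na(object@transfectedFraction), "NA",
           sprintf("%.3f", object@transfectedFraction)),
    object@nApoptotic,
    ifelse(is.na(object@apoptoticFraction), "NA",
           sprintf("%.3f", object@apoptoticFraction))))
})

setMethod("show", "StatReport", function(object) {
  cat("StatReport\n")
  cat(sprintf("  assumptions: Shapiro-Wilk p = %.4g, Bartlett p = %.4g -> %s branch\n",
              object@shapiroP, object@bartlettP, object@branch))
  cat(sprintf("  treatment   p = %.4g\n", object@pTreatment))
  cat(sprintf("  temperature p = %.4g\n", object@pTemperature))
  if (is.na(object@pInteraction))
    cat("  interaction    not assessed (nonparametric branch)\n")
  else
    cat(sprintf("  interaction p = %.4g\n", object@pInteraction))
  if (length(object@posthoc))
    cat("  post hoc tables:", paste(names(object@posthoc), collapse = ", "), "\n")
})
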