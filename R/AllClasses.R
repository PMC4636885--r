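#' Flat circular piston transducer
#'
#' Geometry, drive frequency and medium of a single unfocused circular
#' source. All geometric quantities are in millimetres; the medium enters
#' only through the sound speed, so the 37 degC vs 42 degC bath comparison
#' amounts to changing `soundSpeed` (1524 vs 1532 m/s).
#'
#' @slot radius crystal radius in mm (nominal 10 for a 20-mm crystal).
#' @slot frequency drive frequency in Hz.
#' @slot soundSpeed medium sound speed in m/s (default 1524, water at
#'   37 degC).
#' @slot amplitudeScale dimensionless positive factor multiplying every
#'   simulated pressure; all pressures are relative units.
#' @export
setClass("PistonTransducer",
  representation(radius = "numeric", frequency = "numeric",
                 soundSpeed = "numeric", amplitudeScale = "numeric"),
  prototype(radius = 10, frequency = 1e6, soundSpeed = 1524,
            amplitudeScale = 1),
  validity = function(object) {
    msg <- character()
    for (s in c("radius", "frequency", "soundSpeed", "amplitudeScale")) {
      v <- slot(object, s)
      if (length(v) != 1L || !is.finite(v) || v <= 0)
        msg <- c(msg, sprintf("'%s' must be a single positive finite number", s))
    }
    if (length(msg)) msg else TRUE
  })

#' @describeIn PistonTransducer constructor.
#' @param radius,frequency,soundSpeed,amplitudeScale see slots.
#' @return a `PistonTransducer` object.
#' @examples
#' tx <- PistonTransducer()        # 20-mm crystal at 1 MHz in 37 degC water
#' wavelength(tx)                  # 1.524 mm
#' @export
PistonTransducer <- function(radius = 10, frequency = 1e6,
                             soundSpeed = 1524, amplitudeScale = 1) {
  new("PistonTransducer", radius = radius, frequency = frequency,
      soundSpeed = soundSpeed, amplitudeScale = amplitudeScale)
}

#' Planar pressure scan
#'
#' A regular x-y grid of relative pressure amplitudes at a fixed axial
#' distance `z`, the unit of field characterization (the in-silico
#' counterpart of one planar hydrophone scan).
#'
#' @slot z axial distance in mm.
#' @slot x,y regular coordinate grids in mm (uniform spacing).
#' @slot pressure matrix of nonnegative amplitudes, `length(x)` rows by
#'   `length(y)` columns, relative units.
#' @slot provenance `"simulated"` or `"measured-file"`.
#' @export
setClass("PlanarScan",
  representation(z = "numeric", x = "numeric", y = "numeric",
                 pressure = "matrix", provenance = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@z) != 1L || !is.finite(object@z))
      msg <- c(msg, "'z' must be a single finite number")
    if (!.isUniformGrid(object@x) || !.isUniformGrid(object@y))
      msg <- c(msg, "grid spacing must be uniform in each axis")
    if (!all(is.finite(object@pressure)) || any(object@pressure < 0))
      msg <- c(msg, "pressure values must be finite and >= 0")
    if (!identical(dim(object@pressure),
                   c(length(object@x), length(object@y))))
      msg <- c(msg, "pressure must be length(x) x length(y)")
    if (!object@provenance %in% c("simulated", "measured-file"))
      msg <- c(msg, "provenance must be 'simulated' or 'measured-file'")
    if (length(msg)) msg else TRUE
  })

#' @describeIn PlanarScan constructor.
#' @param z,x,y,pressure,provenance see slots.
#' @export
PlanarScan <- function(z, x, y, pressure, provenance = "simulated") {
  new("PlanarScan", z = as.numeric(z), x = as.numeric(x), y = as.numeric(y),
      pressure = pressure, provenance = provenance)
}

#' On-axis intensity profile
#'
#' Relative acoustic intensity sampled down the centre of the acoustic
#' axis.
#'
#' @slot z axial distances in mm, strictly increasing.
#' @slot intensity nonnegative relative intensities (pressure squared).
#' @export
setClass("AxialProfile",
  representation(z = "numeric", intensity = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@z) != length(object@intensity))
      msg <- c(msg, "z and intensity must have equal length")
    if (length(object@z) > 1L && any(diff(object@z) <= 0))
      msg <- c(msg, "z must be strictly increasing")
    if (any(!is.finite(object@intensity)) || any(object@intensity < 0))
      msg <- c(msg, "intensity must be finite and >= 0")
    if (length(msg)) msg else TRUE
  })

#' Heterogeneity-versus-distance curve
#'
#' Per-slice field heterogeneity (population standard deviation of the
#' pressure within a centred circular mask) along the acoustic axis.
#'
#' @slot z slice distances in mm.
#' @slot heterogeneity nonnegative values, relative pressure units.
#' @slot maskRadius radius of the circular mask in mm.
#' @export
setClass("HeterogeneityCurve",
  representation(z = "numeric", heterogeneity = "numeric",
                 maskRadius = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@z) != length(object@heterogeneity))
      msg <- c(msg, "z and heterogeneity must have equal length")
    if (any(object@heterogeneity < 0)) msg <- c(msg, "heterogeneity must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Treatment plan for one transducer
#'
#' The outcome of near-field characterization: the axial distance whose
#' slice is most homogeneous, the heterogeneity curve behind that choice,
#' optionally a calibration point of ~90 % relative intensity and the
#' cross-talk level at a neighbouring transducer.
#'
#' @slot optimalZ chosen treatment distance in mm.
#' @slot heterogeneityAtOptimum heterogeneity of the optimal slice.
#' @slot curve the full [HeterogeneityCurve-class] for audit/plotting.
#' @slot calibration named numeric `(x, y, value)`: grid point closest to
#'   the target relative intensity, or length 0 if not computed.
#' @slot crosstalkDb cross-talk level in dB (<= 0), `NA` if not computed.
#' @export
setClass("TreatmentPlan",
  representation(optimalZ = "numeric", heterogeneityAtOptimum = "numeric",
                 curve = "HeterogeneityCurve", calibration = "numeric",
                 crosstalkDb = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@curve@z) &&
        (object@optimalZ < min(object@curve@z) ||
         object@optimalZ > max(object@curve@z)))
      msg <- c(msg, "optimalZ must lie within the explored z range")
    if (length(object@calibration) == 3L) {
      v <- object@calibration[["value"]]
      if (!is.na(v) && (v < 0 || v > 1))
        msg <- c(msg, "calibration relative intensity must be in [0, 1]")
    }
    if (length(msg)) msg else TRUE
  })

#' Ultrasound exposure protocol
#'
#' Timing and pressure parameters of one treatment session. Defaults are
#' the validated protocol: 1-MHz pulses at 0.7 MPa peak-negative
#' pressure, bursts of 30 cycles every 625 us, 30 s per site, a 30-s
#' operator switch after each of the 6 sites, and 1 min of temperature
#' equalization.
#'
#' @slot frequency drive frequency, Hz.
#' @slot peakNegativePressure MPa (informational; no derived quantity
#'   depends on it).
#' @slot cyclesPerBurst cycles per burst.
#' @slot burstPeriod burst repetition period, microseconds.
#' @slot exposureDuration insonation time per site, seconds.
#' @slot switchInterval operator switch time after each site, seconds.
#' @slot equalizationTime bath temperature equalization, seconds.
#' @slot nSites number of exposure sites per chamber.
#' @slot scheme `"sequential"` (one transducer at a time) or
#'   `"concurrent"` (all sites insonated together).
#' @export
setClass("ExposureProtocol",
  representation(frequency = "numeric", peakNegativePressure = "numeric",
                 cyclesPerBurst = "numeric", burstPeriod = "numeric",
                 exposureDuration = "numeric", switchInterval = "numeric",
                 equalizationTime = "numeric", nSites = "numeric",
                 scheme = "character"),
  validity = function(object) {
    msg <- character()
    for (s in c("frequency", "peakNegativePressure", "cyclesPerBurst",
                "burstPeriod", "exposureDuration", "switchInterval",
                "equalizationTime")) {
      v <- slot(object, s)
      if (length(v) != 1L || !is.finite(v) || v <= 0)
        msg <- c(msg, sprintf("'%s' must be a single positive number", s))
    }
    if (object@nSites < 1 || object@nSites != round(object@nSites))
      msg <- c(msg, "'nSites' must be an integer >= 1")
    if (!object@scheme %in% c("sequential", "concurrent"))
      msg <- c(msg, "scheme must be 'sequential' or 'concurrent'")
    if (length(msg) == 0 &&
        object@cyclesPerBurst / object@frequency > object@burstPeriod * 1e-6)
      msg <- c(msg, "burst (cyclesPerBurst/frequency) must fit within burstPeriod")
    if (length(msg)) msg else TRUE
  })

#' @describeIn ExposureProtocol constructor.
#' @param frequency,peakNegativePressure,cyclesPerBurst,burstPeriod see slots.
#' @param exposureDuration,switchInterval,equalizationTime,nSites,scheme
#'   see slots.
#' @examples
#' p <- ExposureProtocol()
#' dutyCycle(p)        # 4.8 (%)
#' submersionTime(p)   # 7 (min)
#' @export
ExposureProtocol <- function(frequency = 1e6, peakNegativePressure = 0.7,
                             cyclesPerBurst = 30, burstPeriod = 625,
                             exposureDuration = 30, switchInterval = 30,
                             equalizationTime = 60, nSites = 6,
                             scheme = c("sequential", "concurrent")) {
  new("ExposureProtocol", frequency = frequency,
      peakNegativePressure = peakNegativePressure,
      cyclesPerBurst = cyclesPerBurst, burstPeriod = burstPeriod,
      exposureDuration = exposureDuration, switchInterval = switchInterval,
      equalizationTime = equalizationTime, nSites = nSites,
      scheme = match.arg(scheme))
}

#' Ultrasound contrast agent dose
#'
#' Dose arithmetic inputs for a microbubble contrast agent added to the
#' culture chamber. Defaults are 33 uL of activated agent (nominally
#' 1.2e10 microbubbles/mL) into 10 mL of media over 6e5 seeded cells.
#'
#' @slot stockConcentration microbubbles per mL of activated agent.
#' @slot addedVolume volume of agent added, uL.
#' @slot mediaVolume media volume in the chamber, mL.
#' @slot cellsSeeded number of cells seeded.
#' @export
setClass("UcaDose",
  representation(stockConcentration = "numeric", addedVolume = "numeric",
                 mediaVolume = "numeric", cellsSeeded = "numeric"),
  validity = function(object) {
    msg <- character()
    for (s in c("stockConcentration", "mediaVolume", "cellsSeeded")) {
      v <- slot(object, s)
      if (length(v) != 1L || !is.finite(v) || v <= 0)
        msg <- c(msg, sprintf("'%s' must be a single positive number", s))
    }
    if (length(object@addedVolume) != 1L || !is.finite(object@addedVolume) ||
        object@addedVolume < 0)
      msg <- c(msg, "'addedVolume' must be a single nonnegative number")
    if (length(msg)) msg else TRUE
  })

#' @describeIn UcaDose constructor.
#' @param stockConcentration,addedVolume,mediaVolume,cellsSeeded see slots.
#' @examples
#' d <- UcaDose()
#' microbubbleCellRatio(d)    # 660
#' ucaVolumeConcentration(d)  # 0.33 (%)
#' @export
UcaDose <- function(stockConcentration = 1.2e10, addedVolume = 33,
                    mediaVolume = 10, cellsSeeded = 6e5) {
  new("UcaDose", stockConcentration = stockConcentration,
      addedVolume = addedVolume, mediaVolume = mediaVolume,
      cellsSeeded = cellsSeeded)
}

#' Three-channel field-of-view micrograph
#'
#' Blue (nuclear stain), green (reporter antibody) and red (apoptosis
#' antibody) intensity rasters of one field of view, as captured by a
#' 12-bit camera.
#'
#' @slot blue,green,red numeric matrices of identical dimensions.
#' @slot bitDepth camera bit depth; values must lie in
#'   `[0, 2^bitDepth - 1]`.
#' @slot pixelSize pixel pitch in um, `NA` when unknown.
#' @export
setClass("FieldOfViewImages",
  representation(blue = "matrix", green = "matrix", red = "matrix",
                 bitDepth = "numeric", pixelSize = "numeric"),
  prototype(bitDepth = 12, pixelSize = NA_real_),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@blue), dim(object@green)) ||
        !identical(dim(object@blue), dim(object@red)))
      msg <- c(msg, "channels must have identical dimensions")
    lim <- 2^object@bitDepth - 1
    for (ch in c("blue", "green", "red")) {
      v <- slot(object, ch)
      if (!all(is.finite(v)) || any(v < 0) || any(v > lim))
        msg <- c(msg, sprintf("'%s' values must be finite and in [0, %d]",
                              ch, lim))
    }
    if (length(msg)) msg else TRUE
  })

#' @describeIn FieldOfViewImages constructor.
#' @param blue,green,red,bitDepth,pixelSize see slots.
#' @export
FieldOfViewImages <- function(blue, green, red, bitDepth = 12,
                              pixelSize = NA_real_) {
  new("FieldOfViewImages", blue = blue, green = green, red = red,
      bitDepth = bitDepth, pixelSize = pixelSize)
}

#' Segmented object set
#'
#' Labelled objects (nuclei or cell boundaries) of one field of view,
#' with per-object mean channel intensities and background statistics
#' computed over unlabelled pixels — the ingredients of the positivity
#' criterion `Ibar_obj >= Ibar_bg + n * sigma_bg`.
#'
#' @slot labels integer matrix, 0 = background, objects numbered 1..N.
#' @slot kind `"nuclei"` or `"cell_boundary"`.
#' @slot objects data.frame with one row per object: `label`,
#'   `seedLabel` (nucleus label that seeded a cell-boundary object;
#'   equals `label` for nuclei), `area` (px), `cx`, `cy` (centroid, px),
#'   `meanBlue`, `meanGreen`, `meanRed`.
#' @slot background data.frame with rows blue/green/red: `mean`, `sd`
#'   (population) and `nPixels` over label-0 pixels.
#' @slot minObjectArea the area filter that was applied, px.
#' @export
setClass("ObjectSet",
  representation(labels = "matrix", kind = "character",
                 objects = "data.frame", background = "data.frame",
                 minObjectArea = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("nuclei", "cell_boundary"))
      msg <- c(msg, "kind must be 'nuclei' or 'cell_boundary'")
    n <- nrow(object@objects)
    if (n > 0 && !identical(sort(object@objects$label), seq_len(n)))
      msg <- c(msg, "object labels must be the contiguous integers 1..N")
    if (n > 0 && any(object@objects$area < object@minObjectArea))
      msg <- c(msg, "every object must have area >= minObjectArea")
    if (length(msg)) msg else TRUE
  })

#' Quantification of one field of view
#'
#' Cell, transfection and apoptosis counts of one field of view.
#' Fractions are counts relative to the number of cells; with zero cells
#' they are reported as `NA` (missing), not 0.
#'
#' @slot nCells,nTransfected,nApoptotic counts.
#' @slot transfectedFraction,apoptoticFraction in `[0, 1]` or `NA`.
#' @export
setClass("FovQuantification",
  representation(nCells = "numeric", nTransfected = "numeric",
                 nApoptotic = "numeric", transfectedFraction = "numeric",
                 apoptoticFraction = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nTransfected > object@nCells ||
        object@nApoptotic > object@nCells)
      msg <- c(msg, "counts cannot exceed nCells")
    for (f in c("transfectedFraction", "apoptoticFraction")) {
      v <- slot(object, f)
      if (!is.na(v) && (v < 0 || v > 1))
        msg <- c(msg, sprintf("'%s' must be in [0, 1] or NA", f))
    }
    if (length(msg)) msg else TRUE
  })

#' Ground truth of a synthetic field of view
#'
#' @slot cells data.frame: `x`, `y` (centre, px), `nucleusRadius`,
#'   `cytoRadius` (px), logical `transfected`, `apoptotic`.
#' @slot params generator parameters (list), including the seed.
#' @export
setClass("FovGroundTruth",
  representation(cells = "data.frame", params = "list"))

#' Routed statistical report
#'
#' Result of the assumption-checked decision tree over the
#' 3-treatment x 3-temperature design: Shapiro-Wilk and Bartlett
#' p-values, the branch taken, main-effect (and, on the parametric
#' branch, interaction) p-values and post-hoc pairwise tables.
#'
#' @slot shapiroP,bartlettP assumption-test p-values.
#' @slot branch `"parametric"` or `"nonparametric"`.
#' @slot pTreatment,pTemperature,pInteraction effect p-values
#'   (`pInteraction` is `NA` on the nonparametric branch, where the
#'   interaction is not assessed).
#' @slot posthoc named list of pairwise tables (data.frames with adjusted
#'   p-values), one per significant factor; empty when nothing is
#'   significant.
#' @slot alpha significance level (0.05 a priori).
#' @export
setClass("StatReport",
  representation(shapiroP = "numeric", bartlettP = "numeric",
                 branch = "character", pTreatment = "numeric",
                 pTemperature = "numeric", pInteraction = "numeric",
                 posthoc = "list", alpha = "numeric"),
  validity = function(object) {
    msg <- character()
    ps <- c(object@shapiroP, object@bartlettP, object@pTreatment,
            object@pTemperature, object@pInteraction)
    ps <- ps[!is.na(ps)]
    if (any(ps < 0 | ps > 1)) msg <- c(msg, "p-values must be in [0, 1]")
    if (!object@branch %in% c("parametric", "nonparametric"))
      msg <- c(msg, "branch must be 'parametric' or 'nonparametric'")
    if (length(msg)) msg else TRUE
  })
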