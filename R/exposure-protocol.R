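# Dosimetry and timing arithmetic for one treatment session. Every
# quantity is derived from the protocol/dose parameters; nothing is
# hard-coded beyond the defaults of the constructors.

#' Duty cycle of a pulsed exposure
#'
#' Percentage of time ultrasound is on:
#' `100 * (cyclesPerBurst / frequency) / burstPeriod`. The validated
#' protocol (30 cycles at 1 MHz every 625 us) gives 4.8 %.
#'
#' @param p an [ExposureProtocol-class].
#' @return duty cycle in percent.
#' @export
dutyCycle <- function(p) {
  stopifnot(is(p, "ExposureProtocol"))
  burst <- p@cyclesPerBurst / p@frequency        # s
  100 * burst / (p@burstPeriod * 1e-6)
}

#' Pulse repetition frequency
#'
#' Reciprocal of the burst period: 625 us gives 1.6 kHz.
#'
#' @param p an [ExposureProtocol-class].
#' @return PRF in Hz.
#' @export
pulseRepetitionFrequency <- function(p) {
  stopifnot(is(p, "ExposureProtocol"))
  1 / (p@burstPeriod * 1e-6)
}

#' Microbubble-to-cell ratio
#'
#' Number of microbubbles added per seeded cell:
#' `stockConcentration * addedVolume / cellsSeeded` (volumes converted
#' consistently). The default dose (33 uL of 1.2e10/mL over 6e5 cells)
#' gives 660.
#'
#' @param d a [UcaDose-class].
#' @return dimensionless ratio.
#' @export
microbubbleCellRatio <- function(d) {
  stopifnot(is(d, "UcaDose"))
  d@stockConcentration * (d@addedVolume * 1e-3) / d@cellsSeeded
}

#' Contrast-agent volume concentration
#'
#' `100 * addedVolume / mediaVolume`, following the reporting convention
#' that divides by the stated media volume alone (not media + agent):
#' 33 uL in 10 mL is 0.33 %.
#'
#' @param d a [UcaDose-class].
#' @return percent.
#' @export
ucaVolumeConcentration <- function(d) {
  stopifnot(is(d, "UcaDose"))
  100 * (d@addedVolume * 1e-3) / d@mediaVolume
}

#' Total submersion time of one chamber
#'
#' Sequential scheme: equalization + nSites * (exposure + switch); the
#' operator switch is counted after every site including the last, which
#' is what makes the default protocol total 1 + 6 x 1 = 7 min.
#' Concurrent scheme (all sites insonated together): equalization +
#' exposure, 1.5 min under the defaults.
#'
#' @param p an [ExposureProtocol-class].
#' @return minutes.
#' @export
submersionTime <- function(p) {
  stopifnot(is(p, "ExposureProtocol"))
  s <- switch(p@scheme,
    sequential = p@equalizationTime +
      p@nSites * (p@exposureDuration + p@switchInterval),
    concurrent = p@equalizationTime + p@exposureDuration)
  s / 60
}

#' Relative change in sound speed between two bath temperatures
#'
#' `100 * (cHigh - cLow) / cLow`. For water at 37 vs 42 degC
#' (1524 vs 1532 m/s) this is approximately 0.52 % (commonly rounded to
#' 0.53); the value is approximate also because the denominator
#' convention is not universal.
#'
#' @param cLow,cHigh sound speeds in m/s.
#' @return percent.
#' @export
soundSpeedRelativeChange <- function(cLow, cHigh) {
  cLow <- .scalarNum(cLow, "cLow")
  cHigh <- .scalarNum(cHigh, "cHigh", positive = FALSE)
  100 * (cHigh - cLow) / cLow
}

#' All derived dosimetry quantities of a session
#'
#' @param p an [ExposureProtocol-class].
#' @param d a [UcaDose-class].
#' @return named list: `dutyCyclePercent`, `prfHz`,
#'   `microbubbleCellRatio`, `ucaVolumePercent`,
#'   `submersionTimeMinutes`.
#' @examples
#' exposureReport(ExposureProtocol(), UcaDose())
#' @export
exposureReport <- function(p = ExposureProtocol(), d = UcaDose()) {
  list(dutyCyclePercent = dutyCycle(p),
       prfHz = pulseRepetitionFrequency(p),
       microbubbleCellRatio = microbubbleCellRatio(d),
       ucaVolumePercent = ucaVolumeConcentration(d),
       submersionTimeMinutes = submersionTime(p))
}
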