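# Cell-detachment scoring from marker ("dot") images.
#
# Detachment is imaged by phase contrast before and after treatment;
# each cell is marked manually with a dot on a blank background and the
# dot images are counted automatically. The computational input here is
# the marker image, not the raw phase-contrast frame.

#' Count markers in a dot image
#'
#' Binarizes a (near-)binary raster at the midpoint of its range,
#' labels 8-connected components and counts those larger than one
#' pixel (single-pixel specks are ignored).
#'
#' @param dotImage numeric matrix; dots are the bright phase.
#' @return integer count.
#' @export
countMarkers <- function(dotImage) {
  stopifnot(is.matrix(dotImage))
  rng <- range(dotImage)
  if (diff(rng) == 0) return(0L)       # blank image
  mask <- dotImage > mean(rng)
  lab <- .label8(mask)
  if (max(lab) == 0) return(0L)
  sum(tabulate(lab[lab > 0], nbins = max(lab)) > 1L)
}

#' Relative change in average cell count
#'
#' `100 * (mean(after) - mean(before)) / mean(before)`; negative values
#' represent cell loss. With nonnegative counts the statistic is bounded
#' below by -100 %. Order of the spots is immaterial (mean-based).
#'
#' @param before,after numeric vectors of per-spot cell counts (the
#'   protocol takes 3 spots per exposure area, 18 per replicate).
#' @return percent change.
#' @examples
#' cellLoss(rep(100, 3), rep(69, 3))  # -31
#' @export
cellLoss <- function(before, after) {
  if (!is.numeric(before) || !is.numeric(after) ||
      length(before) == 0 || length(after) == 0)
    stop("'before' and 'after' must be non-empty numeric vectors")
  if (any(before < 0) || any(after < 0)) stop("counts must be >= 0")
  mb <- mean(before)
  if (mb <= 0) stop("undefined baseline: mean of 'before' counts is zero")
  100 * (mean(after) - mb) / mb
}

#' Detachment record for one replicate
#'
#' Convenience constructor bundling before/after counts with the
#' relative change.
#'
#' @param countsBefore,countsAfter numeric count vectors.
#' @return list with `countsBefore`, `countsAfter`, `relativeChange`
#'   (percent).
#' @export
detachmentRecord <- function(countsBefore, countsAfter) {
  list(countsBefore = countsBefore, countsAfter = countsAfter,
       relativeChange = cellLoss(countsBefore, countsAfter))
}
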