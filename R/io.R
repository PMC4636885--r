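# Plain-text and image I/O: planar scans and axial profiles as CSV,
# field-of-view channels as 16-bit TIFF (or PNG on input), replicate
# tables as CSV, plans and statistical reports as JSON.

#' Write / read a planar scan as CSV
#'
#' Format: a first line `# z_mm=<z>`, then columns `x_mm`, `y_mm`,
#' `pressure` in long form.
#'
#' @param scan a [PlanarScan-class].
#' @param path file path.
#' @return `writePlanarScan` invisibly returns `path`; `readPlanarScan`
#'   returns a [PlanarScan-class] with provenance `"measured-file"`.
#' @export
writePlanarScan <- function(scan, path) {
  stopifnot(is(scan, "PlanarScan"))
  g <- expand.grid(x_mm = scan@x, y_mm = scan@y)
  df <- data.frame(g, pressure = as.vector(scan@pressure))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# z_mm=%.10g", scan@z), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePlanarScan
#' @export
readPlanarScan <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("^#\\s*z_mm=", header))
    stop("not a planar-scan CSV: missing '# z_mm=' header")
  z <- as.numeric(sub("^#\\s*z_mm=", "", header))
  df <- read.csv(path, comment.char = "#")
  x <- sort(unique(df$x_mm))
  y <- sort(unique(df$y_mm))
  p <- matrix(NA_real_, length(x), length(y))
  p[cbind(match(df$x_mm, x), match(df$y_mm, y))] <- df$pressure
  if (any(is.na(p))) stop("scan grid is incomplete")
  PlanarScan(z = z, x = x, y = y, pressure = p,
             provenance = "measured-file")
}

#' Write / read an axial profile as CSV
#'
#' Columns `z_mm`, `intensity`.
#'
#' @param profile an [AxialProfile-class].
#' @param path file path.
#' @export
writeAxialProfile <- function(profile, path) {
  stopifnot(is(profile, "AxialProfile"))
  write.csv(data.frame(z_mm = profile@z, intensity = profile@intensity),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeAxialProfile
#' @export
readAxialProfile <- function(path) {
  df <- read.csv(path)
  new("AxialProfile", z = df$z_mm, intensity = df$intensity)
}

# read one channel raster from TIFF or PNG; returns integer counts.
# 16-bit TIFF/PNG decode to [0, 1] scaled by 65535; 8-bit files by 255.
# Segmentation and the positivity criterion are invariant under that
# affine scale, so the bit depth of the container does not matter.
.readChannel <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # grey data in channel 1
  round(img * 65535)
}

#' Write a field of view as 16-bit TIFF triplet
#'
#' Writes `<prefix>_blue.tif`, `<prefix>_green.tif`,
#' `<prefix>_red.tif`, storing raw counts scaled into the 16-bit range.
#'
#' @param fov a [FieldOfViewImages-class].
#' @param prefix path prefix.
#' @return invisibly, the three paths written.
#' @export
writeFov <- function(fov, prefix) {
  stopifnot(is(fov, "FieldOfViewImages"))
  paths <- character(3)
  chans <- c("blue", "green", "red")
  for (i in seq_along(chans)) {
    paths[i] <- paste0(prefix, "_", chans[i], ".tif")
    tiff::writeTIFF(slot(fov, chans[i]) / 65535, paths[i],
                    bits.per.sample = 16L)
  }
  invisible(paths)
}

#' Read a field of view from per-channel image files
#'
#' @param blue,green,red paths to single-channel TIFF or PNG images.
#' @param bitDepth declared camera bit depth of the stored counts.
#' @param pixelSize optional pixel pitch in um.
#' @return a [FieldOfViewImages-class].
#' @export
readFov <- function(blue, green, red, bitDepth = 12,
                    pixelSize = NA_real_) {
  FieldOfViewImages(blue = .readChannel(blue), green = .readChannel(green),
                    red = .readChannel(red), bitDepth = bitDepth,
                    pixelSize = pixelSize)
}

#' Quantify a manifest of fields of view
#'
#' The manifest CSV must have columns `fov_id`, `replicate`, `group`,
#' `blue`, `green`, `red` (image paths, relative to the manifest's
#' directory unless absolute). Each field of view is quantified with
#' [quantifyFov()] and the per-FOV fractions are averaged per
#' (group, replicate) with [replicateAverage()].
#'
#' @param path manifest CSV path.
#' @param n standard-deviation multiplier of the positivity criterion.
#' @param minObjectArea minimum object area in px.
#' @return list with `perFov` and `perReplicate` data.frames.
#' @export
quantifyManifest <- function(path, n = 3, minObjectArea = 30) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("fov_id", "replicate", "group", "blue", "green", "red")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  quants <- lapply(seq_len(nrow(man)), function(i) {
    fov <- readFov(resolve(man$blue[i]), resolve(man$green[i]),
                   resolve(man$red[i]))
    quantifyFov(fov, n = n, minObjectArea = minObjectArea)
  })
  perFov <- data.frame(
    fov_id = man$fov_id, replicate = man$replicate, group = man$group,
    n_cells = vapply(quants, function(q) q@nCells, numeric(1)),
    n_transfected = vapply(quants, function(q) q@nTransfected, numeric(1)),
    n_apoptotic = vapply(quants, function(q) q@nApoptotic, numeric(1)),
    transfected_fraction =
      vapply(quants, function(q) q@transfectedFraction, numeric(1)),
    apoptotic_fraction =
      vapply(quants, function(q) q@apoptoticFraction, numeric(1)))
  keys <- unique(perFov[, c("group", "replicate")])
  perReplicate <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- perFov$group == keys$group[i] &
      perFov$replicate == keys$replicate[i]
    avg <- replicateAverage(quants[sel])
    data.frame(group = keys$group[i], replicate = keys$replicate[i], avg)
  }))
  list(perFov = perFov, perReplicate = perReplicate)
}

#' Read a replicate response table from CSV
#'
#' Columns `treatment`, `temperature`, `replicate`, `response`.
#'
#' @param path CSV path.
#' @return validated replicate table (see [asReplicateTable()]).
#' @export
readReplicateTable <- function(path) {
  asReplicateTable(read.csv(path, stringsAsFactors = FALSE))
}

#' Write a statistical report as JSON
#'
#' @param report a [StatReport-class].
#' @param path output path.
#' @export
writeStatReport <- function(report, path) {
  stopifnot(is(report, "StatReport"))
  jsonlite::write_json(list(
    shapiro_p = report@shapiroP, bartlett_p = report@bartlettP,
    branch = report@branch, p_treatment = report@pTreatment,
    p_temperature = report@pTemperature,
    p_interaction = report@pInteraction,
    posthoc = report@posthoc, alpha = report@alpha),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write a treatment plan as JSON
#'
#' @param plan a [TreatmentPlan-class].
#' @param path output path.
#' @export
writeTreatmentPlan <- function(plan, path) {
  stopifnot(is(plan, "TreatmentPlan"))
  jsonlite::write_json(list(
    optimal_z_mm = plan@optimalZ,
    heterogeneity_at_optimum = plan@heterogeneityAtOptimum,
    curve = data.frame(z_mm = plan@curve@z,
                       heterogeneity = plan@curve@heterogeneity),
    mask_radius_mm = plan@curve@maskRadius,
    calibration_point = if (length(plan@calibration) == 3L)
      as.list(plan@calibration) else NULL,
    crosstalk_db = plan@crosstalkDb),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
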