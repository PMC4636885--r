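# shared fixtures and independent oracles used across test files

popVar <- function(x) mean((x - mean(x))^2)
popSd <- function(x) sqrt(popVar(x))

# exhaustive Otsu oracle: minimizes the weighted intra-class variance
# over all candidate cuts (midpoints between consecutive distinct
# levels); first strict minimum wins, mirroring a deterministic
# tie-break toward the smaller cut.
oracleOtsu <- function(v) {
  v <- as.vector(v)
  u <- sort(unique(v))
  best <- NA_real_
  bestVar <- Inf
  for (i in seq_len(length(u) - 1L)) {
    t <- (u[i] + u[i + 1L]) / 2
    lo <- v[v <= t]
    hi <- v[v > t]
    w <- length(lo) / length(v)
    intra <- w * popVar(lo) + (1 - w) * popVar(hi)
    if (intra < bestVar - 1e-12) {
      bestVar <- intra
      best <- t
    }
  }
  best
}

intraClassVariance <- function(v, t) {
  v <- as.vector(v)
  lo <- v[v <= t]
  hi <- v[v > t]
  w <- length(lo) / length(v)
  w * popVar(lo) + (1 - w) * popVar(hi)
}

# paint a filled disk of value v into matrix m (rows = x, cols = y)
paintDisk <- function(m, cx, cy, r, v) {
  m[(row(m) - cx)^2 + (col(m) - cy)^2 <= r^2] <- v
  m
}

# build an ObjectSet by hand from per-object channel means and
# background statistics; lets criterion tests control every ingredient
manualObjectSet <- function(objMeans, bgMean, bgSd, nPixels = 100,
                            kind = "nuclei") {
  n <- length(objMeans)
  objects <- data.frame(label = seq_len(n), seedLabel = seq_len(n),
                        area = 50, cx = 0, cy = 0, meanBlue = objMeans,
                        meanGreen = objMeans, meanRed = objMeans)
  background <- data.frame(channel = c("blue", "green", "red"),
                           mean = bgMean, sd = bgSd, nPixels = nPixels)
  new("ObjectSet", labels = matrix(0L, 1, 1), kind = kind,
      objects = objects, background = background, minObjectArea = 1)
}

# balanced 3 x 3 replicate-table skeleton
designGrid <- function(nReplicates = 3) {
  g <- expand.grid(temperature = c("37", "39.5", "42"),
                   treatment = c("US+UCA", "US", "UCA"),
                   replicate = seq_len(nReplicates),
                   stringsAsFactors = FALSE)
  g[, c("treatment", "temperature", "replicate")]
}

nullGroupSpec <- function(mean = 5, sd = 1) {
  g <- expand.grid(temperature = c("37", "39.5", "42"),
                   treatment = c("US+UCA", "US", "UCA"),
                   stringsAsFactors = FALSE)
  data.frame(treatment = g$treatment, temperature = g$temperature,
             mean = mean, sd = sd)
}
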