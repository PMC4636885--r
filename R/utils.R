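# internal helpers shared across modules

# population standard deviation (descriptive statistic over a fixed grid)
.popSd <- function(x) sqrt(mean((x - mean(x))^2))

# evaluate `expr` under a temporary RNG state seeded with `seed`;
# the caller's .Random.seed is restored afterwards so generators are
# pure functions of (parameters, seed). seed = NULL leaves the RNG alone.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.scalarNum <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  as.numeric(x)
}

# uniform grid check with tolerance relative to the spacing
.isUniformGrid <- function(v, tol = 1e-8) {
  if (length(v) < 2L) return(TRUE)
  d <- diff(v)
  all(abs(d - d[1L]) <= tol * max(abs(d[1L]), 1))
}
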