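# Internal helpers: seeded evaluation without touching global RNG state,
# and instrumentation counters used by the tuning tests.

.cs_counters <- new.env(parent = emptyenv())
.cs_counters$calibrationFits <- 0L

.bumpCalibrationFits <- function() {
  .cs_counters$calibrationFits <- .cs_counters$calibrationFits + 1L
}

.calibrationFitCount <- function() .cs_counters$calibrationFits

# Evaluate expr with a local RNG seeded at `seed`; the caller's RNG state
# is restored afterwards so no operation leaks global randomness.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Coerce any matrix-like to the dgCMatrix the scorers consume.
.asDgc <- function(x) {
  if (is(x, "dgCMatrix")) return(x)
  as(as(as(Matrix(as.matrix(x), sparse = TRUE), "dMatrix"),
        "generalMatrix"), "CsparseMatrix")
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
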