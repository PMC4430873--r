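#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that a run is reproducible from its recorded seed and so
#' that calling them never perturbs the user's RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Convert 0-based half-open intervals to IRanges (1-based closed).
.as_iranges <- function(start0, end0) {
  IRanges::IRanges(start = start0 + 1L, end = end0)
}

# Count, for each half-open query interval on one chromosome, the number of
# positions from a sorted integer vector falling inside it.
.count_in_intervals <- function(pos_sorted, start0, end0) {
  findInterval(end0 - 1L, pos_sorted) - findInterval(start0 - 1L, pos_sorted)
}

.stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")))
  }
}
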