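# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so seeded simulation calls do
#' not disturb the caller's RNG stream. A `NULL` seed evaluates `code` in the
#' current stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-stream seed for a pipeline stage. Kept below 2^31 - 1 so
# it is always a valid R integer seed.
sub_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + offset) %% 2147483647L)
}

stop_radgut <- function(fmt, ..., class = "radgut_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

# Full-precision numeric formatting for plain-text result files: %.17g round
# trips IEEE doubles exactly through read.delim().
fmt_full <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  out[ok] <- sprintf("%.17g", x[ok])
  out
}
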