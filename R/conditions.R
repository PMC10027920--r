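#' @keywords internal
#' @import data.table
"_PACKAGE"

# Condition helpers. Three classes map onto the CLI exit-code contract:
#   eat_param_error  -> exit 2 (bad parameters / config)
#   eat_data_error   -> exit 1 (runtime or data problem)
#   eat_format_error -> exit 1 (malformed input file; subclass of data error)

stop_param <- function(...) {
  stop(structure(
    class = c("eat_param_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_data <- function(...) {
  stop(structure(
    class = c("eat_data_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_format <- function(...) {
  stop(structure(
    class = c("eat_format_error", "eat_data_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so simulation calls never leak into the global random stream.
with_rng_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_param("seed must be a single integer")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
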