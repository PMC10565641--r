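#' @importFrom stats runif setNames
#' @importFrom utils read.delim write.table modifyList
NULL

# The 20 standard amino-acid one-letter codes, alphabetical.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Ambiguity / non-standard codes tolerated in proteome sequences. They never
# satisfy an explicit residue class but do satisfy wildcard columns.
AA_AMBIGUITY <- c("X", "B", "Z", "U", "O")

#' Signal a validation error
#'
#' Validation errors (bad inputs, malformed files, inconsistent configuration)
#' carry the condition class `degscan_validation_error` so callers — in
#' particular the command-line driver — can distinguish them from runtime
#' failures.
#'
#' @param ... passed to [sprintf()] to build the message.
#' @keywords internal
stop_validation <- function(...) {
  msg <- sprintf(...)
  stop(structure(
    class = c("degscan_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Stage-tagged logging to stderr.
log_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# Evaluate `expr` under a given RNG seed, restoring the caller's RNG state.
# Generators built on this are pure functions of (arguments, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Split a string into single characters.
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]
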