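# Internal helpers shared across modules.

#' The 20 standard amino-acid one-letter codes
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aminoAcids()
aminoAcids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's stream.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# Derive a reproducible child seed from a base seed; offsets keep distinct
# stages on distinct streams while staying inside 32-bit integer range.
childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assertScalarNumber <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}

# Split a sequence string into single-character tokens.
seqChars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]
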