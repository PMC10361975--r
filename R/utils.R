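# Internal helpers: seeding, mode with deterministic tie-break, checks.

# Derive a stream of child seeds from one master seed without disturbing the
# caller's RNG state beyond the set.seed() call. Seeds stay below 2^31 - 1.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 0)
  if (n == 0) return(integer(0))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Mode of a character vector over declared levels; ties broken by the
# earliest level (lowest ordinal code). NA values are ignored; returns NA
# when everything is missing.
mode_categorical <- function(x, levels) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_character_)
  counts <- table(factor(x, levels = levels))
  levels[which.max(counts)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop("'", name, "' must be a single finite number", call. = FALSE)
  }
  invisible(x)
}
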