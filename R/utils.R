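# Internal helpers shared across modules.

stopf <- function(fmt, ..., class = "bt_validation_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == as.integer(x)
}

#' Reverse complement of plain character sequences
#' @param x character vector of DNA sequences (A,C,G,T,N).
#' @return character vector of the same length.
#' @keywords internal
#' @noRd
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(b) {
  chartr("ACGTN", "TGCAN", b)
}

# Run `code` under a fixed RNG state, restoring the caller's state after.
# All synthetic-data generators route their randomness through this so that
# they are pure functions of (parameters, seed).
with_seed <- function(seed, code) {
  if (!is_count(seed, min = 0)) stopf("seed must be a non-negative integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

assert_dna <- function(seq, what = "sequence", allow_n = TRUE) {
  if (!is_string(seq) || nchar(seq) == 0)
    stopf("%s must be a non-empty string", what)
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  if (!grepl(pat, seq))
    stopf("%s contains characters outside %s", what,
          if (allow_n) "A,C,G,T,N" else "A,C,G,T")
  invisible(seq)
}
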