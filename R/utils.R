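# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded simulation helpers do not
#' disturb the caller's RNG stream.
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Round half up: printed percentages such as "24%" are conventional
## half-up roundings, whereas base round() rounds half to even.
roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

## Convert a printed (rounded) percentage back to a count.
pctToCount <- function(pct, total) {
  as.integer(roundHalfUp(pct / 100 * total))
}

.DNA_ALPHABET <- c("A", "C", "G", "T")

.checkDnaString <- function(x, what = "sequence", allowN = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
  allowed <- if (allowN) "ACGTN" else "ACGT"
  if (grepl(sprintf("[^%s]", allowed), x))
    stop(what, " contains characters outside {", allowed, "}", call. = FALSE)
  invisible(x)
}

## Reverse complement of a plain character vector of DNA strings.
revComp <- function(x) {
  if (length(x) == 1L)  # byte-level fast path for the per-read caller
    return(rawToChar(rev(charToRaw(chartr("ACGTN", "TGCAN", x)))))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Per-position Hamming mismatch profile
#'
#' Number of mismatching bases when `pattern` is laid over `subject` at each
#' possible start position (vectorised byte comparison; any non-identical
#' byte, including N, counts as a mismatch).
#'
#' @return integer vector of length `nchar(subject) - nchar(pattern) + 1`
#'   (empty when the pattern is longer than the subject).
#' @noRd
mismatchProfile <- function(subject, pattern) {
  s <- charToRaw(subject)
  p <- charToRaw(pattern)
  m <- length(p)
  n <- length(s) - m + 1L
  if (n < 1L) return(integer(0))
  mism <- integer(n)
  for (j in seq_len(m)) {
    mism <- mism + (s[j:(j + n - 1L)] != p[j])
  }
  mism
}

## Hamming distance between two equal-length strings.
hammingDistance <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}
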