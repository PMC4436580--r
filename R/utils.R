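# Shared alphabets and small helpers.

# The 20 standard amino acids, fixed order used throughout scoring code.
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

DNA_BASES <- c("A", "C", "G", "T")

#' Uniform amino-acid background distribution
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @keywords internal
uniform_background <- function() {
  setNames(rep(1 / 20, 20), AA_ALPHABET)
}

# Run `expr` under a private RNG stream seeded with `seed`, leaving the
# caller's RNG state untouched. All generators route randomness through this.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Derive a child seed from a master seed for documented stream-splitting.
# Keeps results below 2^31 - 1 and deterministic.
split_seed <- function(seed, index) {
  (as.double(seed) * 48271 + 11 * as.double(index)) %% 2147483587 + 1
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA strings (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("GAATATAC")
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(
    strsplit(x, ""),
    function(s) paste(rev(s), collapse = ""),
    character(1)
  ))
}

# split a protein/DNA string into a character vector
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a
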