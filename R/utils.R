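# Shared sequence utilities and seeded-RNG helpers.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "GATTACA"))
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Run `expr` under a derived RNG state without touching the caller's stream.
# `seed` may be NULL (use current stream as-is).
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Derive a distinct 31-bit sub-seed from a master seed and a stream index.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1009 * k) %% 2147483647L)
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T}: %s",
                 what, paste(head(x[bad], 3), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}
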