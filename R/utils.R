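BASES <- c("A", "C", "G", "T")

#' Random DNA strings
#' @param n number of strings
#' @param len length of each string
#' @return character vector of `n` sequences over ACGT
#' @keywords internal
random_dna <- function(n, len) {
  m <- matrix(sample(BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#' @param x character vector of DNA sequences
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(b) chartr("ACGTN", "TGCAN", b)

#' Draw a substitute base different from the current one
#' @keywords internal
other_base <- function(b) {
  n <- length(b)
  if (n == 0L) return(character(0))
  off <- sample.int(3L, n, replace = TRUE)
  idx <- match(b, BASES)
  BASES[((idx - 1L + off) %% 4L) + 1L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
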