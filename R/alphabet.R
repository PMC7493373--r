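#' @importFrom stats setNames
NULL

# The nucleotide alphabet: the four concrete bases plus the IUPAC
# degenerate-base codes. Each code denotes a set of concrete bases.
IUPAC_BASES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

DNA_ALPHABET <- names(IUPAC_BASES)
AMBIGUITY_CODES <- setdiff(DNA_ALPHABET, c("A", "C", "G", "T"))

# Set-wise complement: bases(complement(c)) == complement(bases(c)).
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

# End-marker symbol as it appears in the in-memory eBWT symbol vector and in
# cluster profiles. All per-sequence end markers collapse to this one symbol
# outside of suffix sorting.
END_MARKER <- "$"

#' Reverse complement of a nucleotide sequence with IUPAC codes
#'
#' Complements every symbol set-wise (e.g. the purine code `R` = \{A,G\}
#' becomes the pyrimidine code `Y` = \{C,T\}) and reverses the result.
#' The operation is an involution: applying it twice returns the input.
#'
#' @param seq A character scalar over the IUPAC nucleotide alphabet
#'   (case-insensitive).
#' @return A character scalar, the reverse complement.
#' @examples
#' reverse_complement("GGCGTACCA")
#' reverse_complement("AR")  # "YT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  comp <- IUPAC_COMPLEMENT[chars]
  if (anyNA(comp)) {
    bad <- which(is.na(comp))[1]
    stop(sprintf("no complement for symbol '%s' at position %d", chars[bad], bad))
  }
  paste(rev(comp), collapse = "")
}

# Validate a vector of sequence characters; returns invisibly or stops
# naming the offending record and position.
check_alphabet <- function(chars, id) {
  bad <- which(!(chars %in% DNA_ALPHABET))
  if (length(bad)) {
    stop(sprintf(
      "record '%s': symbol '%s' at position %d is not in the IUPAC nucleotide alphabet",
      id, chars[bad[1]], bad[1]
    ))
  }
  invisible(TRUE)
}
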