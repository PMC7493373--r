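#' Assemble a read+genome sequence collection
#'
#' A collection is the ordered set of sequences the index is built over:
#' reads first (colors `1..r`), genomes after (colors `r+1..r+g`). Each
#' sequence is a string over the IUPAC nucleotide alphabet; sequences are
#' uppercased and validated on construction.
#'
#' @param reads Named character vector of read sequences (names are ids).
#' @param genomes Named character vector of genome sequences.
#' @return An object of class `seq_collection` with elements `ids`, `seqs`,
#'   `role` (`"read"`/`"genome"`), `r`, `g`, `m` and per-sequence `lengths`.
#' @examples
#' sequence_collection(c(read1 = "ACGT"), c(gen1 = "ACGTACGT"))
#' @export
sequence_collection <- function(reads, genomes) {
  stopifnot(is.character(reads), is.character(genomes), length(reads) >= 1L)
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  if (is.null(names(genomes)) && length(genomes)) {
    names(genomes) <- paste0("genome", seq_along(genomes))
  }
  seqs <- toupper(c(reads, genomes))
  ids <- names(seqs)
  if (anyDuplicated(ids)) stop("duplicated sequence ids in collection")
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L) stop(sprintf("record '%s' is empty", ids[i]))
    check_alphabet(strsplit(seqs[i], "", fixed = TRUE)[[1]], ids[i])
  }
  r <- length(reads); g <- length(genomes)
  structure(list(
    ids = unname(ids), seqs = unname(seqs),
    role = c(rep("read", r), rep("genome", g)),
    r = r, g = g, m = r + g,
    lengths = unname(nchar(seqs))
  ), class = "seq_collection")
}

#' @export
print.seq_collection <- function(x, ...) {
  cat(sprintf("seq_collection: %d reads + %d genomes (total length %d)\n",
              x$r, x$g, sum(x$lengths)))
  invisible(x)
}

# Read a FASTA/FASTQ file into a named uppercase character vector, with our
# own alphabet diagnostics (record id and offending position).
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    if (length(first) == 0L) stop(sprintf("file '%s' is empty", path))
    format <- if (startsWith(first, "@")) "fastq" else "fasta"
  }
  ss <- Biostrings::readBStringSet(path, format = format)
  if (length(ss) == 0L) stop(sprintf("file '%s' contains no records", path))
  seqs <- toupper(as.character(ss))
  # FASTA headers may carry descriptions; keep the first token as id
  names(seqs) <- vapply(strsplit(names(ss), "[ \t]"), `[[`, "", 1L)
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L) stop(sprintf("record '%s' in '%s' is empty", names(seqs)[i], path))
    check_alphabet(strsplit(seqs[i], "", fixed = TRUE)[[1]], names(seqs)[i])
  }
  seqs
}

#' Load a read file and a genome file into a collection
#'
#' Reads come first in color order, genomes after; record order follows file
#' order. Reads may be FASTA or FASTQ (qualities are discarded); genomes are
#' FASTA. Sequences are uppercased; any symbol outside the IUPAC nucleotide
#' alphabet is rejected with the offending record id and position.
#'
#' @param reads_path Path to the read file (FASTA or FASTQ).
#' @param genomes_path Path to the genome FASTA file.
#' @return A `seq_collection`.
#' @export
load_collection <- function(reads_path, genomes_path) {
  reads <- read_sequences(reads_path)
  genomes <- read_sequences(genomes_path, format = "fasta")
  sequence_collection(reads, genomes)
}
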