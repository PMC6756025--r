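# Reference sequence container: a named set of contigs with bounds-checked
# slicing. Deliberately minimal -- consequence prediction needs random access
# to small windows, nothing more.

#' Create a genome sequence object
#'
#' @param contigs Named character vector of nucleotide strings
#'   (alphabet A, C, G, T, N; case-insensitive on input). Every contig must be
#'   non-empty and named.
#' @return An object of class `genome_sequence`.
#' @examples
#' genome_sequence(c(chr1 = "ACGTACGT"))
#' @export
genome_sequence <- function(contigs) {
  if (!is.character(contigs) || length(contigs) == 0L) {
    stop("contigs must be a non-empty named character vector", call. = FALSE)
  }
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))) ||
      anyDuplicated(names(contigs))) {
    stop("every contig must carry a unique non-empty name", call. = FALSE)
  }
  contigs <- toupper(contigs)
  if (any(nchar(contigs) == 0L)) {
    stop("contigs must be non-empty", call. = FALSE)
  }
  if (any(grepl("[^ACGTN]", contigs))) {
    stop("contig sequences may only contain A, C, G, T, N", call. = FALSE)
  }
  structure(list(contigs = contigs), class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("<genome_sequence> ", length(x$contigs), " contig(s)\n", sep = "")
  n <- utils::head(names(x$contigs), 5)
  for (nm in n) cat("  ", nm, ": ", nchar(x$contigs[[nm]]), " bp\n", sep = "")
  if (length(x$contigs) > 5) cat("  ...\n")
  invisible(x)
}

# Length of one contig, erroring on unknown names.
contig_length <- function(genome, contig) {
  stopifnot(inherits(genome, "genome_sequence"))
  if (!contig %in% names(genome$contigs)) {
    stop("contig '", contig, "' not present in genome", call. = FALSE)
  }
  nchar(genome$contigs[[contig]])
}

#' Extract a genomic subsequence
#'
#' 1-based inclusive slice of one contig; positions outside the contig are an
#' error (no clipping).
#'
#' @param genome A [genome_sequence()].
#' @param contig Contig name.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @return Forward-strand nucleotide string.
#' @export
genome_subseq <- function(genome, contig, start, end) {
  len <- contig_length(genome, contig)
  if (start < 1L || end > len || start > end) {
    stop("requested slice ", contig, ":", start, "-", end,
         " outside contig bounds (1-", len, ")", call. = FALSE)
  }
  substr(genome$contigs[[contig]], start, end)
}

#' Read a multi-contig FASTA file into a genome sequence
#'
#' @param path FASTA file path.
#' @return A [genome_sequence()].
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  contigs <- as.character(ss)
  # FASTA headers may carry descriptions after the first whitespace
  names(contigs) <- sub("\\s.*$", "", names(ss))
  genome_sequence(contigs)
}

#' Write a genome sequence to FASTA
#'
#' @param genome A [genome_sequence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "genome_sequence"))
  ss <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
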