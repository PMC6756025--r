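# Shared low-level helpers: codon table, reverse complement, variant keys,
# deterministic seed streams.

# Standard genetic code, "*" for stops.
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

#' Translate a coding sequence
#'
#' Standard-table translation of an in-frame nucleotide string. Translation
#' stops at the first stop codon; the returned protein never contains a stop
#' symbol. Codons containing characters outside A/C/G/T translate to `"X"`
#' with a warning.
#'
#' @param cds Nucleotide string, length >= 3. Trailing partial codons are
#'   ignored.
#' @return A list with `protein` (amino-acid string, residues before the first
#'   stop), `stop_reached` (logical) and `stop_codon_index` (codon index of
#'   the first stop, `NA` if none).
#' @examples
#' translate_cds("ATGAAATAA")
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  if (nchar(cds) < 3L) {
    stop("cds must be at least one codon (3 nt) long", call. = FALSE)
  }
  n <- nchar(cds) %/% 3L
  starts <- 3L * (seq_len(n) - 1L) + 1L
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(codon_table()[codons])
  if (anyNA(aa)) {
    warning("codon(s) containing non-ACGT characters translated as 'X'",
            call. = FALSE)
    aa[is.na(aa)] <- "X"
  }
  stop_i <- which(aa == "*")[1]
  if (!is.na(stop_i)) {
    list(protein = paste(aa[seq_len(stop_i - 1L)], collapse = ""),
         stop_reached = TRUE, stop_codon_index = stop_i)
  } else {
    list(protein = paste(aa, collapse = ""), stop_reached = FALSE,
         stop_codon_index = NA_integer_)
  }
}

# Reverse complement of a nucleotide string (A/C/G/T/N).
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# Complement of single bases, no reversal (fast path for SNV alleles).
comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

#' Canonical variant key
#'
#' `"contig:pos:ref:alt"` string used to join variants, genotypes and scores.
#'
#' @param contig,pos,ref,alt Vectors describing variants (genome-forward
#'   alleles, 1-based position).
#' @return Character vector of keys.
#' @export
variant_key <- function(contig, pos, ref, alt) {
  paste(contig, pos, ref, alt, sep = ":")
}

# One-letter -> three-letter amino-acid codes for protein-level names
# ("*" maps to "*", "X" to "Xaa").
aa3 <- function(x) {
  map <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
           E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
           M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
           Y = "Tyr", V = "Val", X = "Xaa", `*` = "*")
  out <- map[strsplit(paste(x, collapse = ""), "")[[1]]]
  out[is.na(out)] <- "Xaa"
  paste(out, collapse = "")
}

# Uniform draw(s) from an integer range, safe when the range collapses to one
# value (avoids base sample()'s scalar expansion).
sample_range <- function(lo, hi, n = 1L) {
  if (lo == hi) rep(as.integer(lo), n) else sample(lo:hi, n, replace = TRUE)
}

# Deterministic per-component seed stream: one root seed, named sub-streams,
# so adding a component never perturbs the draws of another.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  u <- utf8ToInt(stream)
  h <- sum(u * seq_along(u)) %% 1e6
  as.integer((abs(as.double(seed)) * 48271 + h * 7919 + 12345) %% 2147483647)
}
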