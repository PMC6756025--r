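# Independent oracles used across the suite. Deliberately naive and
# implemented with different machinery than the package (string splitting,
# seqinr translation, choose() enumeration) so agreement is informative.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# Naive per-exon slice + concatenation + reverse complement: clip exons to the
# CDS bounds in genomic order, paste, flip for minus strand.
oracle_spliced_cds <- function(contig_seq, exons, strand, cds_lo, cds_hi) {
  exons <- exons[order(exons$start), ]
  pieces <- character(0)
  for (i in seq_len(nrow(exons))) {
    s <- max(exons$start[i], cds_lo)
    e <- min(exons$end[i], cds_hi)
    if (s <= e) pieces <- c(pieces, substr(contig_seq, s, e))
  }
  fwd <- paste(pieces, collapse = "")
  if (strand == "-") oracle_revcomp(fwd) else fwd
}

# seqinr-based translation stopping at the first stop codon.
oracle_translate <- function(cds) {
  aa <- seqinr::translate(seqinr::s2c(cds))
  stop_i <- which(aa == "*")[1]
  if (!is.na(stop_i)) {
    list(protein = paste(aa[seq_len(stop_i - 1)], collapse = ""),
         stop_reached = TRUE, stop_codon_index = stop_i)
  } else {
    list(protein = paste(aa, collapse = ""), stop_reached = FALSE,
         stop_codon_index = NA_integer_)
  }
}

# Brute-force mutate-splice-translate classification of a CDS SNV: apply the
# substitution to the raw contig, re-splice with the unchanged exon structure,
# translate both products and diff them.
oracle_classify_cds_snv <- function(contig_seq, tx, pos, alt) {
  mut_seq <- contig_seq
  substr(mut_seq, pos, pos) <- alt
  cds_lo <- tx$cds_start_g
  cds_hi <- tx$cds_end_g
  ref_cds <- oracle_spliced_cds(contig_seq, tx$exons, tx$strand, cds_lo, cds_hi)
  mut_cds <- oracle_spliced_cds(mut_seq, tx$exons, tx$strand, cds_lo, cds_hi)
  ref_tr <- oracle_translate(ref_cds)
  mut_tr <- oracle_translate(mut_cds)
  native_stop <- nchar(ref_cds) / 3
  if (identical(ref_cds, mut_cds)) stop("oracle: SNV outside spliced CDS")
  if (mut_tr$stop_reached && mut_tr$stop_codon_index < native_stop) {
    list(klass = "stop_gain", ptc_codon = mut_tr$stop_codon_index,
         protein = mut_tr$protein)
  } else if (!mut_tr$stop_reached && ref_tr$stop_reached &&
             nchar(mut_tr$protein) >= nchar(ref_tr$protein) &&
             !identical(mut_tr$protein, ref_tr$protein) &&
             substr(mut_tr$protein, 1, nchar(ref_tr$protein)) ==
               ref_tr$protein) {
    list(klass = "stop_loss", ptc_codon = NA_integer_,
         protein = mut_tr$protein)
  } else if (identical(mut_tr$protein, ref_tr$protein)) {
    list(klass = "synonymous", ptc_codon = NA_integer_,
         protein = mut_tr$protein)
  } else {
    list(klass = "missense", ptc_codon = NA_integer_,
         protein = mut_tr$protein)
  }
}

# Brute-force exon skip: drop one exon, naive splice, translate.
oracle_exon_skip <- function(contig_seq, tx, genomic_exon_index) {
  exons <- tx$exons[-genomic_exon_index, , drop = FALSE]
  ref_cds <- oracle_spliced_cds(contig_seq, tx$exons, tx$strand,
                                tx$cds_start_g, tx$cds_end_g)
  mut_cds <- oracle_spliced_cds(contig_seq, exons, tx$strand,
                                tx$cds_start_g, tx$cds_end_g)
  mut_tr <- oracle_translate(mut_cds)
  removed <- nchar(ref_cds) - nchar(mut_cds)
  list(mutant_protein = mut_tr$protein,
       frame_shifted = removed %% 3 != 0,
       removed = removed,
       stop_codon_index = mut_tr$stop_codon_index,
       mutant_cds_len = nchar(mut_cds))
}

# Exact two-sided Fisher p by full hypergeometric enumeration with choose();
# sums the probabilities of all tables with the observed margins whose
# probability does not exceed the observed one (rel. tol. 1e-7).
oracle_fisher_2x2 <- function(a, b, c, d) {
  m <- a + b
  n2 <- c + d
  k <- a + c
  kk <- max(0, k - n2):min(k, m)
  p_all <- choose(m, kk) * choose(n2, k - kk) / choose(m + n2, k)
  p_obs <- choose(m, a) * choose(n2, c) / choose(m + n2, k)
  sum(p_all[p_all <= p_obs * (1 + 1e-7)])
}

# Enumerated Mendelian transmission: the child genotype must be a sum of one
# gamete from each parent.
oracle_mendel_ok <- function(child, father, mother) {
  gam <- function(g) switch(as.character(g), `0` = 0, `1` = c(0, 1), `2` = 1)
  child %in% outer(gam(father), gam(mother), `+`)
}

# Two-sided exact binomial tail sum at p = 0.5.
oracle_binom_two_sided <- function(x, n) {
  d <- stats::dbinom(0:n, n, 0.5)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

# A small handcrafted plus-strand transcript used by coordinate and
# consequence tests:
#   pad(10) | exon1: utr5(6) + cds(9) | intron(20) | exon2: cds(12) |
#   intron(20) | exon3: cds(9) + utr3(8) | pad(10)
# CDS = ATG AAA CCC | GGG TTT ACG TAC | GAT AAA TAA  (30 nt, 10 codons)
toy_transcript <- function(strand = c("+", "-")) {
  strand <- match.arg(strand)
  utr5 <- "TTTTTT"
  cds_parts <- c("ATGAAACCC", "GGGTTTACGTAC", "GATAAATAA")
  utr3 <- "CCCCCCCC"
  intron1 <- paste0("GT", strrep("A", 16), "AG")
  intron2 <- paste0("GT", strrep("C", 16), "AG")
  pad <- strrep("T", 10)
  fwd <- paste0(pad, utr5, cds_parts[1], intron1, cds_parts[2], intron2,
                cds_parts[3], utr3, pad)
  e1 <- c(11, 11 + 6 + 9 - 1)                       # 11..25
  e2 <- c(e1[2] + 20 + 1, e1[2] + 20 + 12)          # 46..57
  e3 <- c(e2[2] + 20 + 1, e2[2] + 20 + 9 + 8)       # 78..94
  cds_lo <- 11 + 6                                  # 17
  cds_hi <- e3[1] + 9 - 1                           # 86
  if (strand == "+") {
    genome <- genome_sequence(c(chrT = fwd))
    tx <- transcript_model("toy_tx", "toy_gene", "chrT", "+",
                           data.frame(start = c(e1[1], e2[1], e3[1]),
                                      end = c(e1[2], e2[2], e3[2])),
                           cds_lo, cds_hi)
  } else {
    len <- nchar(fwd)
    rc <- oracle_revcomp(fwd)
    genome <- genome_sequence(c(chrT = rc))
    flip <- function(x) len - x + 1
    tx <- transcript_model("toy_tx", "toy_gene", "chrT", "-",
                           data.frame(start = flip(c(e1[2], e2[2], e3[2])),
                                      end = flip(c(e1[1], e2[1], e3[1]))),
                           flip(cds_hi), flip(cds_lo))
  }
  list(genome = genome, tx = tx,
       cds = "ATGAAACCCGGGTTTACGTACGATAAATAA",
       protein = "MKPGFTYDK")
}

# All CDS genomic positions of a transcript, in coding order.
cds_positions <- function(tx) {
  g <- unlist(purrr::map2(tx$exons$start, tx$exons$end, seq))
  cp <- g_to_c(tx, g)
  g[cp$region == "cds"][order(cp$coding_offset[cp$region == "cds"])]
}
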