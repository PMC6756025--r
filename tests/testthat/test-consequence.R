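# Consequence prediction: codon-level classes, splice-as-skip modelling,
# NMD, readthrough extension, qualifying masks.

snv_at <- function(toy, coding_offset, t_alt) {
  # build a genome-forward SNV at a CDS offset of the toy transcript
  tx <- toy$tx
  g <- c_to_g(tx, tibble::tibble(region = "cds",
                                 coding_offset = coding_offset,
                                 intron_offset = 0L))
  ref <- genome_subseq(toy$genome, tx$contig, g, g)
  alt <- if (tx$strand == "-") chartr("ACGT", "TGCA", t_alt) else t_alt
  tibble::tibble(contig = tx$contig, pos = g, ref = ref, alt = alt)
}

test_that("classification errors on REF mismatch and multi-allelic input", {
  toy <- toy_transcript("+")
  v <- snv_at(toy, 4L, "C")
  bad <- dplyr::mutate(v, ref = ifelse(ref == "A", "G", "A"))
  expect_error(classify_variants(bad, toy$tx, toy$genome), "REF mismatch")
  multi <- dplyr::mutate(v, alt = "C,G")
  expect_error(classify_variants(multi, toy$tx, toy$genome), "pre-split")
  expect_equal(nrow(split_multiallelic(multi)), 2L)
})

test_that("codon-level classes and HGVS names are assigned on both strands", {
  for (s in c("+", "-")) {
    toy <- toy_transcript(s)
    # c.6 A>G keeps Lys2 (AAA->AAG): synonymous
    syn <- classify_variants(snv_at(toy, 6L, "G"), toy$tx, toy$genome)
    expect_equal(syn$klass, "synonymous")
    expect_equal(syn$hgvs_c, "c.6A>G")
    expect_false(syn$is_truncating)
    # c.4 A>C makes Lys2Gln
    mis <- classify_variants(snv_at(toy, 4L, "C"), toy$tx, toy$genome)
    expect_equal(mis$klass, "missense")
    expect_equal(mis$hgvs_p, "p.Lys2Gln")
    # c.4 A>T makes AAA->TAA: stop gain at codon 2
    sg <- classify_variants(snv_at(toy, 4L, "T"), toy$tx, toy$genome)
    expect_equal(sg$klass, "stop_gain")
    expect_equal(sg$ptc_codon, 2L)
    expect_true(sg$is_truncating)
    expect_equal(sg$hgvs_p, "p.Lys2*")
    # native stop TAA -> CAA: stop loss, Gln substitution
    sl <- classify_variants(snv_at(toy, 28L, "C"), toy$tx, toy$genome)
    expect_equal(sl$klass, "stop_loss")
    expect_match(sl$hgvs_p, "^p\\.\\*10Gln")
    expect_false(sl$is_truncating)
  }
})

test_that("canonical splice positions map to donor/acceptor with skip modelling attached", {
  toy <- toy_transcript("+")
  tx <- toy$tx
  # +1 of intron 1 (donor of exon 1, a terminal exon -> unresolved)
  d1 <- tibble::tibble(contig = "chrT", pos = tx$exons$end[1] + 1L,
                       ref = "G", alt = "T")
  call1 <- classify_variants(d1, tx, toy$genome)
  expect_equal(call1$klass, "splice_donor")
  expect_true(call1$is_truncating)
  expect_match(call1$note, "terminal exon")
  # +1 of intron 2 = donor of exon 2 (internal, 12 nt -> in-frame skip)
  d2 <- tibble::tibble(contig = "chrT", pos = tx$exons$end[2] + 1L,
                       ref = "G", alt = "T")
  call2 <- classify_variants(d2, tx, toy$genome)
  expect_equal(call2$klass, "splice_donor")
  expect_equal(call2$hgvs_c, "c.21+1G>T")
  expect_match(call2$note, "in-frame")
  # -1 before exon 2: acceptor, skips exon 2
  a2 <- tibble::tibble(contig = "chrT", pos = tx$exons$start[2] - 1L,
                       ref = "G", alt = "C")
  call3 <- classify_variants(a2, tx, toy$genome)
  expect_equal(call3$klass, "splice_acceptor")
  # deeper intronic SNV stays intronic and non-truncating
  deep <- tibble::tibble(contig = "chrT", pos = tx$exons$end[1] + 8L,
                         ref = genome_subseq(toy$genome, "chrT",
                                             tx$exons$end[1] + 8L,
                                             tx$exons$end[1] + 8L),
                         alt = "T")
  deep <- dplyr::filter(deep, ref != alt)
  if (nrow(deep) == 1L) {
    call4 <- classify_variants(deep, tx, toy$genome)
    expect_equal(call4$klass, "intronic")
    expect_false(call4$is_truncating)
  }
})

test_that("classification agrees with the mutate-splice-translate oracle exhaustively on a toy gene", {
  for (s in c("+", "-")) {
    toy <- toy_transcript(s)
    tx <- toy$tx
    contig_seq <- toy$genome$contigs[[tx$contig]]
    positions <- cds_positions(tx)
    for (g in positions) {
      ref <- substr(contig_seq, g, g)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        v <- tibble::tibble(contig = tx$contig, pos = g, ref = ref, alt = alt)
        call <- classify_variants(v, tx, toy$genome)
        ora <- oracle_classify_cds_snv(contig_seq, tx, g, alt)
        expect_equal(call$klass, ora$klass,
                     info = sprintf("strand %s pos %d %s>%s", s, g, ref, alt))
        if (ora$klass == "stop_gain") {
          expect_equal(call$ptc_codon, ora$ptc_codon)
        }
      }
    }
  }
})

test_that("in-frame internal exon skipping deletes residues without a frameshift", {
  # exon 2 of the toy gene carries 12 coding nt (codons 4-7)
  toy <- toy_transcript("+")
  res <- model_exon_skip(toy$tx, 2L, toy$genome)
  expect_false(res$frame_shifted)
  expect_equal(res$removed_coding_length, 12L)
  expect_equal(res$first_affected_codon, 4L)
  expect_true(is.na(res$ptc_codon))
  expect_equal(res$mutant_protein, "MKPDK")
})

test_that("terminal exon skips are flagged unresolved, not computed", {
  toy <- toy_transcript("+")
  expect_error(model_exon_skip(toy$tx, 1L, toy$genome),
               class = "famlof_terminal_exon")
  expect_error(model_exon_skip(toy$tx, 3L, toy$genome),
               class = "famlof_terminal_exon")
})

test_that("exon skipping matches the brute-force oracle on simulated genes", {
  cfg <- sim_config(seed = 21, n_genes = 6, exons_per_gene = c(4, 6))
  ref <- simulate_reference(cfg)
  n_checked <- 0L
  for (tx in ref$transcripts) {
    contig_seq <- ref$genome$contigs[[tx$contig]]
    map <- famlof:::tx_exon_map(tx)
    for (e in famlof:::internal_coding_exons(tx)) {
      res <- model_exon_skip(tx, e, ref$genome)
      ora <- oracle_exon_skip(contig_seq, tx, map$genomic_index[e])
      expect_equal(res$mutant_protein, ora$mutant_protein)
      expect_equal(res$frame_shifted, ora$frame_shifted)
      expect_equal(res$removed_coding_length, ora$removed)
      if (!is.na(res$ptc_codon)) {
        expect_equal(res$ptc_codon, ora$stop_codon_index)
      }
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 10L)
})

test_that("an internal exon of coding length divisible by three never shifts the frame", {
  cfg <- sim_config(seed = 33, n_genes = 8,
                    exon_length_range = c(60, 63))
  ref <- simulate_reference(cfg)
  for (tx in ref$transcripts) {
    for (e in famlof:::internal_coding_exons(tx)) {
      res <- model_exon_skip(tx, e, ref$genome)
      if (res$removed_coding_length %% 3L == 0L) {
        expect_false(res$frame_shifted)
      }
    }
  }
})

test_that("NMD prediction follows the 50-nt last-junction rule inclusively", {
  # two-exon transcript: exon1 = 120 coding nt, exon2 = 90 coding nt + stop
  cds <- paste0("ATG", strrep("AAA", 68), "TAA")   # 210 nt, 70 codons
  intron <- paste0("GT", strrep("T", 30), "AG")
  contig <- paste0(strrep("C", 5), substr(cds, 1, 120), intron,
                   substr(cds, 121, 210), strrep("C", 5))
  g <- genome_sequence(c(cN = contig))
  tx <- transcript_model("t", "g", "cN", "+",
                         data.frame(start = c(6, 160), end = c(125, 249)),
                         6, 249)
  expect_equal(build_cds(tx, g), cds)
  # junction sits after mRNA position 120; PTC first nt = 3*(k-1)+1
  # distance = 120 - (3k - 2) >= 50  <=>  k <= 24
  expect_true(predict_nmd(tx, 24))    # exactly 50 nt upstream: inclusive
  expect_false(predict_nmd(tx, 25))   # 47 nt upstream
  expect_false(predict_nmd(tx, 60))   # PTC in the last exon
  expect_error(predict_nmd(tx, 70), "precede")
  # monotone: upstream of a predicted-decay PTC, prediction never flips off
  nmd_along <- vapply(1:24, function(k) predict_nmd(tx, k), logical(1))
  expect_true(all(nmd_along))
  # single-exon transcript: no junction, never NMD
  g1 <- genome_sequence(c(c1 = paste0("TT", cds, "GG")))
  tx1 <- transcript_model("t1", "g", "c1", "+",
                          data.frame(start = 3, end = 212), 3, 212)
  expect_false(predict_nmd(tx1, 10))
})

test_that("readthrough extension translates the 3'UTR until the next stop", {
  # toy 3'UTR starts right after TAA with CCCCCCCC -> Pro Pro ... no stop
  toy <- toy_transcript("+")
  v <- snv_at(toy, 28L, "C")            # TAA -> CAA (Gln)
  ext <- extend_readthrough(v, toy$tx, toy$genome)
  expect_equal(ext$substituted_residue, "Q")
  expect_false(ext$new_stop_found)
  expect_match(ext$hgvs_p, "ext\\*\\?$")

  # engineered UTRs: in-frame immediate stop, and CAACAATGA (2 residues)
  make_utr_tx <- function(utr3) {
    cds <- "ATGAAATAA"
    contig <- paste0("TT", cds, utr3, "GG")
    g <- genome_sequence(c(cU = contig))
    tx <- transcript_model("t", "g", "cU", "+",
                           data.frame(start = 3, end = 2 + nchar(cds) +
                                        nchar(utr3)),
                           3, 11)
    list(g = g, tx = tx)
  }
  u1 <- make_utr_tx("TGACCC")
  v1 <- tibble::tibble(contig = "cU", pos = 9, ref = "T", alt = "C")
  ext1 <- extend_readthrough(v1, u1$tx, u1$g)
  expect_equal(ext1$extension_residues, 0L)
  expect_true(ext1$new_stop_found)
  expect_equal(ext1$hgvs_p, "p.*3Glnext*1")

  u2 <- make_utr_tx("CAACAATGACC")
  ext2 <- extend_readthrough(v1, u2$tx, u2$g)
  expect_equal(ext2$extension_residues, 2L)
  expect_equal(ext2$hgvs_p, "p.*3Glnext*3")
  expect_error(
    extend_readthrough(tibble::tibble(contig = "cU", pos = 4, ref = "T",
                                      alt = "C"), u2$tx, u2$g),
    "stop codon")
})

test_that("extension length is invariant to re-embedding the transcript reverse-complemented", {
  cfg <- sim_config(seed = 13, n_genes = 2)
  ref <- simulate_reference(cfg)
  # compare each transcript against a hand-flipped copy of its own contig
  for (nm in names(ref$transcripts)) {
    tx <- ref$transcripts[[nm]]
    contig_seq <- ref$genome$contigs[[tx$contig]]
    len <- nchar(contig_seq)
    flip <- function(x) len - x + 1
    g2 <- genome_sequence(stats::setNames(oracle_revcomp(contig_seq),
                                          tx$contig))
    tx2 <- transcript_model(tx$transcript_id, tx$gene_id, tx$contig,
                            if (tx$strand == "+") "-" else "+",
                            data.frame(start = flip(tx$exons$end),
                                       end = flip(tx$exons$start)),
                            flip(tx$cds_end_g), flip(tx$cds_start_g))
    v <- propose_snv(tx, ref$genome, "stop_loss")
    v2 <- dplyr::mutate(v, pos = flip(pos),
                        ref = chartr("ACGT", "TGCA", ref),
                        alt = chartr("ACGT", "TGCA", alt))
    e1 <- extend_readthrough(v, tx, ref$genome)
    e2 <- extend_readthrough(v2, tx2, g2)
    expect_equal(e1$extension_residues, e2$extension_residues)
    expect_equal(e1$substituted_residue, e2$substituted_residue)
  }
})

test_that("the qualifying-variant gate is class-first with an inclusive missense threshold", {
  calls <- tibble::tibble(
    contig = "c", pos = 1:4, ref = "A", alt = "T",
    klass = c("splice_donor", "synonymous", "missense", "missense")
  )
  scores <- tibble::tibble(contig = "c", pos = 1:4, ref = "A", alt = "T",
                           score = c(5, 99, 20, 19.9))
  lof <- is_putative_lof(calls, scores)
  expect_true(lof[1])        # splice always qualifies
  expect_false(lof[2])       # class gate precedes score
  expect_true(lof[3])        # exactly at the threshold: inclusive
  expect_false(lof[4])
  expect_warning(
    no_score <- is_putative_lof(calls[3, ], scores = NULL),
    "without a deleteriousness score")
  expect_false(no_score)
})
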