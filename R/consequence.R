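# Variant consequence prediction against a transcript model:
#   - coding SNVs compared codon-wise (synonymous / missense / stop-gain /
#     stop-loss),
#   - canonical splice-site SNVs (intronic offsets +1/+2 donor, -1/-2
#     acceptor) modelled as skipping the adjacent exon, with frameshift,
#     premature-termination-codon (PTC) and nonsense-mediated-decay (NMD)
#     calls on the skipped product,
#   - stop-loss variants extended by in-frame readthrough into the 3'UTR,
#   - CDS indels called frameshift when the length change is not a multiple
#     of 3 (left-trimmed input assumed; realignment is out of scope).
# REF/ALT alleles are genome-forward (VCF convention); the annotator
# reverse-complements them for minus-strand transcripts, so reported HGVS c.
# alleles are transcript-oriented.

#' Classify variants against a transcript model
#'
#' @param variants Data frame with columns `contig`, `pos`, `ref`, `alt` and
#'   optionally `id`. Alleles are genome-forward; multi-allelic records must
#'   be pre-split (see [split_multiallelic()]); `ref` must match the genome at
#'   `pos` (mismatch is an error).
#' @param tx A [transcript_model()].
#' @param genome A [genome_sequence()].
#' @param flank Passed to [g_to_c()].
#' @return A tibble, one row per variant, with columns `contig`, `pos`, `ref`,
#'   `alt`, `id`, `key`, `transcript_id`, `gene_id`, `klass`, `hgvs_c`,
#'   `hgvs_p`, `ptc_codon`, `nmd_predicted`, `extension_residues`,
#'   `is_truncating`, `note`. `ptc_codon` is the protein position of a newly
#'   introduced stop (mutant-product numbering for exon skips);
#'   `nmd_predicted` is set only when `ptc_codon` is; `extension_residues` is
#'   set only for stop-loss calls. `is_truncating` is `TRUE` exactly for
#'   stop-gain, frameshift and canonical splice classes.
#' @seealso [model_exon_skip()], [predict_nmd()], [extend_readthrough()]
#' @export
classify_variants <- function(variants, tx, genome, flank = 5000L) {
  stopifnot(is.data.frame(variants),
            all(c("contig", "pos", "ref", "alt") %in% names(variants)))
  variants <- tibble::as_tibble(variants)
  if (!"id" %in% names(variants)) variants$id <- NA_character_
  purrr::map_dfr(seq_len(nrow(variants)), function(i) {
    classify_one(variants[i, ], tx, genome, flank)
  })
}

classify_one <- function(v, tx, genome, flank) {
  contig <- v$contig; pos <- as.integer(v$pos)
  ref <- toupper(v$ref); alt <- toupper(v$alt)
  if (grepl(",", alt, fixed = TRUE)) {
    stop("multi-allelic record at ", contig, ":", pos,
         "; pre-split with split_multiallelic()", call. = FALSE)
  }
  if (ref == alt) stop("ref equals alt at ", contig, ":", pos, call. = FALSE)
  if (contig != tx$contig) {
    stop("variant contig ", contig, " does not match transcript contig ",
         tx$contig, call. = FALSE)
  }
  obs <- genome_subseq(genome, contig, pos, pos + nchar(ref) - 1L)
  if (obs != ref) {
    stop("REF mismatch at ", contig, ":", pos, ": expected '", obs,
         "', got '", ref, "'", call. = FALSE)
  }

  cpos <- g_to_c(tx, pos, flank = flank)
  is_snv <- nchar(ref) == 1L && nchar(alt) == 1L
  # transcript-oriented alleles for HGVS c. names
  t_ref <- if (tx$strand == "-") comp_base(ref) else ref
  t_alt <- if (tx$strand == "-") comp_base(alt) else alt
  hgvs_c <- paste0("c.", format_c_position(cpos),
                   if (is_snv) paste0(t_ref, ">", t_alt)
                   else paste0("del", t_ref, "ins", t_alt))

  out <- tibble::tibble(
    contig = contig, pos = pos, ref = ref, alt = alt,
    id = as.character(v$id), key = variant_key(contig, pos, ref, alt),
    transcript_id = tx$transcript_id, gene_id = tx$gene_id,
    klass = "other", hgvs_c = hgvs_c, hgvs_p = NA_character_,
    ptc_codon = NA_integer_, nmd_predicted = NA,
    extension_residues = NA_integer_, is_truncating = FALSE,
    note = NA_character_
  )

  if (cpos$region == "intron") {
    if (is_snv && abs(cpos$intron_offset) <= 2L) {
      out$klass <- if (cpos$intron_offset > 0) "splice_donor"
                   else "splice_acceptor"
      out$is_truncating <- TRUE
      skip <- splice_skip_effect(tx, genome, cpos)
      out$ptc_codon <- skip$ptc_codon
      out$nmd_predicted <- skip$nmd_predicted
      out$hgvs_p <- skip$hgvs_p
      out$note <- skip$note
    } else {
      out$klass <- "intronic"
    }
    return(out)
  }
  if (cpos$region %in% c("utr5", "utr3")) {
    out$klass <- cpos$region
    return(out)
  }

  # CDS
  if (!is_snv) {
    shift <- (nchar(ref) - nchar(alt)) %% 3L
    if (shift != 0L) {
      out$klass <- "frameshift"
      out$is_truncating <- TRUE
    } else {
      out$klass <- "other"
      out$note <- "in-frame indel"
    }
    return(out)
  }

  cds <- build_cds(tx, genome)
  L <- nchar(cds)
  k <- cpos$coding_offset
  codon_index <- (k - 1L) %/% 3L + 1L
  within <- (k - 1L) %% 3L + 1L
  codon_start <- (codon_index - 1L) * 3L + 1L
  ref_codon <- substr(cds, codon_start, codon_start + 2L)
  if (substr(ref_codon, within, within) != t_ref) {
    stop("internal error: CDS/genome disagreement at c.", k, call. = FALSE)
  }
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- t_alt
  tab <- codon_table()
  ref_aa <- unname(tab[ref_codon]); alt_aa <- unname(tab[alt_codon])
  n_codons <- L %/% 3L
  is_native_stop <- codon_index == n_codons && identical(ref_aa, "*")

  if (identical(ref_aa, alt_aa)) {
    out$klass <- "synonymous"
    out$hgvs_p <- if (identical(ref_aa, "*")) {
      paste0("p.*", codon_index, "=")
    } else {
      paste0("p.", aa3(ref_aa), codon_index, "=")
    }
  } else if (is_native_stop && alt_aa != "*") {
    out$klass <- "stop_loss"
    ext <- extend_readthrough(
      tibble::tibble(contig = contig, pos = pos, ref = ref, alt = alt),
      tx, genome
    )
    out$extension_residues <- ext$extension_residues
    out$hgvs_p <- ext$hgvs_p
    if (!ext$new_stop_found) out$note <- "no downstream stop in transcript"
  } else if (alt_aa == "*") {
    out$klass <- "stop_gain"
    out$is_truncating <- TRUE
    out$ptc_codon <- codon_index
    out$nmd_predicted <- predict_nmd(tx, codon_index)
    out$hgvs_p <- paste0("p.", aa3(ref_aa), codon_index, "*")
  } else {
    out$klass <- "missense"
    out$hgvs_p <- paste0("p.", aa3(ref_aa), codon_index, aa3(alt_aa))
  }
  out
}

# Effect of a canonical splice SNV, modelled as skipping the adjacent exon.
# Donor variants (+ offsets) skip the exon they follow; acceptor variants
# (- offsets) skip the exon they precede (transcript orientation).
splice_skip_effect <- function(tx, genome, cpos) {
  map <- tx_exon_map(tx)
  # the anchor base sits at the boundary of the skipped exon
  anchor_m <- cpos$anchor_m
  tx_exon_idx <- which(anchor_m >= map$m_start & anchor_m <= map$m_end)
  res <- tryCatch(
    model_exon_skip(tx, tx_exon_idx, genome),
    famlof_terminal_exon = function(e) e
  )
  if (inherits(res, "condition")) {
    return(list(ptc_codon = NA_integer_, nmd_predicted = NA,
                hgvs_p = NA_character_,
                note = "terminal exon, effect unresolved"))
  }
  hgvs_p <- skip_hgvs_p(res)
  nmd <- if (!is.na(res$ptc_codon)) {
    predict_nmd(res$mutant_tx, res$ptc_codon)
  } else {
    NA
  }
  list(ptc_codon = res$ptc_codon, nmd_predicted = nmd, hgvs_p = hgvs_p,
       note = paste0("modelled as skip of exon ", res$exon_index,
                     if (res$frame_shifted) " (frameshift)" else " (in-frame)"))
}

skip_hgvs_p <- function(res) {
  if (is.na(res$ptc_codon)) return(NA_character_)
  anchor <- res$first_affected_codon
  ref_res <- substr(res$reference_protein, anchor, anchor)
  mut_res <- if (nchar(res$mutant_protein) >= anchor) {
    substr(res$mutant_protein, anchor, anchor)
  } else {
    "*"
  }
  if (res$frame_shifted) {
    # stop offset counts the anchor codon as 1
    paste0("p.", aa3(ref_res), anchor, aa3(mut_res), "fs*",
           res$ptc_codon - anchor + 1L)
  } else {
    paste0("p.", aa3(ref_res), anchor, mut_res_or_stop(mut_res), "*",
           res$ptc_codon)
  }
}

mut_res_or_stop <- function(x) if (x == "*") "*" else aa3(x)

#' Model skipping of an internal coding exon
#'
#' Removes one exon from the spliced transcript, rebuilds and re-translates
#' the CDS, and reports the frameshift/PTC outcome. Only internal coding exons
#' can be skipped: a request for the first or last exon, or for an exon
#' containing a CDS boundary, raises a condition of class
#' `famlof_terminal_exon` ("terminal exon, effect unresolved").
#'
#' @param tx A [transcript_model()].
#' @param exon_index Exon index in transcript (5'->3') order.
#' @param genome A [genome_sequence()].
#' @return A list: `mutant_protein` (translation of the skipped CDS up to its
#'   first stop), `first_affected_codon` (first codon whose underlying
#'   nucleotides change, reported even if its residue is coincidentally
#'   preserved), `ptc_codon` (protein position, in the mutant product, of a
#'   stop arising before the native one; `NA` if none), `frame_shifted`
#'   (skipped coding length mod 3 != 0), plus `reference_protein`,
#'   `removed_coding_length`, `exon_index` and the `mutant_tx` model used for
#'   NMD prediction.
#' @export
model_exon_skip <- function(tx, exon_index, genome) {
  stopifnot(inherits(tx, "transcript_model"))
  map <- tx_exon_map(tx)
  n <- nrow(map)
  if (exon_index < 1L || exon_index > n) {
    stop("exon_index out of range", call. = FALSE)
  }
  ex <- map[exon_index, ]
  terminal <- exon_index %in% c(1L, n) ||
    (tx$cds_start_g >= ex$start && tx$cds_start_g <= ex$end) ||
    (tx$cds_end_g >= ex$start && tx$cds_end_g <= ex$end)
  coding_len <- max(0L, min(ex$end, tx$cds_end_g) -
                        max(ex$start, tx$cds_start_g) + 1L)
  if (terminal || coding_len == 0L) {
    cond <- structure(
      class = c("famlof_terminal_exon", "error", "condition"),
      list(message = paste0("exon ", exon_index,
                            ": terminal or non-coding exon, effect unresolved"),
           call = sys.call())
    )
    stop(cond)
  }

  ref_cds <- build_cds(tx, genome)
  ref_tr <- translate_cds(ref_cds)
  mutant_exons <- tx$exons[-ex$genomic_index, , drop = FALSE]
  mutant_tx <- transcript_model(
    paste0(tx$transcript_id, ":skip", exon_index), tx$gene_id, tx$contig,
    tx$strand, mutant_exons, tx$cds_start_g, tx$cds_end_g
  )
  mut_cds <- build_cds(mutant_tx, genome)
  mut_tr <- translate_cds(mut_cds)

  removed <- nchar(ref_cds) - nchar(mut_cds)
  frame_shifted <- removed %% 3L != 0L
  # c. offset of the skipped exon's first coding base
  first_coding_g <- if (tx$strand == "+") {
    max(ex$start, tx$cds_start_g)
  } else {
    min(ex$end, tx$cds_end_g)
  }
  k0 <- g_to_c(tx, first_coding_g)$coding_offset
  first_affected_codon <- (k0 - 1L) %/% 3L + 1L

  mutant_native_stop <- nchar(mut_cds) %/% 3L
  ptc <- if (mut_tr$stop_reached) {
    s <- mut_tr$stop_codon_index
    if (frame_shifted || s < mutant_native_stop) as.integer(s) else NA_integer_
  } else {
    NA_integer_
  }

  list(mutant_protein = mut_tr$protein,
       first_affected_codon = as.integer(first_affected_codon),
       ptc_codon = ptc,
       frame_shifted = frame_shifted,
       reference_protein = ref_tr$protein,
       removed_coding_length = as.integer(removed),
       exon_index = as.integer(exon_index),
       mutant_tx = mutant_tx)
}

#' Predict nonsense-mediated decay for a premature termination codon
#'
#' Classical 50-nt rule: decay is predicted when the PTC's first nucleotide
#' lies at least 50 nt upstream of the last exon-exon junction of the spliced
#' transcript (inclusive at exactly 50). PTCs in the last exon, or in a
#' single-exon transcript, escape.
#'
#' @param tx The transcript model carrying the PTC (for splice-induced skips,
#'   the skipped model).
#' @param ptc_codon Protein position of the premature stop; must precede the
#'   transcript's native stop.
#' @param rule_nt Distance threshold in nucleotides (default 50).
#' @return Logical.
#' @export
predict_nmd <- function(tx, ptc_codon, rule_nt = 50L) {
  stopifnot(inherits(tx, "transcript_model"), is.numeric(ptc_codon))
  b <- cds_mrna_bounds(tx)
  L <- unname(b["mL"] - b["m1"] + 1L)
  n_codons <- L %/% 3L
  if (ptc_codon >= n_codons) {
    stop("ptc_codon must precede the native stop codon", call. = FALSE)
  }
  map <- tx_exon_map(tx)
  if (nrow(map) == 1L) return(FALSE)
  last_junction <- map$m_end[nrow(map) - 1L]  # last base of penultimate exon
  ptc_first_nt <- unname(b["m1"]) + (as.integer(ptc_codon) - 1L) * 3L
  (last_junction - ptc_first_nt) >= rule_nt
}

#' Readthrough extension for a stop-loss variant
#'
#' Recodes the native stop codon per the variant and translates in frame into
#' the 3'UTR of the spliced transcript until the next stop codon.
#'
#' @param variant One-row data frame with `contig`, `pos`, `ref`, `alt`
#'   (genome-forward SNV overlapping the native stop codon).
#' @param tx A [transcript_model()].
#' @param genome A [genome_sequence()].
#' @return A list: `substituted_residue` (one-letter code of the residue the
#'   stop becomes), `extension_residues` (residues appended after the
#'   substituted one, excluding the new stop), `new_stop_found` (`FALSE` when
#'   the transcript ends before an in-frame stop), and `hgvs_p` of the form
#'   `p.*<pos><Res>ext*<N>` with `N = extension_residues + 1` (the substituted
#'   residue counted once), or `ext*?` when no stop is found.
#' @export
extend_readthrough <- function(variant, tx, genome) {
  v <- tibble::as_tibble(variant)[1, ]
  pos <- as.integer(v$pos); ref <- toupper(v$ref); alt <- toupper(v$alt)
  if (nchar(ref) != 1L || nchar(alt) != 1L) {
    stop("extend_readthrough expects an SNV", call. = FALSE)
  }
  cpos <- g_to_c(tx, pos)
  b <- cds_mrna_bounds(tx)
  L <- unname(b["mL"] - b["m1"] + 1L)
  n_codons <- L %/% 3L
  stop_first_k <- L - 2L
  if (cpos$region != "cds" || cpos$coding_offset < stop_first_k) {
    stop("variant does not overlap the native stop codon", call. = FALSE)
  }
  mrna <- build_mrna(tx, genome)
  t_alt <- if (tx$strand == "-") comp_base(alt) else alt
  m <- cpos$anchor_m
  substr(mrna, m, m) <- t_alt
  stop_m <- unname(b["m1"]) + stop_first_k - 1L  # mRNA coord of stop codon
  tail_seq <- substr(mrna, stop_m, nchar(mrna))
  if (nchar(tail_seq) < 3L) {
    stop("transcript truncated at the stop codon", call. = FALSE)
  }
  tr <- translate_cds(tail_seq)
  sub_res <- substr(tr$protein, 1L, 1L)
  if (identical(sub_res, "") || substr(tail_seq, 1L, 3L) %in%
      c("TAA", "TAG", "TGA")) {
    stop("variant does not abolish the stop codon", call. = FALSE)
  }
  ext <- nchar(tr$protein) - 1L
  hgvs_p <- paste0("p.*", n_codons, aa3(sub_res), "ext*",
                   if (tr$stop_reached) ext + 1L else "?")
  list(substituted_residue = sub_res,
       extension_residues = as.integer(ext),
       new_stop_found = tr$stop_reached,
       hgvs_p = hgvs_p)
}

#' Flag putative loss-of-function calls
#'
#' Truncating classes (stop-gain, frameshift, canonical splice) and stop-loss
#' always qualify. Missense qualifies only when a deleteriousness score meets
#' an inclusive threshold; missense without a score is not qualifying (a
#' warning reports how many were unscored).
#'
#' @param calls Tibble from [classify_variants()].
#' @param scores Optional data frame with columns `contig`, `pos`, `ref`,
#'   `alt`, `score` (e.g. a genome-wide deleteriousness score).
#' @param missense_threshold Inclusive score threshold for missense
#'   (default 20).
#' @return Logical vector along the rows of `calls`.
#' @export
is_putative_lof <- function(calls, scores = NULL, missense_threshold = 20) {
  stopifnot(is.data.frame(calls), "klass" %in% names(calls))
  lof_classes <- c("stop_gain", "frameshift", "splice_donor",
                   "splice_acceptor", "stop_loss")
  out <- calls$klass %in% lof_classes
  mis <- calls$klass == "missense"
  if (any(mis)) {
    sc <- rep(NA_real_, nrow(calls))
    if (!is.null(scores)) {
      stopifnot(all(c("contig", "pos", "ref", "alt", "score") %in%
                      names(scores)))
      skey <- variant_key(scores$contig, scores$pos, scores$ref, scores$alt)
      ckey <- variant_key(calls$contig, calls$pos, calls$ref, calls$alt)
      sc <- scores$score[match(ckey, skey)]
    }
    unscored <- mis & is.na(sc)
    if (any(unscored)) {
      warning(sum(unscored),
              " missense call(s) without a deleteriousness score treated as",
              " non-qualifying", call. = FALSE)
    }
    out[mis] <- !is.na(sc[mis]) & sc[mis] >= missense_threshold
  }
  out
}

#' Split multi-allelic variant records
#'
#' One output row per ALT allele; all other columns are copied.
#'
#' @param variants Data frame with `alt` possibly containing comma-separated
#'   alleles.
#' @return Tibble of biallelic records.
#' @export
split_multiallelic <- function(variants) {
  tibble::as_tibble(variants) |>
    dplyr::mutate(alt = strsplit(as.character(.data$alt), ",", fixed = TRUE)) |>
    tidyr::unnest("alt")
}

#' Annotate a VCF with consequence INFO fields
#'
#' Copies a VCF, adding a `CSQ` INFO entry
#' (`klass|hgvs_c|hgvs_p|is_truncating`) to every record with a matching
#' consequence call; records without a call keep their INFO untouched.
#'
#' @param calls Tibble from [classify_variants()].
#' @param vcf_in,vcf_out Input and output VCF paths.
#' @return `vcf_out`, invisibly.
#' @export
annotate_vcf_info <- function(calls, vcf_in, vcf_out) {
  lines <- readLines(vcf_in)
  is_header <- grepl("^#", lines)
  info_line <- paste0(
    "##INFO=<ID=CSQ,Number=1,Type=String,",
    "Description=\"Consequence: klass|hgvs_c|hgvs_p|is_truncating\">")
  header <- lines[is_header]
  chrom_i <- grep("^#CHROM", header)
  header <- append(header, info_line, after = chrom_i - 1L)
  csq <- stats::setNames(
    paste(calls$klass, calls$hgvs_c,
          dplyr::coalesce(calls$hgvs_p, "."),
          calls$is_truncating, sep = "|"),
    calls$key)
  body <- vapply(lines[!is_header], function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    key <- variant_key(f[1], f[2], f[4], f[5])
    if (!key %in% names(csq)) return(l)
    tag <- paste0("CSQ=", csq[[key]])
    f[8] <- if (f[8] %in% c(".", "")) tag else paste0(f[8], ";", tag)
    paste(f, collapse = "\t")
  }, character(1), USE.NAMES = FALSE)
  writeLines(c(header, body), vcf_out)
  invisible(vcf_out)
}

#' Write consequence calls to TSV
#'
#' Stable column order; list columns are not expected.
#'
#' @param calls Tibble from [classify_variants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consequences_tsv <- function(calls, path) {
  cols <- c("contig", "pos", "ref", "alt", "id", "key", "transcript_id",
            "gene_id", "klass", "hgvs_c", "hgvs_p", "ptc_codon",
            "nmd_predicted", "extension_residues", "is_truncating", "note")
  readr::write_tsv(calls[intersect(cols, names(calls))], path)
  invisible(path)
}
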