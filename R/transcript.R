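# Transcript models: strand-aware exon/CDS structure on a contig, the basis
# for every consequence call. Genomic coordinates are 1-based inclusive
# (the GFF3/VCF convention); mRNA coordinates are 1-based along the spliced
# transcript in transcript orientation.

#' Create a transcript model
#'
#' @param transcript_id,gene_id Identifier strings.
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with columns `start`, `end` (1-based inclusive
#'   genomic intervals). Exons must be non-overlapping; they are sorted by
#'   genomic position.
#' @param cds_start_g,cds_end_g Genomic bounds of the coding sequence
#'   (including the stop codon): the smallest and largest genomic coordinate
#'   of the CDS, independent of strand. Both must fall inside exons.
#' @return An object of class `transcript_model`.
#' @examples
#' tx <- transcript_model("tx1", "gene1", "chr1", "+",
#'                        data.frame(start = 11, end = 30), 14, 25)
#' @export
transcript_model <- function(transcript_id, gene_id, contig, strand,
                             exons, cds_start_g, cds_end_g) {
  stopifnot(is.character(transcript_id), is.character(gene_id),
            is.character(contig), strand %in% c("+", "-"),
            is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  exons <- tibble::as_tibble(exons[c("start", "end")])
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  exons <- dplyr::arrange(exons, .data$start)
  if (any(exons$end < exons$start)) {
    stop("exon end precedes exon start", call. = FALSE)
  }
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("exons overlap or abut out of order", call. = FALSE)
  }
  cds_start_g <- as.integer(cds_start_g)
  cds_end_g <- as.integer(cds_end_g)
  if (cds_end_g < cds_start_g) {
    stop("cds_end_g precedes cds_start_g (give strand-independent bounds)",
         call. = FALSE)
  }
  in_exon <- function(g) any(g >= exons$start & g <= exons$end)
  if (!in_exon(cds_start_g) || !in_exon(cds_end_g)) {
    stop("CDS bounds must fall inside exons", call. = FALSE)
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id, contig = contig,
         strand = strand, exons = exons,
         cds_start_g = cds_start_g, cds_end_g = cds_end_g),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model> ", x$transcript_id, " (", x$gene_id, ") ",
      x$contig, ":", min(x$exons$start), "-", max(x$exons$end),
      " (", x$strand, "), ", nrow(x$exons), " exon(s), CDS ",
      x$cds_start_g, "-", x$cds_end_g, "\n", sep = "")
  invisible(x)
}

# Exon table in transcript (5'->3') order with cumulative mRNA offsets.
# Columns: start, end, len, m_start, m_end (mRNA coordinates of the exon's
# first/last base in transcript orientation), genomic_index.
tx_exon_map <- function(tx) {
  ex <- tx$exons
  ex$genomic_index <- seq_len(nrow(ex))
  if (tx$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), ]
  ex$len <- ex$end - ex$start + 1L
  ex$m_end <- cumsum(ex$len)
  ex$m_start <- ex$m_end - ex$len + 1L
  ex
}

mrna_length <- function(tx) sum(tx$exons$end - tx$exons$start + 1L)

# Genomic position(s) -> mRNA coordinate; NA for positions not in an exon.
mrna_pos <- function(tx, gpos) {
  map <- tx_exon_map(tx)
  vapply(gpos, function(g) {
    i <- which(g >= map$start & g <= map$end)
    if (length(i) == 0L) return(NA_integer_)
    if (tx$strand == "+") map$m_start[i] + (g - map$start[i])
    else map$m_start[i] + (map$end[i] - g)
  }, integer(1))
}

# mRNA coordinate(s) -> genomic position; errors outside 1..mrna_length.
g_from_mrna <- function(tx, m) {
  map <- tx_exon_map(tx)
  vapply(m, function(mm) {
    i <- which(mm >= map$m_start & mm <= map$m_end)
    if (length(i) == 0L) {
      stop("mRNA coordinate ", mm, " outside transcript", call. = FALSE)
    }
    if (tx$strand == "+") map$start[i] + (mm - map$m_start[i])
    else map$end[i] - (mm - map$m_start[i])
  }, integer(1))
}

# mRNA coordinates of the first and last CDS base (translation start, last
# base of the stop codon).
cds_mrna_bounds <- function(tx) {
  g1 <- if (tx$strand == "+") tx$cds_start_g else tx$cds_end_g
  g2 <- if (tx$strand == "+") tx$cds_end_g else tx$cds_start_g
  c(m1 = mrna_pos(tx, g1), mL = mrna_pos(tx, g2))
}

cds_length <- function(tx) {
  b <- cds_mrna_bounds(tx)
  unname(b["mL"] - b["m1"] + 1L)
}

# Spliced mRNA in transcript orientation.
build_mrna <- function(tx, genome) {
  map <- tx_exon_map(tx)
  pieces <- vapply(seq_len(nrow(map)), function(i) {
    s <- genome_subseq(genome, tx$contig, map$start[i], map$end[i])
    if (tx$strand == "-") revcomp(s) else s
  }, character(1))
  paste(pieces, collapse = "")
}

#' Build the spliced coding sequence of a transcript
#'
#' Concatenates exon sequences in transcript orientation (reverse-complemented
#' for minus-strand models) and extracts the CDS, including the stop codon.
#'
#' @param tx A [transcript_model()].
#' @param genome A [genome_sequence()] containing the transcript's contig.
#' @return Nucleotide string (the CDS, 5'->3' in transcript orientation).
#' @export
build_cds <- function(tx, genome) {
  stopifnot(inherits(tx, "transcript_model"))
  mrna <- build_mrna(tx, genome)
  b <- cds_mrna_bounds(tx)
  substr(mrna, b["m1"], b["mL"])
}

#' Validate a transcript model against a genome
#'
#' Checks that the spliced CDS has length a positive multiple of 3, begins
#' with ATG and ends with a stop codon. Violations are flagged, not fatal:
#' models are input data and may legitimately be incomplete.
#'
#' @param tx A [transcript_model()].
#' @param genome A [genome_sequence()].
#' @return A tibble with columns `check`, `ok`, `detail`.
#' @export
validate_transcript <- function(tx, genome) {
  cds <- build_cds(tx, genome)
  len_ok <- nchar(cds) >= 6L && nchar(cds) %% 3L == 0L
  start_ok <- substr(cds, 1L, 3L) == "ATG"
  last <- substr(cds, nchar(cds) - 2L, nchar(cds))
  stop_ok <- last %in% c("TAA", "TAG", "TGA")
  tibble::tibble(
    transcript_id = tx$transcript_id,
    check = c("cds_length_multiple_of_3", "starts_with_ATG",
              "ends_with_stop"),
    ok = c(len_ok, start_ok, stop_ok),
    detail = c(paste0("CDS length ", nchar(cds)),
               paste0("first codon ", substr(cds, 1, 3)),
               paste0("last codon ", last))
  )
}

#' Read transcript models from a GFF3 file
#'
#' Expects the conventional gene/mRNA/exon/CDS feature hierarchy with
#' `ID`/`Parent` attributes; extra attributes are ignored. One model is built
#' per mRNA feature. When several mRNAs share a gene, [pick_transcript()]
#' applies a longest-CDS tie-break.
#'
#' @param path GFF3 file path.
#' @return Named list of [transcript_model()] objects (names = transcript ids).
#' @export
read_transcripts_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- tibble::as_tibble(as.data.frame(gr))
  df$type <- as.character(df$type)
  # Parent comes back as a CharacterList; flatten (pre-split models assumed)
  df$parent <- vapply(as.list(df$Parent), function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, character(1))
  mrnas <- df[df$type %in% c("mRNA", "transcript"), ]
  out <- list()
  for (i in seq_len(nrow(mrnas))) {
    mid <- as.character(mrnas$ID[i])
    gene <- mrnas$parent[i]
    if (is.na(gene)) gene <- mid
    exons <- df[df$type == "exon" & df$parent == mid, ]
    cds <- df[df$type == "CDS" & df$parent == mid, ]
    if (nrow(exons) == 0L || nrow(cds) == 0L) {
      warning("mRNA ", mid, " lacks exon or CDS features; skipped",
              call. = FALSE)
      next
    }
    out[[mid]] <- transcript_model(
      transcript_id = mid, gene_id = gene,
      contig = as.character(mrnas$seqnames[i]),
      strand = as.character(mrnas$strand[i]),
      exons = data.frame(start = exons$start, end = exons$end),
      cds_start_g = min(cds$start), cds_end_g = max(cds$end)
    )
  }
  out
}

#' Select one transcript per gene
#'
#' One model per gene is assumed downstream; where a gene has several, the
#' longest CDS wins, with transcript id as a deterministic tie-break.
#'
#' @param transcripts List of [transcript_model()] objects.
#' @return Named list with one transcript per gene.
#' @export
pick_transcript <- function(transcripts) {
  if (length(transcripts) == 0L) return(transcripts)
  info <- tibble::tibble(
    idx = seq_along(transcripts),
    transcript_id = vapply(transcripts, `[[`, character(1), "transcript_id"),
    gene_id = vapply(transcripts, `[[`, character(1), "gene_id"),
    cds_len = vapply(transcripts, cds_length, integer(1))
  )
  keep <- info |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(dplyr::desc(.data$cds_len), .data$transcript_id,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  transcripts[keep$idx]
}

#' Write transcript models to GFF3
#'
#' Emits the gene/mRNA/exon/CDS hierarchy readable by
#' [read_transcripts_gff3()].
#'
#' @param transcripts List of [transcript_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts_gff3 <- function(transcripts, path) {
  rows <- purrr::map_dfr(transcripts, function(tx) {
    span <- c(min(tx$exons$start), max(tx$exons$end))
    cds <- cds_genomic_intervals(tx)
    # GFF3 phase: bases to skip at a CDS piece's 5' end (transcript order)
    # to reach a codon boundary
    tx_order <- if (tx$strand == "+") seq_len(nrow(cds))
                else rev(seq_len(nrow(cds)))
    lens <- cds$end - cds$start + 1L
    before <- cumsum(c(0L, lens[tx_order]))[seq_len(nrow(cds))]
    phase <- integer(nrow(cds))
    phase[tx_order] <- (3L - before %% 3L) %% 3L
    dplyr::bind_rows(
      tibble::tibble(type = "gene", start = span[1], end = span[2],
                     ID = tx$gene_id, Parent = NA_character_,
                     phase = NA_integer_),
      tibble::tibble(type = "mRNA", start = span[1], end = span[2],
                     ID = tx$transcript_id, Parent = tx$gene_id,
                     phase = NA_integer_),
      tibble::tibble(type = "exon", start = tx$exons$start,
                     end = tx$exons$end,
                     ID = paste0(tx$transcript_id, ":exon:",
                                 seq_len(nrow(tx$exons))),
                     Parent = tx$transcript_id, phase = NA_integer_),
      tibble::tibble(type = "CDS", start = cds$start, end = cds$end,
                     ID = paste0(tx$transcript_id, ":cds:",
                                 seq_len(nrow(cds))),
                     Parent = tx$transcript_id, phase = phase)
    ) |>
      dplyr::mutate(seqnames = tx$contig, strand = tx$strand)
  })
  gr <- GenomicRanges::GRanges(
    seqnames = rows$seqnames,
    ranges = IRanges::IRanges(rows$start, rows$end),
    strand = rows$strand
  )
  gr$type <- rows$type
  gr$phase <- rows$phase
  gr$ID <- rows$ID
  gr$Parent <- ifelse(is.na(rows$Parent), NA_character_, rows$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# Genomic intervals covered by the CDS (exon pieces clipped to CDS bounds).
cds_genomic_intervals <- function(tx) {
  ex <- tx$exons
  s <- pmax(ex$start, tx$cds_start_g)
  e <- pmin(ex$end, tx$cds_end_g)
  keep <- s <= e
  tibble::tibble(start = s[keep], end = e[keep])
}
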