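# Genomic <-> CDS-relative (c.) coordinate mapping. Coding positions are
# 1-based within the CDS (c.1 = first base of the start codon, the stop codon
# included); intronic positions are anchored to the nearest exonic base with a
# signed offset (donor side +k, acceptor side -k, in transcript orientation);
# 5'UTR positions carry negative offsets (c.-k) and 3'UTR positions positive
# offsets past the stop (c.*k).

#' Map genomic positions to CDS-relative coordinates
#'
#' @param tx A [transcript_model()].
#' @param gpos Vector of 1-based genomic positions on the transcript's contig.
#' @param flank How far beyond the transcript span (bp) a position may lie and
#'   still be mapped (labelled upstream/downstream UTR-relative); farther is
#'   an error. Default 5000.
#' @return A tibble with one row per position: `gpos`, `region`
#'   (`cds`/`intron`/`utr5`/`utr3`), `coding_offset` (the c. number: 1..L for
#'   CDS, negative for 5'UTR, bases past the stop for 3'UTR; for intronic rows
#'   the anchor's c. number), `intron_offset` (0 for exonic rows, signed for
#'   intronic), `anchor_region` and `anchor_m` (mRNA coordinate of the anchor
#'   base; internal bookkeeping that makes [c_to_g()] an exact inverse).
#' @export
g_to_c <- function(tx, gpos, flank = 5000L) {
  stopifnot(inherits(tx, "transcript_model"))
  b <- cds_mrna_bounds(tx)
  m1 <- unname(b["m1"]); mL <- unname(b["mL"])
  Lm <- mrna_length(tx)
  span <- c(min(tx$exons$start), max(tx$exons$end))
  ex <- tx$exons

  one <- function(g) {
    if (g < span[1] - flank || g > span[2] + flank) {
      stop("position ", g, " outside transcript span +/- ", flank, " bp",
           call. = FALSE)
    }
    m <- mrna_pos(tx, g)
    if (!is.na(m)) {                       # exonic
      return(exonic_cpos(g, m, m1, mL))
    }
    if (g >= span[1] && g <= span[2]) {    # intronic
      i <- which(ex$end < g)
      i <- i[length(i)]                    # genomic exon upstream of g
      d_low <- g - ex$end[i]               # distance to lower exon's last base
      d_high <- ex$start[i + 1] - g        # distance to upper exon's first base
      if (tx$strand == "+") {
        d_prev <- d_low; d_next <- d_high
        g_prev <- ex$end[i]; g_next <- ex$start[i + 1]
      } else {
        d_prev <- d_high; d_next <- d_low
        g_prev <- ex$start[i + 1]; g_next <- ex$end[i]
      }
      # nearest exonic base wins; ties go to the donor (+) side
      if (d_prev <= d_next) {
        anchor_g <- g_prev; off <- d_prev
      } else {
        anchor_g <- g_next; off <- -d_next
      }
      anchor_m <- mrna_pos(tx, anchor_g)
      anchor <- exonic_cpos(anchor_g, anchor_m, m1, mL)
      return(tibble::tibble(
        gpos = g, region = "intron", coding_offset = anchor$coding_offset,
        intron_offset = as.integer(off), anchor_region = anchor$region,
        anchor_m = anchor_m
      ))
    }
    # beyond the transcript span but within the flank: extend the mRNA scale
    if ((tx$strand == "+" && g < span[1]) ||
        (tx$strand == "-" && g > span[2])) {
      d <- if (tx$strand == "+") span[1] - g else g - span[2]
      m_virtual <- 1L - d                  # upstream of transcript start
    } else {
      d <- if (tx$strand == "+") g - span[2] else span[1] - g
      m_virtual <- Lm + d                  # downstream of transcript end
    }
    exonic_cpos(g, m_virtual, m1, mL)
  }

  exonic_cpos <- function(g, m, m1, mL) {
    if (m < m1) {
      tibble::tibble(gpos = g, region = "utr5",
                     coding_offset = as.integer(m - m1),
                     intron_offset = 0L, anchor_region = "utr5",
                     anchor_m = as.integer(m))
    } else if (m > mL) {
      tibble::tibble(gpos = g, region = "utr3",
                     coding_offset = as.integer(m - mL),
                     intron_offset = 0L, anchor_region = "utr3",
                     anchor_m = as.integer(m))
    } else {
      tibble::tibble(gpos = g, region = "cds",
                     coding_offset = as.integer(m - m1 + 1L),
                     intron_offset = 0L, anchor_region = "cds",
                     anchor_m = as.integer(m))
    }
  }

  purrr::map_dfr(as.integer(gpos), one)
}

#' Map CDS-relative coordinates back to genomic positions
#'
#' Exact inverse of [g_to_c()] on its image: feed it the tibble [g_to_c()]
#' returns (or an equivalent one) and get the genomic positions back.
#'
#' @param tx A [transcript_model()].
#' @param cpos A data frame with columns `region`, `coding_offset`,
#'   `intron_offset`, and optionally `anchor_m` (used for intronic rows whose
#'   anchor lies in a UTR). Rows as produced by [g_to_c()].
#' @return Integer vector of genomic positions.
#' @export
c_to_g <- function(tx, cpos) {
  stopifnot(inherits(tx, "transcript_model"), is.data.frame(cpos))
  b <- cds_mrna_bounds(tx)
  m1 <- unname(b["m1"]); mL <- unname(b["mL"])
  Lm <- mrna_length(tx)
  L <- mL - m1 + 1L
  span <- c(min(tx$exons$start), max(tx$exons$end))
  has_anchor <- "anchor_m" %in% names(cpos)

  g_from_m_extended <- function(m) {
    if (m >= 1L && m <= Lm) return(g_from_mrna(tx, m))
    if (m < 1L) {
      d <- 1L - m
      if (tx$strand == "+") span[1] - d else span[2] + d
    } else {
      d <- m - Lm
      if (tx$strand == "+") span[2] + d else span[1] - d
    }
  }

  vapply(seq_len(nrow(cpos)), function(i) {
    region <- cpos$region[i]
    off <- as.integer(cpos$coding_offset[i])
    ioff <- as.integer(cpos$intron_offset[i])
    if (region == "intron") {
      if (ioff == 0L) stop("intron row with zero intron_offset", call. = FALSE)
      anchor_m <- if (has_anchor && !is.na(cpos$anchor_m[i])) {
        as.integer(cpos$anchor_m[i])
      } else {
        ar <- if ("anchor_region" %in% names(cpos)) cpos$anchor_region[i]
              else "cds"
        switch(ar,
               cds = m1 + off - 1L,
               utr5 = m1 + off,
               utr3 = mL + off,
               stop("unknown anchor_region", call. = FALSE))
      }
      g_anchor <- g_from_mrna(tx, anchor_m)
      dirn <- if (tx$strand == "+") 1L else -1L
      return(as.integer(g_anchor + dirn * ioff))
    }
    if (ioff != 0L) stop("exonic row with non-zero intron_offset",
                         call. = FALSE)
    m <- switch(region,
                cds = {
                  if (off < 1L || off > L) {
                    stop("coding_offset ", off, " outside CDS (1-", L, ")",
                         call. = FALSE)
                  }
                  m1 + off - 1L
                },
                utr5 = m1 + off,
                utr3 = mL + off,
                stop("unknown region '", region, "'", call. = FALSE))
    as.integer(g_from_m_extended(m))
  }, integer(1))
}

#' Format a c. position in HGVS style
#'
#' Renders one row of [g_to_c()] output as the conventional coding-DNA
#' position string: `"1755+1"` for the first donor base after coding position
#' 1755, `"-12"` for a 5'UTR base, `"*14"` for a 3'UTR base.
#'
#' @param cpos One-row data frame as returned by [g_to_c()].
#' @return Character scalar (position only, no alleles).
#' @export
format_c_notation <- function(cpos) {
  stopifnot(is.data.frame(cpos), nrow(cpos) == 1L)
  format_c_position(cpos)
}

# HGVS-style c. position string for one g_to_c row ("1755+1", "-12", "*14").
format_c_position <- function(cpos_row) {
  anchor_str <- switch(cpos_row$anchor_region,
                       cds = as.character(cpos_row$coding_offset),
                       utr5 = as.character(cpos_row$coding_offset),  # negative
                       utr3 = paste0("*", cpos_row$coding_offset))
  if (cpos_row$region == "intron") {
    sign <- if (cpos_row$intron_offset > 0) "+" else "-"
    paste0(anchor_str, sign, abs(cpos_row$intron_offset))
  } else {
    anchor_str
  }
}
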