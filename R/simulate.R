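# Deterministic synthetic-cohort simulator. Everything downstream of this
# module -- consequence calls, segregation, prioritization, burden -- can run
# on inputs generated here, written in standard formats (FASTA/GFF3/VCF/PED/
# TSV). One root seed drives named per-component streams (see derive_seed),
# so adding a component never perturbs the draws of another.

#' Simulation configuration
#'
#' Defaults mirror the study design the package emulates: a discovery arm of
#' 23 families with about 66 genotyped individuals carrying a dominantly
#' transmitted, incompletely penetrant risk allele, and a case-control burden
#' arm of 781 cases vs 3534 controls with carrier frequencies 30/781 and
#' 72/3534.
#'
#' @param seed Integer root seed (mandatory; there is no implicit entropy).
#' @param n_genes Number of simulated genes (one per contig).
#' @param exons_per_gene Integer range (min, max) of exons per gene; genes
#'   need at least 3 exons for an internal exon to be skippable.
#' @param exon_length_range Range (min, max) of coding bases per exon.
#' @param n_families Number of families in the discovery arm.
#' @param pedigree_depth Generations per pedigree (2 or 3).
#' @param penetrance_carrier,penetrance_background Probability of being
#'   affected (MM or MGUS) for risk-allele carriers (`f1`) and non-carriers
#'   (`f0`); `f1 >= f0`.
#' @param n_cases,n_controls Case-control arm sizes.
#' @param carrier_freq_cases,carrier_freq_controls Qualifying-carrier
#'   frequencies in the two arms.
#' @param mean_depth Mean sequencing depth (Poisson) for depth-resolved
#'   genotype calls.
#' @param background_lof_rate Poisson rate of background singleton
#'   loss-of-function variants per family.
#' @param n_spiked_families Families into which the spiked risk allele is
#'   seeded.
#' @param n_genotyped Total genotyped individuals in the discovery arm
#'   (carriers and affected members are genotyped first, as screening would).
#' @param allelic_bias Expected alternate-allele fraction of a heterozygote
#'   read draw (default 0.5, the germline expectation; a negative-control
#'   knob, not a default dial).
#' @return An object of class `sim_config` (validated list).
#' @export
sim_config <- function(seed,
                       n_genes = 20L,
                       exons_per_gene = c(4L, 7L),
                       exon_length_range = c(60L, 120L),
                       n_families = 23L,
                       pedigree_depth = 3L,
                       penetrance_carrier = 0.5,
                       penetrance_background = 0.02,
                       n_cases = 781L,
                       n_controls = 3534L,
                       carrier_freq_cases = 30 / 781,
                       carrier_freq_controls = 72 / 3534,
                       mean_depth = 100,
                       background_lof_rate = 0.3,
                       n_spiked_families = 2L,
                       n_genotyped = 66L,
                       allelic_bias = 0.5) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed is mandatory (integer)", call. = FALSE)
  }
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length_range = as.integer(exon_length_range),
              n_families = as.integer(n_families),
              pedigree_depth = as.integer(pedigree_depth),
              penetrance_carrier = penetrance_carrier,
              penetrance_background = penetrance_background,
              n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              carrier_freq_cases = carrier_freq_cases,
              carrier_freq_controls = carrier_freq_controls,
              mean_depth = mean_depth,
              background_lof_rate = background_lof_rate,
              n_spiked_families = as.integer(n_spiked_families),
              n_genotyped = as.integer(n_genotyped),
              allelic_bias = allelic_bias)
  freqs <- c(cfg$carrier_freq_cases, cfg$carrier_freq_controls,
             cfg$penetrance_carrier, cfg$penetrance_background,
             cfg$allelic_bias)
  if (any(freqs < 0) || any(freqs > 1)) {
    stop("frequencies and penetrances must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$penetrance_carrier < cfg$penetrance_background) {
    stop("penetrance_carrier must be >= penetrance_background", call. = FALSE)
  }
  if (cfg$exons_per_gene[1] < 1L) {
    stop("exons_per_gene must be at least 1", call. = FALSE)
  }
  if (cfg$n_spiked_families > cfg$n_families) {
    stop("n_spiked_families exceeds n_families", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

sense_codons <- function() {
  tab <- codon_table()
  names(tab)[tab != "*"]
}

#' Simulate reference contigs and transcript models
#'
#' One multi-exon gene per contig, on alternating strands; UTRs in the first
#' and last exon, canonical GT..AG introns, spliced CDS guaranteed to start
#' with ATG, end with a stop and have length a multiple of 3. Deterministic
#' given the config seed.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (a [genome_sequence()]) and `transcripts`
#'   (named list of [transcript_model()]).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(derive_seed(config$seed, "reference"), {
    contigs <- character(0)
    transcripts <- list()
    for (g in seq_len(config$n_genes)) {
      gene_id <- sprintf("gene%02d", g)
      tx_id <- sprintf("tx%02d", g)
      contig <- sprintf("ctg%02d", g)
      strand <- if (g %% 2L == 0L) "-" else "+"
      n_ex <- sample_range(config$exons_per_gene[1], config$exons_per_gene[2])
      chunk <- sample_range(config$exon_length_range[1],
                            config$exon_length_range[2], n_ex)
      excess <- sum(chunk) %% 3L
      chunk[n_ex] <- chunk[n_ex] - excess     # total coding length %% 3 == 0
      n_codons <- sum(chunk) %/% 3L
      cds <- paste0("ATG",
                    paste(sample(sense_codons(), n_codons - 2L,
                                 replace = TRUE), collapse = ""),
                    sample(c("TAA", "TAG", "TGA"), 1L))
      utr5 <- random_dna(sample_range(20L, 60L))
      utr3 <- random_dna(sample_range(30L, 100L))
      introns <- vapply(seq_len(n_ex - 1L), function(i) {
        paste0("GT", random_dna(sample_range(50L, 200L) - 4L), "AG")
      }, character(1))
      pad5 <- random_dna(sample_range(30L, 80L))
      pad3 <- random_dna(sample_range(30L, 80L))

      # assemble forward layout, tracking exon coordinates as we go
      cursor <- nchar(pad5)
      pieces <- pad5
      exon_start <- integer(n_ex); exon_end <- integer(n_ex)
      cds_chunks <- split_cds(cds, chunk)
      for (i in seq_len(n_ex)) {
        exon_seq <- paste0(if (i == 1L) utr5 else "",
                           cds_chunks[i],
                           if (i == n_ex) utr3 else "")
        exon_start[i] <- cursor + 1L
        cursor <- cursor + nchar(exon_seq)
        exon_end[i] <- cursor
        pieces <- paste0(pieces, exon_seq)
        if (i < n_ex) {
          pieces <- paste0(pieces, introns[i])
          cursor <- cursor + nchar(introns[i])
        }
      }
      pieces <- paste0(pieces, pad3)
      cds_start_g <- exon_start[1] + nchar(utr5)
      cds_end_g <- exon_end[n_ex] - nchar(utr3)

      if (strand == "-") {
        len <- nchar(pieces)
        pieces <- revcomp(pieces)
        new_start <- len - exon_end + 1L
        new_end <- len - exon_start + 1L
        exon_start <- rev(new_start); exon_end <- rev(new_end)
        cds_bounds <- sort(c(len - cds_start_g + 1L, len - cds_end_g + 1L))
        cds_start_g <- cds_bounds[1]; cds_end_g <- cds_bounds[2]
      }

      contigs[contig] <- pieces
      transcripts[[tx_id]] <- transcript_model(
        tx_id, gene_id, contig, strand,
        data.frame(start = exon_start, end = exon_end),
        cds_start_g, cds_end_g
      )
    }
    list(genome = genome_sequence(contigs), transcripts = transcripts)
  })
}

# Split a CDS string into chunks of the given lengths.
split_cds <- function(cds, lengths) {
  stopifnot(sum(lengths) == nchar(cds))
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1L
  substring(cds, starts, ends)
}

#' Propose an SNV of a requested consequence class on a transcript
#'
#' Scans the transcript for the first position (after a seeded random start
#' offset) where a single-nucleotide change produces the requested class.
#' Returned alleles are genome-forward.
#'
#' @param tx A [transcript_model()].
#' @param genome A [genome_sequence()].
#' @param klass One of `"stop_gain"`, `"synonymous"`, `"missense"`,
#'   `"splice_donor"`, `"stop_loss"`.
#' @param exon_index For `"splice_donor"`: transcript-order exon whose donor
#'   site to hit (default: first internal coding exon).
#' @param avoid Variant keys to avoid (so repeated proposals stay distinct).
#' @return One-row tibble `contig`, `pos`, `ref`, `alt`, `gene_id`, `key`.
#' @export
propose_snv <- function(tx, genome, klass, exon_index = NULL, avoid = NULL) {
  tab <- codon_table()
  bases <- c("A", "C", "G", "T")
  to_fwd <- function(b) if (tx$strand == "-") comp_base(b) else b
  mk <- function(g, t_ref, t_alt) {
    tibble::tibble(contig = tx$contig, pos = g,
                   ref = to_fwd(t_ref), alt = to_fwd(t_alt),
                   gene_id = tx$gene_id) |>
      dplyr::mutate(key = variant_key(.data$contig, .data$pos, .data$ref,
                                      .data$alt))
  }

  if (klass == "splice_donor") {
    map <- tx_exon_map(tx)
    if (is.null(exon_index)) {
      internal <- internal_coding_exons(tx)
      if (length(internal) == 0L) {
        stop("transcript has no internal coding exon to disrupt",
             call. = FALSE)
      }
      exon_index <- internal[1]
    }
    ex <- map[exon_index, ]
    g <- if (tx$strand == "+") ex$end + 1L else ex$start - 1L
    t_ref <- if (tx$strand == "+") genome_subseq(genome, tx$contig, g, g)
             else comp_base(genome_subseq(genome, tx$contig, g, g))
    t_alt <- setdiff(c("T", "A", "C"), t_ref)[1]
    return(mk(g, t_ref, t_alt))
  }

  cds <- build_cds(tx, genome)
  L <- nchar(cds)
  n_codons <- L %/% 3L

  if (klass == "stop_loss") {
    stop_codon <- substr(cds, L - 2L, L)
    for (w in 1:3) {
      t_ref <- substr(stop_codon, w, w)
      for (t_alt in setdiff(bases, t_ref)) {
        new <- stop_codon
        substr(new, w, w) <- t_alt
        if (tab[new] != "*") {
          g <- c_to_g(tx, tibble::tibble(region = "cds",
                                         coding_offset = L - 3L + w,
                                         intron_offset = 0L))
          cand <- mk(g, t_ref, t_alt)
          if (!cand$key %in% avoid) return(cand)
        }
      }
    }
    stop("no stop-loss SNV available", call. = FALSE)
  }

  # coding classes: scan codons from a random start for variety
  offset <- sample.int(n_codons - 2L, 1L)
  for (ci in c(seq(offset, n_codons - 1L), seq_len(offset - 1L))) {
    if (ci == 1L) next                      # keep the start codon intact
    cst <- (ci - 1L) * 3L + 1L
    codon <- substr(cds, cst, cst + 2L)
    for (w in 1:3) {
      t_ref <- substr(codon, w, w)
      for (t_alt in setdiff(bases, t_ref)) {
        new <- codon
        substr(new, w, w) <- t_alt
        ok <- switch(klass,
          stop_gain = tab[codon] != "*" && tab[new] == "*",
          synonymous = tab[codon] == tab[new] && tab[codon] != "*",
          missense = tab[codon] != tab[new] && tab[codon] != "*" &&
            tab[new] != "*",
          stop("unknown class '", klass, "'", call. = FALSE))
        if (ok) {
          g <- c_to_g(tx, tibble::tibble(region = "cds",
                                         coding_offset = cst + w - 1L,
                                         intron_offset = 0L))
          cand <- mk(g, t_ref, t_alt)
          if (!cand$key %in% avoid) return(cand)
        }
      }
    }
  }
  stop("no ", klass, " SNV available on this transcript", call. = FALSE)
}

# Transcript-order indices of exons fully inside the CDS (skippable).
internal_coding_exons <- function(tx) {
  map <- tx_exon_map(tx)
  n <- nrow(map)
  idx <- seq_len(n)
  keep <- idx > 1L & idx < n &
    map$start > min(tx$cds_start_g, tx$cds_end_g) &
    map$end < max(tx$cds_start_g, tx$cds_end_g) &
    map$start >= tx$cds_start_g & map$end <= tx$cds_end_g
  idx[keep]
}

#' Simulate pedigrees with a dominantly transmitted risk allele
#'
#' Builds `n_families` multi-generation pedigrees; in the first
#' `n_spiked_families` families a founder carries the spiked allele
#' heterozygously and transmits it under strict Mendelian rules. Affection is
#' drawn with penetrance `f1` for carriers and `f0` for non-carriers, so
#' unaffected carriers and affected non-carriers (phenocopies) arise at the
#' rates those parameters force. One carrier founder per spiked family is set
#' affected (the proband through whom the family would ascertain). Background
#' singleton loss-of-function variants are seeded into non-spiked genes at
#' `background_lof_rate` per family. Genotype calls are depth-resolved:
#' depth ~ Poisson(`mean_depth`), heterozygote alternate reads ~
#' Binomial(depth, `allelic_bias`); a depth of zero is emitted as a missing
#' call.
#'
#' @param config A [sim_config()].
#' @param reference Output of [simulate_reference()].
#' @param spiked_tx Transcript (model or id) carrying the spiked variant;
#'   default the first transcript.
#' @param spiked_variant One-row tibble (`contig`, `pos`, `ref`, `alt`) of a
#'   qualifying variant in `spiked_tx`; default a splice-donor +1 SNV of its
#'   first internal coding exon.
#' @param plant_discordant Force one genotyped non-carrier in the first spiked
#'   family to be affected, so a family-D-style discordant segregation pattern
#'   is present by construction (default `TRUE`).
#' @param background_collisions `"avoid"` (default) samples background genes
#'   without replacement across families, so no background gene recurs in two
#'   families; `"allow"` samples independently.
#' @return List: `ped` (pedigree tibble), `genotypes` (depth-resolved calls,
#'   platform `"wes"`, plus confirmatory `"targeted"` re-calls of the spiked
#'   variant), `variants` (simulated variant table with `gene_id` and `label`
#'   `"spiked"`/`"background"`), `spiked_key`, `spiked_gene`.
#' @export
simulate_families <- function(config, reference,
                              spiked_tx = NULL, spiked_variant = NULL,
                              plant_discordant = TRUE,
                              background_collisions = c("avoid", "allow")) {
  stopifnot(inherits(config, "sim_config"))
  background_collisions <- match.arg(background_collisions)
  transcripts <- reference$transcripts
  genome <- reference$genome
  if (is.null(spiked_tx)) spiked_tx <- transcripts[[1]]
  if (is.character(spiked_tx)) spiked_tx <- transcripts[[spiked_tx]]

  withr::with_seed(derive_seed(config$seed, "families"), {
    if (is.null(spiked_variant)) {
      spiked_variant <- propose_snv(spiked_tx, genome, "splice_donor")
    }
    spiked_variant <- tibble::as_tibble(spiked_variant)[
      1, c("contig", "pos", "ref", "alt")]
    spiked_variant$gene_id <- spiked_tx$gene_id
    spiked_variant$key <- variant_key(spiked_variant$contig,
                                      spiked_variant$pos,
                                      spiked_variant$ref, spiked_variant$alt)

    f1 <- config$penetrance_carrier
    f0 <- config$penetrance_background
    ped_rows <- list()
    carrier_rows <- list()          # individual_id x key -> allele_count
    variants <- list(spiked = dplyr::mutate(spiked_variant,
                                            label = "spiked"))

    other_tx <- transcripts[vapply(transcripts, function(t) {
      t$gene_id != spiked_tx$gene_id
    }, logical(1))]
    bg_pool <- names(other_tx)

    for (f in seq_len(config$n_families)) {
      fam <- sprintf("FAM%02d", f)
      spiked_here <- f <= config$n_spiked_families
      fam_ped <- build_pedigree(fam, config$pedigree_depth)
      # dominant transmission of the spiked allele from founder <fam>_P1
      carrier <- if (spiked_here) {
        transmit_dominant(fam_ped, paste0(fam, "_P1"))
      } else {
        stats::setNames(rep(0L, nrow(fam_ped)), fam_ped$individual_id)
      }
      # penetrance draw
      aff <- stats::rbinom(nrow(fam_ped), 1L,
                           ifelse(carrier[fam_ped$individual_id] > 0L,
                                  f1, f0)) == 1L
      pheno <- ifelse(aff, sample(c("MM", "MGUS"), nrow(fam_ped),
                                  replace = TRUE), "unaffected")
      if (spiked_here) pheno[fam_ped$individual_id == paste0(fam, "_P1")] <-
        "MM"                               # affected carrier proband
      if (spiked_here && plant_discordant && f == 1L) {
        noncar <- fam_ped$individual_id[
          carrier[fam_ped$individual_id] == 0L &
            fam_ped$individual_id != paste0(fam, "_P1")]
        if (length(noncar) > 0L) {
          pheno[fam_ped$individual_id == noncar[1]] <- "MM"
        }
      }
      fam_ped$phenotype <- pheno
      ped_rows[[fam]] <- fam_ped
      if (spiked_here) {
        carrier_rows[[paste0(fam, ":spiked")]] <- tibble::tibble(
          individual_id = names(carrier),
          key = spiked_variant$key,
          allele_count = unname(carrier)
        )
      }

      # background singleton LoF in this family
      n_bg <- stats::rpois(1L, config$background_lof_rate)
      n_bg <- min(n_bg, length(bg_pool))
      if (n_bg > 0L) {
        gidx <- sample(seq_along(bg_pool), n_bg)
        for (tx_name in bg_pool[gidx]) {
          bgtx <- transcripts[[tx_name]]
          bg <- propose_snv(bgtx, genome, "stop_gain",
                            avoid = purrr::map_chr(variants, function(v)
                              v$key[1]))
          bg$label <- "background"
          variants[[paste0(fam, ":", tx_name)]] <- bg
          # background alleles also enter through a founder and transmit
          # under strict Mendelian rules; ascertainment prefers a founder on
          # the affected branch (an affected founder when one exists)
          founders <- fam_ped$individual_id[is.na(fam_ped$father_id) &
                                              is.na(fam_ped$mother_id)]
          aff_founders <- founders[
            fam_ped$phenotype[match(founders, fam_ped$individual_id)] %in%
              c("MM", "MGUS")]
          origin <- if (length(aff_founders) > 0L) aff_founders[1]
                    else founders[sample.int(length(founders), 1L)]
          bg_carrier <- transmit_dominant(fam_ped, origin)
          carrier_rows[[paste0(fam, ":", tx_name)]] <- tibble::tibble(
            individual_id = names(bg_carrier),
            key = bg$key, allele_count = unname(bg_carrier)
          )
        }
        if (background_collisions == "avoid") {
          bg_pool <- bg_pool[-gidx]
        }
      }
    }

    ped <- dplyr::bind_rows(ped_rows)
    variants <- dplyr::bind_rows(variants)

    # choose genotyped subset: carriers and affected first, then fill
    nonzero <- dplyr::bind_rows(carrier_rows) |>
      dplyr::filter(.data$allele_count > 0L)
    genotyped <- select_genotyped(ped, nonzero$individual_id,
                                  config$n_genotyped)

    genotypes <- depth_resolved_calls(
      ped |> dplyr::filter(.data$individual_id %in% genotyped),
      variants, dplyr::bind_rows(carrier_rows), config, platform = "wes"
    )
    # confirmatory targeted re-calls of the spiked variant in spiked families
    spiked_fams <- sprintf("FAM%02d", seq_len(config$n_spiked_families))
    confirm <- genotypes |>
      dplyr::filter(.data$key == spiked_variant$key,
                    .data$individual_id %in%
                      ped$individual_id[ped$family_id %in% spiked_fams],
                    !is.na(.data$allele_count))
    if (nrow(confirm) > 0L) {
      depth_reads <- pmax(1L, stats::rpois(nrow(confirm), config$mean_depth))
      alt_reads <- ifelse(
        confirm$allele_count == 1L,
        stats::rbinom(nrow(confirm), depth_reads, config$allelic_bias),
        ifelse(confirm$allele_count == 2L, depth_reads, 0L))
      confirm <- confirm |>
        dplyr::mutate(platform = "targeted",
                      ref_depth = depth_reads - alt_reads,
                      alt_depth = alt_reads)
      genotypes <- dplyr::bind_rows(genotypes, confirm)
    }

    list(ped = ped, genotypes = genotypes, variants = variants,
         spiked_key = spiked_variant$key, spiked_gene = spiked_tx$gene_id)
  })
}

# Dominant single-allele drop through a pedigree: the founder is
# heterozygous, every child of a carrier inherits with probability 1/2
# (pedigree rows must list parents before children).
transmit_dominant <- function(fam_ped, founder_id) {
  carrier <- stats::setNames(rep(0L, nrow(fam_ped)), fam_ped$individual_id)
  carrier[founder_id] <- 1L
  for (i in seq_len(nrow(fam_ped))) {
    id <- fam_ped$individual_id[i]
    fa <- fam_ped$father_id[i]; mo <- fam_ped$mother_id[i]
    if (is.na(fa) && is.na(mo)) next
    inherited <- 0L
    for (p in c(fa, mo)) {
      if (!is.na(p) && carrier[[p]] == 1L) {
        inherited <- inherited + stats::rbinom(1L, 1L, 0.5)
      }
    }
    carrier[[id]] <- min(inherited, 1L)
  }
  carrier
}

# A 2- or 3-generation pedigree skeleton for one family. Founders coded 0;
# ids <fam>_P1/_P2 (founders), _S<j> (married-in spouses), _C<j> (children),
# _G<j> (grandchildren).
build_pedigree <- function(fam, depth) {
  p1 <- paste0(fam, "_P1"); p2 <- paste0(fam, "_P2")
  rows <- list(
    tibble::tibble(family_id = fam, individual_id = c(p1, p2),
                   father_id = NA_character_, mother_id = NA_character_,
                   sex = c("1", "2"), phenotype = "unaffected")
  )
  n_children <- sample_range(2L, 4L)
  kid_ids <- paste0(fam, "_C", seq_len(n_children))
  kid_sex <- sample(c("1", "2"), n_children, replace = TRUE)
  rows$children <- tibble::tibble(
    family_id = fam, individual_id = kid_ids,
    father_id = p1, mother_id = p2, sex = kid_sex, phenotype = "unaffected"
  )
  if (depth >= 3L) {
    g <- 0L
    for (j in seq_len(n_children)) {
      if (stats::rbinom(1L, 1L, 0.8) == 0L) next    # not every child reproduces
      spouse <- paste0(fam, "_S", j)
      spouse_sex <- if (kid_sex[j] == "1") "2" else "1"
      rows[[paste0("sp", j)]] <- tibble::tibble(
        family_id = fam, individual_id = spouse,
        father_id = NA_character_, mother_id = NA_character_,
        sex = spouse_sex, phenotype = "unaffected"
      )
      n_g <- sample_range(1L, 3L)
      gids <- paste0(fam, "_G", g + seq_len(n_g))
      g <- g + n_g
      father <- if (kid_sex[j] == "1") kid_ids[j] else spouse
      mother <- if (kid_sex[j] == "1") spouse else kid_ids[j]
      rows[[paste0("g", j)]] <- tibble::tibble(
        family_id = fam, individual_id = gids,
        father_id = father, mother_id = mother,
        sex = sample(c("1", "2"), n_g, replace = TRUE),
        phenotype = "unaffected"
      )
    }
  }
  dplyr::bind_rows(rows)
}

# Pick the genotyped subset: all carriers, then affected, then random fill
# distributed across families up to n_total.
select_genotyped <- function(ped, carrier_ids, n_total) {
  must <- unique(c(carrier_ids,
                   ped$individual_id[ped$phenotype %in% c("MM", "MGUS")]))
  must <- intersect(must, ped$individual_id)
  if (length(must) >= n_total) return(must)
  rest <- setdiff(ped$individual_id, must)
  fill <- sample(rest, min(length(rest), n_total - length(must)))
  c(must, fill)
}

# Expand carrier assignments to a full calls table with simulated read depths.
depth_resolved_calls <- function(ped, variants, carrier_rows, config,
                                 platform = "wes") {
  grid <- tidyr::expand_grid(
    individual_id = ped$individual_id,
    key = variants$key
  ) |>
    dplyr::left_join(carrier_rows, by = c("individual_id", "key")) |>
    dplyr::mutate(allele_count = dplyr::coalesce(.data$allele_count, 0L)) |>
    dplyr::left_join(
      variants |> dplyr::select("key", "contig", "pos", "ref", "alt"),
      by = "key"
    )
  n <- nrow(grid)
  depth_reads <- stats::rpois(n, config$mean_depth)
  alt_reads <- integer(n)
  het <- grid$allele_count == 1L & depth_reads > 0L
  hom <- grid$allele_count == 2L
  alt_reads[het] <- stats::rbinom(sum(het), depth_reads[het],
                                  config$allelic_bias)
  alt_reads[hom] <- depth_reads[hom]
  grid |>
    dplyr::mutate(
      allele_count = dplyr::if_else(depth_reads == 0L, NA_integer_,
                                    .data$allele_count),
      ref_depth = depth_reads - alt_reads, alt_depth = alt_reads,
      platform = platform
    ) |>
    dplyr::select("individual_id", "contig", "pos", "ref", "alt", "key",
                  "allele_count", "ref_depth", "alt_depth", "platform")
}

#' Simulate a case-control genotype matrix
#'
#' Carrier status is drawn per individual at the configured arm frequencies;
#' each carrier receives one qualifying variant uniformly from the gene mask.
#' `"exact"` mode assigns exactly `round(freq * n)` carriers per arm
#' (hypergeometric assignment), making downstream counts analytically forced;
#' `"bernoulli"` draws independently, making them stochastic with known
#' expectations. A synonymous (neutral) mask is simulated the same way at
#' equal frequency in both arms unless overridden.
#'
#' @param config A [sim_config()].
#' @param mask Tibble of qualifying variants (`contig`, `pos`, `ref`, `alt`,
#'   `key`).
#' @param mode `"bernoulli"` or `"exact"`.
#' @param synonymous_mask Optional tibble of neutral variants.
#' @param syn_freq_cases,syn_freq_controls Neutral carrier frequencies
#'   (default 0.10 in both arms: no systemic bias).
#' @param depths Simulate read depths (default `TRUE`; `FALSE` emits
#'   depth-free calls, faster for replicated statistical runs).
#' @return List: `genotypes` (long calls table, platform `"simulated"`),
#'   `phenotypes` (`individual_id`, `group`).
#' @export
simulate_case_control <- function(config, mask,
                                  mode = c("bernoulli", "exact"),
                                  synonymous_mask = NULL,
                                  syn_freq_cases = 0.10,
                                  syn_freq_controls = 0.10,
                                  depths = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  mode <- match.arg(mode)
  mask <- tibble::as_tibble(mask)
  if (!"key" %in% names(mask)) {
    mask$key <- variant_key(mask$contig, mask$pos, mask$ref, mask$alt)
  }
  withr::with_seed(derive_seed(config$seed, "case_control"), {
    ids <- c(sprintf("CASE%04d", seq_len(config$n_cases)),
             sprintf("CTRL%04d", seq_len(config$n_controls)))
    group <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
    phenotypes <- tibble::tibble(individual_id = ids, group = group)

    draw_carriers <- function(n, freq) {
      if (mode == "exact") {
        k <- round(freq * n)
        idx <- rep(FALSE, n); idx[sample.int(n, k)] <- TRUE
        idx
      } else {
        stats::rbinom(n, 1L, freq) == 1L
      }
    }
    assign_mask <- function(carrier_flags, mask_tbl) {
      n_carrier <- sum(carrier_flags)
      picked <- mask_tbl$key[sample.int(nrow(mask_tbl), n_carrier,
                                        replace = TRUE)]
      out <- rep(NA_character_, length(carrier_flags))
      out[carrier_flags] <- picked
      out
    }

    carrier <- c(draw_carriers(config$n_cases, config$carrier_freq_cases),
                 draw_carriers(config$n_controls,
                               config$carrier_freq_controls))
    assigned <- assign_mask(carrier, mask)
    gts <- genotype_long(ids, mask, assigned, config, depths)

    if (!is.null(synonymous_mask)) {
      synonymous_mask <- tibble::as_tibble(synonymous_mask)
      if (!"key" %in% names(synonymous_mask)) {
        synonymous_mask$key <- variant_key(
          synonymous_mask$contig, synonymous_mask$pos,
          synonymous_mask$ref, synonymous_mask$alt)
      }
      syn_carrier <- c(draw_carriers(config$n_cases, syn_freq_cases),
                       draw_carriers(config$n_controls, syn_freq_controls))
      syn_assigned <- assign_mask(syn_carrier, synonymous_mask)
      gts <- dplyr::bind_rows(
        gts, genotype_long(ids, synonymous_mask, syn_assigned, config, depths)
      )
    }
    list(genotypes = gts, phenotypes = phenotypes)
  })
}

# Long genotype table for a mask: one row per individual x variant,
# allele_count 1 where `assigned` matches the variant key.
genotype_long <- function(ids, mask_tbl, assigned, config, depths) {
  grid <- tidyr::expand_grid(individual_id = ids, key = mask_tbl$key) |>
    dplyr::left_join(
      tibble::tibble(individual_id = ids, assigned = assigned),
      by = "individual_id"
    ) |>
    dplyr::mutate(allele_count =
                    dplyr::if_else(!is.na(.data$assigned) &
                                     .data$assigned == .data$key, 1L, 0L)) |>
    dplyr::select(-"assigned") |>
    dplyr::left_join(
      mask_tbl |> dplyr::select("key", "contig", "pos", "ref", "alt"),
      by = "key"
    )
  n <- nrow(grid)
  if (depths) {
    depth_reads <- pmax(1L, stats::rpois(n, config$mean_depth))
    alt_reads <- integer(n)
    het <- grid$allele_count == 1L
    alt_reads[het] <- stats::rbinom(sum(het), depth_reads[het],
                                    config$allelic_bias)
  } else {
    depth_reads <- rep(NA_integer_, n); alt_reads <- rep(NA_integer_, n)
  }
  grid |>
    dplyr::mutate(ref_depth = depth_reads - alt_reads,
                  alt_depth = alt_reads, platform = "simulated") |>
    dplyr::select("individual_id", "contig", "pos", "ref", "alt", "key",
                  "allele_count", "ref_depth", "alt_depth", "platform")
}

#' Simulate per-variant deleteriousness scores
#'
#' Truncating and spiked variants draw high scores, synonymous and background
#' neutral variants low ones; purely cosmetic for exercising the missense
#' threshold.
#'
#' @param variants Tibble with `contig`, `pos`, `ref`, `alt` and optionally
#'   `label`.
#' @param config A [sim_config()].
#' @return Tibble `contig`, `pos`, `ref`, `alt`, `score`.
#' @export
simulate_scores <- function(variants, config) {
  withr::with_seed(derive_seed(config$seed, "scores"), {
    tibble::as_tibble(variants) |>
      dplyr::distinct(.data$contig, .data$pos, .data$ref, .data$alt) |>
      dplyr::mutate(score = round(stats::runif(dplyr::n(), 15, 40), 2))
  })
}
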