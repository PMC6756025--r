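# End-to-end orchestration: simulate -> annotate -> QC/segregation ->
# prioritize -> burden, with per-stage record accounting and TSV/JSON reports.

#' Simulate a discovery-preset cohort
#'
#' 23 families, ~66 genotyped individuals, one gene spiked with a canonical
#' splice-donor variant in 2 families, background singleton loss-of-function
#' variants elsewhere; mirrors the familial discovery design.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_config()].
#' @return Bundle list (see [write_fixture_bundle()]) with `genome`,
#'   `transcripts`, `ped`, `genotypes`, `variants`, `scores`, `config`,
#'   `spiked_key`, `spiked_gene`.
#' @export
simulate_discovery <- function(seed, ...) {
  config <- sim_config(seed = seed, ...)
  ref <- simulate_reference(config)
  fam <- simulate_families(config, ref)
  scores <- simulate_scores(fam$variants, config)
  c(list(genome = ref$genome, transcripts = ref$transcripts,
         scores = scores, config = config), fam)
}

#' Simulate a burden-preset cohort
#'
#' 781 cases vs 3534 controls with qualifying-carrier frequencies 30/781 and
#' 72/3534 and a neutral synonymous mask at equal frequency in both arms.
#'
#' @param seed Integer seed.
#' @param mode `"exact"` (counts forced, default) or `"bernoulli"`.
#' @param ... Overrides passed to [sim_config()].
#' @return List with `genome`, `transcripts`, `mask`, `synonymous_mask`,
#'   `genotypes`, `phenotypes`, `config`, `gene_id`.
#' @export
simulate_burden <- function(seed, mode = c("exact", "bernoulli"), ...) {
  mode <- match.arg(mode)
  config <- sim_config(seed = seed, ...)
  ref <- simulate_reference(config)
  tx <- ref$transcripts[[1]]
  mask <- withr::with_seed(derive_seed(config$seed, "mask"), {
    dplyr::bind_rows(
      propose_snv(tx, ref$genome, "splice_donor"),
      propose_snv(tx, ref$genome, "stop_gain"),
      propose_snv(tx, ref$genome, "stop_loss"),
      propose_snv(tx, ref$genome, "missense")
    )
  })
  syn <- withr::with_seed(derive_seed(config$seed, "synmask"), {
    a <- propose_snv(tx, ref$genome, "synonymous")
    b <- propose_snv(tx, ref$genome, "synonymous", avoid = a$key)
    dplyr::bind_rows(a, b)
  })
  cc <- simulate_case_control(config, mask, mode = mode,
                              synonymous_mask = syn, depths = TRUE)
  list(genome = ref$genome, transcripts = ref$transcripts, mask = mask,
       synonymous_mask = syn, genotypes = cc$genotypes,
       phenotypes = cc$phenotypes, config = config, gene_id = tx$gene_id)
}

#' Share of screened families carrying a qualifying gene hit
#'
#' @param n_hit_families Families with a qualifying hit.
#' @param n_screened_families Families screened.
#' @return Percentage (0-100).
#' @examples
#' family_hit_frequency(4, 154)  # 2.6
#' @export
family_hit_frequency <- function(n_hit_families, n_screened_families) {
  if (n_screened_families <= 0) stop("no families screened", call. = FALSE)
  100 * n_hit_families / n_screened_families
}

#' Run the discovery pipeline on standard-format inputs
#'
#' annotate -> QC -> prioritize, with per-stage record accounting. Inputs are
#' in-memory objects; see [run_pipeline()] for the file-based entry point.
#'
#' @param genome A [genome_sequence()].
#' @param transcripts Named list of [transcript_model()] (one per gene;
#'   [pick_transcript()] is applied).
#' @param variants Variant tibble (`contig`, `pos`, `ref`, `alt`).
#' @param genotypes,ped Cohort tables.
#' @param scores Optional score table.
#' @param mode Mask mode for [qualifying_variants()].
#' @param min_families,min_affected_carriers See [cross_family_recurrence()].
#' @param missense_threshold See [is_putative_lof()].
#' @param n_screened_families Denominator for the family-frequency summary
#'   (default: families present in `ped`).
#' @return List: `calls`, `qualifying`, `qc` (VAF check on heterozygous
#'   calls), `hits`, `summary` (counts per stage, recurrent genes, family
#'   frequency), `log` (tibble of stage in/out counts).
#' @export
discovery_analysis <- function(genome, transcripts, variants, genotypes, ped,
                               scores = NULL, mode = "discovery",
                               min_families = 2L, min_affected_carriers = 1L,
                               missense_threshold = 20,
                               n_screened_families = NULL) {
  transcripts <- pick_transcript(transcripts)
  log <- list()
  note <- function(stage, n_in, n_out) {
    log[[length(log) + 1]] <<- tibble::tibble(
      stage = stage, records_in = n_in, records_out = n_out,
      records_dropped = n_in - n_out)
  }

  variants <- tibble::as_tibble(variants)
  if (nrow(variants) == 0L) {
    warning("empty variant set: reports will be empty", call. = FALSE)
  }
  # annotate each variant against its contig's transcript
  tx_by_contig <- stats::setNames(
    transcripts, vapply(transcripts, `[[`, character(1), "contig"))
  calls <- purrr::map_dfr(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    tx <- tx_by_contig[[v$contig]]
    if (is.null(tx)) return(NULL)
    classify_variants(v, tx, genome)
  })
  note("annotate", nrow(variants), nrow(calls))

  qual <- qualifying_variants(calls, scores = scores, mode = mode,
                              missense_threshold = missense_threshold)
  note("qualifying_mask", nrow(calls), nrow(qual))

  het <- genotypes |> dplyr::filter(.data$allele_count == 1L,
                                    .data$ref_depth + .data$alt_depth > 0L)
  qc <- if (nrow(het) > 0L) vaf_germline_check(het) else
    het |> dplyr::mutate(vaf = double(0), vaf_status = character(0))
  conc <- platform_concordance(genotypes)
  note("vaf_qc", nrow(het), sum(qc$vaf_status == "germline_consistent"))

  hits <- cross_family_recurrence(qual, genotypes, ped,
                                  min_families = min_families,
                                  min_affected_carriers = min_affected_carriers)
  note("cross_family_recurrence", nrow(qual), nrow(hits))

  n_screened <- n_screened_families %||% dplyr::n_distinct(ped$family_id)
  n_hit_fams <- if (nrow(hits) == 0L) 0L else
    dplyr::n_distinct(unlist(hits$families))
  summary <- list(
    n_variants = nrow(variants),
    n_calls = nrow(calls),
    n_qualifying = nrow(qual),
    recurrent_genes = hits$gene_id,
    n_recurrent_genes = nrow(hits),
    n_hit_families = n_hit_fams,
    n_screened_families = n_screened,
    family_hit_frequency_pct = family_hit_frequency(n_hit_fams, n_screened),
    vaf_germline_consistent = sum(qc$vaf_status == "germline_consistent"),
    vaf_checked = nrow(qc),
    discordant_families = if (nrow(hits) == 0L) character(0) else
      unique(unlist(purrr::map(hits$segregation, function(s)
        s$family_id[s$discordant_affected])))
  )
  list(calls = calls, qualifying = qual, qc = qc, concordance = conc,
       hits = hits, summary = summary, log = dplyr::bind_rows(log))
}

#' Run the full pipeline from files
#'
#' Reads FASTA/GFF3/VCF/PED (and optional score TSV), runs annotation, QC,
#' prioritization and (when phenotype labels allow) the burden test, and
#' writes reports: `consequences.tsv`, `qc.tsv`, `gene_hits.tsv` (+ `.json`),
#' `burden.tsv` and `summary.json`.
#'
#' @param fasta,gff3,vcf,ped File paths (`vcf` variants + genotypes).
#' @param scores Optional score TSV (`contig`, `pos`, `ref`, `alt`, `score`).
#' @param out_dir Output directory.
#' @param mode `"discovery"` or `"burden"` mask.
#' @param min_families,min_affected_carriers,missense_threshold Filter knobs.
#' @param quiet Suppress progress messages.
#' @return The [discovery_analysis()] result, invisibly.
#' @export
run_pipeline <- function(fasta, gff3, vcf, ped, scores = NULL,
                         out_dir = ".", mode = "discovery",
                         min_families = 2L, min_affected_carriers = 1L,
                         missense_threshold = 20, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  for (f in c(fasta, gff3, vcf, ped)) {
    if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  say("reading reference: ", fasta)
  genome <- read_genome_fasta(fasta)
  say("reading transcripts: ", gff3)
  transcripts <- read_transcripts_gff3(gff3)
  say("reading genotypes: ", vcf)
  genotypes <- read_genotypes_vcf(vcf)
  pedigree <- read_ped(ped)
  score_tbl <- if (!is.null(scores)) {
    readr::read_tsv(scores, show_col_types = FALSE, progress = FALSE)
  } else {
    NULL
  }
  variants <- genotypes |>
    dplyr::distinct(.data$contig, .data$pos, .data$ref, .data$alt)

  res <- discovery_analysis(genome, transcripts, variants, genotypes,
                            pedigree, scores = score_tbl, mode = mode,
                            min_families = min_families,
                            min_affected_carriers = min_affected_carriers,
                            missense_threshold = missense_threshold)

  write_consequences_tsv(res$calls, file.path(out_dir, "consequences.tsv"))
  readr::write_tsv(res$qc, file.path(out_dir, "qc.tsv"))
  write_gene_hits(res$hits, file.path(out_dir, "gene_hits.tsv"))
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_len(nrow(res$log))) {
    say(sprintf("[%s] in=%d out=%d dropped=%d", res$log$stage[i],
                res$log$records_in[i], res$log$records_out[i],
                res$log$records_dropped[i]))
  }
  invisible(res)
}
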