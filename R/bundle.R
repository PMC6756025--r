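# Standard-format serialization of a simulated cohort: FASTA (+ index), GFF3,
# VCF 4.2 with GT:AD:DP genotypes, PED, score TSV and a JSON manifest carrying
# the generating configuration. Re-reading a bundle reproduces the in-memory
# objects.

#' Write depth-resolved genotypes to a VCF 4.2 file
#'
#' One row per variant, one sample column per individual, FORMAT `GT:AD:DP`.
#' Missing calls are emitted as `./.:.,.:.`. Only one platform may be written
#' per file (VCF has one genotype per sample); filter beforehand.
#'
#' @param genotypes Long genotype tibble (`individual_id`, `contig`, `pos`,
#'   `ref`, `alt`, `key`, `allele_count`, `ref_depth`, `alt_depth`), a single
#'   platform.
#' @param path Output path.
#' @param contig_lengths Named integer vector for `##contig` header lines
#'   (optional but recommended).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path, contig_lengths = NULL) {
  stopifnot(is.data.frame(genotypes))
  if ("platform" %in% names(genotypes) &&
      dplyr::n_distinct(genotypes$platform) > 1L) {
    stop("one platform per VCF; filter the genotype table first",
         call. = FALSE)
  }
  sites <- genotypes |>
    dplyr::distinct(.data$contig, .data$pos, .data$ref, .data$alt,
                    .data$key) |>
    dplyr::arrange(.data$contig, .data$pos, .data$ref, .data$alt)
  samples <- sort(unique(genotypes$individual_id))

  fmt_one <- function(ac, rd, ad) {
    if (is.na(ac)) return("./.:.,.:.")
    gt <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")[[as.character(ac)]]
    paste0(gt, ":", rd, ",", ad, ":", rd + ad)
  }
  # sample x site matrix of formatted calls, default missing
  cells <- matrix("./.:.,.:.", nrow = nrow(sites), ncol = length(samples),
                  dimnames = list(sites$key, samples))
  known <- genotypes |> dplyr::filter(!is.na(.data$allele_count))
  if (nrow(known) > 0L) {
    cells[cbind(match(known$key, sites$key),
                match(known$individual_id, samples))] <-
      mapply(fmt_one, known$allele_count, known$ref_depth, known$alt_depth)
  }

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=famlof",
    if (!is.null(contig_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              as.integer(contig_lengths))
    },
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic ",
           "depths for the ref and alt alleles\">"),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(sites)), function(i) {
    paste(c(sites$contig[i], sites$pos[i], ".", sites$ref[i], sites$alt[i],
            ".", "PASS", ".", "GT:AD:DP", cells[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a simulated cohort as a standard-format fixture bundle
#'
#' Writes `reference.fasta` (+ `.fai` index), `transcripts.gff3`,
#' `genotypes.vcf` (platform `wes`/`simulated` calls), additional
#' `genotypes_<platform>.vcf` files for confirmatory platforms, `cohort.ped`,
#' `scores.tsv` and `manifest.json` (config and seed).
#'
#' @param bundle List with elements `genome`, `transcripts`, `ped`,
#'   `genotypes`, `variants`, `scores` (optional) and `config`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory ", dir, call. = FALSE)
  }
  write_genome_fasta(bundle$genome, file.path(dir, "reference.fasta"))
  Rsamtools::indexFa(file.path(dir, "reference.fasta"))
  write_transcripts_gff3(bundle$transcripts, file.path(dir, "transcripts.gff3"))
  lens <- vapply(bundle$genome$contigs, nchar, integer(1))

  platforms <- unique(bundle$genotypes$platform)
  main <- platforms[1]
  write_genotypes_vcf(
    bundle$genotypes |> dplyr::filter(.data$platform == main),
    file.path(dir, "genotypes.vcf"), contig_lengths = lens
  )
  for (p in setdiff(platforms, main)) {
    write_genotypes_vcf(
      bundle$genotypes |> dplyr::filter(.data$platform == p),
      file.path(dir, sprintf("genotypes_%s.vcf", p)), contig_lengths = lens
    )
  }
  write_ped(bundle$ped, file.path(dir, "cohort.ped"))
  if (!is.null(bundle$scores)) {
    readr::write_tsv(bundle$scores, file.path(dir, "scores.tsv"))
  }
  manifest <- list(
    package = "famlof",
    config = unclass(bundle$config),
    main_platform = main,
    platforms = platforms,
    spiked_key = bundle$spiked_key,
    spiked_gene = bundle$spiked_gene
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a fixture bundle back into memory
#'
#' @param dir Directory written by [write_fixture_bundle()].
#' @return List with `genome`, `transcripts`, `ped`, `genotypes`, `scores`
#'   (or `NULL`), `manifest`.
#' @export
read_fixture_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  genome <- read_genome_fasta(file.path(dir, "reference.fasta"))
  transcripts <- read_transcripts_gff3(file.path(dir, "transcripts.gff3"))
  genotypes <- read_genotypes_vcf(file.path(dir, "genotypes.vcf"),
                                  platform = manifest$main_platform)
  extra <- setdiff(manifest$platforms, manifest$main_platform)
  for (p in extra) {
    f <- file.path(dir, sprintf("genotypes_%s.vcf", p))
    if (file.exists(f)) {
      genotypes <- dplyr::bind_rows(genotypes,
                                    read_genotypes_vcf(f, platform = p))
    }
  }
  ped <- read_ped(file.path(dir, "cohort.ped"))
  scores_path <- file.path(dir, "scores.tsv")
  scores <- if (file.exists(scores_path)) {
    readr::read_tsv(scores_path, show_col_types = FALSE, progress = FALSE)
  } else {
    NULL
  }
  list(genome = genome, transcripts = transcripts, ped = ped,
       genotypes = genotypes, scores = scores, manifest = manifest)
}
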