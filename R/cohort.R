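# Pedigree and genotype handling: PED and VCF readers, germline VAF check,
# cross-platform concordance, Mendelian transmission checks, and per-family
# segregation summaries.
#
# PED dialect: 6 tab-separated columns (family_id, individual_id, father_id,
# mother_id, sex, phenotype), founders coded 0, with extended phenotype codes
#   0 = unknown, 1 = unaffected, 2 = MM, 3 = MGUS, 4 = other_heme,
#   5 = amyloidosis.

ped_phenotype_codes <- c(unknown = 0L, unaffected = 1L, MM = 2L, MGUS = 3L,
                         other_heme = 4L, amyloidosis = 5L)

#' Read a 6-column PED file
#'
#' @param path PED file path (tab-separated, no header, `0` = missing parent).
#' @return Tibble with columns `family_id`, `individual_id`, `father_id`,
#'   `mother_id`, `sex`, `phenotype` (decoded to
#'   MM/MGUS/other_heme/amyloidosis/unaffected/unknown). Parent ids, when set,
#'   must reference individuals in the same family.
#' @export
read_ped <- function(path) {
  ped <- readr::read_tsv(
    path,
    col_names = c("family_id", "individual_id", "father_id", "mother_id",
                  "sex", "phenotype_code"),
    col_types = "cccccc", progress = FALSE
  )
  codes <- stats::setNames(names(ped_phenotype_codes), ped_phenotype_codes)
  ped <- ped |>
    dplyr::mutate(
      father_id = dplyr::na_if(.data$father_id, "0"),
      mother_id = dplyr::na_if(.data$mother_id, "0"),
      phenotype = unname(codes[.data$phenotype_code])
    ) |>
    dplyr::select(-"phenotype_code")
  if (anyNA(ped$phenotype)) {
    stop("unknown phenotype code(s) in PED file", call. = FALSE)
  }
  validate_ped(ped)
  ped
}

validate_ped <- function(ped) {
  by_fam <- split(ped, ped$family_id)
  for (fam in by_fam) {
    parents <- stats::na.omit(c(fam$father_id, fam$mother_id))
    missing <- setdiff(parents, fam$individual_id)
    if (length(missing) > 0) {
      stop("parent id(s) ", paste(missing, collapse = ", "),
           " not present in family ", fam$family_id[1], call. = FALSE)
    }
  }
  invisible(ped)
}

#' Write a 6-column PED file
#'
#' @param ped Tibble as returned by [read_ped()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  out <- ped |>
    dplyr::mutate(
      father_id = dplyr::coalesce(.data$father_id, "0"),
      mother_id = dplyr::coalesce(.data$mother_id, "0"),
      phenotype_code = unname(ped_phenotype_codes[.data$phenotype])
    ) |>
    dplyr::select("family_id", "individual_id", "father_id", "mother_id",
                  "sex", "phenotype_code")
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read depth-resolved genotypes from a VCF
#'
#' Consumes GT, AD and DP from a VCF 4.x file (pre-split biallelic records)
#' and returns one row per sample x variant.
#'
#' @param path VCF file path.
#' @param platform Platform tag to attach
#'   (`wes`/`targeted`/`sanger`/`array`/`simulated`).
#' @return Tibble with columns `individual_id`, `contig`, `pos`, `ref`, `alt`,
#'   `key`, `allele_count` (0/1/2, `NA` for missing), `ref_depth`,
#'   `alt_depth`, `platform`.
#' @export
read_genotypes_vcf <- function(path, platform = "simulated") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcf@fix, stringsAsFactors = FALSE))
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    stop("multi-allelic records present; pre-split the VCF", call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ad <- vcfR::extract.gt(vcf, element = "AD")
  samples <- colnames(gt)
  n_var <- nrow(fix)
  purrr::map_dfr(seq_along(samples), function(j) {
    gt_j <- gt[, j]
    ad_j <- ad[, j]
    ac <- dplyr::case_when(
      gt_j %in% c("0/0", "0|0") ~ 0L,
      gt_j %in% c("0/1", "1/0", "0|1", "1|0") ~ 1L,
      gt_j %in% c("1/1", "1|1") ~ 2L,
      TRUE ~ NA_integer_
    )
    ad_split <- stringr::str_split_fixed(dplyr::coalesce(ad_j, ".,."), ",", 2)
    tibble::tibble(
      individual_id = samples[j],
      contig = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT,
      key = variant_key(fix$CHROM, as.integer(fix$POS), fix$REF, fix$ALT),
      allele_count = ac,
      ref_depth = suppressWarnings(as.integer(ad_split[, 1])),
      alt_depth = suppressWarnings(as.integer(ad_split[, 2])),
      platform = platform
    )
  })
}

#' Germline consistency check on heterozygous variant allele fraction
#'
#' A germline heterozygote should show a variant allele fraction near 0.5.
#' Each call is tested with an exact two-sided binomial test of `alt_depth`
#' out of total depth against p = 0.5; calls with p below `alpha` are flagged
#' inconsistent, calls with depth below `min_depth` are not judged.
#'
#' @param calls Tibble of genotype calls with `allele_count`, `ref_depth`,
#'   `alt_depth` (heterozygous rows expected, `allele_count == 1`).
#' @param alpha Significance level of the exact test (default 0.01).
#' @param min_depth Minimum total depth to attempt the test (default 10).
#' @return `calls` with added columns `vaf` and `vaf_status`
#'   (`germline_consistent` / `inconsistent` / `insufficient_depth`).
#' @export
vaf_germline_check <- function(calls, alpha = 0.01, min_depth = 10L) {
  stopifnot(is.data.frame(calls),
            all(c("allele_count", "ref_depth", "alt_depth") %in% names(calls)))
  if (any(calls$allele_count != 1L, na.rm = TRUE) ||
      anyNA(calls$allele_count)) {
    stop("vaf_germline_check expects heterozygous calls (allele_count == 1)",
         call. = FALSE)
  }
  depth <- calls$ref_depth + calls$alt_depth
  if (any(depth == 0L)) {
    stop("zero total read depth in genotype call(s)", call. = FALSE)
  }
  status <- purrr::map2_chr(calls$alt_depth, depth, function(a, d) {
    if (d < min_depth) return("insufficient_depth")
    p <- stats::binom.test(a, d, p = 0.5)$p.value
    if (p >= alpha) "germline_consistent" else "inconsistent"
  })
  calls |>
    dplyr::mutate(vaf = .data$alt_depth / depth, vaf_status = status)
}

#' Cross-platform genotype concordance
#'
#' @param calls Tibble of genotype calls for one or more individual x variant
#'   combinations, across platforms.
#' @return Tibble with one row per `individual_id` x `key`:
#'   `n_platforms` (non-missing calls) and `concordance`
#'   (`concordant` / `discordant` / `single_platform`).
#' @export
platform_concordance <- function(calls) {
  stopifnot(is.data.frame(calls),
            all(c("individual_id", "key", "allele_count") %in% names(calls)))
  calls |>
    dplyr::filter(!is.na(.data$allele_count)) |>
    dplyr::group_by(.data$individual_id, .data$key) |>
    dplyr::summarise(
      n_platforms = dplyr::n(),
      concordance = dplyr::case_when(
        dplyr::n() == 1L ~ "single_platform",
        dplyr::n_distinct(.data$allele_count) == 1L ~ "concordant",
        TRUE ~ "discordant"
      ),
      .groups = "drop"
    )
}

#' Count Mendelian transmission errors in trios
#'
#' For biallelic genotypes coded 0/1/2, checks that the child's genotype can
#' be formed from one allele of each parent. Missing parents (or missing
#' parental genotypes) leave that side unconstrained; a missing child genotype
#' skips the trio.
#'
#' @param child,father,mother Integer vectors of allele counts (0/1/2, `NA`
#'   allowed), recycled to a common length.
#' @return Integer vector: 1 where transmission is impossible, else 0.
#' @export
mendelian_check <- function(child, father, mother) {
  n <- max(length(child), length(father), length(mother))
  child <- rep_len(as.integer(child), n)
  father <- rep_len(as.integer(father), n)
  mother <- rep_len(as.integer(mother), n)
  gametes <- function(g) {
    if (is.na(g)) c(0L, 1L)
    else switch(as.character(g), `0` = 0L, `1` = c(0L, 1L), `2` = 1L,
                stop("allele counts must be 0, 1, 2 or NA", call. = FALSE))
  }
  vapply(seq_len(n), function(i) {
    if (is.na(child[i])) return(0L)
    possible <- unique(outer(gametes(father[i]), gametes(mother[i]), `+`))
    if (child[i] %in% possible) 0L else 1L
  }, integer(1))
}

#' Mendelian error counts across a cohort
#'
#' Applies [mendelian_check()] to every genotyped child with at least one
#' genotyped parent, per variant.
#'
#' @param ped Pedigree tibble ([read_ped()]).
#' @param genotypes Genotype tibble ([read_genotypes_vcf()]).
#' @return Tibble with `key`, `family_id`, `individual_id`, `errors`.
#' @export
mendelian_errors <- function(ped, genotypes) {
  gt <- genotypes |>
    dplyr::select("individual_id", "key", "allele_count")
  trios <- ped |>
    dplyr::filter(!is.na(.data$father_id) | !is.na(.data$mother_id))
  purrr::map_dfr(unique(gt$key), function(k) {
    g <- gt |> dplyr::filter(.data$key == k)
    lut <- stats::setNames(g$allele_count, g$individual_id)
    look <- function(id) {
      if (is.na(id) || !id %in% names(lut)) NA_integer_ else lut[[id]]
    }
    trios |>
      dplyr::mutate(
        key = k,
        errors = mendelian_check(
          vapply(.data$individual_id, look, integer(1)),
          vapply(.data$father_id, look, integer(1)),
          vapply(.data$mother_id, look, integer(1))
        )
      ) |>
      dplyr::select("key", "family_id", "individual_id", "errors")
  })
}

#' Per-family segregation summary for one variant
#'
#' Tallies carriers among affected and unaffected genotyped members and raises
#' a qualitative `discordant_affected` flag when the family contains at least
#' one affected carrier *and* at least one genotyped affected non-carrier
#' (the pattern where an affected relative on the transmission path does not
#' carry the variant, so the variant cannot explain their disease).
#'
#' @param variant_key_ Variant key string.
#' @param ped Pedigree tibble for one family (or more; grouped by family).
#' @param genotypes Genotype tibble.
#' @param affected Phenotypes counted as affected (default MM and MGUS;
#'   amyloidosis and other hematological conditions are reported in the
#'   unaffected stratum but can be promoted via this argument).
#' @return Tibble with one row per family: `key`, `family_id`,
#'   `affected_carriers`, `affected_genotyped`, `unaffected_carriers`,
#'   `unaffected_genotyped`, `mendelian_errors`, `discordant_affected`.
#' @export
segregation <- function(variant_key_, ped, genotypes,
                        affected = c("MM", "MGUS")) {
  gt <- genotypes |>
    dplyr::filter(.data$key == variant_key_, !is.na(.data$allele_count))
  unknown <- setdiff(gt$individual_id, ped$individual_id)
  if (length(unknown) > 0) {
    stop("genotyped individual(s) not in pedigree: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  me <- mendelian_errors(ped, gt |> dplyr::mutate(key = variant_key_))
  me_by_fam <- me |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(mendelian_errors = sum(.data$errors), .groups = "drop")
  ped |>
    dplyr::inner_join(gt, by = "individual_id") |>
    dplyr::mutate(
      is_affected = .data$phenotype %in% affected,
      carrier = .data$allele_count > 0L
    ) |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(
      key = variant_key_,
      affected_carriers = sum(.data$is_affected & .data$carrier),
      affected_genotyped = sum(.data$is_affected),
      unaffected_carriers = sum(!.data$is_affected & .data$carrier),
      unaffected_genotyped = sum(!.data$is_affected),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      discordant_affected = .data$affected_carriers >= 1L &
        .data$affected_genotyped > .data$affected_carriers
    ) |>
    dplyr::left_join(me_by_fam, by = "family_id") |>
    dplyr::mutate(mendelian_errors =
                    dplyr::coalesce(.data$mendelian_errors, 0L)) |>
    dplyr::select("key", "family_id", "affected_carriers",
                  "affected_genotyped", "unaffected_carriers",
                  "unaffected_genotyped", "mendelian_errors",
                  "discordant_affected")
}
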