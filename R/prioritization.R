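# The discovery filter: qualifying-variant masks and cross-family recurrence
# of putative loss-of-function genes.

#' Select qualifying variants under a mask
#'
#' Two masks are supported. `discovery` keeps only truncating classes plus
#' stop-loss (putative loss-of-function); `burden` additionally admits
#' missense calls whose deleteriousness score meets the inclusive threshold.
#'
#' @param calls Tibble from [classify_variants()].
#' @param scores Optional score table (see [is_putative_lof()]).
#' @param mode `"discovery"` or `"burden"`.
#' @param missense_threshold Inclusive missense score threshold (default 20).
#' @return The qualifying subset of `calls` (same columns).
#' @export
qualifying_variants <- function(calls, scores = NULL,
                                mode = c("discovery", "burden"),
                                missense_threshold = 20) {
  mode <- match.arg(mode)
  if (nrow(calls) == 0L) return(calls)
  if (mode == "discovery") {
    keep <- calls$klass %in% c("stop_gain", "frameshift", "splice_donor",
                               "splice_acceptor", "stop_loss")
  } else {
    keep <- is_putative_lof(calls, scores = scores,
                            missense_threshold = missense_threshold)
  }
  calls[keep, , drop = FALSE]
}

#' Cross-family recurrence of qualifying loss-of-function genes
#'
#' A family counts toward a gene when at least one member carries at least one
#' qualifying allele and the family has at least `min_affected_carriers`
#' affected carriers (default 1, the variant is present in an affected member;
#' 0 relaxes to any-member carriage; 2 demands sharing by two affected
#' members). Genes observed in at least `min_families` distinct families are
#' returned with per-family variant lists and segregation summaries; a family
#' is counted once however many carriers or variants it has.
#'
#' @param qualifying Tibble of qualifying consequence calls (must carry
#'   `key` and `gene_id`).
#' @param genotypes Genotype tibble ([read_genotypes_vcf()]).
#' @param ped Pedigree tibble ([read_ped()]).
#' @param min_families Minimum number of distinct families (default 2).
#' @param min_affected_carriers Per-family minimum count of affected carriers
#'   (default 1).
#' @param affected Phenotypes counted as affected (default MM, MGUS).
#' @return Tibble sorted by descending family count then gene id:
#'   `gene_id`, `n_families`, `families` (list of family ids), `variants`
#'   (list of per-family variant keys) and `segregation` (list of
#'   [segregation()] tibbles).
#' @export
cross_family_recurrence <- function(qualifying, genotypes, ped,
                                    min_families = 2L,
                                    min_affected_carriers = 1L,
                                    affected = c("MM", "MGUS")) {
  stopifnot(is.data.frame(qualifying), is.data.frame(genotypes),
            is.data.frame(ped))
  empty <- tibble::tibble(gene_id = character(), n_families = integer(),
                          families = list(), variants = list(),
                          segregation = list())
  if (nrow(qualifying) == 0L) return(empty)
  carriers <- genotypes |>
    dplyr::filter(.data$key %in% qualifying$key,
                  .data$allele_count %in% c(1L, 2L)) |>
    dplyr::inner_join(
      qualifying |> dplyr::distinct(.data$key, .data$gene_id),
      by = "key"
    )
  missing_ind <- setdiff(carriers$individual_id, ped$individual_id)
  if (length(missing_ind) > 0) {
    stop("carrier individual(s) without pedigree entry: ",
         paste(missing_ind, collapse = ", "), call. = FALSE)
  }
  carriers <- carriers |>
    dplyr::inner_join(
      ped |> dplyr::select("individual_id", "family_id", "phenotype"),
      by = "individual_id"
    ) |>
    dplyr::mutate(is_affected = .data$phenotype %in% affected)

  fam_gene <- carriers |>
    dplyr::group_by(.data$gene_id, .data$family_id) |>
    dplyr::summarise(
      n_carriers = dplyr::n_distinct(.data$individual_id),
      n_affected_carriers = dplyr::n_distinct(
        .data$individual_id[.data$is_affected]),
      keys = list(sort(unique(.data$key))),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_carriers >= 1L,
                  .data$n_affected_carriers >= min_affected_carriers)

  hits <- fam_gene |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_families = dplyr::n_distinct(.data$family_id),
      families = list(sort(unique(.data$family_id))),
      variants = list(stats::setNames(.data$keys, .data$family_id)),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_families >= min_families) |>
    dplyr::arrange(dplyr::desc(.data$n_families), .data$gene_id)
  if (nrow(hits) == 0L) return(empty)

  hits$segregation <- purrr::map(seq_len(nrow(hits)), function(i) {
    fams <- hits$families[[i]]
    keys <- sort(unique(unlist(hits$variants[[i]])))
    fam_ped <- ped |> dplyr::filter(.data$family_id %in% fams)
    fam_gt <- genotypes |>
      dplyr::filter(.data$individual_id %in% fam_ped$individual_id)
    purrr::map_dfr(keys, function(k) {
      segregation(k, fam_ped, fam_gt, affected = affected)
    })
  })
  hits
}

#' Write a gene-hit report
#'
#' TSV (one row per gene, list columns flattened) plus a JSON equivalent for
#' machine consumption.
#'
#' @param hits Tibble from [cross_family_recurrence()].
#' @param path Output TSV path; the JSON is written alongside with extension
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_gene_hits <- function(hits, path) {
  flat <- hits |>
    dplyr::mutate(
      families = purrr::map_chr(.data$families, paste, collapse = ","),
      variants = purrr::map_chr(
        .data$variants,
        function(v) paste(purrr::imap_chr(
          v, function(keys, fam) paste0(fam, ":", paste(keys, collapse = "|"))
        ), collapse = ";")
      ),
      discordant_families = purrr::map_chr(
        .data$segregation,
        function(s) paste(unique(s$family_id[s$discordant_affected]),
                          collapse = ",")
      )
    ) |>
    dplyr::select("gene_id", "n_families", "families", "variants",
                  "discordant_families")
  readr::write_tsv(flat, path)
  json_path <- sub("\\.tsv$", ".json", path)
  if (identical(json_path, path)) json_path <- paste0(path, ".json")
  jsonlite::write_json(
    purrr::map(seq_len(nrow(hits)), function(i) {
      list(gene_id = hits$gene_id[i],
           n_families = hits$n_families[i],
           families = hits$families[[i]],
           variants = hits$variants[[i]],
           segregation = hits$segregation[[i]])
    }),
    json_path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
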