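# Gene-based carrier-collapsing case-control burden test: 2x2 construction,
# crude cross-product odds ratio with a Woolf (log-normal) confidence
# interval, Fisher's exact two-sided p, and a synonymous-mask calibration for
# systemic case/control bias. The crude OR + Woolf CI reproduce the familiar
# printed statistics from raw carrier counts; zero cells receive the
# Haldane-Anscombe +0.5 correction (OR/CI only -- the exact p is never
# corrected).

#' Construct a 2x2 carrier table
#'
#' @param a,b,c,d Case carriers, case non-carriers, control carriers, control
#'   non-carriers (non-negative integers).
#' @return An object of class `cohort_2x2`.
#' @export
cohort_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("2x2 cells must be non-negative integers", call. = FALSE)
  }
  cells <- as.integer(round(cells))
  structure(list(a = cells[1], b = cells[2], c = cells[3], d = cells[4]),
            class = "cohort_2x2")
}

#' @export
print.cohort_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), nrow = 2, byrow = TRUE,
              dimnames = list(c("case", "control"),
                              c("carrier", "non-carrier")))
  print(m)
  invisible(x)
}

as_matrix_2x2 <- function(tab) {
  matrix(c(tab$a, tab$b, tab$c, tab$d), nrow = 2, byrow = TRUE)
}

#' Build the carrier 2x2 table for one gene
#'
#' An individual is a carrier when they carry at least one qualifying allele
#' across the gene's qualifying variants (an individual with several
#' qualifying variants still counts once). Individuals whose genotypes are
#' missing at every qualifying site are dropped with a logged count.
#'
#' @param genotypes Genotype tibble (`individual_id`, `key`, `allele_count`).
#' @param phenotypes Tibble with `individual_id` and `group`
#'   (`"case"`/`"control"`); an individual labelled both is an error.
#' @param qualifying_keys Character vector of qualifying variant keys for the
#'   gene.
#' @return A [cohort_2x2()] with attribute `n_dropped` (all-missing
#'   individuals excluded from the table).
#' @export
build_2x2 <- function(genotypes, phenotypes, qualifying_keys) {
  stopifnot(is.data.frame(genotypes), is.data.frame(phenotypes),
            all(c("individual_id", "group") %in% names(phenotypes)))
  dup <- phenotypes |>
    dplyr::distinct(.data$individual_id, .data$group) |>
    dplyr::count(.data$individual_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop("individual(s) labelled both case and control: ",
         paste(dup$individual_id, collapse = ", "), call. = FALSE)
  }
  if (!all(phenotypes$group %in% c("case", "control"))) {
    stop("group must be 'case' or 'control'", call. = FALSE)
  }
  gene_gt <- genotypes |>
    dplyr::filter(.data$key %in% qualifying_keys) |>
    dplyr::semi_join(phenotypes, by = "individual_id")
  status <- phenotypes |>
    dplyr::distinct(.data$individual_id, .data$group) |>
    dplyr::left_join(
      gene_gt |>
        dplyr::group_by(.data$individual_id) |>
        dplyr::summarise(
          n_called = sum(!is.na(.data$allele_count)),
          carrier = any(.data$allele_count %in% c(1L, 2L)),
          .groups = "drop"
        ),
      by = "individual_id"
    ) |>
    dplyr::mutate(n_called = dplyr::coalesce(.data$n_called, 0L),
                  carrier = dplyr::coalesce(.data$carrier, FALSE))
  # no qualifying variants at all: nobody has a site to be missing at
  if (length(qualifying_keys) == 0L) status$n_called <- 1L
  dropped <- status |> dplyr::filter(.data$n_called == 0L)
  if (nrow(dropped) > 0L) {
    message(nrow(dropped),
            " individual(s) with all-missing genotypes dropped from the 2x2")
  }
  status <- status |> dplyr::filter(.data$n_called > 0L)
  tab <- cohort_2x2(
    a = sum(status$group == "case" & status$carrier),
    b = sum(status$group == "case" & !status$carrier),
    c = sum(status$group == "control" & status$carrier),
    d = sum(status$group == "control" & !status$carrier)
  )
  attr(tab, "n_dropped") <- nrow(dropped)
  tab
}

#' Crude odds ratio with Woolf confidence interval
#'
#' Cross-product odds ratio `(a d)/(b c)` with the Woolf (log-normal) interval
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is zero,
#' the Haldane-Anscombe correction adds 0.5 to every cell first and the result
#' is flagged.
#'
#' @param tab A [cohort_2x2()] (or anything with fields `a`, `b`, `c`, `d`).
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble with `or`, `ci_low`, `ci_high`, `correction_applied`.
#' @export
odds_ratio <- function(tab, conf_level = 0.95) {
  cells <- c(tab$a, tab$b, tab$c, tab$d)
  if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0 ||
      sum(cells[c(1, 3)]) == 0 || sum(cells[c(2, 4)]) == 0) {
    stop("empty row or column margin: odds ratio undefined", call. = FALSE)
  }
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / cells))
  tibble::tibble(
    or = or,
    ci_low = exp(log(or) - z * se),
    ci_high = exp(log(or) + z * se),
    correction_applied = corrected
  )
}

#' Fisher's exact two-sided p for a 2x2 table
#'
#' Two-sided p as the sum of hypergeometric probabilities, over all tables
#' with the observed margins, that do not exceed the observed table's
#' probability (relative tolerance 1e-7 on the comparison); computed in log
#' space for large margins.
#'
#' @param tab A [cohort_2x2()].
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact <- function(tab) {
  m <- as_matrix_2x2(tab)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("empty row or column margin: exact test undefined", call. = FALSE)
  }
  stats::fisher.test(m)$p.value
}

#' Synonymous-mask calibration for systemic bias
#'
#' Runs the identical carrier collapse on a neutral (synonymous) variant mask.
#' Cases and controls drawn from comparably sequenced populations should show
#' no carrier-frequency difference on neutral variation; a Woolf 95% CI of the
#' calibration odds ratio that excludes 1 flags systemic bias (differential
#' capture, coverage or population mismatch).
#'
#' @param genotypes,phenotypes As in [build_2x2()].
#' @param synonymous_keys Keys of the synonymous (neutral) mask. Empty mask:
#'   returns `NA` with a warning.
#' @return Tibble with `calibration_or`, `calibration_ci_low`,
#'   `calibration_ci_high`, `bias_flag`.
#' @export
calibration <- function(genotypes, phenotypes, synonymous_keys) {
  if (length(synonymous_keys) == 0L) {
    warning("no synonymous variants supplied; calibration skipped",
            call. = FALSE)
    return(tibble::tibble(calibration_or = NA_real_,
                          calibration_ci_low = NA_real_,
                          calibration_ci_high = NA_real_,
                          bias_flag = NA))
  }
  tab <- build_2x2(genotypes, phenotypes, synonymous_keys)
  est <- odds_ratio(tab)
  tibble::tibble(
    calibration_or = est$or,
    calibration_ci_low = est$ci_low,
    calibration_ci_high = est$ci_high,
    bias_flag = est$ci_low > 1 | est$ci_high < 1
  )
}

#' Gene-based carrier burden test
#'
#' Collapses qualifying variants of one gene to carrier status, builds the
#' case-control 2x2 table and reports the crude odds ratio with Woolf CI and
#' Fisher's exact two-sided p, optionally with a synonymous-mask calibration.
#'
#' @param genotypes,phenotypes As in [build_2x2()].
#' @param qualifying_keys Qualifying variant keys for the gene.
#' @param gene_id Gene label for reporting.
#' @param synonymous_keys Optional neutral mask for [calibration()].
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `burden_result`; see [tidy.burden_result()].
#' @export
burden_test <- function(genotypes, phenotypes, qualifying_keys,
                        gene_id = "gene", synonymous_keys = NULL,
                        conf_level = 0.95) {
  tab <- build_2x2(genotypes, phenotypes, qualifying_keys)
  res <- burden_from_counts(tab$a, tab$b, tab$c, tab$d, gene_id = gene_id,
                            conf_level = conf_level)
  res$n_dropped <- attr(tab, "n_dropped")
  if (!is.null(synonymous_keys)) {
    res$calibration <- calibration(genotypes, phenotypes, synonymous_keys)
  }
  res
}

#' Burden statistics from explicit 2x2 counts
#'
#' Table-only mode: reproduce the burden statistics directly from printed
#' carrier counts, no genotypes needed.
#'
#' @param a,b,c,d Case carriers, case non-carriers, control carriers, control
#'   non-carriers.
#' @param gene_id Gene label.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `burden_result`.
#' @examples
#' burden_from_counts(30, 751, 72, 3462)
#' @export
burden_from_counts <- function(a, b, c, d, gene_id = "gene",
                               conf_level = 0.95) {
  tab <- cohort_2x2(a, b, c, d)
  est <- odds_ratio(tab, conf_level = conf_level)
  structure(
    list(gene_id = gene_id, table = tab,
         or = est$or, ci_low = est$ci_low, ci_high = est$ci_high,
         conf_level = conf_level,
         correction_applied = est$correction_applied,
         p_fisher = fisher_exact(tab),
         calibration = NULL, n_dropped = 0L),
    class = "burden_result"
  )
}

#' @export
print.burden_result <- function(x, ...) {
  cat("Carrier burden test:", x$gene_id, "\n")
  cat(sprintf("  carriers %d/%d cases vs %d/%d controls\n",
              x$table$a, x$table$a + x$table$b,
              x$table$c, x$table$c + x$table$d))
  cat(sprintf("  OR = %.2f, %d%% CI %.2f-%.2f, Fisher p = %.3g%s\n",
              x$or, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$p_fisher,
              if (x$correction_applied) " (Haldane-Anscombe corrected)"
              else ""))
  if (!is.null(x$calibration) && !is.na(x$calibration$calibration_or)) {
    cat(sprintf("  calibration (synonymous mask) OR = %.2f, bias %s\n",
                x$calibration$calibration_or,
                if (isTRUE(x$calibration$bias_flag)) "FLAGGED"
                else "not detected"))
  }
  invisible(x)
}

#' Tidy a burden result
#'
#' @param x A `burden_result`.
#' @param ... Unused.
#' @return One-row tibble: gene, cell counts, OR, CI bounds, exact p,
#'   correction flag, calibration OR and bias flag.
#' @method tidy burden_result
#' @export
tidy.burden_result <- function(x, ...) {
  tibble::tibble(
    gene_id = x$gene_id,
    a = x$table$a, b = x$table$b, c = x$table$c, d = x$table$d,
    or = x$or, ci_low = x$ci_low, ci_high = x$ci_high,
    p_fisher = x$p_fisher,
    correction_applied = x$correction_applied,
    calibration_or = if (is.null(x$calibration)) NA_real_
                     else x$calibration$calibration_or,
    bias_flag = if (is.null(x$calibration)) NA
                else x$calibration$bias_flag
  )
}

#' Glance at a burden result
#'
#' @param x A `burden_result`.
#' @param ... Unused.
#' @return One-row tibble with cohort sizes, carrier frequencies and dropped
#'   count.
#' @method glance burden_result
#' @export
glance.burden_result <- function(x, ...) {
  tibble::tibble(
    n_cases = x$table$a + x$table$b,
    n_controls = x$table$c + x$table$d,
    case_carrier_freq = x$table$a / (x$table$a + x$table$b),
    control_carrier_freq = x$table$c / (x$table$c + x$table$d),
    n_dropped = x$n_dropped
  )
}

#' Forest-style plot of one or more burden results
#'
#' @param object A `burden_result` or list of them.
#' @param ... Unused.
#' @return A ggplot object (odds ratio with CI per gene, log scale, unity
#'   line).
#' @method autoplot burden_result
#' @export
autoplot.burden_result <- function(object, ...) {
  results <- if (inherits(object, "burden_result")) list(object) else object
  df <- purrr::map_dfr(results, tidy)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$gene_id)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.15
    ) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "carrier odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Benjamini-Hochberg adjustment across gene burden results
#'
#' @param results List of `burden_result` objects.
#' @return Tidy tibble with an added `p_adjusted` column (BH).
#' @export
adjust_burden <- function(results) {
  df <- purrr::map_dfr(results, tidy)
  df$p_adjusted <- stats::p.adjust(df$p_fisher, method = "BH")
  df
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
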