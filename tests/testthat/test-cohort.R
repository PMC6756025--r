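# Pedigree IO, germline VAF QC, platform concordance, Mendelian checks and
# per-family segregation.

make_ped <- function(...) {
  # rows: list(family, id, father, mother, sex, phenotype)
  rows <- list(...)
  tibble::tibble(
    family_id = vapply(rows, `[[`, character(1), 1),
    individual_id = vapply(rows, `[[`, character(1), 2),
    father_id = vapply(rows, function(r) r[[3]], character(1)),
    mother_id = vapply(rows, function(r) r[[4]], character(1)),
    sex = vapply(rows, `[[`, character(1), 5),
    phenotype = vapply(rows, `[[`, character(1), 6)
  ) |>
    dplyr::mutate(father_id = dplyr::na_if(father_id, "0"),
                  mother_id = dplyr::na_if(mother_id, "0"))
}

gt_row <- function(id, key, ac, rd = 50L, ad = 50L, platform = "wes") {
  tibble::tibble(individual_id = id, key = key,
                 allele_count = as.integer(ac),
                 ref_depth = as.integer(rd), alt_depth = as.integer(ad),
                 platform = platform)
}

test_that("PED files round-trip with extended phenotype codes", {
  ped <- make_ped(
    list("F1", "F1_P1", "0", "0", "1", "MM"),
    list("F1", "F1_P2", "0", "0", "2", "amyloidosis"),
    list("F1", "F1_C1", "F1_P1", "F1_P2", "1", "MGUS"),
    list("F1", "F1_C2", "F1_P1", "F1_P2", "2", "unaffected"),
    list("F1", "F1_C3", "F1_P1", "F1_P2", "2", "other_heme"),
    list("F1", "F1_C4", "F1_P1", "F1_P2", "1", "unknown")
  )
  path <- withr::local_tempfile(fileext = ".ped")
  write_ped(ped, path)
  back <- read_ped(path)
  expect_equal(as.data.frame(back), as.data.frame(ped))
  # parent outside the family is rejected
  bad <- dplyr::mutate(ped, father_id = dplyr::if_else(
    individual_id == "F1_C1", "F2_P1", father_id))
  path2 <- withr::local_tempfile(fileext = ".ped")
  write_ped(bad, path2)
  expect_error(read_ped(path2), "not present in family")
})

test_that("heterozygous VAF near one half is judged germline-consistent by the exact test", {
  calls <- dplyr::bind_rows(
    gt_row("i1", "k", 1, rd = 52, ad = 48),   # 48/100
    gt_row("i2", "k", 1, rd = 50, ad = 0),    # 0/50
    gt_row("i3", "k", 1, rd = 90, ad = 10),   # 10/100
    gt_row("i4", "k", 1, rd = 4, ad = 3)      # depth 7
  )
  out <- vaf_germline_check(calls)
  expect_equal(out$vaf_status,
               c("germline_consistent", "inconsistent", "inconsistent",
                 "insufficient_depth"))
  # agreement with an independent two-sided binomial tail sum at alpha 0.01
  expect_true(oracle_binom_two_sided(48, 100) >= 0.01)
  expect_lt(oracle_binom_two_sided(10, 100), 0.01)
  expect_error(vaf_germline_check(gt_row("i", "k", 1, rd = 0, ad = 0)),
               "zero total read depth")
  expect_error(vaf_germline_check(gt_row("i", "k", 2)), "heterozygous")
})

test_that("simulated binomial heterozygotes pass the VAF check at the expected rate", {
  withr::with_seed(404, {
    depth <- 100L
    alt <- stats::rbinom(500, depth, 0.5)
    calls <- tibble::tibble(individual_id = sprintf("i%03d", 1:500),
                            key = "k", allele_count = 1L,
                            ref_depth = depth - alt, alt_depth = alt,
                            platform = "wes")
    out <- vaf_germline_check(calls)
    expect_gte(mean(out$vaf_status == "germline_consistent"), 0.98)
  })
})

test_that("platform concordance distinguishes concordant, discordant and single calls", {
  calls <- dplyr::bind_rows(
    gt_row("i1", "k", 1, platform = "wes"),
    gt_row("i1", "k", 1, platform = "targeted"),
    gt_row("i1", "k", 1, platform = "sanger"),
    gt_row("i2", "k", 1, platform = "wes"),
    gt_row("i3", "k", 1, platform = "wes"),
    gt_row("i3", "k", 0, platform = "targeted")
  )
  out <- platform_concordance(calls)
  expect_equal(out$concordance[out$individual_id == "i1"], "concordant")
  expect_equal(out$concordance[out$individual_id == "i2"], "single_platform")
  expect_equal(out$concordance[out$individual_id == "i3"], "discordant")
})

test_that("mendelian_check matches exhaustive enumeration of allowed transmissions", {
  combos <- expand.grid(child = 0:2, father = 0:2, mother = 0:2)
  got <- mendelian_check(combos$child, combos$father, combos$mother)
  want <- vapply(seq_len(nrow(combos)), function(i) {
    if (oracle_mendel_ok(combos$child[i], combos$father[i],
                         combos$mother[i])) 0L else 1L
  }, integer(1))
  expect_equal(got, want)
  # spot checks forced by inheritance
  expect_equal(mendelian_check(1, 1, 0), 0L)
  expect_equal(mendelian_check(2, 0, 2), 1L)
  # a missing parent releases only that parent's constraint; a missing child
  # skips the trio
  expect_equal(mendelian_check(2, NA, 1), 0L)
  expect_equal(mendelian_check(2, NA, 0), 1L)  # mother can only transmit ref
  expect_equal(mendelian_check(NA, 0, 0), 0L)
})

test_that("segregation reproduces the concordant-siblings and discordant-parent patterns", {
  # two affected siblings, both heterozygous: concordant
  ped_b <- make_ped(
    list("B", "B_P1", "0", "0", "1", "unaffected"),
    list("B", "B_P2", "0", "0", "2", "unaffected"),
    list("B", "B_S1", "B_P1", "B_P2", "1", "MGUS"),
    list("B", "B_S2", "B_P1", "B_P2", "2", "MM")
  )
  gt_b <- dplyr::bind_rows(gt_row("B_S1", "v1", 1), gt_row("B_S2", "v1", 1),
                           gt_row("B_P2", "v1", 1))
  seg_b <- segregation("v1", ped_b, gt_b)
  expect_equal(seg_b$affected_carriers, 2L)
  expect_equal(seg_b$affected_genotyped, 2L)
  expect_equal(seg_b$unaffected_carriers, 1L)
  expect_false(seg_b$discordant_affected)
  expect_equal(seg_b$mendelian_errors, 0L)

  # affected proband carries, affected mother does not: discordant
  ped_d <- make_ped(
    list("D", "D_M", "0", "0", "2", "MM"),
    list("D", "D_F", "0", "0", "1", "unaffected"),
    list("D", "D_C", "D_F", "D_M", "1", "MM")
  )
  gt_d <- dplyr::bind_rows(gt_row("D_C", "v2", 1), gt_row("D_M", "v2", 0))
  seg_d <- segregation("v2", ped_d, gt_d)
  expect_true(seg_d$discordant_affected)
  expect_equal(seg_d$affected_carriers, 1L)
  expect_equal(seg_d$affected_genotyped, 2L)

  # amyloidosis counts as unaffected unless promoted
  seg_d2 <- segregation("v2",
                        dplyr::mutate(ped_d, phenotype = dplyr::if_else(
                          individual_id == "D_M", "amyloidosis", phenotype)),
                        gt_d)
  expect_false(seg_d2$discordant_affected)
  expect_equal(seg_d2$unaffected_genotyped, 1L)
  seg_d3 <- segregation("v2",
                        dplyr::mutate(ped_d, phenotype = dplyr::if_else(
                          individual_id == "D_M", "amyloidosis", phenotype)),
                        gt_d, affected = c("MM", "MGUS", "amyloidosis"))
  expect_true(seg_d3$discordant_affected)

  # single genotyped member: one stratum, no discordance possible
  seg_1 <- segregation("v2", ped_d, gt_d[1, ])
  expect_false(seg_1$discordant_affected)
  expect_equal(seg_1$affected_genotyped, 1L)

  # unknown individual in genotypes is an error
  expect_error(
    segregation("v2", ped_d, dplyr::bind_rows(gt_d, gt_row("ghost", "v2", 1))),
    "not in pedigree")
})

test_that("a genuine Mendelian violation in a trio is counted in the segregation summary", {
  ped <- make_ped(
    list("T", "T_F", "0", "0", "1", "unaffected"),
    list("T", "T_M", "0", "0", "2", "unaffected"),
    list("T", "T_C", "T_F", "T_M", "1", "MM")
  )
  gt <- dplyr::bind_rows(gt_row("T_F", "v", 0), gt_row("T_M", "v", 0),
                         gt_row("T_C", "v", 2, rd = 0, ad = 100))
  seg <- segregation("v", ped, gt)
  expect_equal(seg$mendelian_errors, 1L)
})

test_that("VCF genotype round trip preserves calls and read depths", {
  gt <- dplyr::bind_rows(
    gt_row("s1", "c1:5:A:T", 1, rd = 30, ad = 28),
    gt_row("s2", "c1:5:A:T", 0, rd = 55, ad = 0),
    gt_row("s1", "c1:9:G:C", 2, rd = 0, ad = 61),
    gt_row("s2", "c1:9:G:C", NA, rd = NA, ad = NA)
  ) |>
    tidyr::separate_wider_delim("key", ":", names = c("contig", "pos", "ref",
                                                      "alt"),
                                cols_remove = FALSE) |>
    dplyr::mutate(pos = as.integer(pos))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes_vcf(gt, path, contig_lengths = c(c1 = 20L))
  back <- read_genotypes_vcf(path, platform = "wes")
  merged <- dplyr::inner_join(
    gt, back, by = c("individual_id", "key"), suffix = c("", ".back"))
  expect_equal(nrow(merged), 4L)
  expect_equal(merged$allele_count.back, merged$allele_count)
  ok <- !is.na(merged$allele_count)
  expect_equal(merged$ref_depth.back[ok], merged$ref_depth[ok])
  expect_equal(merged$alt_depth.back[ok], merged$alt_depth[ok])
})
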