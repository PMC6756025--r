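# Synthetic-cohort simulator: determinism, model validity, penetrance and
# transmission behaviour, serialization round trips.

test_that("sim_config validates its invariants", {
  expect_error(sim_config(), "seed is mandatory")
  expect_error(sim_config(seed = 1, penetrance_carrier = 0.1,
                          penetrance_background = 0.5), ">=")
  expect_error(sim_config(seed = 1, carrier_freq_cases = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(seed = 1, n_spiked_families = 99), "exceeds")
})

test_that("the same seed regenerates byte-identical FASTA and GFF3", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  for (d in c(dir1, dir2)) {
    b <- simulate_discovery(123)
    write_fixture_bundle(b, d)
  }
  for (f in c("reference.fasta", "transcripts.gff3", "genotypes.vcf",
              "cohort.ped", "scores.tsv")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), info = f)
  }
})

test_that("simulated references always carry valid transcript models", {
  for (seed in 1:20) {
    cfg <- sim_config(seed = seed, n_genes = 2)
    ref <- simulate_reference(cfg)
    v <- purrr::map_dfr(ref$transcripts, validate_transcript,
                        genome = ref$genome)
    expect_true(all(v$ok), info = paste("seed", seed))
  }
})

test_that("a single-exon gene is simulated cleanly and its PTCs always escape NMD", {
  cfg <- sim_config(seed = 9, n_genes = 1, exons_per_gene = c(1, 1),
                    exon_length_range = c(120, 150))
  ref <- simulate_reference(cfg)
  tx <- ref$transcripts[[1]]
  expect_equal(nrow(tx$exons), 1L)
  expect_true(all(validate_transcript(tx, ref$genome)$ok))
  n_codons <- nchar(build_cds(tx, ref$genome)) / 3
  for (k in c(2, 10, n_codons - 1)) {
    expect_false(predict_nmd(tx, k))
  }
})

test_that("penetrance parameters drive the affected fraction among carriers", {
  # extreme penetrances are deterministic
  cfg1 <- sim_config(seed = 2, n_families = 4, n_spiked_families = 4,
                     penetrance_carrier = 1, penetrance_background = 0,
                     background_lof_rate = 0, n_genotyped = 200L)
  ref1 <- simulate_reference(cfg1)
  fam1 <- simulate_families(cfg1, ref1, plant_discordant = FALSE)
  joined <- fam1$genotypes |>
    dplyr::filter(key == fam1$spiked_key, platform == "wes",
                  !is.na(allele_count)) |>
    dplyr::inner_join(fam1$ped, by = "individual_id")
  expect_true(all(joined$phenotype[joined$allele_count > 0] %in%
                    c("MM", "MGUS")))
  expect_true(all(joined$phenotype[joined$allele_count == 0] == "unaffected"))

  # stochastic penetrance: pooled affected fraction within 3 binomial SDs
  carriers <- 0L; affected <- 0L
  for (seed in 1:40) {
    cfg <- sim_config(seed = seed, n_families = 10, n_spiked_families = 10,
                      penetrance_carrier = 0.4, penetrance_background = 0.02,
                      background_lof_rate = 0, n_genotyped = 500L,
                      pedigree_depth = 3)
    ref <- simulate_reference(cfg)
    fam <- simulate_families(cfg, ref, plant_discordant = FALSE)
    j <- fam$genotypes |>
      dplyr::filter(key == fam$spiked_key, allele_count %in% 1:2,
                    platform == "wes") |>
      dplyr::inner_join(fam$ped, by = "individual_id") |>
      # probands are forced affected; exclude them from the rate check
      dplyr::filter(!grepl("_P1$", individual_id))
    carriers <- carriers + nrow(j)
    affected <- affected + sum(j$phenotype %in% c("MM", "MGUS"))
  }
  expect_gt(carriers, 500L)
  p_hat <- affected / carriers
  expect_lt(abs(p_hat - 0.4), 3 * sqrt(0.4 * 0.6 / carriers))
})

test_that("simulated transmission is strictly Mendelian", {
  for (seed in c(3, 14, 27)) {
    cfg <- sim_config(seed = seed, n_genes = 6, n_families = 8,
                      n_spiked_families = 3, n_genotyped = 300L)
    ref <- simulate_reference(cfg)
    fam <- simulate_families(cfg, ref)
    errs <- mendelian_errors(fam$ped,
                             fam$genotypes |>
                               dplyr::filter(platform == "wes"))
    expect_equal(sum(errs$errors), 0L, info = paste("seed", seed))
  }
})

test_that("heterozygote read draws center on the configured allelic fraction", {
  cfg <- sim_config(seed = 31, n_families = 6, n_spiked_families = 6,
                    background_lof_rate = 0, n_genotyped = 300L)
  ref <- simulate_reference(cfg)
  fam <- simulate_families(cfg, ref)
  het <- fam$genotypes |>
    dplyr::filter(allele_count == 1L, ref_depth + alt_depth > 0)
  vaf <- sum(het$alt_depth) / sum(het$ref_depth + het$alt_depth)
  n_reads <- sum(het$ref_depth + het$alt_depth)
  expect_lt(abs(vaf - 0.5), 3 * sqrt(0.25 / n_reads))
  # the QC op agrees at scale
  qc <- vaf_germline_check(het)
  expect_gte(mean(qc$vaf_status == "germline_consistent"), 0.95)
})

test_that("exact-counts case-control assignment forces the printed 2x2", {
  cfg <- sim_config(seed = 77)
  mask <- tibble::tibble(contig = "c", pos = 1:3, ref = "A", alt = "T") |>
    dplyr::mutate(key = variant_key(contig, pos, ref, alt))
  cc <- simulate_case_control(cfg, mask, mode = "exact", depths = FALSE)
  tab <- build_2x2(cc$genotypes, cc$phenotypes, mask$key)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(30L, 751L, 72L, 3462L))
})

test_that("bernoulli carrier draws hit the configured frequency", {
  cfg <- sim_config(seed = 8, n_cases = 5000, n_controls = 5000,
                    carrier_freq_cases = 0.5, carrier_freq_controls = 0.5)
  mask <- tibble::tibble(contig = "c", pos = 1L, ref = "A", alt = "T",
                         key = "c:1:A:T")
  cc <- simulate_case_control(cfg, mask, mode = "bernoulli", depths = FALSE)
  frac <- mean(cc$genotypes$allele_count > 0)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
  # zero frequency: nobody carries
  cfg0 <- sim_config(seed = 8, carrier_freq_cases = 0,
                     carrier_freq_controls = 0)
  cc0 <- simulate_case_control(cfg0, mask, mode = "bernoulli",
                               depths = FALSE)
  expect_true(all(cc0$genotypes$allele_count == 0L))
})

test_that("fixture bundles round-trip through standard formats", {
  b <- simulate_discovery(55)
  dir <- withr::local_tempdir()
  write_fixture_bundle(b, dir)
  expect_true(file.exists(file.path(dir, "reference.fasta.fai")))
  back <- read_fixture_bundle(dir)
  expect_equal(back$genome$contigs, b$genome$contigs)
  expect_setequal(names(back$transcripts), names(b$transcripts))
  expect_equal(as.data.frame(back$ped), as.data.frame(b$ped))
  # genotype calls identical where non-missing
  orig <- b$genotypes |> dplyr::filter(platform == "wes",
                                       !is.na(allele_count))
  readback <- back$genotypes |> dplyr::filter(platform == "wes")
  m <- dplyr::inner_join(orig, readback,
                         by = c("individual_id", "key"),
                         suffix = c("", ".r"))
  expect_equal(nrow(m), nrow(orig))
  expect_equal(m$allele_count.r, m$allele_count)
  expect_equal(m$ref_depth.r, m$ref_depth)
  expect_equal(m$alt_depth.r, m$alt_depth)
  expect_equal(back$manifest$config$seed, 55L)
})

test_that("the written VCF satisfies a strict re-parse", {
  b <- simulate_discovery(56)
  dir <- withr::local_tempdir()
  write_fixture_bundle(b, dir)
  lines <- readLines(file.path(dir, "genotypes.vcf"))
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  header <- strsplit(grep("^#CHROM", lines, value = TRUE), "\t")[[1]]
  expect_equal(header[1:9], c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT"))
  body <- strsplit(grep("^[^#]", lines, value = TRUE), "\t")
  expect_true(all(lengths(body) == length(header)))
  gt_fields <- unlist(purrr::map(body, ~ .x[10:length(.x)]))
  expect_true(all(grepl("^([012./|]{3}):[0-9.]+,[0-9.]+:[0-9.]+$", gt_fields)))
  # positions are integers within contig bounds
  pos <- as.integer(purrr::map_chr(body, 2))
  expect_false(anyNA(pos))
})
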