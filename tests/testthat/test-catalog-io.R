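test_that("read_maf collapses duplicate rows and keeps all profiled samples in m", {
  rows <- tibble::tibble(
    sample_id = c("s1", "s1", "s1", "s2", "s2"),
    gene = c("KRAS", "KRAS", "TP53", "KRAS", "EGFR"),
    variant_class = "Missense_Mutation",
    variant_type = "SNP",
    protein_change = c("G12D", "G12D", "R175H", "G12D", "L858R"))
  path <- withr::local_tempfile(fileext = ".maf")
  write_toy_maf(rows, path)
  cohort <- suppressMessages(read_maf(path))
  expect_s3_class(cohort, "cohort")
  expect_equal(cohort$m, 2L)
  expect_equal(nrow(cohort$records), 4L)  # one duplicate collapsed
  expect_message(read_maf(path), "duplicate")
})

test_that("a sample whose variants are all filtered away still counts in m", {
  rows <- tibble::tibble(
    sample_id = c("s1", "s2", "s2"),
    gene = c("KRAS", "TP53", "TP53"),
    variant_class = c("Missense_Mutation", "Silent", "Silent"),
    variant_type = "SNP",
    protein_change = c("G12D", "X1X", "X2X"))
  path <- withr::local_tempfile(fileext = ".maf")
  write_toy_maf(rows, path)
  cohort <- filter_nonsynonymous(read_maf(path))
  expect_equal(cohort$m, 2L)
  expect_equal(unique(cohort$records$sample_id), "s1")
})

test_that("missing mandatory MAF columns raise a configuration error naming them", {
  path <- withr::local_tempfile(fileext = ".maf")
  readr::write_tsv(tibble::tibble(Tumor_Sample_Barcode = "s1",
                                  Hugo_Symbol = "KRAS"), path)
  expect_error(read_maf(path), "Variant_Classification",
               class = "raremut_config_error")
  expect_error(read_maf("/nonexistent/file.maf"), class = "raremut_io_error")
})

test_that("the non-synonymous SNV filter keeps exactly the configured classes", {
  rec <- tibble::tibble(
    sample_id = sprintf("s%d", 1:10),
    gene = "G1",
    variant_key = sprintf("G1:V%d", 1:10),
    variant_class = c("Missense_Mutation", "Missense_Mutation",
                      "Nonsense_Mutation", "Splice_Site",
                      "Translation_Start_Site", "Nonstop_Mutation",
                      "Silent", "3'UTR", "Missense_Mutation",
                      "Frame_Shift_Del"),
    variant_type = c(rep("SNP", 8), "DEL", "DEL"))
  cohort <- as_cohort(rec)
  kept <- filter_nonsynonymous(cohort)
  expect_equal(nrow(kept$records), 6L)  # 6 non-synonymous SNPs by hand
  expect_true(all(kept$records$variant_type == "SNP"))
  expect_equal(kept$m, cohort$m)

  # a frameshift DEL never survives even with a permissive class set
  del_only <- as_cohort(tibble::tibble(
    sample_id = c("a", "b"), gene = "G",
    variant_key = c("G:V1", "G:V2"),
    variant_class = c("Missense_Mutation", "Frame_Shift_Del"),
    variant_type = c("SNP", "DEL")))
  expect_equal(nrow(filter_nonsynonymous(
    del_only, classes = c("Missense_Mutation", "Frame_Shift_Del"))$records), 1L)
})

test_that("frequency vectors count tumors, not records", {
  cohort <- toy_cohort(list(
    s1 = c("G1:A", "G1:B", "G1:C"),
    s2 = c("G1:C"),
    s3 = character(),
    s4 = c("G1:D")),
    extra_samples = sprintf("x%d", 1:5))
  fv <- variant_frequency(cohort, gene = "G1")
  expect_equal(fv$r, c(1L, 2L))
  expect_equal(fv$N_r, c(3L, 1L))   # A, B, D singletons; C doubleton
  expect_equal(fv_m(fv), 9L)

  # absent gene: empty counts with m still set, not an error
  fv0 <- variant_frequency(cohort, gene = "NOSUCH")
  expect_equal(nrow(fv0), 0L)
  expect_equal(fv_m(fv0), 9L)
})

test_that("the KRAS-profile fixture reproduces its frequency vector", {
  cohort <- kras_fixture(m = 6696)
  fv <- variant_frequency(cohort, gene = "KRAS")
  expect_equal(n_r(fv, 1L), 24L)
  expect_equal(n_r(fv, 2L), 3L)
  expect_equal(n_r(fv, c(142L, 120L, 44L)), c(1L, 1L, 1L))
  expect_equal(sum(fv$N_r), 30L)            # distinct variants
  expect_equal(sum(fv$r * fv$N_r), 24 + 6 + 142 + 120 + 44)  # incidences
})

test_that("MAF round-trip preserves every frequency vector", {
  models <- log_series_panel(8, n_variants = 60, rate = 400, seed = 11)
  sim <- simulate_cohort(models, m = 150,
                         tissue_mix = c(LUAD = 0.5, BRCA = 0.5), seed = 12)
  maf <- withr::local_tempfile(fileext = ".maf")
  ann <- withr::local_tempfile(fileext = ".tsv")
  write_maf(sim$cohort, maf, annotations_path = ann)
  back <- read_maf(maf, annotations = read_sample_annotations(ann))
  expect_equal(back$m, sim$cohort$m)
  expect_equal(as.data.frame(variant_frequency(back)),
               as.data.frame(variant_frequency(sim$cohort)))
  for (g in c("G001", "G004", "G008")) {
    expect_equal(as.data.frame(variant_frequency(back, gene = g)),
                 as.data.frame(variant_frequency(sim$cohort, gene = g)))
  }
})

test_that("gene-scope variant totals add up to the global total", {
  models <- log_series_panel(6, n_variants = 50, rate = 300, seed = 21)
  sim <- simulate_cohort(models, m = 120, seed = 22)
  cohort <- sim$cohort
  global <- variant_frequency(cohort)
  per_gene <- vapply(unique(cohort$records$gene), function(g) {
    sum(variant_frequency(cohort, gene = g)$N_r)
  }, numeric(1))
  expect_equal(sum(per_gene), sum(global$N_r))

  # duplicating records never changes any N_r
  dup <- as_cohort(dplyr::bind_rows(cohort$records, cohort$records),
                   samples = cohort$samples)
  expect_equal(as.data.frame(variant_frequency(dup)), as.data.frame(global))
})

test_that("reading a simulator-emitted MAF matches the simulator's bookkeeping", {
  models <- log_series_panel(10, n_variants = 80, rate = 600, seed = 31)
  sim <- simulate_cohort(models, m = 100, seed = 32)
  maf <- withr::local_tempfile(fileext = ".maf")
  ann <- withr::local_tempfile(fileext = ".tsv")
  write_maf(sim$cohort, maf, annotations_path = ann)
  cohort <- read_maf(maf, annotations = read_sample_annotations(ann))
  expect_equal(cohort$m, 100L)
  expect_equal(nrow(cohort$records), nrow(sim$cohort$records))
})
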