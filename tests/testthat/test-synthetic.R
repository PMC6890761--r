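test_that("a certain variant appears in every tumor", {
  sim <- simulate_cohort(gene_model("G", c(HOT = 1)), m = 10, seed = 1)
  fv <- variant_frequency(sim$cohort, gene = "G")
  expect_equal(fv$r, 10L)
  expect_equal(fv$N_r, 1L)
  expect_equal(sim$cohort$m, 10L)
})

test_that("zipf pools at moderate depth are singleton dominated", {
  sim <- simulate_cohort(
    withr::with_seed(2, gene_model("Z", probs_zipf(1000, s = 1.2, p_max = 0.02))),
    m = 500, seed = 3)
  fv <- variant_frequency(sim$cohort, gene = "Z")
  singleton_fraction <- n_r(fv, 1L) / sum(fv$N_r)
  expect_gt(singleton_fraction, 0.5)
})

test_that("the same seed reproduces the emitted MAF byte for byte", {
  models <- log_series_panel(5, n_variants = 50, rate = 400, seed = 151)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulated_cohort(simulate_cohort(models, m = 80, seed = 9), d1)
  write_simulated_cohort(simulate_cohort(models, m = 80, seed = 9), d2)
  expect_identical(readLines(file.path(d1, "cohort.maf")),
                   readLines(file.path(d2, "cohort.maf")))
  expect_identical(unname(tools::md5sum(file.path(d1, "annotations.tsv"))),
                   unname(tools::md5sum(file.path(d2, "annotations.tsv"))))
  # a different seed gives a different cohort
  write_simulated_cohort(simulate_cohort(models, m = 80, seed = 10), d2)
  expect_false(identical(readLines(file.path(d1, "cohort.maf")),
                         readLines(file.path(d2, "cohort.maf"))))
})

test_that("the exact unseen-probability oracle handles its closed-form cases", {
  sim <- simulate_cohort(gene_model("G", c(HOT = 1)), m = 5, seed = 4)
  expect_equal(true_unseen_probability(sim, gene = "G"), 0)  # pool exhausted
  expect_equal(true_new_variant_count(sim, t = 2, gene = "G"), 0)

  # an untouched pool: empty training cohort sees nothing
  sim2 <- simulate_cohort(gene_model("G", c(A = 0.01)), m = 5, seed = 5)
  empty <- as_cohort(
    tibble::tibble(sample_id = character(), gene = character(),
                   variant_key = character()),
    samples = sim2$cohort$samples)
  expect_equal(true_unseen_probability(sim2, gene = "G", training = empty),
               0.01, tolerance = 1e-12)
  expect_equal(true_new_variant_count(sim2, t = 1, gene = "G",
                                      training = empty),
               1 - (1 - 0.01)^5, tolerance = 1e-12)
})

test_that("the oracle agrees with fresh Monte-Carlo tumors", {
  model <- withr::with_seed(6, gene_model("G", probs_zipf(150, s = 1.1,
                                                          p_max = 0.03)))
  sim <- simulate_cohort(model, m = 200, seed = 7)
  p_true <- true_unseen_probability(sim, gene = "G")
  unseen_p <- sim$truth$p_base[!sim$truth$variant_key %in%
                                 sim$cohort$records$variant_key]
  n_mc <- 40000
  hits <- withr::with_seed(8, {
    # a fresh tumor carries >= 1 unseen variant iff any coin lands heads
    colSums(matrix(rbinom(length(unseen_p) * n_mc, 1, unseen_p),
                   nrow = length(unseen_p))) > 0
  })
  se <- sqrt(p_true * (1 - p_true) / n_mc)
  expect_lt(abs(mean(hits) - p_true), 3 * se)
})

test_that("tissue multipliers shift occurrence probabilities tissue by tissue", {
  model <- gene_model("G", c(A = 0.02, B = 0.01),
                      tissue_multipliers = c(PAAD = 5))
  sim <- simulate_cohort(model, m = 50,
                         tissue_mix = c(PAAD = 0.5, LUAD = 0.5), seed = 11)
  expect_equal(sim$truth$p_PAAD, c(0.10, 0.05), tolerance = 1e-12)
  expect_equal(sim$truth$p_LUAD, c(0.02, 0.01), tolerance = 1e-12)
  # tissue-specific oracle uses the tissue-adjusted pool
  empty <- as_cohort(
    tibble::tibble(sample_id = character(), gene = character(),
                   variant_key = character()),
    samples = sim$cohort$samples)
  expect_equal(true_unseen_probability(sim, gene = "G", tissue = "PAAD",
                                       training = empty),
               1 - (1 - 0.10) * (1 - 0.05), tolerance = 1e-12)
})

test_that("the zipf exponent is a monotone dial of the singleton fraction", {
  # steeper exponents concentrate incidences in the head of the pool, which
  # depresses the singleton share of the observed catalog (the KRAS-like
  # hotspot regime); shallower exponents give FAT1-like singleton dominance
  s_grid <- c(0.8, 1.1, 1.4, 1.7, 2.0)
  m <- 400
  # exact-expectation dial from the closed-form binomial moments
  expected_frac <- vapply(s_grid, function(s) {
    p <- probs_zipf(800, s = s, p_max = 0.02)
    sum(m * p * (1 - p)^(m - 1)) / sum(1 - (1 - p)^m)
  }, numeric(1))
  expect_true(all(diff(expected_frac) < 0))
  # realized catalogs follow the same ordering
  frac <- vapply(seq_along(s_grid), function(i) {
    mean(vapply(1:4, function(rep) {
      sim <- simulate_cohort(
        gene_model("Z", probs_zipf(800, s = s_grid[i], p_max = 0.02)),
        m = m, seed = 600 + 10 * i + rep)
      fv <- variant_frequency(sim$cohort, gene = "Z")
      n_r(fv, 1L) / sum(fv$N_r)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(cor(s_grid, frac, method = "spearman"), -0.8)
})

test_that("a misspecified model with mass capping warns", {
  model <- gene_model("G", rep(0.5, 20), tissue_multipliers = c(T1 = 10))
  expect_warning(
    simulate_cohort(model, m = 50, tissue_mix = c(T1 = 0.5, T2 = 0.5),
                    seed = 12),
    "capped")
})

test_that("hypermutated tumors inflate burden through the multiplier", {
  model <- withr::with_seed(13, gene_model("G", probs_zipf(300, s = 1.0,
                                                           p_max = 0.02)))
  sim <- simulate_cohort(model, m = 400, hyper_fraction = 0.1,
                         hyper_multiplier = 8, seed = 14)
  s <- sim$cohort$samples
  expect_true(any(s$hypermutated))
  expect_gt(mean(s$mutation_burden[s$hypermutated]),
            3 * mean(s$mutation_burden[!s$hypermutated]))
})
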