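test_that("identity smoothing returns raw counts and flags gaps", {
  fv <- frequency_from_counts(c(1, 1, 1, 2), m = 9)
  sm <- gt_smooth(fv, method = "none")
  expect_equal(sm$S[sm$r == 1], 3)
  expect_equal(sm$S[sm$r == 2], 1)
  expect_false(any(sm$gap))

  gappy <- frequency_from_counts(c(1, 1, 1, 1, 1, 3, 3, 3), m = 20)  # {1:5, 3:1}
  smg <- gt_smooth(gappy, method = "none")
  expect_true(smg$gap[smg$r == 2])
  expect_error(gt_probability(gappy, r = 1, smoothing = "none"),
               class = "raremut_gap_error")
})

test_that("the Simple Good-Turing log-log fit matches a hand least-squares fit", {
  # geometric frequency-of-frequency counts 100, 50, 25, ...
  r <- 1:8
  nr <- as.integer(round(100 * 2^(-(r - 1))))
  fv <- frequency_from_counts(rep(r, nr), m = 5000)
  sm <- gt_smooth(fv, method = "sgt")

  # hand fit: averaging transform then closed-form least squares
  r_prev <- c(0L, r[-8]); r_next <- c(r[-1], 2L * r[8] - r[7])
  z <- nr / (0.5 * (r_next - r_prev))
  x <- log(r); y <- log(z)
  b_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a_hand <- mean(y) - b_hand * mean(x)
  expect_equal(attr(sm, "b"), b_hand, tolerance = 1e-10)
  expect_equal(attr(sm, "a"), a_hand, tolerance = 1e-10)
  expect_lt(b_hand, 0)
  # fitted values are positive everywhere, including one past the maximum
  expect_true(all(sm$S > 0))
  expect_true(max(sm$r) == 9L)
})

test_that("SGT-adjusted counts agree with an independent implementation", {
  skip_if_not_installed("edgeR")
  counts <- c(rep(1, 200), rep(2, 80), rep(3, 35), rep(4, 18), rep(5, 9),
              rep(6, 5), rep(7, 3), rep(10, 2), 15, 25)
  fv <- frequency_from_counts(counts, m = 2000)
  q <- gt_probability(fv, smoothing = "sgt")
  rstar_ours <- q$q * (fv_m(fv) + 1)
  gt <- edgeR::goodTuring(counts)
  # edgeR works in the multinomial-token framing and renormalizes its
  # proportions against the missing mass; compare the adjusted counts
  # r* = (r+1) S(N_{r+1})/S(N_r) on the smoothed classes
  rstar_edger <- gt$proportion * sum(counts)
  idx <- q$r >= 2
  expect_true(all(abs(rstar_ours[idx] - rstar_edger[idx]) /
                    rstar_edger[idx] < 0.1))
})

test_that("the Good-Turing recurrence probability matches direct evaluation", {
  fv <- frequency_from_counts(c(1, 1, 1, 2), m = 9)
  q <- gt_probability(fv, smoothing = "none")
  expect_equal(q$q[q$r == 1], (2 / 10) * (1 / 3), tolerance = 1e-15)
  # empty class above the maximum frequency: q = 0, not an error
  expect_equal(q$q[q$r == 2], 0)
  expect_error(gt_probability(fv, r = 0), class = "raremut_domain_error")
  expect_error(gt_probability(fv, r = 5), class = "raremut_domain_error")
})

test_that("probabilities stay in [0, 1] with a warning when clamped", {
  # tiny scope engineered so the raw ratio exceeds 1: N2 >> N1
  fv <- frequency_from_counts(c(1, rep(2, 12)), m = 3)
  expect_warning(q <- gt_probability(fv, r = 1, smoothing = "none"),
                 "clamped")
  expect_equal(q$q, 1)
})

test_that("unseen-variant probability follows its closed form", {
  expect_equal(unseen_probability(0, 100), 0)
  expect_equal(unseen_probability(24, 6696), 1 - exp(-24 / 6697),
               tolerance = 1e-15)
  expect_error(unseen_probability(-1, 10), class = "raremut_domain_error")
  expect_error(unseen_probability(5, 0), class = "raremut_domain_error")

  # monotone increasing in N1, decreasing in m
  n1_grid <- unseen_probability(0:50, 1000)
  expect_true(all(diff(n1_grid) > 0))
  m_grid <- unseen_probability(20, c(100, 500, 1000, 5000))
  expect_true(all(diff(m_grid) < 0))
})

test_that("the unseen rate and probability are mutually consistent", {
  n1 <- c(0, 3, 24, 120)
  m <- c(10, 99, 6696, 10000)
  expect_identical(unseen_probability(n1, m), 1 - exp(-unseen_rate(n1, m)))
  expect_equal(unseen_rate(24, 6696), 24 / 6697, tolerance = 1e-15)
})

test_that("total Good-Turing mass accounts for observed variants plus missing mass", {
  # with identity smoothing, sum_r N_r q(r) + N1/(m+1) telescopes to
  # (total incidences)/(m+1); on a gene scope with a per-tumor variant count
  # below one this stays below 1
  fv <- frequency_from_counts(rep(1:4, c(15, 6, 2, 1)), m = 40)
  q <- gt_probability(fv, smoothing = "none")
  total_mass <- sum(q$N_r * q$q) + n_r(fv, 1L) / (fv_m(fv) + 1)
  incidences <- sum(fv$r * fv$N_r)
  expect_equal(total_mass, incidences / (fv_m(fv) + 1), tolerance = 1e-12)
  expect_lte(total_mass, 1 + 1e-12)
})

test_that("class-averaged recurrence probabilities are calibrated against holdout tumors", {
  # product-binomial pool; per replicate, compare q(r) for the singleton and
  # doubleton classes with the empirical occurrence frequency of those same
  # variants in fresh holdout tumors
  model <- withr::with_seed(5, gene_model("G1", probs_zipf(250, s = 1.0, p_max = 0.05)))
  p_pool <- stats::setNames(unname(model$probs), names(model$probs))
  n_rep <- 120
  m <- 300
  h <- 100  # holdout tumors per replicate
  diffs <- withr::with_seed(77, {
    vapply(seq_len(n_rep), function(i) {
      sim <- simulate_cohort(model, m = m, seed = 10000 + i)
      counts <- variant_counts(sim$cohort)
      fv <- frequency_from_counts(counts$r, m, scope = "G1")
      out <- c(NA_real_, NA_real_)
      for (rc in 1:2) {
        if (n_r(fv, rc) == 0L || n_r(fv, rc + 1L) == 0L) next
        qbar <- suppressWarnings(
          gt_probability(fv, r = rc, smoothing = "none")$q)
        in_class <- counts$variant_key[counts$r == rc]
        p_true <- p_pool[in_class]
        emp <- mean(rbinom(length(p_true), h, p_true) / h)
        out[rc] <- qbar - emp
      }
      out
    }, numeric(2))
  })
  for (rc in 1:2) {
    d <- diffs[rc, ]
    d <- d[is.finite(d)]
    expect_gt(length(d), 50)
    se <- sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d)), 3 * se)
  }
})
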