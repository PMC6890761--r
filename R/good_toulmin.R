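#' Good-Toulmin extrapolation of the number of new variants
#'
#' Estimates \eqn{\Delta(t)}, the expected number of distinct new variants
#' that would be observed if the cohort of `m` tumors were extended by
#' `t * m` additional tumors. The plain Good-Toulmin estimator is the
#' alternating series
#' \deqn{\Delta(t) = \sum_{r \ge 1} (-1)^{r+1} t^r N_r}
#' which is accurate for `t <= 1` but diverges beyond the observed sample
#' size. For `t > 1` the Euler (binomial-tail) smoothed version is used:
#' each term is weighted by \eqn{P(L \ge r)} with
#' \eqn{L \sim \mathrm{Binomial}(k, 2/(t+2))} and
#' \eqn{k = \lceil \tfrac12 \log_2(m t^2/(t-1)) \rceil}, which tames the
#' divergence at a small cost in bias. A negative estimate is truncated to 0
#' with a warning.
#'
#' @param fv A `freq_vector`.
#' @param t Positive extrapolation factor (future tumors = `t * m`).
#' @param method `"auto"` (plain for `t <= 1`, Euler-smoothed above),
#'   `"plain"`, or `"euler"`.
#' @return A one-row tibble: `scope`, `t`, `m`, `delta`, `method`,
#'   `truncated`.
#' @export
#' @examples
#' fv <- frequency_from_counts(c(1, 1, 1, 2), m = 9)
#' good_toulmin(fv, t = 1)  # 3 - 1 = 2
good_toulmin <- function(fv, t, method = c("auto", "plain", "euler")) {
  method <- match.arg(method)
  check_positive(t, "t")
  m <- fv_m(fv)
  if (method == "auto") method <- if (t <= 1) "plain" else "euler"
  if (!nrow(fv)) {
    return(tibble(scope = attr(fv, "scope") %||% NA_character_, t = t, m = m,
                  delta = 0, method = method, truncated = FALSE))
  }
  r <- fv$r
  nr <- as.numeric(fv$N_r)
  if (method == "plain") {
    terms <- (-1)^(r + 1) * t^r * nr
  } else {
    k <- max(1L, ceiling(0.5 * log2(m * t^2 / abs(t - 1))))
    w <- 1 - pbinom(r - 1, size = k, prob = 2 / (t + 2))
    terms <- (-1)^(r + 1) * t^r * nr * w
  }
  delta <- sum(terms)
  truncated <- FALSE
  if (delta < 0) {
    warn(sprintf("Good-Toulmin estimate was negative (%.4g); truncated to 0.",
                 delta))
    delta <- 0
    truncated <- TRUE
  }
  tibble(scope = attr(fv, "scope") %||% NA_character_, t = t, m = m,
         delta = delta, method = method, truncated = truncated)
}

#' Expected number of new variants in one additional tumor
#'
#' [good_toulmin()] evaluated at `t = 1/m` with the plain series (which
#' converges for `t <= 1`); the per-tumor analogue of the subgroup-level
#' discovery rates.
#'
#' @param fv A `freq_vector` with `m >= 1`.
#' @return A one-row tibble as in [good_toulmin()].
#' @export
new_variants_one_tumor <- function(fv) {
  m <- fv_m(fv)
  check_positive(m, "m")
  good_toulmin(fv, t = 1 / m, method = "plain")
}

#' Bootstrap standard error for a Good-Toulmin estimate
#'
#' Resamples tumors with replacement `B` times, rebuilds the frequency vector
#' of the requested scope from each resample, re-evaluates \eqn{\Delta(t)},
#' and reports the standard deviation across resamples.
#'
#' @param cohort A filtered `cohort`.
#' @param t Extrapolation factor.
#' @param gene Optional gene scope (`NULL` = genome-wide).
#' @param B Number of bootstrap resamples (>= 2; default 200).
#' @param seed Seed for reproducibility (the caller's RNG state is restored).
#' @param method Passed to [good_toulmin()].
#' @return A one-row tibble: `scope`, `t`, `m`, `delta` (full-data estimate),
#'   `se`, `B`, `method`.
#' @export
gt_bootstrap <- function(cohort, t, gene = NULL, B = 200, seed = NULL,
                         method = c("auto", "plain", "euler")) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "cohort"))
  if (!is.numeric(B) || B < 2) {
    abort("`B` must be at least 2.", class = "raremut_domain_error")
  }
  B <- as.integer(B)
  if (B < 50) warn("Bootstrap with B < 50 resamples gives unstable standard errors.")
  m <- cohort$m
  records <- cohort$records
  if (!is.null(gene)) records <- filter(records, .data$gene %in% !!gene)
  fv <- frequency_from_counts(
    count(records, .data$variant_key, name = "r")$r, m,
    scope = gene %||% "global")
  point <- good_toulmin(fv, t, method = method)

  # incidence matrix (variants x samples); a resampled frequency vector is
  # the row sums under multinomial sample weights
  sample_idx <- match(records$sample_id, cohort$samples$sample_id)
  variant_idx <- match(records$variant_key, unique(records$variant_key))
  n_var <- max(variant_idx, 0L)
  deltas <- numeric(B)
  if (n_var > 0L) {
    inc <- Matrix::sparseMatrix(i = variant_idx, j = sample_idx, x = 1,
                                dims = c(n_var, m))
    deltas <- with_preserved_seed(seed, {
      vapply(seq_len(B), function(b) {
        w <- tabulate(sample.int(m, m, replace = TRUE), nbins = m)
        rstar <- as.numeric(inc %*% w)
        fvb <- frequency_from_counts(rstar[rstar > 0], m,
                                     scope = attr(fv, "scope"))
        suppressWarnings(good_toulmin(fvb, t, method = method)$delta)
      }, numeric(1))
    })
  }
  tibble(scope = attr(fv, "scope"), t = t, m = m, delta = point$delta,
         se = stats::sd(deltas), B = B, method = point$method)
}
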