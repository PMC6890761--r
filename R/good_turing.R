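#' Smooth a frequency vector for Good-Turing estimation
#'
#' The Good-Turing probability for frequency class `r` needs the ratio
#' `S(N_{r+1}) / S(N_r)`, where `S` is a smoothing function of the
#' frequency-of-frequency counts. Two methods are provided:
#'
#' * `"none"` — identity, `S(N_r) = N_r`. Interior gaps (an empty class
#'   below the largest observed frequency) are flagged in the output; asking
#'   for a probability that needs a flagged gap is an error.
#' * `"sgt"` — Simple Good-Turing (Gale-Sampson). The frequency counts are
#'   variance-stabilised with the averaging transform
#'   `Z_r = N_r / (0.5 (r'' - r'))` over the neighbouring non-empty classes,
#'   a line `log Z = a + b log r` is fit by least squares, and the fitted
#'   value `exp(a) r^b` replaces the raw count from the first class where the
#'   raw and fitted Turing-adjusted counts are statistically
#'   indistinguishable (difference below 1.96 standard deviations of the raw
#'   estimate), onwards. Below the switch point the raw counts are kept; empty
#'   classes always take the fitted value.
#'
#' @param fv A `freq_vector` from [variant_frequency()] or
#'   [frequency_from_counts()].
#' @param method `"sgt"` (default) or `"none"`.
#' @return A tibble with one row per frequency needed downstream (all
#'   observed `r` plus each `r + 1`): columns `r`, `N_r` (raw count, 0 for
#'   empty classes), `S` (smoothed value), `fitted` (logical, whether `S`
#'   came from the log-log fit), `gap` (logical, empty interior class under
#'   identity smoothing). The log-log fit coefficients are attached as
#'   attributes `a` and `b` when `method = "sgt"`.
#' @export
#' @examples
#' fv <- frequency_from_counts(c(1, 1, 1, 2), m = 9)
#' gt_smooth(fv, method = "none")
gt_smooth <- function(fv, method = c("sgt", "none")) {
  method <- match.arg(method)
  if (!nrow(fv)) {
    abort("Cannot smooth an empty frequency vector.",
          class = "raremut_domain_error")
  }
  obs_r <- fv$r
  obs_N <- as.numeric(fv$N_r)
  need_r <- sort(union(obs_r, obs_r + 1L))
  raw <- n_r(fv, need_r)
  max_r <- max(obs_r)

  if (method == "none" || nrow(fv) < 3L) {
    if (method == "sgt" && nrow(fv) < 3L) {
      warn("Fewer than 3 frequency classes: falling back to identity smoothing.")
      method <- "none"
    }
    out <- tibble(
      r = need_r, N_r = raw, S = as.numeric(raw), fitted = FALSE,
      gap = raw == 0L & need_r <= max_r
    )
    return(structure(out, method = method))
  }

  k <- length(obs_r)
  r_prev <- c(0L, obs_r[-k])
  r_next <- c(obs_r[-1], 2L * obs_r[k] - obs_r[k - 1L])
  z <- obs_N / (0.5 * (r_next - r_prev))
  fit <- lm(log(z) ~ log(obs_r))
  a <- coef(fit)[[1]]
  b <- coef(fit)[[2]]
  s_fit <- function(rr) exp(a + b * log(rr))

  # Gale-Sampson switch rule, evaluated on the Turing-adjusted counts
  # r* = (r+1) N_{r+1} / N_r: keep raw counts while the empirical adjusted
  # count differs significantly from the fitted one, then stay on the fit.
  use_fit <- logical(k)
  switched <- FALSE
  for (j in seq_len(k)) {
    if (!switched) {
      rj <- obs_r[j]
      n_next <- n_r(fv, rj + 1L)
      if (n_next == 0L) {
        switched <- TRUE
      } else {
        x_emp <- (rj + 1) * n_next / obs_N[j]
        x_fit <- (rj + 1) * s_fit(rj + 1L) / s_fit(rj)
        sd_emp <- (rj + 1) / obs_N[j] * sqrt(n_next * (1 + n_next / obs_N[j]))
        if (abs(x_emp - x_fit) <= 1.96 * sd_emp) switched <- TRUE
      }
    }
    use_fit[j] <- switched
  }

  s_obs <- ifelse(use_fit, s_fit(obs_r), obs_N)
  s_all <- s_fit(need_r)
  idx <- match(obs_r, need_r)
  s_all[idx] <- s_obs
  fitted_all <- rep(TRUE, length(need_r))
  fitted_all[idx] <- use_fit
  out <- tibble(r = need_r, N_r = raw, S = s_all, fitted = fitted_all,
                gap = FALSE)
  structure(out, method = "sgt", a = a, b = b)
}

smoothed_value <- function(sm, r) {
  idx <- match(as.integer(r), sm$r)
  if (anyNA(idx)) {
    # a frequency outside the smoothed range: 0 under identity (empty class
    # beyond the maximum), fitted value under SGT
    out <- numeric(length(r))
    a <- attr(sm, "a")
    if (!is.null(a)) out <- exp(a + attr(sm, "b") * log(as.numeric(r)))
    out[!is.na(idx)] <- sm$S[idx[!is.na(idx)]]
    return(out)
  }
  sm$S[idx]
}

#' Good-Turing probability of recurrence for seen variants
#'
#' For a variant observed in `r` of `m` tumors, the Good-Turing estimate of
#' the probability that it occurs in one randomly selected new tumor is
#' \deqn{q^{GT} = \frac{r+1}{m+1} \cdot \frac{S(N_{r+1})}{S(N_r)}}
#' where `S` smooths the frequency-of-frequency counts ([gt_smooth()]).
#' Values are clamped to `[0, 1]` with a warning when the raw ratio exceeds 1
#' (possible in tiny scopes).
#'
#' @param fv A `freq_vector`.
#' @param r Frequency class(es) to evaluate; default all observed classes.
#'   Every requested `r` must have `N_r > 0`; `r = 0` is refused (unseen
#'   variants are handled by [unseen_probability()]).
#' @param smoothing `"sgt"` or `"none"` (see [gt_smooth()]). With `"none"`,
#'   an empty class `N_{r+1} = 0` below the maximum observed frequency is an
#'   unsmoothable gap and raises an error; above the maximum it legitimately
#'   gives `q = 0`.
#' @return A tibble with columns `r`, `N_r`, `q`, `smoothed` (whether either
#'   `S` value came from the log-log fit).
#' @export
#' @examples
#' fv <- frequency_from_counts(c(1, 1, 1, 2), m = 9)
#' gt_probability(fv, smoothing = "none")  # q(1) = (2/10) * (1/3)
gt_probability <- function(fv, r = NULL, smoothing = c("sgt", "none")) {
  smoothing <- match.arg(smoothing)
  m <- fv_m(fv)
  if (is.null(r)) r <- fv$r
  r <- as.integer(r)
  if (any(r < 1L)) {
    abort("r must be >= 1; unseen variants are handled by unseen_probability().",
          class = "raremut_domain_error")
  }
  nr <- n_r(fv, r)
  if (any(nr == 0L)) {
    abort(sprintf("No variant has frequency r = %s in this scope (N_r = 0).",
                  paste(r[nr == 0L], collapse = ", ")),
          class = "raremut_domain_error")
  }
  sm <- gt_smooth(fv, method = smoothing)
  max_r <- max(fv$r)
  if (identical(attr(sm, "method"), "none")) {
    interior_gap <- (r + 1L) <= max_r & n_r(fv, r + 1L) == 0L
    if (any(interior_gap)) {
      abort(sprintf(
        "Unsmoothable gap: N_%d = 0 with identity smoothing; use smoothing = \"sgt\".",
        r[interior_gap][1] + 1L),
        class = "raremut_gap_error")
    }
  }
  s_r <- smoothed_value(sm, r)
  s_r1 <- smoothed_value(sm, r + 1L)
  if (identical(attr(sm, "method"), "none")) {
    s_r1[(r + 1L) > max_r] <- 0
  }
  q <- (r + 1) / (m + 1) * s_r1 / s_r
  if (any(q > 1)) {
    warn(sprintf("%d Good-Turing probability value(s) exceeded 1 and were clamped.",
                 sum(q > 1)))
    q <- pmin(q, 1)
  }
  q <- pmax(q, 0)
  fitted_at <- function(rr) {
    idx <- match(rr, sm$r)
    out <- rep(TRUE, length(rr))
    out[!is.na(idx)] <- sm$fitted[idx[!is.na(idx)]]
    out
  }
  tibble(r = r, N_r = nr, q = q,
         smoothed = fitted_at(r) | fitted_at(r + 1L))
}

#' Per-variant Good-Turing probabilities within a gene
#'
#' Convenience wrapper joining each observed variant of a gene to the
#' Good-Turing probability of its frequency class.
#'
#' @param cohort A filtered `cohort`.
#' @param gene HUGO symbol.
#' @param smoothing Passed to [gt_probability()].
#' @return A tibble with columns `variant_key`, `r`, `q`, `smoothed`.
#' @export
gene_gt_probabilities <- function(cohort, gene, smoothing = c("sgt", "none")) {
  counts <- variant_counts(cohort, gene = gene)
  fv <- frequency_from_counts(counts$r, cohort$m, scope = gene)
  q <- gt_probability(fv, smoothing = smoothing)
  counts |>
    left_join(select(q, "r", "q", "smoothed"), by = "r") |>
    select("variant_key", "r", "q", "smoothed") |>
    arrange(dplyr::desc(.data$r), .data$variant_key)
}

#' Probability of encountering at least one unseen variant
#'
#' The probability that a new tumor carries one or more variants never
#' observed in the `m` profiled tumors, approximated by
#' \deqn{1 - \exp\{-N_1 / (m + 1)\}}
#' which involves only the singleton count `N_1`, not the unknown number of
#' unseen variants.
#'
#' @param n1 Singleton count(s) `N_1` (vectorised).
#' @param m Cohort size(s).
#' @return Probability in `[0, 1)`.
#' @export
#' @examples
#' unseen_probability(24, 6696)
unseen_probability <- function(n1, m) {
  check_non_negative(n1, "n1")
  if (any(m < 1)) {
    abort("`m` must be >= 1.", class = "raremut_domain_error")
  }
  1 - exp(-n1 / (m + 1))
}

#' Expected number of new variants per additional tumor
#'
#' The Poisson rate `N_1 / (m + 1)` underlying [unseen_probability()]:
#' `unseen_probability(n1, m) == 1 - exp(-unseen_rate(n1, m))`.
#'
#' @inheritParams unseen_probability
#' @return Non-negative rate.
#' @export
unseen_rate <- function(n1, m) {
  check_non_negative(n1, "n1")
  if (any(m < 1)) {
    abort("`m` must be >= 1.", class = "raremut_domain_error")
  }
  n1 / (m + 1)
}

#' Unseen-variant probability per gene
#'
#' Tabulates, for each gene (optionally within each tissue), the singleton
#' count, cohort size and [unseen_probability()].
#'
#' @param cohort A filtered `cohort`.
#' @param genes Optional character vector restricting the output; defaults to
#'   every mutated gene.
#' @param by_tissue If `TRUE`, stratify by `tumor_type`: each tissue uses its
#'   own sample count `m_c` and its own singleton count.
#' @return A tibble with columns `gene` (and `tumor_type` when stratified),
#'   `n1`, `m`, `p_unseen`.
#' @export
unseen_by_gene <- function(cohort, genes = NULL, by_tissue = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  records <- cohort$records
  if (!is.null(genes)) records <- filter(records, .data$gene %in% genes)
  if (!by_tissue) {
    out <- records |>
      count(.data$gene, .data$variant_key, name = "r") |>
      group_by(.data$gene) |>
      summarise(n1 = sum(.data$r == 1L), .groups = "drop") |>
      mutate(m = cohort$m)
  } else {
    m_c <- count(cohort$samples, .data$tumor_type, name = "m")
    out <- records |>
      count(.data$tumor_type, .data$gene, .data$variant_key, name = "r") |>
      group_by(.data$tumor_type, .data$gene) |>
      summarise(n1 = sum(.data$r == 1L), .groups = "drop") |>
      left_join(m_c, by = "tumor_type")
  }
  if (!is.null(genes)) {
    # genes never mutated still get a row: N1 = 0, p = 0
    missing_g <- setdiff(genes, out$gene)
    if (length(missing_g) && !by_tissue) {
      out <- bind_rows(out, tibble(gene = missing_g, n1 = 0L, m = cohort$m))
    }
  }
  out |>
    mutate(p_unseen = unseen_probability(.data$n1, .data$m)) |>
    arrange(.data$gene)
}
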