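#' Normalized mutual information between tissue and a binary mutation event
#'
#' Quantifies how strongly an event's occurrence probability depends on
#' tissue of origin. The joint distribution over (tissue `T`, event `E`) is
#' built as `P(T = c, E = 1) = w_c * p_c` and
#' `P(T = c, E = 0) = w_c * (1 - p_c)`, and the score is the mutual
#' information `I(T; E)` divided by a normalizer. A score of 0 means the
#' event is lineage independent (all `p_c` equal); with the default tissue
#' normalizer `H(T)`, a tissue-deterministic event scores 1. The ratio is
#' base-invariant.
#'
#' @param p Per-tissue event probabilities in `[0, 1]`, optionally named by
#'   tissue.
#' @param weights Tissue proportions (summing to 1, or normalised if not); by
#'   default the sample-count shares `m_c / m`.
#' @param normalizer `"tissue"` (`H(T)`, default), `"event"` (`H(E)`),
#'   `"min"` (`min(H(T), H(E))`), or `"sqrt"` (`sqrt(H(T) H(E))`). Reported
#'   alongside scores by the cohort-level wrappers.
#' @return A single value in `[0, 1]` (0 when only one tissue is present or
#'   the normalizer is degenerate).
#' @export
#' @examples
#' nmi(c(1, 0), c(0.5, 0.5))  # tissue-deterministic event: 1
#' nmi(c(0.1, 0.1, 0.1), rep(1 / 3, 3))  # lineage independent: 0
nmi <- function(p, weights = NULL,
                normalizer = c("tissue", "event", "min", "sqrt")) {
  normalizer <- match.arg(normalizer)
  if (!length(p)) {
    abort("`p` must contain at least one tissue.", class = "raremut_domain_error")
  }
  if (any(p < -1e-12 | p > 1 + 1e-12) || anyNA(p)) {
    abort("Event probabilities must lie in [0, 1].",
          class = "raremut_domain_error")
  }
  p <- pmin(pmax(p, 0), 1)
  if (is.null(weights)) weights <- rep(1 / length(p), length(p))
  if (length(weights) != length(p) || any(weights < 0) || sum(weights) <= 0) {
    abort("`weights` must be non-negative with a positive sum, one per tissue.",
          class = "raremut_domain_error")
  }
  w <- weights / sum(weights)
  keep <- w > 0
  w <- w[keep]
  p <- p[keep]
  if (length(p) < 2L) return(0)

  joint <- cbind(w * p, w * (1 - p))        # columns: E = 1, E = 0
  p_e <- colSums(joint)
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  # I(T;E) = sum P log(P / (P_T P_E))
  mi <- sum(xlogx(joint)) - sum(xlogx(w)) - sum(xlogx(p_e))
  h_t <- -sum(xlogx(w))
  h_e <- -sum(xlogx(p_e))
  denom <- switch(normalizer,
                  tissue = h_t,
                  event = h_e,
                  min = min(h_t, h_e),
                  sqrt = sqrt(h_t * h_e))
  if (denom <= 0) return(0)
  max(0, mi / denom)
}

#' Index-tissue NMI: one cancer type against the rest
#'
#' Binarizes the tissue label into "index tissue" versus the weighted pool of
#' all other tissues, then applies [nmi()]. Used to ask how much an event is
#' elevated in one cancer type compared with the average of the others. With
#' only two tissues this equals `nmi()` on the same data.
#'
#' @param p Named per-tissue event probabilities.
#' @param weights Named tissue proportions (same names as `p`).
#' @param index Name of the index tissue.
#' @inheritParams nmi
#' @return NMI of the binarized contrast.
#' @export
index_tissue_nmi <- function(p, weights, index,
                             normalizer = c("tissue", "event", "min", "sqrt")) {
  normalizer <- match.arg(normalizer)
  if (is.null(names(p)) || is.null(names(weights))) {
    abort("`p` and `weights` must be named by tissue.",
          class = "raremut_config_error")
  }
  if (!index %in% names(p)) {
    abort(sprintf("Index tissue %s is not present.", index),
          class = "raremut_domain_error")
  }
  w <- weights / sum(weights)
  rest <- setdiff(names(p), index)
  if (!length(rest)) return(0)
  w_rest <- sum(w[rest])
  p_rest <- if (w_rest > 0) sum(w[rest] * p[rest]) / w_rest else 0
  nmi(c(p[[index]], p_rest), c(w[[index]], w_rest), normalizer = normalizer)
}

#' Per-tissue unseen-variant probabilities for a gene
#'
#' Stratifies the cohort by tissue: each tissue `c` contributes its own
#' sample count `m_c` and its own singleton count `N_1^{(c)}` for the gene,
#' giving `p_c = 1 - exp(-N_1^{(c)} / (m_c + 1))`. These probabilities, with
#' weights `m_c / m`, feed the gene-level tissue-specificity NMI.
#'
#' @param cohort A filtered `cohort` whose samples carry `tumor_type`.
#' @param gene HUGO symbol.
#' @return A tibble: `tumor_type`, `m`, `weight`, `n1`, `p`.
#' @export
tissue_unseen_probabilities <- function(cohort, gene) {
  stopifnot(inherits(cohort, "cohort"))
  m_c <- count(cohort$samples, .data$tumor_type, name = "m")
  n1 <- cohort$records |>
    filter(.data$gene %in% !!gene) |>
    count(.data$tumor_type, .data$variant_key, name = "r") |>
    group_by(.data$tumor_type) |>
    summarise(n1 = sum(.data$r == 1L), .groups = "drop")
  m_c |>
    left_join(n1, by = "tumor_type") |>
    mutate(n1 = ifelse(is.na(.data$n1), 0L, .data$n1),
           weight = .data$m / sum(.data$m),
           p = unseen_probability(.data$n1, .data$m)) |>
    select("tumor_type", "m", "weight", "n1", "p")
}

#' Per-tissue Good-Turing probabilities for one seen variant
#'
#' For a specific variant, estimates its occurrence probability separately in
#' each tissue from the tissue-stratified frequency vector of its gene. In a
#' tissue where the variant was never observed the Good-Turing machinery does
#' not apply (that is unseen mass); the probability is reported as 0 there.
#'
#' @param cohort A filtered `cohort`.
#' @param gene HUGO symbol.
#' @param variant Variant key (e.g. `"KRAS:G12D"`).
#' @param smoothing Passed to [gt_probability()].
#' @return A tibble: `tumor_type`, `m`, `weight`, `r`, `q`.
#' @export
tissue_variant_probabilities <- function(cohort, gene, variant,
                                         smoothing = c("sgt", "none")) {
  smoothing <- match.arg(smoothing)
  stopifnot(inherits(cohort, "cohort"))
  m_c <- count(cohort$samples, .data$tumor_type, name = "m") |>
    mutate(weight = .data$m / sum(.data$m))
  counts <- cohort$records |>
    filter(.data$gene %in% !!gene) |>
    count(.data$tumor_type, .data$variant_key, name = "r")
  per_tissue <- function(tt, mm) {
    cc <- filter(counts, .data$tumor_type %in% tt)
    r_v <- cc$r[cc$variant_key == variant]
    if (!length(r_v) || r_v == 0L) return(0)
    fv <- frequency_from_counts(cc$r, mm, scope = gene)
    suppressWarnings(gt_probability(fv, r = r_v, smoothing = smoothing)$q)
  }
  m_c |>
    mutate(
      r = vapply(.data$tumor_type, function(tt) {
        cc <- filter(counts, .data$tumor_type %in% tt)
        rv <- cc$r[cc$variant_key == variant]
        if (length(rv)) as.integer(rv) else 0L
      }, integer(1)),
      q = purrr::map2_dbl(.data$tumor_type, .data$m, per_tissue)
    )
}

#' Tissue-specificity NMI for a gene
#'
#' Computes the NMI between tissue label and either the unseen-variant event
#' of a gene (default) or the occurrence of one specific seen variant.
#'
#' @param cohort A filtered `cohort`.
#' @param gene HUGO symbol.
#' @param type `"unseen"` (probability of a new variant in the gene, from
#'   [tissue_unseen_probabilities()]) or `"variant"` (per-tissue Good-Turing
#'   probability of `variant`).
#' @param variant Variant key, required when `type = "variant"`.
#' @param normalizer Passed to [nmi()].
#' @param smoothing Passed to [tissue_variant_probabilities()].
#' @return A one-row tibble: `scope`, `type`, `nmi`, `normalizer`.
#' @export
gene_tissue_nmi <- function(cohort, gene, type = c("unseen", "variant"),
                            variant = NULL,
                            normalizer = c("tissue", "event", "min", "sqrt"),
                            smoothing = c("sgt", "none")) {
  type <- match.arg(type)
  normalizer <- match.arg(normalizer)
  if (type == "unseen") {
    tbl <- tissue_unseen_probabilities(cohort, gene)
    p <- tbl$p
    scope <- gene
  } else {
    if (is.null(variant)) {
      abort("`variant` is required when type = \"variant\".",
            class = "raremut_config_error")
    }
    tbl <- tissue_variant_probabilities(cohort, gene, variant,
                                        smoothing = smoothing)
    p <- tbl$q
    scope <- variant
  }
  if (nrow(tbl) < 2L) {
    abort("At least two tissues are required for a tissue-specificity score.",
          class = "raremut_domain_error")
  }
  tibble(scope = scope, type = type,
         nmi = nmi(p, tbl$weight, normalizer = normalizer),
         normalizer = normalizer)
}

#' Permutation null distribution for a gene's tissue-specificity NMI
#'
#' Randomly reallocates tissue labels across tumors (preserving each tissue's
#' sample count), recomputes the gene's per-tissue unseen-variant
#' probabilities and their NMI for each permutation, and returns the null
#' sample together with its 95th percentile — the reference against which an
#' observed NMI is judged.
#'
#' @param cohort A filtered `cohort` with at least two tissues.
#' @param gene HUGO symbol.
#' @param n_permutations Number of label permutations (default 1000).
#' @param seed Seed (caller's RNG state is restored).
#' @param normalizer Passed to [nmi()].
#' @return An object of class `nmi_null`: a list with `null` (numeric vector
#'   of null NMIs), `percentile_95`, `observed` (the unpermuted NMI),
#'   `exceeds_null` (`observed > percentile_95`), `n_permutations`, `seed`,
#'   `gene`, `normalizer`.
#' @export
nmi_null <- function(cohort, gene, n_permutations = 1000, seed = NULL,
                     normalizer = c("tissue", "event", "min", "sqrt")) {
  normalizer <- match.arg(normalizer)
  stopifnot(inherits(cohort, "cohort"))
  if (!is.numeric(n_permutations) || n_permutations < 2) {
    abort("`n_permutations` must be at least 2 (1000 recommended).",
          class = "raremut_domain_error")
  }
  n_permutations <- as.integer(n_permutations)
  tissues <- sort(unique(cohort$samples$tumor_type))
  n_tis <- length(tissues)
  if (n_tis < 2L) {
    abort("At least two tissues are required for a permutation null.",
          class = "raremut_domain_error")
  }
  m <- cohort$m
  tis_idx <- match(cohort$samples$tumor_type, tissues)
  m_c <- tabulate(tis_idx, nbins = n_tis)
  w <- m_c / m

  gene_rec <- filter(cohort$records, .data$gene %in% !!gene)
  v_keys <- unique(gene_rec$variant_key)
  n_var <- length(v_keys)
  v_idx <- match(gene_rec$variant_key, v_keys)
  s_idx <- match(gene_rec$sample_id, cohort$samples$sample_id)

  nmi_for_labels <- function(lab) {
    if (n_var == 0L) {
      p <- rep(0, n_tis)
    } else {
      cnt <- tabulate(v_idx + n_var * (lab[s_idx] - 1L), nbins = n_var * n_tis)
      cnt <- matrix(cnt, nrow = n_var, ncol = n_tis)
      n1_c <- colSums(cnt == 1L)
      p <- unseen_probability(n1_c, m_c)
    }
    nmi(p, w, normalizer = normalizer)
  }

  observed <- nmi_for_labels(tis_idx)
  null <- with_preserved_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      nmi_for_labels(tis_idx[sample.int(m)])
    }, numeric(1))
  })
  p95 <- unname(quantile(null, 0.95, type = 7))
  structure(
    list(null = null, percentile_95 = p95, observed = observed,
         exceeds_null = observed > p95, n_permutations = n_permutations,
         seed = seed, gene = gene, normalizer = normalizer),
    class = "nmi_null")
}

#' @export
print.nmi_null <- function(x, ...) {
  cat(sprintf(
    "<nmi_null> gene %s: observed NMI %.4f vs null 95th percentile %.4f (%s, %d permutations)\n",
    x$gene, x$observed, x$percentile_95,
    if (x$exceeds_null) "exceeds null" else "within null", x$n_permutations))
  invisible(x)
}
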