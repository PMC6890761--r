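#' New variants in a validation cohort relative to a training cohort
#'
#' A validation variant is "new" when its variant key never occurs in the
#' training cohort. For each gene, reports the number of distinct new
#' variants and the fraction of validation tumors carrying at least one new
#' variant in that gene.
#'
#' @param train,valid Filtered `cohort`s keyed with the same scheme.
#' @param genes Optional genes to report; defaults to the genes mutated in
#'   either cohort. Genes with no validation mutations report `(0, 0)`.
#' @return A tibble: `gene`, `n_new` (distinct new variants),
#'   `fraction_new` (validation tumors with >= 1 new variant / `m_valid`).
#' @export
observed_new_variants <- function(train, valid, genes = NULL) {
  stopifnot(inherits(train, "cohort"), inherits(valid, "cohort"))
  if (!identical(train$key_scheme, valid$key_scheme)) {
    abort(sprintf("Variant key schemes differ between cohorts (%s vs %s).",
                  train$key_scheme, valid$key_scheme),
          class = "raremut_config_error")
  }
  if (is.null(genes)) {
    genes <- sort(union(unique(train$records$gene),
                        unique(valid$records$gene)))
  }
  seen <- unique(train$records$variant_key)
  new_rec <- valid$records |>
    filter(.data$gene %in% genes, !.data$variant_key %in% seen)
  per_gene <- new_rec |>
    group_by(.data$gene) |>
    summarise(n_new = n_distinct(.data$variant_key),
              n_tumors_new = n_distinct(.data$sample_id),
              .groups = "drop")
  tibble(gene = genes) |>
    left_join(per_gene, by = "gene") |>
    mutate(n_new = ifelse(is.na(.data$n_new), 0L, .data$n_new),
           fraction_new = ifelse(is.na(.data$n_tumors_new), 0,
                                 .data$n_tumors_new / valid$m)) |>
    select("gene", "n_new", "fraction_new")
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of paired measurements with the identity line:
#' \deqn{\rho_c = \frac{2\,\mathrm{cov}(x, y)}
#'   {\mathrm{var}(x) + \mathrm{var}(y) + (\bar x - \bar y)^2}}
#' using population (n-denominator) moments. Equals 1 only for `y = x`,
#' satisfies `|rho_c| <= |Pearson r|`, and penalises both scale and location
#' shifts.
#'
#' @param x,y Equal-length finite numeric vectors (length >= 2).
#' @return A value in `[-1, 1]`. Two identical constant vectors give 1 by
#'   convention.
#' @export
#' @examples
#' lin_ccc(c(0, 1), c(1, 2))  # 1/3
lin_ccc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    abort("`x` and `y` must have equal length >= 2.",
          class = "raremut_domain_error")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("`x` and `y` must be finite.", class = "raremut_domain_error")
  }
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / n
  vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) return(1)  # both constant with equal means
  2 * cxy / denom
}

#' Train/validate concordance of unseen-variant predictions
#'
#' For each gene in the intersection of the two cohorts' gene universes,
#' compares training-cohort predictions against validation-cohort
#' observations:
#'
#' * `predicted_p_unseen` = `1 - exp(-N_1/(m_train + 1))` from the training
#'   frequency vector, vs `observed_fraction`, the share of validation tumors
#'   with at least one variant of the gene unseen in training;
#' * `predicted_new_count` = the gene's Good-Toulmin \eqn{\Delta(t)} at
#'   `t = m_valid / m_train`, vs `observed_new_count`, the distinct
#'   validation variants absent from training.
#'
#' Gene-level agreement is scored by [lin_ccc()] for both quantities.
#'
#' @param train,valid Filtered `cohort`s with the same key scheme (typically
#'   restricted to the same mutational subgroup).
#' @param genes Gene universe; defaults to genes mutated in both cohorts
#'   (genes absent from either are dropped with a message).
#' @param t Extrapolation factor for the count prediction; defaults to
#'   `m_valid / m_train`.
#' @param method Good-Toulmin series variant, see [good_toulmin()].
#' @return An object of class `richness_validation`: list with `by_gene`
#'   (tibble of the four quantities per gene), `ccc_probability`,
#'   `ccc_counts`, `t`, `m_train`, `m_valid`, `n_genes`. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
validate_richness <- function(train, valid, genes = NULL, t = NULL,
                              method = c("auto", "plain", "euler")) {
  method <- match.arg(method)
  stopifnot(inherits(train, "cohort"), inherits(valid, "cohort"))
  g_train <- unique(train$records$gene)
  g_valid <- unique(valid$records$gene)
  if (is.null(genes)) {
    genes <- sort(intersect(g_train, g_valid))
  } else {
    requested <- unique(genes)
    genes <- sort(intersect(requested, union(g_train, g_valid)))
    dropped <- setdiff(requested, genes)
    if (length(dropped)) {
      inform(sprintf("validate_richness: dropped %d gene(s) absent from both cohorts.",
                     length(dropped)))
    }
  }
  if (length(genes) < 2L) {
    abort("Need at least two genes common to the analysis to score concordance.",
          class = "raremut_domain_error")
  }
  if (is.null(t)) t <- valid$m / train$m
  check_positive(t, "t")

  train_counts <- variant_counts(train) |> filter(.data$gene %in% genes)
  predicted <- purrr::map_dfr(genes, function(g) {
    r_g <- train_counts$r[train_counts$gene == g]
    fv <- frequency_from_counts(r_g, train$m, scope = g)
    tibble(
      gene = g,
      predicted_p_unseen = unseen_probability(n_r(fv, 1L), train$m),
      predicted_new_count = suppressWarnings(
        good_toulmin(fv, t, method = method)$delta)
    )
  })
  observed <- observed_new_variants(train, valid, genes = genes)
  by_gene <- predicted |>
    left_join(observed, by = "gene") |>
    rename(observed_new_count = "n_new", observed_fraction = "fraction_new")

  structure(
    list(by_gene = by_gene,
         ccc_probability = lin_ccc(by_gene$predicted_p_unseen,
                                   by_gene$observed_fraction),
         ccc_counts = lin_ccc(by_gene$predicted_new_count,
                              by_gene$observed_new_count),
         t = t, m_train = train$m, m_valid = valid$m,
         n_genes = length(genes)),
    class = "richness_validation")
}

#' @export
print.richness_validation <- function(x, ...) {
  cat(sprintf(
    "<richness_validation> %d genes, m_train = %d, m_valid = %d, t = %.3f\n",
    x$n_genes, x$m_train, x$m_valid, x$t))
  cat(sprintf("  Lin's CCC: probability %.3f, counts %.3f\n",
              x$ccc_probability, x$ccc_counts))
  invisible(x)
}

#' Subgroup-stratified train/validate concordance
#'
#' Runs [validate_richness()] separately within each mutational subgroup
#' shared by the two cohorts. POLE-dominant tumors are a known failure mode
#' of the product-binomial model (their discovery rate is over-predicted);
#' they are still reported.
#'
#' @inheritParams validate_richness
#' @param assignments_train,assignments_valid Output of [assign_subgroups()]
#'   for the respective cohorts.
#' @param min_samples Subgroups with fewer samples than this in either cohort
#'   are skipped (default 20).
#' @return A tibble with one row per subgroup: `subgroup`, `m_train`,
#'   `m_valid`, `n_genes`, `ccc_probability`, `ccc_counts`.
#' @export
validate_by_subgroup <- function(train, valid, assignments_train,
                                 assignments_valid, genes = NULL,
                                 min_samples = 20) {
  subgroups <- intersect(unique(assignments_train$subgroup),
                         unique(assignments_valid$subgroup))
  subgroups <- setdiff(subgroups, "excluded")
  purrr::map_dfr(sort(subgroups), function(sg) {
    ids_t <- assignments_train$sample_id[assignments_train$subgroup == sg]
    ids_v <- assignments_valid$sample_id[assignments_valid$subgroup == sg]
    if (length(ids_t) < min_samples || length(ids_v) < min_samples) {
      return(tibble(subgroup = sg, m_train = length(ids_t),
                    m_valid = length(ids_v), n_genes = NA_integer_,
                    ccc_probability = NA_real_, ccc_counts = NA_real_))
    }
    fit <- validate_richness(filter_samples(train, ids_t),
                             filter_samples(valid, ids_v), genes = genes)
    tibble(subgroup = sg, m_train = fit$m_train, m_valid = fit$m_valid,
           n_genes = fit$n_genes, ccc_probability = fit$ccc_probability,
           ccc_counts = fit$ccc_counts)
  })
}
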