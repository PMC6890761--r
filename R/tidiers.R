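#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a train/validate concordance fit
#'
#' @param x A `richness_validation` object from [validate_richness()].
#' @param ... Unused.
#' @return The per-gene tibble: `gene`, `predicted_p_unseen`,
#'   `observed_fraction`, `predicted_new_count`, `observed_new_count`.
#' @method tidy richness_validation
#' @export
tidy.richness_validation <- function(x, ...) {
  x$by_gene |>
    select("gene", "predicted_p_unseen", "observed_fraction",
           "predicted_new_count", "observed_new_count")
}

#' One-row summary of a train/validate concordance fit
#'
#' @inheritParams tidy.richness_validation
#' @return A one-row tibble: `ccc_probability`, `ccc_counts`, `n_genes`,
#'   `t`, `m_train`, `m_valid`.
#' @method glance richness_validation
#' @export
glance.richness_validation <- function(x, ...) {
  tibble(ccc_probability = x$ccc_probability, ccc_counts = x$ccc_counts,
         n_genes = x$n_genes, t = x$t, m_train = x$m_train,
         m_valid = x$m_valid)
}

#' Tidy a permutation null for a tissue-specificity NMI
#'
#' @param x An `nmi_null` object from [nmi_null()].
#' @param ... Unused.
#' @return A tibble with one row per permutation: `permutation`, `nmi`.
#' @method tidy nmi_null
#' @export
tidy.nmi_null <- function(x, ...) {
  tibble(permutation = seq_along(x$null), nmi = x$null)
}

#' One-row summary of a permutation null
#'
#' @inheritParams tidy.nmi_null
#' @return A one-row tibble: `gene`, `observed`, `percentile_95`,
#'   `exceeds_null`, `n_permutations`, `normalizer`.
#' @method glance nmi_null
#' @export
glance.nmi_null <- function(x, ...) {
  tibble(gene = x$gene, observed = x$observed,
         percentile_95 = x$percentile_95, exceeds_null = x$exceeds_null,
         n_permutations = x$n_permutations, normalizer = x$normalizer)
}
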