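#' Plot a frequency-of-frequencies vector
#'
#' Log-log scatter of `N_r` against `r` — the canonical view of a long-tailed
#' variant catalog (a straight descending cloud with isolated hotspot points
#' far to the right).
#'
#' @param fv A `freq_vector`.
#' @return A ggplot object.
#' @export
plot_frequency_vector <- function(fv) {
  ggplot2::ggplot(as_tibble(fv), ggplot2::aes(x = .data$r, y = .data$N_r)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "variant frequency r (tumors)",
      y = expression(N[r]),
      title = paste0("Frequency vector: ", attr(fv, "scope") %||% ""),
      subtitle = sprintf("m = %d tumors", fv_m(fv))) +
    ggplot2::theme_minimal()
}

#' @rdname plot_frequency_vector
#' @param object A `freq_vector`.
#' @param ... Unused.
#' @method autoplot freq_vector
#' @export
autoplot.freq_vector <- function(object, ...) plot_frequency_vector(object)

#' Plot predicted versus observed unseen-variant quantities
#'
#' Two-panel scatter of the train/validate comparison: gene-level predicted
#' unseen-variant probability against the observed validation fraction, and
#' predicted against observed new-variant counts, each with the identity
#' line and its Lin concordance correlation coefficient.
#'
#' @param object A `richness_validation` from [validate_richness()].
#' @param ... Unused.
#' @return A ggplot object (faceted).
#' @method autoplot richness_validation
#' @export
autoplot.richness_validation <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble(panel = sprintf("P(new variant), CCC = %.2f",
                           object$ccc_probability),
           predicted = object$by_gene$predicted_p_unseen,
           observed = object$by_gene$observed_fraction),
    tibble(panel = sprintf("new-variant count, CCC = %.2f",
                           object$ccc_counts),
           predicted = object$by_gene$predicted_new_count,
           observed = as.numeric(object$by_gene$observed_new_count)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "observed (validation cohort)",
                  y = "predicted (training cohort)") +
    ggplot2::theme_minimal()
}

#' Plot a permutation null against the observed NMI
#'
#' Histogram of the null NMI sample with the 95th percentile (dotted) and the
#' observed score (solid).
#'
#' @param object An `nmi_null` from [nmi_null()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nmi_null
#' @export
autoplot.nmi_null <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$nmi)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$percentile_95, linetype = 3) +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick") +
    ggplot2::labs(
      x = "NMI", y = "permutations",
      title = sprintf("%s: observed NMI vs random variant-tissue allocation",
                      object$gene)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
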