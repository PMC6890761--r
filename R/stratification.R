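#' Mutational subgroup labels
#'
#' The five dominant single-base-substitution (SBS) signature groups used for
#' cohort stratification. Together with `non_hypermutated` and `excluded`
#' they partition a cohort.
#'
#' @return Character vector of group names.
#' @export
signature_groups <- function() c("APOBEC", "Smoking", "MMR", "UV", "POLE")

#' Default SBS-to-group map
#'
#' COSMIC-convention mapping from SBS signature numbers to the five
#' stratification groups (APOBEC = SBS2/SBS13, Smoking = SBS4,
#' MMR = SBS6/15/20/26, UV = SBS7a-d, POLE = SBS10a/b). Configurable: pass a
#' modified list to [dominant_signature()].
#'
#' @return Named list mapping group name to SBS labels.
#' @export
sbs_group_map <- function() {
  list(
    APOBEC = c("SBS2", "SBS13"),
    Smoking = "SBS4",
    MMR = c("SBS6", "SBS15", "SBS20", "SBS26"),
    UV = c("SBS7a", "SBS7b", "SBS7c", "SBS7d"),
    POLE = c("SBS10a", "SBS10b")
  )
}

#' Map a signature-exposure vector to a dominant group label
#'
#' Helper for cohorts annotated with per-sample SBS exposures rather than
#' pre-assigned labels: sums the exposure within each group of `map` and
#' returns the argmax group, or `"none"` when no mapped signature carries
#' positive exposure.
#'
#' @param exposures Named numeric vector of SBS exposures (names like
#'   `"SBS2"`).
#' @param map SBS-to-group map, see [sbs_group_map()].
#' @return A single group label or `"none"`.
#' @export
dominant_signature <- function(exposures, map = sbs_group_map()) {
  if (is.null(names(exposures))) {
    abort("`exposures` must be a named vector of SBS exposures.",
          class = "raremut_config_error")
  }
  totals <- vapply(map, function(sbs) {
    sum(exposures[names(exposures) %in% sbs], na.rm = TRUE)
  }, numeric(1))
  if (all(totals <= 0)) return("none")
  names(totals)[which.max(totals)]
}

#' Scale a hypermutation threshold across cohorts
#'
#' A mutation-burden threshold calibrated on one assay (e.g. whole exome)
#' is rescaled to another (e.g. a targeted panel) by the ratio of median
#' total mutation burdens, rounded up to an integer:
#' `ceiling(base_threshold * median_burden_target / median_burden_reference)`.
#'
#' @param base_threshold Threshold in the reference cohort (mutations).
#' @param median_burden_target Median total mutation burden in the target
#'   cohort.
#' @param median_burden_reference Median total mutation burden in the
#'   reference cohort.
#' @return Integer threshold for the target cohort.
#' @export
#' @examples
#' scale_hypermutation_threshold(500, 4, 54)  # 38
scale_hypermutation_threshold <- function(base_threshold,
                                          median_burden_target,
                                          median_burden_reference) {
  check_positive(base_threshold, "base_threshold")
  check_positive(median_burden_target, "median_burden_target")
  check_positive(median_burden_reference, "median_burden_reference")
  as.integer(ceiling(base_threshold * median_burden_target /
                       median_burden_reference))
}

#' Assign tumors to mutational subgroups
#'
#' Each tumor receives exactly one label. A dominant SBS signature label in
#' one of the five groups assigns that group regardless of burden; unlabeled
#' tumors with burden strictly below the threshold are `non_hypermutated`;
#' unlabeled tumors at or above the threshold are `excluded` (hypermutated
#' without an explaining signature).
#'
#' @param samples Data frame with columns `sample_id`, `mutation_burden`, and
#'   optionally `signature_label` (`NA`/`"none"` = no dominant signature).
#'   A cohort's `$samples` table works directly.
#' @param threshold Hypermutation burden threshold (strict: burden exactly at
#'   the threshold is hypermutated-side). See
#'   [scale_hypermutation_threshold()] for cross-assay scaling.
#' @param groups Legal signature labels; defaults to [signature_groups()].
#' @return A tibble: `sample_id`, `subgroup`, `burden`, `threshold_used`.
#' @export
assign_subgroups <- function(samples, threshold = 500,
                             groups = signature_groups()) {
  check_positive(threshold, "threshold")
  samples <- as_tibble(samples)
  needed <- c("sample_id", "mutation_burden")
  missing_cols <- setdiff(needed, names(samples))
  if (length(missing_cols)) {
    abort(sprintf("`samples` is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "raremut_config_error")
  }
  label <- if ("signature_label" %in% names(samples)) {
    samples$signature_label
  } else {
    rep(NA_character_, nrow(samples))
  }
  label[is.na(label)] <- "none"
  bad <- setdiff(unique(label), c(groups, "none"))
  if (length(bad)) {
    abort(sprintf(
      "Unrecognized signature label(s): %s. Legal labels: %s, or none/NA.",
      paste(bad, collapse = ", "), paste(groups, collapse = ", ")),
      class = "raremut_config_error")
  }
  if (any(is.na(samples$mutation_burden))) {
    abort("Every sample needs a mutation_burden to be stratified.",
          class = "raremut_domain_error")
  }
  subgroup <- ifelse(label %in% groups, label,
                     ifelse(samples$mutation_burden < threshold,
                            "non_hypermutated", "excluded"))
  tibble(sample_id = samples$sample_id, subgroup = subgroup,
         burden = samples$mutation_burden,
         threshold_used = as.integer(threshold))
}
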