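#' Default run configuration
#'
#' The resolved settings shared by the command-line interface and available
#' for scripted use: MAF column mapping, the non-synonymous classification
#' set, smoothing method, subgroup thresholds and SBS-to-group map, and
#' resampling sizes.
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(
    columns = maf_columns(),
    nonsyn_classes = nonsyn_classes(),
    variant_key = "protein",
    smoothing = "sgt",
    hypermutation_threshold = 500,
    signature_groups = signature_groups(),
    sbs_group_map = sbs_group_map(),
    nmi_normalizer = "tissue",
    n_permutations = 1000,
    bootstrap_B = 200
  )
}

#' Resolve a run configuration from a YAML file
#'
#' Reads a YAML file and merges it over [default_config()]: keys present in
#' the file override the defaults, everything else keeps its default.
#' Unknown top-level keys are a configuration error.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A named list as in [default_config()].
#' @export
resolve_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "raremut_io_error")
  }
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s. Legal keys: %s.",
                  paste(unknown, collapse = ", "),
                  paste(names(cfg), collapse = ", ")),
          class = "raremut_config_error")
  }
  for (key in names(user)) {
    if (key %in% c("columns", "sbs_group_map") && is.list(user[[key]])) {
      cfg[[key]][names(user[[key]])] <- user[[key]]
    } else {
      cfg[[key]] <- user[[key]]
    }
  }
  cfg
}

#' Write the resolved configuration next to a run's outputs
#'
#' Every CLI run snapshots its fully resolved configuration so outputs are
#' self-describing.
#'
#' @param config A configuration list.
#' @param dir Output directory.
#' @return Invisibly, the snapshot path.
#' @export
write_config_snapshot <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "resolved-config.yaml")
  yaml::write_yaml(config, path)
  invisible(path)
}
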