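#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   distinct left_join inner_join anti_join semi_join n n_distinct count
#'   bind_rows rename all_of pull first
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rbinom runif coef lm pbinom quantile sd setNames
NULL

# run `code` under a fixed seed, restoring the caller's RNG state afterwards
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.", class = "raremut_domain_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number, not %s.",
                  name, paste(format(x), collapse = ", ")),
          class = "raremut_domain_error")
  }
  invisible(x)
}

check_non_negative <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be non-negative and finite.", name),
          class = "raremut_domain_error")
  }
  invisible(x)
}
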