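#' Variant probability laws for synthetic genes
#'
#' Generators for per-variant, per-tumor occurrence probabilities. Each
#' returns a named numeric vector of probabilities, one per variant in the
#' gene's pool. Three laws cover the regimes seen in real catalogs:
#'
#' * `probs_zipf()` — power-law pool `p_v = p_max * v^{-s}`; larger `s` means
#'   a steeper tail and a higher realized singleton fraction.
#' * `probs_log_series()` — the continuous analogue of the Fisher log-series
#'   abundance model: probabilities are drawn from the density
#'   `f(p) proportional to exp(-rate * p) / p` on `[p_min, p_max]` (rejection
#'   sampling from a log-uniform proposal). Under per-tumor binomial sampling
#'   this produces the `N_r ~ x^r / r` frequency-of-frequency decay
#'   characteristic of somatic variant catalogs.
#' * `probs_hotspot()` — a few explicit hotspot probabilities on top of a
#'   power-law tail; reproduces the hotspot-dominated profile of oncogenes
#'   (contrast: a tumor suppressor is nearly all tail).
#'
#' `probs_log_series()` consumes random numbers; call it under a seed (or let
#' [simulate_cohort()] regenerate pools under its own seed).
#'
#' @param n_variants Pool size (number of distinct possible variants).
#' @param s Zipf exponent (> 0).
#' @param p_max Probability of the most frequent tail variant.
#' @param rate Decay rate of the log-series density (larger = rarer variants).
#' @param p_min Lower truncation of the log-series density.
#' @param hotspots Named or unnamed numeric vector of hotspot probabilities.
#' @return Numeric vector of per-tumor occurrence probabilities.
#' @name variant_laws
NULL

#' @rdname variant_laws
#' @export
probs_zipf <- function(n_variants, s = 1.2, p_max = 0.01) {
  check_positive(n_variants, "n_variants")
  check_positive(s, "s")
  check_positive(p_max, "p_max")
  p_max * seq_len(n_variants)^(-s)
}

#' @rdname variant_laws
#' @export
probs_log_series <- function(n_variants, rate = 2000, p_min = 1e-5,
                             p_max = 0.05) {
  check_positive(n_variants, "n_variants")
  check_positive(rate, "rate")
  stopifnot(p_min > 0, p_max > p_min, p_max <= 1)
  n_variants <- as.integer(n_variants)
  out <- numeric(0)
  log_ratio <- log(p_max / p_min)
  while (length(out) < n_variants) {
    n_draw <- max(100L, 2L * (n_variants - length(out)))
    prop <- p_min * exp(runif(n_draw) * log_ratio)   # log-uniform ~ 1/p
    keep <- runif(n_draw) < exp(-rate * (prop - p_min))
    out <- c(out, prop[keep])
  }
  out[seq_len(n_variants)]
}

#' @rdname variant_laws
#' @export
probs_hotspot <- function(hotspots, n_variants = 200, s = 1.2,
                          p_max = 0.002) {
  check_non_negative(hotspots, "hotspots")
  c(hotspots, probs_zipf(n_variants, s = s, p_max = p_max))
}

#' Define a synthetic gene
#'
#' Couples a variant probability pool with optional per-tissue rate
#' multipliers. Multiplier 1 in every tissue gives a lineage-independent
#' gene; e.g. `tissue_multipliers = c(PAAD = 10)` makes every variant of the
#' gene 10 times as likely in pancreatic tumors (other tissues stay at 1).
#'
#' @param gene HUGO-style symbol for the synthetic gene.
#' @param probs Per-variant per-tumor probabilities (see [variant_laws]).
#' @param tissue_multipliers Named positive numeric vector; tissues not named
#'   default to 1.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene, probs, tissue_multipliers = NULL) {
  if (any(probs < 0 | probs > 1)) {
    abort("Variant probabilities must lie in [0, 1].",
          class = "raremut_domain_error")
  }
  if (!is.null(tissue_multipliers)) {
    check_positive(min(tissue_multipliers), "tissue_multipliers")
    if (is.null(names(tissue_multipliers))) {
      abort("`tissue_multipliers` must be named by tissue.",
            class = "raremut_config_error")
    }
  }
  variant_keys <- names(probs) %||% character(length(probs))
  blank <- is.na(variant_keys) | variant_keys == ""
  variant_keys[blank] <- sprintf("V%04d", which(blank))
  if (anyDuplicated(variant_keys)) {
    abort("Variant names within a gene must be unique.",
          class = "raremut_config_error")
  }
  variant_keys <- paste(gene, variant_keys, sep = ":")
  structure(
    list(gene = gene, probs = setNames(as.numeric(probs), variant_keys),
         tissue_multipliers = tissue_multipliers),
    class = "gene_model")
}

# variants x tissues matrix of raw (uncapped) tissue-adjusted probabilities;
# callers cap at 1 and are responsible for flagging how much mass was capped
model_tissue_probs <- function(model, tissues) {
  mult <- setNames(rep(1, length(tissues)), tissues)
  tm <- model$tissue_multipliers
  if (!is.null(tm)) mult[names(tm)[names(tm) %in% tissues]] <- tm[names(tm) %in% tissues]
  outer(model$probs, mult, function(p, k) p * k)
}

#' Simulate a MAF-like tumor cohort with known truth
#'
#' Implements the product-binomial model the estimators assume: each tumor
#' draws a tissue from `tissue_mix` (and, with probability
#' `hyper_fraction`, a hypermutation multiplier), then every variant of every
#' gene occurs independently with its tissue- and multiplier-adjusted
#' probability (capped at 1). Tissue assignment happens before variant draws,
#' so per-tissue sample counts are exact. The per-variant generative
#' probabilities are retained as ground truth for the oracle functions
#' [true_unseen_probability()] and [true_new_variant_count()].
#'
#' @param models List of [gene_model()] objects.
#' @param m Number of tumors.
#' @param tissue_mix Named vector of tissue proportions (normalised
#'   internally); default a single pan-cancer tissue.
#' @param hyper_fraction Fraction of tumors that are hypermutated.
#' @param hyper_multiplier Rate multiplier applied to every variant in a
#'   hypermutated tumor.
#' @param seed Mandatory seed; the same seed reproduces the cohort exactly
#'   (the caller's RNG state is restored).
#' @return An object of class `simulated_cohort`: list with `cohort` (a
#'   [as_cohort()] cohort), `truth` (tibble of per-variant probabilities per
#'   tissue), `tissue_mix`, `hyper_fraction`, `hyper_multiplier`, `seed`.
#' @export
simulate_cohort <- function(models, m, tissue_mix = c(PAN = 1),
                            hyper_fraction = 0, hyper_multiplier = 1,
                            seed) {
  if (inherits(models, "gene_model")) models <- list(models)
  stopifnot(all(vapply(models, inherits, logical(1), "gene_model")))
  check_positive(m, "m")
  m <- as.integer(m)
  if (is.null(names(tissue_mix))) {
    abort("`tissue_mix` must be named by tissue.",
          class = "raremut_config_error")
  }
  stopifnot(hyper_fraction >= 0, hyper_fraction <= 1, hyper_multiplier >= 1)
  if (missing(seed)) {
    abort("`seed` is mandatory for reproducible simulation.",
          class = "raremut_config_error")
  }
  tissues <- names(tissue_mix)
  mix <- tissue_mix / sum(tissue_mix)

  sim <- with_preserved_seed(seed, {
    sample_ids <- sprintf("S%06d", seq_len(m))
    tissue_of <- sample(tissues, m, replace = TRUE, prob = mix)
    hyper <- runif(m) < hyper_fraction

    # strata of tumors sharing the same probability vector
    strata <- split(seq_len(m), paste(tissue_of, hyper))
    n_capped <- 0L
    n_pairs <- 0
    rec <- vector("list", length(models) * length(strata))
    k <- 0L
    for (mod in models) {
      p_tis <- model_tissue_probs(mod, tissues)
      for (st in strata) {
        tis <- tissue_of[st[1]]
        hm <- if (hyper[st[1]]) hyper_multiplier else 1
        p_s <- p_tis[, tis] * hm
        n_capped <- n_capped + sum(p_s > 1) * length(st)
        n_pairs <- n_pairs + length(p_s) * length(st)
        p_s <- pmin(1, p_s)
        r_v <- rbinom(length(p_s), length(st), p_s)
        nz <- which(r_v > 0L)
        if (!length(nz)) next
        carriers <- lapply(nz, function(v) st[sample.int(length(st), r_v[v])])
        k <- k + 1L
        rec[[k]] <- tibble(
          sample_idx = unlist(carriers),
          gene = mod$gene,
          variant_key = rep(names(mod$probs)[nz], r_v[nz])
        )
      }
    }
    if (n_capped > 0 && n_capped > 0.01 * n_pairs) {
      warn("More than 1% of variant-tumor probabilities were capped at 1; the generative model is likely misspecified.")
    }
    records <- if (k > 0L) {
      bind_rows(rec[seq_len(k)])
    } else {
      tibble(sample_idx = integer(), gene = character(),
             variant_key = character())
    }
    records <- tibble(
      sample_id = sample_ids[records$sample_idx],
      tumor_type = tissue_of[records$sample_idx],
      gene = records$gene,
      variant_key = records$variant_key,
      variant_class = rep("Missense_Mutation", nrow(records)),
      variant_type = rep("SNP", nrow(records))
    ) |>
      arrange(.data$sample_id, .data$gene, .data$variant_key)
    burden <- tabulate(match(records$sample_id, sample_ids), nbins = m)
    samples <- tibble(
      sample_id = sample_ids, tumor_type = tissue_of,
      mutation_burden = as.integer(burden),
      signature_label = NA_character_, hypermutated = hyper)
    list(records = records, samples = samples)
  })

  truth <- purrr::map_dfr(models, function(mod) {
    p_tis <- model_tissue_probs(mod, tissues)
    out <- tibble(gene = mod$gene, variant_key = names(mod$probs),
                  p_base = unname(mod$probs))
    for (tis in tissues) out[[paste0("p_", tis)]] <- pmin(1, unname(p_tis[, tis]))
    out
  })

  structure(
    list(cohort = as_cohort(sim$records, samples = sim$samples),
         truth = truth, tissue_mix = mix, hyper_fraction = hyper_fraction,
         hyper_multiplier = hyper_multiplier, seed = seed),
    class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("<simulated_cohort> seed %s, %d genes, %d variants in pool\n",
              format(x$seed), n_distinct(x$truth$gene), nrow(x$truth)))
  print(x$cohort)
  invisible(x)
}

# effective per-tumor probability of variant rows `tr` (truth tibble) for a
# new tumor: of a given tissue (mixing over hypermutation), or marginal over
# the tissue mix
effective_probs <- function(sim, tr, tissue = NULL) {
  hf <- sim$hyper_fraction
  hm <- sim$hyper_multiplier
  one_tissue <- function(tis) {
    p <- tr[[paste0("p_", tis)]]
    (1 - hf) * p + hf * pmin(1, p * hm)
  }
  if (!is.null(tissue)) {
    if (!tissue %in% names(sim$tissue_mix)) {
      abort(sprintf("Unknown tissue: %s", tissue),
            class = "raremut_domain_error")
    }
    return(one_tissue(tissue))
  }
  out <- numeric(nrow(tr))
  for (tis in names(sim$tissue_mix)) {
    out <- out + sim$tissue_mix[[tis]] * one_tissue(tis)
  }
  out
}

unseen_truth_rows <- function(sim, gene = NULL, training = NULL) {
  training <- training %||% sim$cohort
  tr <- sim$truth
  if (!is.null(gene)) tr <- filter(tr, .data$gene %in% !!gene)
  seen <- unique(training$records$variant_key)
  filter(tr, !.data$variant_key %in% seen)
}

#' Exact unseen-variant probability of a simulated gene
#'
#' Ground-truth oracle for [unseen_probability()]: given the variants
#' actually observed in the training cohort, the exact probability that one
#' new tumor carries at least one of the still-unseen variants is
#' `1 - prod(1 - p_v)` over the unseen pool, with `p_v` the generative
#' per-tumor probability (tissue-specific, or marginal over the tissue mix).
#'
#' @param sim A `simulated_cohort`.
#' @param gene Optional gene scope (`NULL` = whole pool).
#' @param tissue Optional tissue for the new tumor; `NULL` marginalises over
#'   the simulation's tissue mix.
#' @param training Cohort defining what has been seen; defaults to the
#'   simulated cohort itself.
#' @return Exact probability in `[0, 1]`.
#' @export
true_unseen_probability <- function(sim, gene = NULL, tissue = NULL,
                                    training = NULL) {
  stopifnot(inherits(sim, "simulated_cohort"))
  tr <- unseen_truth_rows(sim, gene = gene, training = training)
  if (!nrow(tr)) return(0)
  1 - prod(1 - effective_probs(sim, tr, tissue = tissue))
}

#' Exact expected number of new variants in a cohort extension
#'
#' Ground-truth oracle for [good_toulmin()]: the expected number of
#' still-unseen variants that would appear in `t * m` additional tumors,
#' \eqn{\sum_{v\ \mathrm{unseen}} (1 - (1 - \bar p_v)^{t m})}, where
#' \eqn{\bar p_v} is the per-tumor probability marginalised over the tissue
#' mix. Exact arithmetic, no simulation.
#'
#' @inheritParams true_unseen_probability
#' @param t Extrapolation factor (future tumors = `t * m`).
#' @return Expected count (>= 0).
#' @export
true_new_variant_count <- function(sim, t, gene = NULL, training = NULL) {
  stopifnot(inherits(sim, "simulated_cohort"))
  check_positive(t, "t")
  training <- training %||% sim$cohort
  tr <- unseen_truth_rows(sim, gene = gene, training = training)
  if (!nrow(tr)) return(0)
  p_bar <- effective_probs(sim, tr, tissue = NULL)
  n_future <- t * training$m
  sum(1 - (1 - p_bar)^n_future)
}

#' Write a simulated cohort to disk
#'
#' Emits the MAF (TSV), the per-sample annotation table (TSV), and the
#' ground-truth pool (JSON) into a directory.
#'
#' @param sim A `simulated_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulated_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  maf <- file.path(dir, "cohort.maf")
  ann <- file.path(dir, "annotations.tsv")
  truth <- file.path(dir, "truth.json")
  write_maf(sim$cohort, maf, annotations_path = ann)
  jsonlite::write_json(
    list(seed = sim$seed, tissue_mix = as.list(sim$tissue_mix),
         hyper_fraction = sim$hyper_fraction,
         hyper_multiplier = sim$hyper_multiplier, truth = sim$truth),
    truth, digits = NA, auto_unbox = TRUE)
  invisible(c(maf = maf, annotations = ann, truth = truth))
}
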