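#' Per-tumor mutation status for a set of genes
#'
#' A tumor is "mutated in gene g" when it carries any retained
#' (non-synonymous SNV) variant of g — co-mutation analysis is gene-level,
#' not variant-level.
#'
#' @param cohort A filtered `cohort`.
#' @param genes Character vector of HUGO symbols (the pair universe, e.g. a
#'   cancer-gene panel).
#' @return A logical matrix, samples (rows, named) by genes (columns, named);
#'   samples with no mutations in any panel gene are included as all-FALSE
#'   rows.
#' @export
gene_status <- function(cohort, genes) {
  stopifnot(inherits(cohort, "cohort"))
  genes <- unique(genes)
  m <- cohort$m
  status <- matrix(FALSE, nrow = m, ncol = length(genes),
                   dimnames = list(cohort$samples$sample_id, genes))
  rec <- filter(cohort$records, .data$gene %in% genes)
  if (nrow(rec)) {
    i <- match(rec$sample_id, cohort$samples$sample_id)
    j <- match(rec$gene, genes)
    status[cbind(i, j)] <- TRUE
  }
  status
}

#' Count gene-pair events in a cohort
#'
#' For an unordered gene pair, counts tumors with a co-mutation (both genes
#' mutated) or a mutually exclusive mutation (exactly one of the two
#' mutated). In any single tumor the two events are disjoint; together with
#' "neither" they are exhaustive. Counts are of tumors, not records, and the
#' pair is symmetric in its genes.
#'
#' @param cohort A filtered `cohort` — typically already restricted to one
#'   subgroup (e.g. the non-hypermutated tumors) via [filter_samples()].
#' @param gene_a,gene_b Distinct HUGO symbols.
#' @param event `"co_mutation"` or `"mutual_exclusive"`.
#' @return A tibble with one row per tissue: `tumor_type`, `m` (tissue sample
#'   count), `n` (tumors with the event); the cohort-wide count is `sum(n)`
#'   and is attached as attribute `total`.
#' @export
pair_event_counts <- function(cohort, gene_a, gene_b,
                              event = c("co_mutation", "mutual_exclusive")) {
  event <- match.arg(event)
  if (identical(gene_a, gene_b)) {
    abort("A pair needs two distinct genes.", class = "raremut_domain_error")
  }
  status <- gene_status(cohort, c(gene_a, gene_b))
  hit <- if (event == "co_mutation") {
    status[, 1L] & status[, 2L]
  } else {
    xor(status[, 1L], status[, 2L])
  }
  out <- cohort$samples |>
    mutate(hit = hit[match(.data$sample_id, rownames(status))]) |>
    group_by(.data$tumor_type) |>
    summarise(m = n(), n = sum(.data$hit), .groups = "drop")
  structure(out, total = sum(out$n), event = event)
}

#' Event counts for every pair in a gene panel
#'
#' Tumor counts of the chosen event for all unordered pairs within `genes`
#' (canonical order `gene_a < gene_b`), including pairs never observed with
#' the event (`r = 0`). These per-pair counts are the items from which the
#' pair-scope frequency vector is built.
#'
#' @inheritParams pair_event_counts
#' @param genes Panel of HUGO symbols defining the pair universe. A
#'   genome-wide universe is allowed but the frequency classes become sparse;
#'   a warning is issued above 200 genes.
#' @return A tibble: `gene_a`, `gene_b`, `r`.
#' @export
pair_counts <- function(cohort, genes,
                        event = c("co_mutation", "mutual_exclusive")) {
  event <- match.arg(event)
  genes <- sort(unique(genes))
  if (length(genes) < 2L) {
    abort("The pair universe needs at least two genes.",
          class = "raremut_domain_error")
  }
  if (length(genes) > 200L) {
    warn("Large pair universe: frequency classes may be sparsely populated.")
  }
  status <- gene_status(cohort, genes)
  mode(status) <- "numeric"
  co <- crossprod(status)               # co-mutation counts for all pairs
  n_g <- diag(co)
  ut <- upper.tri(co)
  idx <- which(ut, arr.ind = TRUE)
  r <- if (event == "co_mutation") {
    co[ut]
  } else {
    # |A xor B| = n_A + n_B - 2 |A and B|
    n_g[idx[, 1L]] + n_g[idx[, 2L]] - 2 * co[ut]
  }
  tibble(gene_a = genes[idx[, 1L]], gene_b = genes[idx[, 2L]],
         r = as.integer(r)) |>
    arrange(.data$gene_a, .data$gene_b)
}

#' Frequency vector over a gene-pair universe
#'
#' `N_r` = number of pairs whose event occurs in exactly `r` tumors; pairs
#' with `r = 0` form the unseen-pair mass and are excluded from the vector.
#'
#' @inheritParams pair_counts
#' @return A `freq_vector` with scope `"pair:<event>"`.
#' @export
pair_frequency <- function(cohort, genes,
                           event = c("co_mutation", "mutual_exclusive")) {
  event <- match.arg(event)
  pc <- pair_counts(cohort, genes, event = event)
  frequency_from_counts(pc$r, cohort$m, scope = paste0("pair:", event))
}

#' Good-Turing probabilities for gene-pair events
#'
#' Applies the Good-Turing estimator to the pair-scope frequency vector: a
#' pair whose event was observed in `r` tumors receives
#' `q = (r+1)/(m+1) * S(N_{r+1})/S(N_r)`, pooling frequency classes across
#' the pair universe. Pairs never observed with the event are reported as
#' unseen (`q = NA`) rather than given a probability.
#'
#' @inheritParams pair_counts
#' @param smoothing Passed to [gt_probability()].
#' @return A tibble: `gene_a`, `gene_b`, `event`, `r`, `q`, `unseen`.
#' @export
pair_gt_probabilities <- function(cohort, genes,
                                  event = c("co_mutation", "mutual_exclusive"),
                                  smoothing = c("sgt", "none")) {
  event <- match.arg(event)
  smoothing <- match.arg(smoothing)
  pc <- pair_counts(cohort, genes, event = event)
  fv <- frequency_from_counts(pc$r, cohort$m, scope = paste0("pair:", event))
  if (nrow(fv)) {
    q_tbl <- suppressWarnings(gt_probability(fv, smoothing = smoothing))
    pc <- left_join(pc, select(q_tbl, "r", "q"), by = "r")
  } else {
    pc$q <- NA_real_
  }
  pc |>
    mutate(event = event, unseen = .data$r == 0L,
           q = ifelse(.data$unseen, NA_real_, .data$q)) |>
    select("gene_a", "gene_b", "event", "r", "q", "unseen")
}

#' Permutation null for a gene-pair tissue-specificity NMI
#'
#' Randomly reallocates tissue labels across tumors (fixing each tissue's
#' sample count), recomputes the pair's per-tissue event frequencies and
#' their (index-)NMI each time, and returns the null sample with its 95th
#' percentile.
#'
#' @inheritParams pair_tissue_nmi
#' @param n_permutations Number of permutations.
#' @param seed Seed (caller's RNG state is restored).
#' @return An `nmi_null` object (see [nmi_null()]) whose `gene` field names
#'   the pair and event.
#' @export
pair_nmi_null <- function(cohort, gene_a, gene_b,
                          event = c("co_mutation", "mutual_exclusive"),
                          n_permutations = 1000, seed = NULL, index = NULL,
                          normalizer = c("tissue", "event", "min", "sqrt")) {
  event <- match.arg(event)
  normalizer <- match.arg(normalizer)
  if (!is.numeric(n_permutations) || n_permutations < 2) {
    abort("`n_permutations` must be at least 2 (1000 recommended).",
          class = "raremut_domain_error")
  }
  n_permutations <- as.integer(n_permutations)
  if (identical(gene_a, gene_b)) {
    abort("A pair needs two distinct genes.", class = "raremut_domain_error")
  }
  tissues <- sort(unique(cohort$samples$tumor_type))
  if (length(tissues) < 2L) {
    abort("At least two tissues are required for a permutation null.",
          class = "raremut_domain_error")
  }
  status <- gene_status(cohort, c(gene_a, gene_b))
  hit <- if (event == "co_mutation") {
    status[, 1L] & status[, 2L]
  } else {
    xor(status[, 1L], status[, 2L])
  }
  tis_idx <- match(cohort$samples$tumor_type, tissues)
  m_c <- tabulate(tis_idx, nbins = length(tissues))
  w <- setNames(m_c / sum(m_c), tissues)
  nmi_for_labels <- function(lab) {
    n_hit <- vapply(seq_along(tissues),
                    function(c) sum(hit[lab == c]), numeric(1))
    p <- setNames(n_hit / m_c, tissues)
    if (is.null(index)) nmi(p, w, normalizer = normalizer)
    else index_tissue_nmi(p, w, index, normalizer = normalizer)
  }
  observed <- nmi_for_labels(tis_idx)
  null <- with_preserved_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      nmi_for_labels(tis_idx[sample.int(length(tis_idx))])
    }, numeric(1))
  })
  p95 <- unname(quantile(null, 0.95, type = 7))
  structure(
    list(null = null, percentile_95 = p95, observed = observed,
         exceeds_null = observed > p95, n_permutations = n_permutations,
         seed = seed,
         gene = sprintf("%s-%s (%s)", min(gene_a, gene_b),
                        max(gene_a, gene_b), event),
         normalizer = normalizer),
    class = "nmi_null")
}

#' Index-tissue NMI for a gene-pair event
#'
#' How much a pair's co-mutation (or exclusivity) is elevated in one cancer
#' type compared with the average of all the others. Per-tissue event
#' probabilities are the empirical per-tissue tumor fractions; the contrast
#' is the binarized index-versus-rest NMI.
#'
#' @inheritParams pair_event_counts
#' @param index Index tissue (`tumor_type` value). When `NULL`, the NMI over
#'   the full (non-binarized) tissue partition is returned.
#' @param normalizer Passed to [nmi()].
#' @return A one-row tibble: `gene_a`, `gene_b`, `event`, `index`, `nmi`,
#'   `normalizer`.
#' @export
pair_tissue_nmi <- function(cohort, gene_a, gene_b,
                            event = c("co_mutation", "mutual_exclusive"),
                            index = NULL,
                            normalizer = c("tissue", "event", "min", "sqrt")) {
  event <- match.arg(event)
  normalizer <- match.arg(normalizer)
  counts <- pair_event_counts(cohort, gene_a, gene_b, event = event)
  p <- setNames(counts$n / counts$m, counts$tumor_type)
  w <- setNames(counts$m / sum(counts$m), counts$tumor_type)
  val <- if (is.null(index)) {
    nmi(p, w, normalizer = normalizer)
  } else {
    index_tissue_nmi(p, w, index, normalizer = normalizer)
  }
  tibble(gene_a = min(gene_a, gene_b), gene_b = max(gene_a, gene_b),
         event = event, index = index %||% NA_character_, nmi = val,
         normalizer = normalizer)
}
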