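# Fixture builders shared across test files. Everything is generated in code;
# no data files are stored.

`%||%` <- function(x, y) if (is.null(x)) y else x

# minimal cohort from a list of per-sample variant keys; samples with no
# entry in `variants` can be added through `extra_samples`
toy_cohort <- function(variants, tumor_types = NULL, extra_samples = NULL) {
  rec <- purrr::imap_dfr(variants, function(keys, sid) {
    if (!length(keys)) return(NULL)
    tibble::tibble(
      sample_id = sid,
      gene = sub(":.*$", "", keys),
      variant_key = keys,
      variant_class = "Missense_Mutation",
      variant_type = "SNP")
  })
  ids <- c(names(variants), extra_samples)
  tt <- tumor_types %||% stats::setNames(rep("PAN", length(ids)), ids)
  samples <- tibble::tibble(
    sample_id = ids,
    tumor_type = unname(tt[ids]),
    mutation_burden = as.integer(table(factor(rec$sample_id, levels = ids))))
  as_cohort(rec, samples = samples)
}

# cohort reproducing the KRAS frequency profile: 24 singletons, 3 doubletons,
# and hotspots at r = 142, 120, 44, in a cohort of m tumors
kras_fixture <- function(m = 6696) {
  r_per_variant <- c(rep(1L, 24), rep(2L, 3), 142L, 120L, 44L)
  keys <- c(sprintf("KRAS:S%02d", 1:24), sprintf("KRAS:D%02d", 1:3),
            "KRAS:G12D", "KRAS:G12V", "KRAS:G12C")
  # assign carriers so that no tumor exceeds its own variant once
  rec <- purrr::map2_dfr(keys, r_per_variant, function(k, r) {
    tibble::tibble(sample_id = sprintf("T%05d", seq_len(r)),
                   gene = "KRAS", variant_key = k,
                   variant_class = "Missense_Mutation", variant_type = "SNP")
  })
  samples <- tibble::tibble(sample_id = sprintf("T%05d", seq_len(m)),
                            tumor_type = "PAN")
  as_cohort(rec, samples = samples)
}

# write a MAF-format TSV from a records-like data frame
write_toy_maf <- function(rows, path) {
  maf <- tibble::tibble(
    Tumor_Sample_Barcode = rows$sample_id,
    Hugo_Symbol = rows$gene,
    Variant_Classification = rows$variant_class,
    Variant_Type = rows$variant_type,
    HGVSp_Short = rows$protein_change)
  readr::write_tsv(maf, path)
  path
}

# panel of lineage-independent log-series genes used by several calibration
# tests; pools are realized once under `seed` so truth is shared
log_series_panel <- function(n_genes, n_variants = 120, rate = 1500,
                             seed = 101, multipliers = NULL) {
  withr::with_seed(seed, {
    lapply(seq_len(n_genes), function(i) {
      mult <- if (is.null(multipliers)) NULL else multipliers[[i]]
      gene_model(sprintf("G%03d", i),
                 probs_log_series(n_variants, rate = rate),
                 tissue_multipliers = mult)
    })
  })
}
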