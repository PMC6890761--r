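#' Default MAF column mapping
#'
#' Maps the logical fields used throughout the package to the column names of
#' a standard MAF (Mutation Annotation Format) table. Override any entry to
#' read non-standard dialects.
#'
#' @param sample,gene,variant_class,variant_type,protein_change,tumor_type
#'   Column names in the input table for, respectively, the tumor sample
#'   barcode, HUGO gene symbol, variant classification, variant type
#'   (SNP/INS/DEL), short protein change (HGVSp), and tumor/tissue type.
#'   `tumor_type` is optional in a MAF; it is usually supplied through the
#'   per-sample annotation table instead.
#' @param chromosome,position,ref_allele,alt_allele Optional genomic
#'   coordinate columns, required only when `variant_key = "genomic"`.
#'
#' @return A named list of column names.
#' @export
#' @examples
#' maf_columns(sample = "patient_id")
maf_columns <- function(sample = "Tumor_Sample_Barcode",
                        gene = "Hugo_Symbol",
                        variant_class = "Variant_Classification",
                        variant_type = "Variant_Type",
                        protein_change = "HGVSp_Short",
                        tumor_type = "tumor_type",
                        chromosome = "Chromosome",
                        position = "Start_Position",
                        ref_allele = "Reference_Allele",
                        alt_allele = "Tumor_Seq_Allele2") {
  list(sample = sample, gene = gene, variant_class = variant_class,
       variant_type = variant_type, protein_change = protein_change,
       tumor_type = tumor_type, chromosome = chromosome, position = position,
       ref_allele = ref_allele, alt_allele = alt_allele)
}

#' Default non-synonymous variant classification set
#'
#' The variant classifications retained by [filter_nonsynonymous()]. Protein
#' truncating and missense classes are kept; silent and non-coding classes are
#' dropped. Splice_Site is retained only for single-nucleotide substitutions
#' (the SNP variant-type filter enforces this).
#'
#' @return Character vector of MAF `Variant_Classification` values.
#' @export
nonsyn_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Translation_Start_Site", "Splice_Site")
}

new_cohort <- function(records, samples, key_scheme) {
  structure(
    list(records = records, samples = samples,
         m = nrow(samples), key_scheme = key_scheme),
    class = "cohort"
  )
}

#' Build a cohort from record and sample tables
#'
#' A cohort couples a table of sample-variant incidences with a sample roster.
#' The roster defines the cohort size `m`; samples with zero surviving
#' variants stay in `m` (the denominator of every probability in the package
#' is "tumors profiled", not "tumors mutated").
#'
#' @param records A data frame with columns `sample_id`, `gene`,
#'   `variant_key`, and optionally `tumor_type`, `variant_class`,
#'   `variant_type`. Duplicate `(sample_id, variant_key)` rows are collapsed
#'   to a single incidence.
#' @param samples Optional data frame with columns `sample_id` and optionally
#'   `tumor_type`, `mutation_burden`, `signature_label`. When `NULL`, the
#'   roster is derived from the distinct samples in `records` with
#'   `mutation_burden` set to the per-sample record count.
#' @param key_scheme How `variant_key` was formed: `"protein"`
#'   (gene:protein-change) or `"genomic"` (chrom:pos:ref>alt).
#'
#' @return An object of class `cohort` with elements `records` (tibble),
#'   `samples` (tibble), `m` (integer) and `key_scheme`.
#' @export
as_cohort <- function(records, samples = NULL, key_scheme = "protein") {
  records <- as_tibble(records)
  required <- c("sample_id", "gene", "variant_key")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    abort(sprintf("`records` is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "raremut_config_error")
  }
  for (col in c("tumor_type", "variant_class", "variant_type")) {
    if (!col %in% names(records)) records[[col]] <- NA_character_
  }
  records <- distinct(records, .data$sample_id, .data$variant_key,
                      .keep_all = TRUE)
  if (is.null(samples)) {
    samples <- records |>
      count(.data$sample_id, .data$tumor_type, name = "mutation_burden") |>
      mutate(signature_label = NA_character_)
  } else {
    samples <- as_tibble(samples)
    if (!"sample_id" %in% names(samples)) {
      abort("`samples` must have a `sample_id` column.",
            class = "raremut_config_error")
    }
    if (!"tumor_type" %in% names(samples)) samples$tumor_type <- NA_character_
    if (!"mutation_burden" %in% names(samples)) {
      burden <- count(records, .data$sample_id, name = "mutation_burden")
      samples <- left_join(samples, burden, by = "sample_id") |>
        mutate(mutation_burden = ifelse(is.na(.data$mutation_burden), 0L,
                                        .data$mutation_burden))
    }
    if (!"signature_label" %in% names(samples)) {
      samples$signature_label <- NA_character_
    }
    samples <- distinct(samples, .data$sample_id, .keep_all = TRUE)
    orphan <- setdiff(unique(records$sample_id), samples$sample_id)
    if (length(orphan)) {
      abort(sprintf(
        "%d record sample_id(s) are absent from the sample roster (e.g. %s).",
        length(orphan), orphan[1]),
        class = "raremut_config_error")
    }
    # records inherit the roster's tumor_type so both tables agree
    records <- records |>
      select(-"tumor_type") |>
      left_join(select(samples, "sample_id", "tumor_type"), by = "sample_id")
  }
  new_cohort(records, samples, key_scheme)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d samples (m), %d incidences, %d distinct variants, key = %s\n",
              x$m, nrow(x$records), n_distinct(x$records$variant_key),
              x$key_scheme))
  invisible(x)
}

#' Read a MAF-style somatic mutation table
#'
#' Reads a tab-separated MAF, keeps one incidence per (sample, variant) pair,
#' and returns a [as_cohort()] cohort. Rows missing the gene or sample field
#' are dropped and reported. The variant key is formed at protein level
#' (`"KRAS:G12D"`) by default, or from genomic coordinates.
#'
#' @param path Path to a tab-separated MAF file with a header.
#' @param columns Column mapping from [maf_columns()].
#' @param variant_key `"protein"` (default) or `"genomic"`.
#' @param annotations Optional per-sample annotation table (see
#'   [read_sample_annotations()]) supplying the roster, tumor types,
#'   mutation burdens and signature labels. When `NULL` the roster is derived
#'   from the MAF itself.
#'
#' @return A `cohort`.
#' @export
read_maf <- function(path, columns = maf_columns(),
                     variant_key = c("protein", "genomic"),
                     annotations = NULL) {
  variant_key <- match.arg(variant_key)
  if (!file.exists(path)) {
    abort(sprintf("MAF file not found: %s", path), class = "raremut_io_error")
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                         col_types = readr::cols(.default = "c"))
  mandatory <- c("sample", "gene", "variant_class", "variant_type")
  mandatory <- c(mandatory,
                 if (variant_key == "protein") "protein_change"
                 else c("chromosome", "position", "ref_allele", "alt_allele"))
  wanted <- unlist(columns[mandatory], use.names = FALSE)
  absent <- wanted[!wanted %in% names(raw)]
  if (length(absent)) {
    abort(sprintf("MAF is missing mandatory column(s): %s.",
                  paste(absent, collapse = ", ")),
          class = "raremut_config_error")
  }
  records <- tibble(
    sample_id = raw[[columns$sample]],
    gene = raw[[columns$gene]],
    variant_class = raw[[columns$variant_class]],
    variant_type = raw[[columns$variant_type]]
  )
  if (columns$tumor_type %in% names(raw)) {
    records$tumor_type <- raw[[columns$tumor_type]]
  } else {
    records$tumor_type <- NA_character_
  }
  if (variant_key == "protein") {
    pc <- raw[[columns$protein_change]]
    pc <- sub("^p\\.", "", pc)
    records$variant_key <- paste(records$gene, pc, sep = ":")
    bad_key <- is.na(pc) | pc == ""
  } else {
    records$variant_key <- paste0(
      raw[[columns$chromosome]], ":", raw[[columns$position]], ":",
      raw[[columns$ref_allele]], ">", raw[[columns$alt_allele]])
    bad_key <- is.na(raw[[columns$chromosome]]) | is.na(raw[[columns$position]])
  }
  drop <- is.na(records$sample_id) | records$sample_id == "" |
    is.na(records$gene) | records$gene == "" | bad_key
  if (any(drop)) {
    inform(sprintf("read_maf: dropped %d row(s) with missing sample, gene or variant key.",
                   sum(drop)))
    records <- records[!drop, , drop = FALSE]
  }
  n_before <- nrow(records)
  records <- distinct(records, .data$sample_id, .data$variant_key,
                      .keep_all = TRUE)
  if (nrow(records) < n_before) {
    inform(sprintf("read_maf: collapsed %d duplicate (sample, variant) row(s).",
                   n_before - nrow(records)))
  }
  as_cohort(records, samples = annotations, key_scheme = variant_key)
}

#' Read a per-sample annotation table
#'
#' Tab-separated table with columns `sample_id`, `tumor_type`, and optionally
#' `mutation_burden` and `signature_label`.
#'
#' @param path Path to the TSV file.
#' @return A tibble, one row per sample.
#' @export
read_sample_annotations <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Annotation file not found: %s", path),
          class = "raremut_io_error")
  }
  ann <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"sample_id" %in% names(ann)) {
    abort("Annotation table is missing mandatory column: sample_id.",
          class = "raremut_config_error")
  }
  if ("mutation_burden" %in% names(ann)) {
    ann$mutation_burden <- as.integer(ann$mutation_burden)
  }
  distinct(as_tibble(ann), .data$sample_id, .keep_all = TRUE)
}

#' Write a cohort back to MAF and annotation files
#'
#' Writes the records as a standard-column MAF TSV (deterministic row order)
#' and, optionally, the sample roster as an annotation TSV.
#'
#' @param cohort A `cohort`.
#' @param path Output MAF path.
#' @param annotations_path Optional output path for the sample roster.
#' @return Invisibly, `path`.
#' @export
write_maf <- function(cohort, path, annotations_path = NULL) {
  cols <- maf_columns()
  protein_change <- sub("^[^:]*:", "", cohort$records$variant_key)
  out <- tibble(
    !!cols$sample := cohort$records$sample_id,
    !!cols$gene := cohort$records$gene,
    !!cols$variant_class := cohort$records$variant_class,
    !!cols$variant_type := cohort$records$variant_type,
    !!cols$protein_change := protein_change
  ) |>
    arrange(.data[[cols$sample]], .data[[cols$gene]],
            .data[[cols$protein_change]])
  readr::write_tsv(out, path)
  if (!is.null(annotations_path)) {
    readr::write_tsv(arrange(cohort$samples, .data$sample_id),
                     annotations_path)
  }
  invisible(path)
}

#' Keep only non-synonymous single-nucleotide variants
#'
#' Retains records whose variant type is `SNP` and whose classification is in
#' `classes`. The sample roster, and hence the cohort size `m`, is unchanged:
#' a tumor whose variants are all filtered away still counts as a profiled
#' tumor.
#'
#' @param cohort A `cohort`.
#' @param classes Character vector of classifications to keep; defaults to
#'   [nonsyn_classes()].
#' @return A `cohort` with filtered records.
#' @export
filter_nonsynonymous <- function(cohort, classes = nonsyn_classes()) {
  stopifnot(inherits(cohort, "cohort"))
  records <- filter(cohort$records,
                    .data$variant_type %in% "SNP",
                    .data$variant_class %in% classes)
  new_cohort(records, cohort$samples, cohort$key_scheme)
}

#' Subset a cohort to a set of samples
#'
#' Used e.g. to restrict analyses to one mutational subgroup. Both records
#' and roster are subset, and `m` is updated.
#'
#' @param cohort A `cohort`.
#' @param sample_ids Character vector of sample identifiers to keep.
#' @return A `cohort`.
#' @export
filter_samples <- function(cohort, sample_ids) {
  stopifnot(inherits(cohort, "cohort"))
  samples <- filter(cohort$samples, .data$sample_id %in% sample_ids)
  records <- filter(cohort$records, .data$sample_id %in% samples$sample_id)
  new_cohort(records, samples, cohort$key_scheme)
}

#' Per-variant tumor counts
#'
#' Number of distinct tumors harboring each variant (the per-variant `r`),
#' genome-wide or within one gene.
#'
#' @param cohort A filtered `cohort`.
#' @param gene Optional HUGO symbol restricting the scope to one gene.
#' @return A tibble with columns `gene`, `variant_key`, `r`.
#' @export
variant_counts <- function(cohort, gene = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  records <- cohort$records
  if (!is.null(gene)) records <- filter(records, .data$gene %in% !!gene)
  records |>
    count(.data$gene, .data$variant_key, name = "r") |>
    arrange(.data$gene, .data$variant_key)
}

new_freq_vector <- function(tbl, m, scope) {
  tbl <- as_tibble(tbl)
  structure(tbl, m = as.integer(m), scope = scope,
            class = c("freq_vector", class(tbl)))
}

#' Frequency-of-frequencies vector from per-item counts
#'
#' Tabulates `N_r`, the number of items (variants, or gene-pair events)
#' observed in exactly `r` tumors, from a vector of per-item tumor counts.
#' Items with zero count are dropped (they are the unseen mass the estimators
#' target).
#'
#' @param r Integer vector of per-item tumor counts.
#' @param m Cohort size (number of tumors profiled).
#' @param scope Label describing what the items are (e.g. `"global"`,
#'   a gene symbol, `"pair:co_mutation"`).
#' @return A `freq_vector`: a tibble with columns `r` and `N_r`, carrying
#'   attributes `m` and `scope`.
#' @export
frequency_from_counts <- function(r, m, scope = "global") {
  check_non_negative(r, "r")
  check_positive(m, "m")
  r <- as.integer(r[r >= 1L])
  if (any(r > m)) {
    abort("Per-item counts cannot exceed the cohort size m.",
          class = "raremut_domain_error")
  }
  if (!length(r)) {
    return(new_freq_vector(tibble(r = integer(), N_r = integer()), m, scope))
  }
  tab <- table(r)
  new_freq_vector(
    tibble(r = as.integer(names(tab)), N_r = as.integer(tab)) |>
      arrange(.data$r),
    m, scope)
}

#' Build a variant frequency vector
#'
#' The pairs `(r, N_r)` over one scope: `N_r` is the number of distinct
#' variants appearing in exactly `r` tumors of the cohort. These vectors
#' drive every estimator in the package.
#'
#' @param cohort A filtered `cohort`.
#' @param gene Optional HUGO symbol; `NULL` builds the genome-wide vector. A
#'   gene absent from the data yields an empty vector (with `m` still set),
#'   not an error.
#' @return A `freq_vector` (see [frequency_from_counts()]).
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   sample_id = c("s1", "s2", "s1", "s2"),
#'   gene = "TP53",
#'   variant_key = c("TP53:R175H", "TP53:R175H", "TP53:R280K", "TP53:C176F"))
#' variant_frequency(as_cohort(rec), gene = "TP53")
variant_frequency <- function(cohort, gene = NULL) {
  counts <- variant_counts(cohort, gene = gene)
  frequency_from_counts(counts$r, cohort$m, scope = gene %||% "global")
}

#' Look up N_r values in a frequency vector
#'
#' @param fv A `freq_vector`.
#' @param r Integer vector of frequencies.
#' @return Integer vector of `N_r` (0 where the class is empty).
#' @export
n_r <- function(fv, r) {
  idx <- match(as.integer(r), fv$r)
  out <- fv$N_r[idx]
  out[is.na(out)] <- 0L
  as.integer(out)
}

#' Cohort size stored in a frequency vector
#' @param fv A `freq_vector`.
#' @return Integer `m`.
#' @export
fv_m <- function(fv) attr(fv, "m")

#' Write a frequency vector to TSV
#'
#' Columns: scope, r, N_r, m.
#'
#' @param fv A `freq_vector`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_frequency_tsv <- function(fv, path) {
  readr::write_tsv(
    tibble(scope = attr(fv, "scope"), r = fv$r, N_r = fv$N_r, m = fv_m(fv)),
    path)
  invisible(path)
}
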