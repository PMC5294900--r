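# File I/O: gene x sample counts tables and sample phenotype tables.
# Counts travel as TSV/CSV with genes as rows, first column the gene id,
# header of sample ids; gzipped files are read transparently.

counts_delim <- function(path) {
  base <- sub("\\.gz$", "", path)
  if (grepl("\\.csv$", base, ignore.case = TRUE)) "," else "\t"
}

#' Read a gene x sample count matrix
#'
#' TSV or CSV (by extension; `.gz` accepted), genes as rows, first column
#' gene ids, remaining columns one per sample. Duplicate gene ids, missing
#' cells, negative or non-integer counts are rejected with the offending
#' gene/sample named.
#'
#' @param path File path.
#' @return Counts tibble (`gene_id` + one column per sample).
#' @export
read_counts <- function(path) {
  tbl <- readr::read_delim(path, delim = counts_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  if (ncol(tbl) < 2L) abort("count file needs a gene id column and at least one sample")
  names(tbl)[1L] <- "gene_id"
  ids <- as.character(tbl$gene_id)
  dup <- ids[duplicated(ids)]
  if (length(dup)) abort(paste0("duplicate gene ids: ", paste(unique(dup), collapse = ", ")))
  for (j in names(tbl)[-1L]) {
    v <- tbl[[j]]
    if (!is.numeric(v)) abort(paste0("sample column '", j, "' is not numeric"))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad)) {
      abort(sprintf("invalid count at gene '%s', sample '%s': %s",
                    ids[bad[1L]], j, format(v[bad[1L]])))
    }
  }
  tbl$gene_id <- ids
  tbl
}

#' Write a counts tibble
#'
#' @param counts Counts tibble.
#' @param path Output path (`.csv` selects CSV, otherwise TSV; `.gz`
#'   compresses).
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  readr::write_delim(counts, path, delim = counts_delim(path))
  invisible(path)
}

#' Read a sample phenotype table
#'
#' TSV/CSV with columns `sample_id`, `status` (0 = control, 1 = case) and
#' any covariate or stratum columns. Status must be non-missing and binary
#' with both classes present.
#'
#' @param path File path.
#' @param status Name of the status column.
#' @return Phenotype tibble.
#' @export
read_phenotype <- function(path, status = "status") {
  tbl <- readr::read_delim(path, delim = counts_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(tbl)) names(tbl)[1L] <- "sample_id"
  tbl$sample_id <- as.character(tbl$sample_id)
  if (anyDuplicated(tbl$sample_id)) abort("duplicate sample ids in phenotype table")
  if (!status %in% names(tbl)) abort(paste0("no '", status, "' column in phenotype table"))
  check_status(tbl[[status]])
  tbl
}

# order-insensitive id join of counts columns and phenotype rows
align_samples <- function(counts, phenotype, gene_id = "gene_id") {
  samples <- setdiff(names(counts), gene_id)
  missing_ph <- setdiff(samples, phenotype$sample_id)
  extra_ph <- setdiff(phenotype$sample_id, samples)
  if (length(missing_ph) || length(extra_ph)) {
    abort(paste0(
      "counts and phenotype samples disagree",
      if (length(missing_ph)) paste0("; missing from phenotype: ",
                                     paste(missing_ph, collapse = ", ")),
      if (length(extra_ph)) paste0("; missing from counts: ",
                                   paste(extra_ph, collapse = ", "))))
  }
  phenotype[match(samples, phenotype$sample_id), , drop = FALSE]
}
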