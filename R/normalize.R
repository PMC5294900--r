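# Count matrices travel as tibbles: a `gene_id` column plus one numeric
# column per sample. counts_to_matrix()/matrix_to_counts() convert to the
# matrix form used internally.

#' Convert a counts tibble to a gene x sample matrix
#'
#' @param counts Tibble with a gene-id column and one column per sample.
#' @param gene_id Name of the gene-id column.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
counts_to_matrix <- function(counts, gene_id = "gene_id") {
  if (!gene_id %in% names(counts)) abort(paste0("no '", gene_id, "' column"))
  ids <- as.character(counts[[gene_id]])
  if (anyDuplicated(ids)) abort("duplicate gene ids")
  m <- as.matrix(counts[setdiff(names(counts), gene_id)])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

matrix_to_counts <- function(m, gene_id = "gene_id") {
  out <- as_tibble(m)
  dplyr::bind_cols(tibble(!!gene_id := rownames(m)), out)
}

check_count_matrix <- function(m) {
  if (anyNA(m)) abort("counts contain missing values")
  if (any(m < 0)) abort("counts must be non-negative")
  if (any(m != round(m))) abort("counts must be integers")
  invisible(m)
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling constants equalizing sequencing depth: for each sample
#' the factor is the median, over genes with a positive geometric mean
#' across samples (i.e. no zero count), of the ratio of that sample's count
#' to the gene's geometric mean. This is the DESeq normalization.
#'
#' @inheritParams counts_to_matrix
#' @return Tibble with columns `sample_id`, `size_factor`.
#' @examples
#' cm <- tibble::tibble(gene_id = paste0("g", 1:4),
#'                      s1 = c(10, 20, 40, 80), s2 = c(20, 40, 80, 160))
#' size_factors(cm)   # 1/sqrt(2), sqrt(2)
#' @export
size_factors <- function(counts, gene_id = "gene_id") {
  m <- check_count_matrix(counts_to_matrix(counts, gene_id))
  use <- rowSums(m == 0) == 0L
  if (!any(use)) {
    abort("no gene has nonzero counts in every sample; size factors undefined")
  }
  logm <- log(m[use, , drop = FALSE])
  ref <- rowMeans(logm)                       # log geometric means
  f <- apply(logm - ref, 2L, median)          # median ties: midpoint
  tibble(sample_id = colnames(m), size_factor = unname(exp(f)))
}

#' Normalize counts by size factors
#'
#' Divides each sample's counts by its size factor (computed with
#' [size_factors()] when not supplied). Returned values are non-negative
#' reals in the same tibble layout.
#'
#' @inheritParams counts_to_matrix
#' @param factors Optional tibble from [size_factors()] (columns
#'   `sample_id`, `size_factor`), matched to samples by id.
#' @return Tibble of normalized counts.
#' @export
normalize_counts <- function(counts, factors = NULL, gene_id = "gene_id") {
  m <- check_count_matrix(counts_to_matrix(counts, gene_id))
  if (is.null(factors)) factors <- size_factors(counts, gene_id)
  if (!all(c("sample_id", "size_factor") %in% names(factors))) {
    abort("factors must have columns sample_id and size_factor")
  }
  idx <- match(colnames(m), factors$sample_id)
  if (anyNA(idx)) abort("size factors missing for some samples")
  f <- factors$size_factor[idx]
  if (any(!is.finite(f)) || any(f <= 0)) abort("size factors must be positive")
  matrix_to_counts(sweep(m, 2L, f, `/`), gene_id)
}
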