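#' Read and write gene-level count tables
#'
#' Counts travel as TSV: header row of sample ids, first column `gene_id`.
#' `read_counts()` validates that gene and sample ids are unique and that all
#' entries are non-negative integers, reporting the offending coordinate
#' otherwise. Writing then reading reproduces values and names exactly.
#'
#' @param path File path.
#' @return `read_counts()`: a count tibble (`gene_id` + one column per sample).
#' @export
read_counts <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  names(tbl)[1] <- "gene_id"
  m <- count_matrix(tbl) # validates
  as_count_tbl(m)
}

#' @rdname read_counts
#' @param counts Count tibble or matrix with gene rownames.
#' @export
write_counts <- function(counts, path) {
  m <- count_matrix(counts)
  readr::write_tsv(as_count_tbl(m), path, progress = FALSE)
  invisible(path)
}

#' Read/write counts in MatrixMarket coordinate format
#'
#' The sparse triplet file is accompanied by one-id-per-line row and column
#' name files (`<stem>.mtx`, `<stem>.rownames`, `<stem>.colnames`).
#'
#' @param stem Path stem without extension.
#' @return A count tibble, as [read_counts()].
#' @export
read_counts_mtx <- function(stem) {
  m <- as.matrix(Matrix::readMM(paste0(stem, ".mtx")))
  rownames(m) <- readLines(paste0(stem, ".rownames"))
  colnames(m) <- readLines(paste0(stem, ".colnames"))
  m <- count_matrix(m)
  as_count_tbl(m)
}

#' @rdname read_counts_mtx
#' @param counts Count tibble or matrix.
#' @export
write_counts_mtx <- function(counts, stem) {
  m <- count_matrix(counts)
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), paste0(stem, ".mtx"))
  writeLines(rownames(m), paste0(stem, ".rownames"))
  writeLines(colnames(m), paste0(stem, ".colnames"))
  invisible(stem)
}

#' Read and write sample metadata tables
#'
#' A sample table is a TSV with a `sample_id` column plus experimental
#' factors (experiment/batch, region, sex, stress, treatment, timepoint,
#' group). Columns other than `sample_id` and `timepoint` are read as
#' character and left verbatim.
#'
#' @param path File path.
#' @export
read_sample_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"sample_id" %in% names(tbl)) abort("Sample table needs a `sample_id` column.")
  if (anyDuplicated(tbl$sample_id)) abort("Duplicated sample ids in sample table.")
  if ("timepoint" %in% names(tbl)) tbl$timepoint <- as.numeric(tbl$timepoint)
  tbl
}

#' @rdname read_sample_table
#' @param samples Sample tibble.
#' @export
write_sample_table <- function(samples, path) {
  readr::write_tsv(samples, path, progress = FALSE)
  invisible(path)
}

#' Read a transcript-to-gene map
#'
#' Three tab-separated columns: `transcript_id`, `gene_id`, `biotype`.
#' Transcript ids must be unique.
#'
#' @param path File path.
#' @export
read_tx2gene <- function(path) {
  map <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  names(map)[1:3] <- c("transcript_id", "gene_id", "biotype")
  if (anyDuplicated(map$transcript_id)) {
    abort("Duplicated transcript ids in tx2gene map.")
  }
  map
}

#' Aggregate transcript-level estimated counts to gene level
#'
#' Estimated (fractional) transcript counts are summed per gene and sample
#' over transcripts whose biotype is in `biotypes`, then rounded
#' half-to-even to integers, matching the aggregation of protein-coding
#' transcripts that precedes differential expression analysis. Transcripts
#' absent from the map are dropped and reported in the `unmapped` attribute.
#'
#' @param tx Transcript table: either wide (`transcript_id` + one numeric
#'   column per sample) or long (`transcript_id`, `sample_id`,
#'   `estimated_count`).
#' @param map Transcript-to-gene map ([read_tx2gene()]).
#' @param biotypes Biotypes to keep; defaults to protein-coding only.
#' @return Count tibble; attribute `unmapped` lists dropped transcript ids.
#' @export
aggregate_transcripts_to_genes <- function(tx, map, biotypes = "protein_coding") {
  if (!"transcript_id" %in% names(tx)) abort("`tx` needs a `transcript_id` column.")
  if (all(c("sample_id", "estimated_count") %in% names(tx))) {
    tx <- tidyr::pivot_wider(tx[c("transcript_id", "sample_id", "estimated_count")],
                             names_from = "sample_id",
                             values_from = "estimated_count", values_fill = 0)
  }
  vals <- as.matrix(tx[, setdiff(names(tx), "transcript_id"), drop = FALSE])
  if (any(vals < 0)) abort("Estimated counts must be non-negative.")
  unmapped <- setdiff(tx$transcript_id, map$transcript_id)
  if (length(unmapped) > 0) {
    warn(sprintf("%d transcripts not in the map were dropped.", length(unmapped)))
  }
  keep <- map[map$biotype %in% biotypes, c("transcript_id", "gene_id")]
  merged <- dplyr::inner_join(tx, keep, by = "transcript_id")
  if (nrow(merged) == 0) {
    abort("No transcripts left after the biotype filter; nothing to aggregate.")
  }
  out <- merged |>
    dplyr::select(-"transcript_id") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), sum), .groups = "drop") |>
    dplyr::mutate(dplyr::across(-"gene_id", round)) # round() is half-to-even
  out <- as_count_tbl(count_matrix(out))
  attr(out, "unmapped") <- unmapped
  out
}
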