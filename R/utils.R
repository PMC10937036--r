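# Internal helpers shared across modules.

# Convert a count tibble (gene_id + one column per sample) to an integer-ish
# numeric matrix with gene rownames. Validates identifiers and values.
count_matrix <- function(counts, require_integer = TRUE, arg = "counts") {
  if (is.matrix(counts)) {
    if (is.null(rownames(counts))) {
      abort(sprintf("`%s` given as a matrix must have gene rownames.", arg))
    }
    m <- counts
  } else {
    if (!is.data.frame(counts)) {
      abort(sprintf("`%s` must be a data frame or matrix.", arg))
    }
    if (ncol(counts) < 2) {
      abort(sprintf("`%s` needs a gene id column plus at least one sample.", arg))
    }
    ids <- as.character(counts[[1]])
    m <- as.matrix(counts[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
  }
  if (anyDuplicated(rownames(m))) {
    dup <- unique(rownames(m)[duplicated(rownames(m))])
    abort(sprintf("Duplicated gene ids: %s", paste(utils::head(dup, 5), collapse = ", ")))
  }
  if (anyDuplicated(colnames(m))) {
    dup <- unique(colnames(m)[duplicated(colnames(m))])
    abort(sprintf("Duplicated sample ids: %s", paste(utils::head(dup, 5), collapse = ", ")))
  }
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("Negative or non-finite count at gene '%s', sample '%s'.",
                  rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  if (require_integer) {
    off <- which(abs(m - round(m)) > 1e-8, arr.ind = TRUE)
    if (nrow(off) > 0) {
      abort(sprintf("Non-integer count at gene '%s', sample '%s'.",
                    rownames(m)[off[1, 1]], colnames(m)[off[1, 2]]))
    }
  }
  m
}

as_count_tbl <- function(m) {
  tibble::as_tibble(as.data.frame(m), rownames = "gene_id")
}

# Align a normalization-factor table (sample_id, library_size, tmm_factor,
# effective_library_size) to the columns of a count matrix; NULL factors
# default to raw library sizes with unit factors.
effective_lib_sizes <- function(m, factors = NULL) {
  if (is.null(factors)) {
    return(colSums(m))
  }
  if (!is.data.frame(factors) || !all(c("sample_id", "effective_library_size") %in% names(factors))) {
    abort("`factors` must be a norm-factor table from `tmm_factors()`.")
  }
  idx <- match(colnames(m), factors$sample_id)
  if (anyNA(idx)) {
    abort(sprintf("Samples missing from `factors`: %s",
                  paste(colnames(m)[is.na(idx)], collapse = ", ")))
  }
  eff <- factors$effective_library_size[idx]
  if (any(eff <= 0)) abort("Zero or negative effective library size.")
  stats::setNames(eff, colnames(m))
}

check_samples <- function(m, samples) {
  if (!is.data.frame(samples) || !"sample_id" %in% names(samples)) {
    abort("`samples` must be a data frame with a `sample_id` column.")
  }
  if (anyDuplicated(samples$sample_id)) abort("Duplicated sample ids in `samples`.")
  missing <- setdiff(colnames(m), samples$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("Samples absent from metadata: %s", paste(missing, collapse = ", ")))
  }
  samples[match(colnames(m), samples$sample_id), , drop = FALSE]
}

# Evaluate code with a temporary RNG state seeded at `seed`.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

new_dge_tbl <- function(df) {
  structure(tibble::as_tibble(df), class = c("nrx_dge", class(tibble::tibble())))
}
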