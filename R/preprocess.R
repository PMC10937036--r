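#' Remove genes with low expression
#'
#' Keeps genes with counts-per-million (computed on raw library sizes) of at
#' least `min_cpm` in at least `min_samples` samples. Removed genes are not
#' discarded silently: their ids are kept in the `removed` attribute, since a
#' biologically interesting gene can fail this step purely through low
#' baseline expression.
#'
#' @param counts Count tibble (`gene_id` + samples).
#' @param samples Optional sample table; when given and `min_samples` is
#'   `NULL`, the smallest `group` size is used.
#' @param min_cpm CPM threshold.
#' @param min_samples Number of samples that must reach `min_cpm`.
#' @return Filtered count tibble (gene order preserved) with attribute
#'   `removed` (tibble of dropped gene ids).
#' @export
filter_low_expression <- function(counts, samples = NULL, min_cpm = 1,
                                  min_samples = NULL) {
  m <- count_matrix(counts)
  if (is.null(min_samples)) {
    if (is.null(samples)) abort("Give `samples` or `min_samples`.")
    samples <- check_samples(m, samples)
    grp <- if ("group" %in% names(samples)) samples$group
           else interaction(samples[setdiff(names(samples), "sample_id")], drop = TRUE)
    min_samples <- min(table(grp))
  }
  if (min_samples < 1) abort("`min_samples` must be >= 1.")
  lib <- colSums(m)
  if (any(lib == 0)) abort("Sample with zero total counts.")
  cpm_raw <- sweep(m, 2, lib, `/`) * 1e6
  keep <- rowSums(cpm_raw >= min_cpm) >= min_samples
  if (!any(keep)) abort("Filtering removed every gene.")
  out <- as_count_tbl(m[keep, , drop = FALSE])
  attr(out, "removed") <- tibble::tibble(gene_id = rownames(m)[!keep])
  out
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Estimates relative compositional scaling factors between samples. The
#' reference sample is the one whose 75th count percentile, as a fraction of
#' its library, is closest to the mean such fraction. For every sample, over
#' genes positive in both it and the reference, gene-wise log2 ratios of
#' library-normalized proportions (M) are doubly trimmed — the top and bottom
#' `trim_M` fraction by M and `trim_A` fraction by average log2 abundance (A)
#' are discarded — and the factor is two to the precision-weighted mean of
#' the remaining M values (weights are inverse asymptotic binomial
#' variances). Factors are rescaled to geometric mean 1.
#'
#' @param counts Count tibble.
#' @param trim_M,trim_A Trim fractions for log-ratios and abundances.
#' @return Tibble: `sample_id`, `library_size`, `tmm_factor`,
#'   `effective_library_size` (= library_size * tmm_factor).
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  m <- count_matrix(counts)
  if (ncol(m) < 2) abort("TMM needs at least two samples.")
  lib <- colSums(m)
  if (any(lib <= 0)) abort("Every sample needs a positive total.")

  f75 <- apply(m, 2, function(x) quantile(x, 0.75, names = FALSE)) / lib
  ref <- which.min(abs(f75 - mean(f75)))

  fac <- vapply(seq_len(ncol(m)), function(s) {
    if (s == ref) return(1)
    tmm_pair(m[, s], lib[s], m[, ref], lib[ref], trim_M, trim_A)
  }, numeric(1))
  fac <- fac / exp(mean(log(fac)))
  tibble::tibble(sample_id = colnames(m), library_size = lib,
                 tmm_factor = fac,
                 effective_library_size = lib * fac)
}

# one sample against the reference; exported logic kept separate so tests can
# compare against a literal re-derivation
tmm_pair <- function(y, n, yr, nr, trim_M, trim_A) {
  pos <- y > 0 & yr > 0
  y <- y[pos]; yr <- yr[pos]
  M <- log2((y / n) / (yr / nr))
  A <- 0.5 * log2((y / n) * (yr / nr))
  w <- 1 / y - 1 / n + 1 / yr - 1 / nr # asymptotic variance of M
  k <- length(M)
  loM <- floor(k * trim_M) + 1; hiM <- k - floor(k * trim_M)
  loA <- floor(k * trim_A) + 1; hiA <- k - floor(k * trim_A)
  keep <- intersect(order(M)[loM:hiM], order(A)[loA:hiA])
  if (length(keep) < 10) {
    warn("Fewer than 10 genes survive TMM trimming; using untrimmed weighted mean.")
    keep <- seq_len(k)
  }
  2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
}

#' Counts per million
#'
#' `count / effective library size * 1e6`; with `log = TRUE`, returns
#' `log2(CPM + prior)` where the prior count is scaled to the mean effective
#' library size so the damping is comparable across samples.
#'
#' @param counts Count tibble.
#' @param factors Norm-factor table from [tmm_factors()]; `NULL` uses raw
#'   library sizes with unit factors.
#' @param log Return log2 values?
#' @param prior_count Prior count used only when `log = TRUE`.
#' @return Tibble (`gene_id` + samples) of (log-)CPM values.
#' @export
cpm <- function(counts, factors = NULL, log = FALSE, prior_count = 0.5) {
  m <- count_matrix(counts, require_integer = FALSE)
  eff <- effective_lib_sizes(m, factors)
  out <- sweep(m, 2, eff, `/`) * 1e6
  if (log) {
    prior_cpm <- prior_count / mean(eff) * 1e6
    out <- log2(out + prior_cpm)
  }
  as_count_tbl(out)
}

#' Variance-stabilizing transform for surrogate-variable estimation
#'
#' `log2(CPM + 4)`: the pseudo-count flattens the mean-variance relationship
#' of NB counts enough for the residual SVD in
#' [estimate_surrogate_variables()], which needs approximate
#' homoskedasticity, not an exact transform.
#'
#' @inheritParams cpm
#' @return Tibble (`gene_id` + samples).
#' @export
variance_stabilize <- function(counts, factors = NULL) {
  m <- count_matrix(counts, require_integer = FALSE)
  eff <- effective_lib_sizes(m, factors)
  as_count_tbl(log2(sweep(m, 2, eff, `/`) * 1e6 + 4))
}
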