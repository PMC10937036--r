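# broom-style accessors for fitted objects.

#' Tidy a negative-binomial GLM fit
#'
#' One row per gene and coefficient, with the log2-scale estimate and its
#' approximate standard error from the inverse weighted information.
#'
#' @param x An `nrx_glm_fit`.
#' @param ... Ignored.
#' @return Tibble: `gene_id`, `term`, `estimate` (log2), `std_error` (log2).
#' @export
tidy.nrx_glm_fit <- function(x, ...) {
  p <- ncol(x$beta)
  se <- t(vapply(seq_along(x$gene_id), function(g) {
    sqrt(pmax(diag(x$cov[, , g]), 0)) / log(2)
  }, numeric(p)))
  out <- tibble::tibble(
    gene_id = rep(x$gene_id, each = p),
    term = rep(colnames(x$beta), length(x$gene_id)),
    estimate = as.numeric(t(x$log2fc)),
    std_error = as.numeric(t(se))
  )
  out
}

#' @rdname tidy.nrx_glm_fit
#' @export
glance.nrx_glm_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$gene_id),
    n_samples = ncol(x$fitted),
    n_coefficients = ncol(x$beta),
    df_residual = x$df_residual,
    n_converged = sum(x$converged),
    n_degenerate = sum(x$degenerate)
  )
}

#' Tidy dispersion estimates
#'
#' @param x An `nrx_dispersion` from [estimate_tagwise_dispersion()].
#' @param ... Ignored.
#' @return `tidy()`: tibble `gene_id`, `dispersion`; `glance()`: one row with
#'   the common dispersion, prior df and gene count.
#' @export
tidy.nrx_dispersion <- function(x, ...) x$tagwise

#' @rdname tidy.nrx_dispersion
#' @export
glance.nrx_dispersion <- function(x, ...) {
  tibble::tibble(
    common_dispersion = x$common,
    prior_df = x$prior_df,
    n_genes = nrow(x$tagwise),
    median_tagwise = median(x$tagwise$dispersion)
  )
}

#' @exportS3Method base::print
print.nrx_dispersion <- function(x, ...) {
  cat(sprintf("Dispersion estimates: common = %.4g, prior df = %g, %d genes\n",
              x$common, x$prior_df, nrow(x$tagwise)))
  invisible(x)
}
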