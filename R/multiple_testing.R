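#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_i` is the minimum over `j` with
#' `p_(j) >= p_(i)` of `p_(j) * m / j`, returned in the original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`, no missing values.
#' @return Vector of adjusted p-values, elementwise in `[p, 1]`.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p)) abort("Missing p-values are not allowed.")
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Conditional FDR for interaction terms
#'
#' Interaction-term FDR computed only over the genes that already show a
#' significant main effect: the conditioning set is
#' `S = {genes with main fdr < alpha_main}` and BH is applied to the
#' interaction p-values restricted to `S`, with `m = |S|`. Genes outside `S`
#' get an explicit `NA` ("not tested") rather than an invented value.
#'
#' @param main,interaction `nrx_dge` tibbles (or any tibble with `gene_id`,
#'   `p_value`, `fdr`) over the same gene universe.
#' @param alpha_main Main-effect FDR threshold defining the conditioning set.
#' @return An `nrx_cfdr` tibble: `gene_id`, `main_p`, `main_fdr`,
#'   `interaction_p`, `interaction_fdr` (NA outside the conditioning set),
#'   `in_conditioning_set`, plus `interaction_log2fc` when available.
#' @export
conditional_interaction_fdr <- function(main, interaction, alpha_main = 0.05) {
  extra_main <- setdiff(main$gene_id, interaction$gene_id)
  extra_int <- setdiff(interaction$gene_id, main$gene_id)
  if (length(extra_main) > 0 || length(extra_int) > 0) {
    abort(paste0(
      "Gene universes differ. Only in `main`: ",
      paste(utils::head(extra_main, 5), collapse = ", "),
      "; only in `interaction`: ",
      paste(utils::head(extra_int, 5), collapse = ", ")
    ))
  }
  interaction <- interaction[match(main$gene_id, interaction$gene_id), ]
  in_set <- main$fdr < alpha_main
  int_fdr <- rep(NA_real_, nrow(main))
  if (any(in_set)) int_fdr[in_set] <- bh_adjust(interaction$p_value[in_set])
  out <- tibble::tibble(
    gene_id = main$gene_id,
    main_p = main$p_value, main_fdr = main$fdr,
    interaction_p = interaction$p_value, interaction_fdr = int_fdr,
    in_conditioning_set = in_set
  )
  if ("log2fc" %in% names(interaction)) out$interaction_log2fc <- interaction$log2fc
  if ("se_log2fc" %in% names(interaction)) out$interaction_se <- interaction$se_log2fc
  structure(out, class = c("nrx_cfdr", class(tibble::tibble())))
}

#' Normal-prior shrinkage of log2 fold changes
#'
#' Posterior-mean shrinkage under a zero-centred normal prior whose variance
#' is estimated by moments: `tau2 = max(0, var(estimates) - mean(se^2))`,
#' with `shrunk = estimate * tau2 / (tau2 + se^2)`. Pure-noise estimates
#' (`tau2 = 0`) shrink to exactly zero; an estimate with vanishing standard
#' error is returned unchanged. Used to discount fold-change differences
#' that are driven by noisy coefficient estimates.
#'
#' @param estimates Per-gene log2 fold changes (finite).
#' @param standard_errors Matching positive standard errors.
#' @return Numeric vector of shrunken log2 fold changes.
#' @export
shrink_logfc <- function(estimates, standard_errors) {
  if (length(estimates) != length(standard_errors)) {
    abort("`estimates` and `standard_errors` must have the same length.")
  }
  if (any(!is.finite(estimates))) abort("Estimates must be finite.")
  if (any(!is.finite(standard_errors) | standard_errors <= 0)) {
    abort("Standard errors must be positive and finite.")
  }
  tau2 <- max(0, var(estimates) - mean(standard_errors^2))
  estimates * tau2 / (tau2 + standard_errors^2)
}
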