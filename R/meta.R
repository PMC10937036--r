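#' One-step surrogate-variable estimation
#'
#' Residualizes the variance-stabilized expression matrix on the primary
#' design by least squares and takes the top right singular vectors of the
#' gene-by-sample residual matrix as surrogate variables (one SVD pass, no
#' iterative reweighting). The SVs capture unmodelled structure — batch or
#' processing effects — and are meant to be appended to the design, never to
#' replace it.
#'
#' @param expr Expression tibble (`gene_id` + samples), typically from
#'   [variance_stabilize()].
#' @param samples Sample tibble (used when `design` is a formula).
#' @param design Formula, string, or design matrix of the primary effects.
#' @param n_sv Number of surrogate variables; must satisfy
#'   `n_sv < n_samples - rank(design)`.
#' @return An `nrx_sv` tibble: `sample_id` plus unit-norm columns `sv1..svk`.
#' @export
estimate_surrogate_variables <- function(expr, samples = NULL, design, n_sv) {
  m <- count_matrix(expr, require_integer = FALSE, arg = "expr")
  X <- if (is.matrix(design)) design else build_design(check_samples(m, samples), design)
  r <- qr(X)$rank
  if (n_sv >= ncol(m) - r) {
    abort(sprintf("n_sv must be < n_samples - rank(design) = %d.", ncol(m) - r))
  }
  R <- residualize(m, X)
  if (max(abs(R)) < 1e-8) {
    abort("Expression lies in the design's column space; use n_sv = 0.")
  }
  if (n_sv == 0) {
    sv <- matrix(numeric(0), nrow = ncol(m), ncol = 0)
  } else {
    sv <- svd(R, nu = 0, nv = n_sv)$v
  }
  colnames(sv) <- if (ncol(sv) > 0) paste0("sv", seq_len(ncol(sv))) else character(0)
  out <- dplyr::bind_cols(tibble::tibble(sample_id = colnames(m)),
                          tibble::as_tibble(sv))
  structure(out, class = c("nrx_sv", class(tibble::tibble())), n_sv = n_sv)
}

residualize <- function(m, X) {
  H <- X %*% solve(crossprod(X), t(X))
  m - m %*% H
}

sv_matrix <- function(sv) {
  as.matrix(sv[, setdiff(names(sv), "sample_id"), drop = FALSE])
}

#' Choose the number of surrogate variables by parallel analysis
#'
#' Compares the residual singular values against the per-rank
#' `quantile` of singular values obtained after independently permuting each
#' gene's residuals across samples; the count of observed values exceeding
#' their permutation quantile is returned.
#'
#' @inheritParams estimate_surrogate_variables
#' @param n_permutations Number of permutations.
#' @param quantile Per-rank null quantile.
#' @param seed Integer seed (results are deterministic given the seed).
#' @return Integer count of surrogate variables to keep.
#' @export
num_sv <- function(expr, samples = NULL, design, n_permutations = 20,
                   quantile = 0.95, seed = 1) {
  m <- count_matrix(expr, require_integer = FALSE, arg = "expr")
  X <- if (is.matrix(design)) design else build_design(check_samples(m, samples), design)
  # work in an orthonormal basis of the residual subspace: there the rows of
  # null residuals are exchangeable, so within-row permutation is an exact
  # null for the singular values
  qrX <- qr(X)
  r <- qrX$rank
  Q <- qr.Q(qrX, complete = TRUE)[, seq(r + 1, ncol(m)), drop = FALSE]
  Rstar <- m %*% Q
  kmax <- min(nrow(m), ncol(Rstar))
  d_obs <- svd(Rstar, nu = 0, nv = 0)$d
  null_d <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      Rp <- t(apply(Rstar, 1, sample))
      svd(Rp, nu = 0, nv = 0)$d
    }, numeric(length(d_obs)))
  })
  thresh <- apply(null_d, 1, stats::quantile, probs = quantile, names = FALSE)
  exceeds <- d_obs > thresh
  # count the leading run of exceedances, capped by the residual dimension
  n <- 0
  for (k in seq_along(exceeds)) {
    if (!exceeds[k]) break
    n <- n + 1
  }
  min(n, max(kmax, 0))
}

# Merge a list of experiments (each list(counts, samples)) on the
# intersection of gene ids. Sample ids are prefixed with the experiment name
# when not already unique.
merge_experiments <- function(experiments) {
  if (is.list(experiments) && !is.null(experiments$experiments)) {
    experiments <- experiments$experiments
  }
  if (length(experiments) < 2) abort("Need at least two experiments.")
  nm <- names(experiments) %||% paste0("exp", seq_along(experiments))
  nm[nm == ""] <- paste0("exp", which(nm == ""))
  mats <- lapply(experiments, function(e) count_matrix(e$counts))
  genes <- Reduce(intersect, lapply(mats, rownames))
  if (length(genes) == 0) abort("Experiments share no gene ids.")
  all_ids <- unlist(lapply(experiments, function(e) e$samples$sample_id))
  prefix <- anyDuplicated(all_ids) > 0
  pieces <- purrr::map2(experiments, nm, function(e, n) {
    m <- count_matrix(e$counts)[genes, , drop = FALSE]
    s <- tibble::as_tibble(e$samples)
    s$experiment <- n
    if (prefix) {
      s$sample_id <- paste(n, s$sample_id, sep = "_")
      colnames(m) <- s$sample_id
    }
    list(m = m, s = s)
  })
  m <- do.call(cbind, lapply(pieces, `[[`, "m"))
  s <- dplyr::bind_rows(lapply(pieces, `[[`, "s"))
  list(counts = as_count_tbl(m), samples = s)
}

#' Combined-response analysis across heterogeneous experiments
#'
#' Merges several experiments on their shared genes, maps each experiment's
#' original group labels onto a common two-level `response` variable
#' (control/response), refilters and renormalizes jointly, estimates
#' surrogate variables against the response design to absorb
#' experiment-specific processing effects, and fits an additive NB GLM
#' `counts ~ response + SVs`, testing the response coefficient with the
#' quasi-likelihood F-test.
#'
#' @param experiments Named list of experiments (each a list with `counts`
#'   and `samples`), or the output of [simulate_multi_experiment()].
#' @param labels Per-experiment named character vectors mapping each original
#'   `group` label to `"control"` or `"response"`.
#' @param min_cpm Filtering threshold (see [filter_low_expression()]).
#' @param n_sv Number of surrogate variables; `NULL` chooses by [num_sv()].
#' @param sv_seed Seed for the parallel-analysis permutations.
#' @return An `nrx_dge` tibble for the response coefficient, with attributes
#'   `n_sv` and `samples`.
#' @export
combined_response_analysis <- function(experiments, labels, min_cpm = 1,
                                       n_sv = NULL, sv_seed = 1) {
  merged <- merge_experiments(experiments)
  s <- merged$samples
  if (!"group" %in% names(s)) abort("Each sample table needs a `group` column.")
  resp <- character(nrow(s))
  for (e in unique(s$experiment)) {
    map <- labels[[e]]
    if (is.null(map)) abort(sprintf("No label map for experiment `%s`.", e))
    sel <- s$experiment == e
    r <- map[as.character(s$group[sel])]
    if (anyNA(r)) {
      missing <- setdiff(unique(as.character(s$group[sel])), names(map))
      abort(sprintf("Unmapped group labels in `%s`: %s", e,
                    paste(missing, collapse = ", ")))
    }
    if (length(unique(r)) < 2) {
      abort(sprintf("Experiment `%s` has only one response level.", e))
    }
    resp[sel] <- r
  }
  if (!all(resp %in% c("control", "response"))) {
    abort("Label maps must assign `control` or `response`.")
  }
  s$response <- factor(resp, levels = c("control", "response"))
  s$filter_group <- interaction(s$experiment, s$response, drop = TRUE)

  counts <- filter_low_expression(
    merged$counts, min_cpm = min_cpm,
    min_samples = min(table(s$filter_group))
  )
  nf <- tmm_factors(counts)
  X0 <- build_design(s, ~response)
  vst <- variance_stabilize(counts, nf)
  if (is.null(n_sv)) n_sv <- num_sv(vst, design = X0, seed = sv_seed)
  sv <- if (n_sv > 0) {
    sv_matrix(estimate_surrogate_variables(vst, design = X0, n_sv = n_sv))
  } else NULL
  X <- if (is.null(sv)) X0 else {
    Xf <- cbind(X0, sv)
    if (qr(Xf)$rank < ncol(Xf)) abort("Surrogate variables are confounded with the design.")
    Xf
  }

  # QL fits pair with the common dispersion: gene-level dispersion
  # variability belongs to the quasi-dispersion, not the NB fit
  common <- estimate_common_dispersion(counts, s, X, nf)
  fit <- fit_glm(counts, s, X, nf, common)
  res <- ql_ftest(fit, "responseresponse")
  attr(res, "n_sv") <- n_sv
  attr(res, "samples") <- s
  res
}

#' Cumulative p-value rank aggregation across analyses
#'
#' Within every analysis, the gene with the smallest p-value gets rank 1 and
#' the largest rank N (average ranks on ties); ranks are summed across
#' analyses. A low cumulative rank marks a gene as consistently significant.
#' The gene universe is the intersection of the analyses' genes, keeping
#' ranks comparable when filtered backgrounds differ.
#'
#' @param analyses Either a named list (>= 2) of `nrx_dge` tibbles (or any
#'   tibble with `gene_id` and `p_value`), or a single wide tibble with
#'   `gene_id` plus one numeric p-value column per analysis, e.g. from
#'   [simulate_pvalue_table()].
#' @return An `nrx_cumrank` tibble sorted by ascending cumulative rank (ties
#'   broken by gene id): `gene_id`, one `rank_*` column per analysis,
#'   `cumulative_rank`, `log10_cumulative_rank`.
#' @export
cumulative_rank <- function(analyses) {
  if (is.data.frame(analyses)) {
    nmv <- setdiff(names(analyses), "gene_id")
    analyses <- lapply(nmv, function(n) {
      tibble::tibble(gene_id = analyses$gene_id, p_value = analyses[[n]])
    })
    names(analyses) <- nmv
  }
  if (length(analyses) < 2) abort("Need at least two analyses.")
  nm <- names(analyses) %||% paste0("analysis", seq_along(analyses))
  nm[nm == ""] <- paste0("analysis", which(nm == ""))
  genes <- Reduce(intersect, lapply(analyses, function(a) a$gene_id))
  if (length(genes) == 0) abort("Analyses share no genes.")
  ranks <- vapply(analyses, function(a) {
    p <- a$p_value[match(genes, a$gene_id)]
    if (anyNA(p)) abort("Missing p-values on the shared gene universe.")
    rank(p, ties.method = "average")
  }, numeric(length(genes)))
  colnames(ranks) <- paste0("rank_", nm)
  out <- dplyr::bind_cols(
    tibble::tibble(gene_id = genes),
    tibble::as_tibble(ranks)
  )
  out$cumulative_rank <- rowSums(ranks)
  out$log10_cumulative_rank <- log10(out$cumulative_rank)
  out <- out[order(out$cumulative_rank, out$gene_id), ]
  structure(out, class = c("nrx_cumrank", class(tibble::tibble())))
}

#' Meta-analysis of sex-by-stress interactions across experiments
#'
#' Merges experiments profiling both sexes, corrects batch structure with
#' surrogate variables, fits `counts ~ stress * sex + SVs`, and tests the
#' stress:sex interaction with the conditional FDR rule (conditioning on the
#' stress main effect). Interaction log2 fold changes are additionally
#' shrunk with the normal-prior posterior mean ([shrink_logfc()]) so that
#' apparent sex differences driven by noisy coefficient estimates are
#' discounted.
#'
#' @inheritParams combined_response_analysis
#' @param alpha_main Main-effect FDR defining the conditioning set.
#' @return An `nrx_cfdr` tibble with `interaction_log2fc`,
#'   `interaction_log2fc_shrunk`, and attributes `n_sv` and `samples`.
#' @export
sex_interaction_meta <- function(experiments, min_cpm = 1, n_sv = NULL,
                                 sv_seed = 1, alpha_main = 0.05) {
  merged <- merge_experiments(experiments)
  s <- merged$samples
  for (v in c("sex", "stress")) {
    if (!v %in% names(s)) abort(sprintf("Sample tables need a `%s` column.", v))
    if (!is.factor(s[[v]])) s[[v]] <- factor(s[[v]])
    s[[v]] <- droplevels(s[[v]])
  }
  for (e in unique(s$experiment)) {
    if (length(unique(s$sex[s$experiment == e])) < 2) {
      abort(sprintf("Experiment `%s` includes a single sex.", e))
    }
  }
  s$filter_group <- interaction(s$experiment, s$stress, s$sex, drop = TRUE)
  counts <- filter_low_expression(merged$counts, min_cpm = min_cpm,
                                  min_samples = min(table(s$filter_group)))
  nf <- tmm_factors(counts)
  X0 <- build_design(s, ~ stress * sex)
  vst <- variance_stabilize(counts, nf)
  if (is.null(n_sv)) n_sv <- num_sv(vst, design = X0, seed = sv_seed)
  X <- X0
  if (n_sv > 0) {
    sv <- sv_matrix(estimate_surrogate_variables(vst, design = X0, n_sv = n_sv))
    X <- cbind(X0, sv)
    if (qr(X)$rank < ncol(X)) abort("Surrogate variables are confounded with the design.")
  }
  common <- estimate_common_dispersion(counts, s, X, nf)
  fit <- fit_glm(counts, s, X, nf, common)

  coefs <- colnames(fit$design)
  main_coef <- grep("^stress", coefs[!grepl(":", coefs)], value = TRUE)[1]
  int_coef <- grep(":", coefs, value = TRUE)[1]
  main <- ql_ftest(fit, main_coef)
  inter <- ql_ftest(fit, int_coef)
  res <- conditional_interaction_fdr(main, inter, alpha_main = alpha_main)
  res$interaction_log2fc_shrunk <- shrink_logfc(inter$log2fc, inter$se_log2fc)
  attr(res, "n_sv") <- n_sv
  attr(res, "samples") <- s
  res
}
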