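#' Genewise negative-binomial exact test for two-group comparisons
#'
#' Counts are first rescaled to the geometric mean of the effective library
#' sizes (proportional scaling, rounded) so the two groups are comparable.
#' Group sums are then modelled as NB — a sum of n iid NB(mu, phi) counts has
#' mean n*mu and dispersion phi/n — and, conditional on the gene's total, the
#' two-sided p-value is the "doubletail" sum of the probabilities of all
#' group-one sums at most as probable as the observed one. log2 fold changes
#' come from group mean CPMs with a prior count of 0.125 (display only; the
#' prior never enters the test).
#'
#' @param counts Filtered count tibble.
#' @param samples Sample tibble.
#' @param group Name of a two-level factor column in `samples`, or a
#'   length-`n_samples` vector. The first level is the reference; the
#'   reported log2FC is second level vs first.
#' @param factors Norm-factor table from [tmm_factors()] (or `NULL`).
#' @param dispersion An `nrx_dispersion`, or numeric (scalar or per-gene).
#' @return An `nrx_dge` tibble: `gene_id`, `log2fc`, `avg_log2cpm`,
#'   `statistic` (NA: the test is conditional, not statistic-based),
#'   `p_value`, `fdr`, `test`, `contrast`.
#' @export
exact_test <- function(counts, samples, group, factors = NULL, dispersion) {
  m <- count_matrix(counts)
  samples <- check_samples(m, samples)
  g <- if (length(group) == 1 && is.character(group)) {
    if (!group %in% names(samples)) abort(sprintf("No `%s` column in samples.", group))
    samples[[group]]
  } else group
  g <- if (is.factor(g)) droplevels(g) else factor(g)
  if (nlevels(g) != 2) abort("Exact test needs exactly two groups.")
  if (any(table(g) < 2)) abort("Each group needs n >= 2.")
  phi <- resolve_phi(dispersion, rownames(m))

  eff <- effective_lib_sizes(m, factors)
  geo <- exp(mean(log(eff)))
  pseudo <- round(sweep(m, 2, geo / eff, `*`))
  i1 <- g == levels(g)[1]
  n1 <- sum(i1); n2 <- sum(!i1)
  s1 <- rowSums(pseudo[, i1, drop = FALSE])
  s2 <- rowSums(pseudo[, !i1, drop = FALSE])

  p <- vapply(seq_len(nrow(m)), function(i) {
    exact_nb_doubletail(s1[i], s2[i], n1, n2, phi[i])
  }, numeric(1))

  prior <- 0.125
  log2fc <- unname(log2((s2 / n2 + prior) / (s1 / n1 + prior)))
  avg <- unname(log2(((s1 + s2) / (n1 + n2) + prior) / geo * 1e6))
  new_dge_tbl(tibble::tibble(
    gene_id = rownames(m), log2fc = log2fc, avg_log2cpm = avg,
    statistic = NA_real_, p_value = p, fdr = bh_adjust(p),
    test = "exact", contrast = paste(levels(g)[2], "vs", levels(g)[1])
  ))
}

# conditional doubletail p-value for one gene; for very large totals the
# support is restricted to a window carrying all but ~1e-15 of the
# conditional mass (the observed value is always included)
exact_nb_doubletail <- function(s1, s2, n1, n2, phi) {
  t <- s1 + s2
  if (t == 0) return(1)
  mhat <- t / (n1 + n2)
  if (t <= 10000) {
    x <- 0:t
  } else {
    lo <- stats::qnbinom(1e-15, size = n1 / max(phi, 1e-10), mu = n1 * mhat)
    hi <- stats::qnbinom(1e-15, size = n1 / max(phi, 1e-10), mu = n1 * mhat,
                         lower.tail = FALSE)
    x <- max(0, min(lo, s1)):min(t, max(hi, s1))
  }
  if (phi < 1e-10) {
    # Poisson limit: conditional distribution is binomial
    lp <- stats::dbinom(x, t, n1 / (n1 + n2), log = TRUE)
  } else {
    lp <- stats::dnbinom(x, size = n1 / phi, mu = n1 * mhat, log = TRUE) +
      stats::dnbinom(t - x, size = n2 / phi, mu = n2 * mhat, log = TRUE)
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  pobs <- pr[x == s1]
  min(1, sum(pr[pr <= pobs * (1 + 1e-10)]))
}

#' Fit per-gene negative-binomial GLMs
#'
#' IRLS with log link, offsets equal to log effective library sizes, and
#' fixed per-gene dispersion; convergence when the maximum relative change in
#' the linear predictor drops below `eps` (or `maxit` iterations).
#' Coefficients are kept on the natural-log scale with a log2 view for
#' reporting. Genes with an all-zero design cell are flagged as degenerate
#' but not dropped.
#'
#' @inheritParams exact_test
#' @param design Formula, string, or design matrix (see [build_design()]).
#' @param eps,maxit IRLS convergence controls.
#' @return An `nrx_glm_fit` object; see [tidy()] and [glance()] methods.
#' @export
fit_glm <- function(counts, samples, design, factors = NULL, dispersion,
                    eps = 1e-8, maxit = 100) {
  m <- count_matrix(counts)
  samples <- check_samples(m, samples)
  X <- as_design(design, samples)
  phi <- resolve_phi(dispersion, rownames(m))
  eff <- effective_lib_sizes(m, factors)
  fit <- .nb_glm_fit_cpp(m, X, log(eff), phi, eps, maxit, TRUE)

  # degenerate genes: all zeros within some design cell (cells defined by the
  # dummy-coded columns; continuous covariates such as SVs are ignored here)
  degenerate <- rep(FALSE, nrow(m))
  bin <- apply(X, 2, function(cc) all(cc %in% c(0, 1)))
  if (any(bin)) {
    cell <- interaction(as.data.frame(X[, bin, drop = FALSE]), drop = TRUE)
    for (idx in split(seq_len(ncol(m)), cell)) {
      if (length(idx) >= 2) {
        degenerate <- degenerate | rowSums(m[, idx, drop = FALSE]) == 0
      }
    }
  }

  beta <- fit$beta
  dimnames(beta) <- list(rownames(m), colnames(X))
  structure(list(
    gene_id = rownames(m),
    beta = beta,
    log2fc = beta / log(2),
    fitted = fit$fitted,
    deviance = as.numeric(fit$deviance),
    df_residual = ncol(m) - ncol(X),
    design = X,
    offset = log(eff),
    dispersion = phi,
    cov = fit$cov,
    converged = as.logical(fit$converged),
    degenerate = as.logical(degenerate),
    avg_log2cpm = log2(rowMeans(sweep(m, 2, eff, `/`) * 1e6) + 0.125),
    counts = m
  ), class = "nrx_glm_fit")
}

#' @exportS3Method base::print
print.nrx_glm_fit <- function(x, ...) {
  cat(sprintf("Negative-binomial GLM fit: %d genes, %d samples, %d coefficients\n",
              length(x$gene_id), ncol(x$fitted), ncol(x$beta)))
  cat("Coefficients:", paste(colnames(x$beta), collapse = ", "), "\n")
  invisible(x)
}

#' Empirical-Bayes quasi-likelihood F-test
#'
#' The genewise quasi-dispersion (residual deviance over residual df) is
#' squeezed towards a common value with prior df estimated by moment
#' matching of the scaled-F distribution of the genewise values (falling
#' back to 10 prior df when the moment estimator is not finite). The test
#' statistic divides the per-df drop in deviance for the contrast by the
#' squeezed quasi-dispersion and is referred to an F distribution with
#' `contrast df` and `prior df + residual df` degrees of freedom.
#'
#' @param fit An `nrx_glm_fit` from [fit_glm()].
#' @param contrast A coefficient name from the design, or a numeric contrast
#'   vector in coefficient space.
#' @return An `nrx_dge` tibble with columns `gene_id`, `log2fc`,
#'   `se_log2fc`, `avg_log2cpm`, `statistic` (F), `p_value`, `fdr`, `test`,
#'   `contrast`.
#' @export
ql_ftest <- function(fit, contrast) {
  if (!inherits(fit, "nrx_glm_fit")) abort("`fit` must come from fit_glm().")
  if (fit$df_residual <= 0) {
    abort("Zero residual degrees of freedom: the quasi-likelihood test needs replication.")
  }
  X <- fit$design
  p <- ncol(X)
  if (is.character(contrast)) {
    if (!contrast %in% colnames(X)) {
      abort(sprintf("Coefficient `%s` not in the design (%s).", contrast,
                    paste(colnames(X), collapse = ", ")))
    }
    cvec <- as.numeric(colnames(X) == contrast)
    cname <- contrast
  } else {
    cvec <- as.numeric(contrast)
    if (length(cvec) != p) abort("Contrast vector length must match the design.")
    if (all(cvec == 0)) abort("Contrast vector is all zeros.")
    cname <- paste(signif(cvec, 3), collapse = ",")
  }
  # reduced design spans the subspace where the contrast is zero
  B <- qr.Q(qr(matrix(cvec, ncol = 1)), complete = TRUE)[, -1, drop = FALSE]
  Xr <- X %*% B
  df_c <- p - ncol(Xr)

  red <- .nb_glm_fit_cpp(fit$counts, Xr, fit$offset, fit$dispersion, 1e-8, 100, FALSE)
  drop_dev <- pmax(as.numeric(red$deviance) - fit$deviance, 0)

  s2 <- pmax(fit$deviance, 0) / fit$df_residual
  sq <- squeeze_var(s2, fit$df_residual)
  Fstat <- (drop_dev / df_c) / sq$var_post
  pval <- pf(Fstat, df_c, sq$df_prior + fit$df_residual, lower.tail = FALSE)

  lfc <- as.numeric(fit$beta %*% cvec) / log(2)
  cvc <- apply(fit$cov, 3, function(V) drop(t(cvec) %*% V %*% cvec))
  se <- sqrt(pmax(cvc, 0) * sq$var_post) / log(2)

  out <- new_dge_tbl(tibble::tibble(
    gene_id = fit$gene_id, log2fc = lfc, se_log2fc = se,
    avg_log2cpm = fit$avg_log2cpm, statistic = Fstat, p_value = pval,
    fdr = bh_adjust(pval), test = "ql_f", contrast = cname
  ))
  attr(out, "df_prior") <- sq$df_prior
  attr(out, "var_prior") <- sq$var_prior
  out
}

# Moment-matching squeeze of genewise variances towards a common prior.
squeeze_var <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  d0 <- 10; s02 <- if (any(ok)) mean(s2[ok]) else 1 # fallback
  if (sum(ok) >= 2) {
    z <- log(s2[ok])
    e <- z - digamma(df / 2) + log(df / 2)
    evar <- var(e) - trigamma(df / 2)
    if (is.finite(evar)) {
      if (evar > 0) {
        d0 <- 2 * trigamma_inverse(evar)
        s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
      } else {
        d0 <- Inf
        s02 <- exp(mean(e))
      }
    }
  }
  var_post <- if (is.infinite(d0)) rep(s02, length(s2))
              else (d0 * s02 + df * pmax(s2, 0)) / (d0 + df)
  list(df_prior = d0, var_prior = s02, var_post = var_post)
}

# Newton solve of trigamma(y) = x.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}
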