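# Dispersion estimation by Cox-Reid adjusted profile likelihood (APL).
# The APL of a gene at dispersion phi is the NB log-likelihood at the
# IRLS-fitted means minus half the log-determinant of the weighted Fisher
# information; maximizing it across genes gives the common dispersion, and a
# weighted combination of the genewise and pooled APL gives empirical-Bayes
# shrunken tagwise values.

golden_max <- function(f, lo, hi, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  a <- log(lo); b <- log(hi)
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(exp(x1)); f2 <- f(exp(x2))
  while ((b - a) > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(exp(x2))
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(exp(x1))
    }
  }
  exp((a + b) / 2)
}

resolve_phi <- function(dispersion, gene_ids) {
  if (inherits(dispersion, "nrx_dispersion")) {
    idx <- match(gene_ids, dispersion$tagwise$gene_id)
    if (anyNA(idx)) abort("Genes missing from the dispersion estimates.")
    return(dispersion$tagwise$dispersion[idx])
  }
  if (!is.numeric(dispersion) || any(dispersion < 0)) {
    abort("`dispersion` must be non-negative numeric or an nrx_dispersion.")
  }
  if (length(dispersion) == 1) rep(dispersion, length(gene_ids))
  else if (length(dispersion) == length(gene_ids)) dispersion
  else abort("Dispersion length must be 1 or the number of genes.")
}

#' Estimate the common negative-binomial dispersion
#'
#' Maximizes the sum across genes of the Cox-Reid adjusted profile
#' log-likelihood over dispersion, first on a log-spaced grid spanning
#' `span`, then by golden-section refinement to relative tolerance `tol`.
#' Genes whose APL cannot be evaluated (non-convergent fits) are skipped
#' with a warning.
#'
#' @param counts Filtered count tibble.
#' @param samples Sample tibble.
#' @param design Formula, string, or design matrix (see [build_design()]).
#' @param factors Norm-factor table from [tmm_factors()] (or `NULL`).
#' @param span Dispersion search interval.
#' @param grid_length Number of initial grid points.
#' @param tol Relative tolerance of the golden-section refinement.
#' @return A single positive dispersion value.
#' @export
estimate_common_dispersion <- function(counts, samples, design, factors = NULL,
                                       span = c(1e-4, 10), grid_length = 11,
                                       tol = 1e-4) {
  m <- count_matrix(counts)
  X <- as_design(design, check_samples(m, samples))
  offset <- log(effective_lib_sizes(m, factors))
  warned <- FALSE
  obj <- function(phi) {
    apl <- .nb_apl_cpp(m, X, offset, rep(phi, nrow(m)))
    bad <- !is.finite(apl)
    if (any(bad) && !warned) {
      warned <<- TRUE
      warn(sprintf("Skipping %d genes with non-evaluable profile likelihood.", sum(bad)))
    }
    sum(apl[!bad])
  }
  grid <- exp(seq(log(span[1]), log(span[2]), length.out = grid_length))
  vals <- vapply(grid, obj, numeric(1))
  k <- which.max(vals)
  lo <- grid[max(1, k - 1)]
  hi <- grid[min(grid_length, k + 1)]
  golden_max(obj, lo, hi, tol = tol)
}

#' Estimate tagwise dispersions by weighted-likelihood empirical Bayes
#'
#' Per gene, maximizes `APL_g(phi) + (prior_df / residual_df) * APL_pooled(phi)`
#' where `APL_pooled` is the across-gene mean adjusted profile likelihood
#' (interpolated from a shared log-spaced grid by a natural cubic spline).
#' The genewise term is evaluated exactly; all genes run a lockstep
#' golden-section search over `span`. Large `prior_df` shrinks every gene to
#' the common value; `prior_df = 0` gives the genewise maximum.
#'
#' @inheritParams estimate_common_dispersion
#' @param common Common dispersion from [estimate_common_dispersion()].
#' @param prior_df Prior degrees of freedom of the shared likelihood.
#' @param grid_length Grid size for the pooled-APL interpolant.
#' @return An `nrx_dispersion` object: list with `common`, `prior_df`, and
#'   `tagwise` (tibble: `gene_id`, `dispersion`).
#' @export
estimate_tagwise_dispersion <- function(counts, samples, design, factors = NULL,
                                        common, prior_df = 10,
                                        span = c(1e-4, 10), grid_length = 21,
                                        tol = 1e-4) {
  m <- count_matrix(counts)
  X <- as_design(design, check_samples(m, samples))
  offset <- log(effective_lib_sizes(m, factors))
  G <- nrow(m)
  df_res <- ncol(m) - ncol(X)
  if (df_res <= 0) abort("No residual degrees of freedom; cannot pool.")

  if (is.infinite(prior_df)) {
    tw <- rep(common, G)
  } else if (prior_df < 0) {
    abort("`prior_df` must be non-negative.")
  } else {
    wt <- prior_df / df_res
    if (wt > 0) {
      grid <- exp(seq(log(span[1]), log(span[2]), length.out = grid_length))
      apl_grid <- .nb_apl_grid_cpp(m, X, offset, grid)
      pooled <- apply(apl_grid, 2, function(x) mean(x[is.finite(x)]))
      pooled_fun <- stats::splinefun(log(grid), pooled, method = "natural")
    } else {
      pooled_fun <- function(x) 0
    }
    tw <- golden_max_vec(
      function(phi) {
        .nb_apl_cpp(m, X, offset, phi) + wt * pooled_fun(log(phi))
      },
      G, span[1], span[2], tol = tol
    )
  }
  structure(list(
    common = common, prior_df = prior_df,
    tagwise = tibble::tibble(gene_id = rownames(m), dispersion = tw)
  ), class = "nrx_dispersion")
}

# lockstep golden-section maximization of a vectorized objective: f takes a
# vector of per-gene dispersions and returns per-gene objective values.
golden_max_vec <- function(f, n, lo, hi, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  clean <- function(x) { x[!is.finite(x)] <- -Inf; x }
  a <- rep(log(lo), n); b <- rep(log(hi), n)
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- clean(f(exp(x1))); f2 <- clean(f(exp(x2)))
  while (max(b - a) > tol) {
    left <- f1 >= f2 # maximum bracketed in [a, x2]
    # shrink, reusing the interior point that survives
    b[left] <- x2[left]; x2[left] <- x1[left]; f2[left] <- f1[left]
    x1[left] <- b[left] - gr * (b[left] - a[left])
    a[!left] <- x1[!left]; x1[!left] <- x2[!left]; f1[!left] <- f2[!left]
    x2[!left] <- a[!left] + gr * (b[!left] - a[!left])
    phi_new <- numeric(n)
    phi_new[left] <- exp(x1[left]); phi_new[!left] <- exp(x2[!left])
    fnew <- clean(f(phi_new))
    f1[left] <- fnew[left]; f2[!left] <- fnew[!left]
  }
  exp((a + b) / 2)
}
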