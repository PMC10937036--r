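make_two_group <- function(G = 60, n = 4, mu = 50, phi = 0.1, seed = 51) {
  withr::with_seed(seed, {
    m <- matrix(rnbinom(G * 2 * n, mu = mu, size = 1 / phi), G, 2 * n,
                dimnames = list(sprintf("g%03d", 1:G), sprintf("s%02d", 1:(2 * n))))
    counts <- tibble::as_tibble(as.data.frame(m), rownames = "gene_id")
    samples <- tibble::tibble(sample_id = colnames(m),
                              stress = rep(c("control", "stress"), each = n))
    list(counts = counts, samples = samples, m = m)
  })
}

test_that("exact test gives p = 1 for a modal observation", {
  d <- make_two_group(G = 5, n = 3)
  m <- d$m
  m[1, ] <- 10 # identical group sums, equal libraries after equalization
  counts <- tibble::as_tibble(as.data.frame(m), rownames = "gene_id")
  nf <- tibble::tibble(sample_id = colnames(m),
                       library_size = colSums(m),
                       tmm_factor = 1,
                       effective_library_size = colSums(m) * 0)
  # equal effective libraries: bypass TMM entirely
  nf$effective_library_size <- rep(1e4, ncol(m))
  res <- exact_test(counts, d$samples, "stress", nf, 0.1)
  expect_equal(res$p_value[1], 1)
  expect_equal(res$log2fc[1], 0)
})

test_that("exact test equals exhaustive conditional enumeration on small totals", {
  d <- make_two_group(G = 80, n = 3, mu = 12, phi = 0.15, seed = 53)
  eq_lib <- tibble::tibble(sample_id = d$samples$sample_id,
                           library_size = colSums(d$m), tmm_factor = 1,
                           effective_library_size = rep(1e4, 6))
  res <- exact_test(d$counts, d$samples, "stress", eq_lib, 0.15)
  s1 <- rowSums(d$m[, 1:3]); s2 <- rowSums(d$m[, 4:6])
  keep <- (s1 + s2) <= 200 & (s1 + s2) > 0
  oracle <- mapply(function(a, b) exact_oracle(a, b, 3, 3, 0.15),
                   s1[keep], s2[keep])
  expect_equal(res$p_value[keep], unname(oracle), tolerance = 1e-10)
})

test_that("exact test is invariant to sample order and flips sign on relabel", {
  d <- make_two_group(G = 50, n = 4, seed = 55)
  nf <- tmm_factors(d$counts)
  res <- exact_test(d$counts, d$samples, "stress", nf, 0.1)

  perm <- withr::with_seed(2, sample(nrow(d$samples)))
  counts_p <- d$counts[, c(1, perm + 1)]
  res_p <- exact_test(counts_p, d$samples[perm, ], "stress", nf, 0.1)
  expect_equal(res$p_value, res_p$p_value)

  flipped <- factor(d$samples$stress, levels = c("stress", "control"))
  res_f <- exact_test(d$counts, d$samples, flipped, nf, 0.1)
  expect_equal(res_f$p_value, res$p_value)
  expect_equal(res_f$log2fc, -res$log2fc)
})

test_that("exact test p-values are uniform or super-uniform on Poisson nulls", {
  withr::with_seed(57, {
    G <- 1500
    m <- matrix(rpois(G * 12, lambda = 60), G, 12,
                dimnames = list(sprintf("g%04d", 1:G), sprintf("s%02d", 1:12)))
  })
  counts <- tibble::as_tibble(as.data.frame(m), rownames = "gene_id")
  samples <- tibble::tibble(sample_id = colnames(m),
                            stress = rep(c("control", "stress"), each = 6))
  nf <- tibble::tibble(sample_id = colnames(m), library_size = colSums(m),
                       tmm_factor = 1, effective_library_size = rep(720, 12) * 1)
  nf$effective_library_size <- rep(mean(colSums(m)), 12)
  res <- exact_test(counts, samples, "stress", nf, 0)
  grid <- seq(0.05, 0.95, by = 0.05)
  ecdf_vals <- stats::ecdf(res$p_value)(grid)
  expect_true(all(ecdf_vals <= grid + 2.5 * sqrt(grid * (1 - grid) / G)))
})

test_that("GLM reproduces group means and rejects rank-deficient designs", {
  # saturated intercept: constant counts, equal libraries
  counts <- tibble::tibble(gene_id = "g1", s1 = 40, s2 = 40, s3 = 40, s4 = 40)
  samples <- tibble::tibble(sample_id = paste0("s", 1:4))
  nf <- tibble::tibble(sample_id = paste0("s", 1:4), library_size = 40,
                       tmm_factor = 1, effective_library_size = 1000)
  fit <- fit_glm(counts, samples, ~1, nf, 0.1)
  expect_equal(as.numeric(fit$fitted), rep(40, 4), tolerance = 1e-6)

  # saturated one-factor design reproduces groupwise mean CPMs
  d <- make_two_group(G = 30, n = 4, seed = 59)
  eq <- tibble::tibble(sample_id = d$samples$sample_id,
                       library_size = colSums(d$m), tmm_factor = 1,
                       effective_library_size = rep(1e4, 8))
  fit2 <- fit_glm(d$counts, d$samples, "stress", eq, 0.1)
  gm <- cbind(rowMeans(d$m[, 1:4]), rowMeans(d$m[, 5:8]))
  fitted_gm <- cbind(fit2$fitted[, 1], fit2$fitted[, 5])
  expect_equal(unname(fitted_gm), unname(gm), tolerance = 1e-6)

  X <- build_design(d$samples, "stress")
  expect_error(fit_glm(d$counts, d$samples, cbind(X, 0), eq, 0.1), "rank")
})

test_that("GLM recovers simulated fold changes", {
  # balanced up/down effects keep the TMM assumption (most genes null or
  # symmetric) intact, so fold changes are estimated without composition bias
  cfg <- two_group_config(n_genes = 500, n = 6, phi = 0.05, seed = 61,
                          frac_stress_de = 0.2,
                          effect_size = c(mean = 1, sd = 0, prob_up = 0.5))
  sim <- simulate_experiment(cfg)
  out <- run_standard_dge(sim, "stress", "stressstress")
  truth <- sim$truth[match(out$res$gene_id, sim$truth$gene_id), ]
  mean_lfc <- mean(out$res$log2fc[truth$de_stress] *
                     sign(truth$lfc_stress[truth$de_stress]))
  expect_gt(mean_lfc, 0.9)
  expect_lt(mean_lfc, 1.1)

  td <- tidy(out$fit)
  expect_setequal(names(td), c("gene_id", "term", "estimate", "std_error"))
  expect_equal(nrow(td), length(out$fit$gene_id) * 2)
  g <- glance(out$fit)
  expect_equal(g$df_residual, 10)
})

test_that("quasi-likelihood F-test agrees with the exact test where both apply", {
  cfg <- two_group_config(n_genes = 600, n = 6, phi = 0.08, seed = 63,
                          frac_stress_de = 0.2)
  sim <- simulate_experiment(cfg)
  counts <- filter_low_expression(sim$counts, sim$samples)
  nf <- tmm_factors(counts)
  common <- estimate_common_dispersion(counts, sim$samples, "stress", nf)
  disp <- estimate_tagwise_dispersion(counts, sim$samples, "stress", nf, common)
  fit <- fit_glm(counts, sim$samples, "stress", nf, disp)
  ql <- ql_ftest(fit, "stressstress")
  et <- exact_test(counts, sim$samples, "stress", nf, disp)
  strong <- ql$p_value < 0.01
  agree <- sign(ql$log2fc[strong]) == sign(et$log2fc[strong])
  expect_gte(mean(agree), 0.99)
})

test_that("QL F-test rejects invalid contrasts and unreplicated designs", {
  d <- make_two_group(G = 80, n = 3, seed = 65)
  nf <- tmm_factors(d$counts)
  fit <- fit_glm(d$counts, d$samples, "stress", nf, 0.1)
  expect_error(ql_ftest(fit, c(0, 0)), "zeros")
  expect_error(ql_ftest(fit, "nonexistent"), "not in the design")
  expect_error(ql_ftest(fit, c(0, 1, 1)), "length")

  # saturated design: no residual df
  sat <- tibble::tibble(sample_id = d$samples$sample_id,
                        cell = paste0("c", seq_len(6)))
  fit_sat <- fit_glm(d$counts, sat, "cell", nf, 0.1)
  expect_error(ql_ftest(fit_sat, "cellc2"), "replication")
})

test_that("contrast vectors reproduce coefficient tests", {
  d <- make_two_group(G = 40, n = 4, seed = 67)
  nf <- tmm_factors(d$counts)
  fit <- fit_glm(d$counts, d$samples, "stress", nf, 0.08)
  by_name <- ql_ftest(fit, "stressstress")
  by_vec <- ql_ftest(fit, c(0, 1))
  expect_equal(by_vec$p_value, by_name$p_value, tolerance = 1e-8)
  expect_equal(by_vec$log2fc, by_name$log2fc, tolerance = 1e-10)
})
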