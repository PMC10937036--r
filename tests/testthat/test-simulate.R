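test_that("null config produces zero effects and valid counts", {
  cfg <- factorial_config(n_genes = 200, frac_stress_de = 0,
                          frac_sex_baseline_de = 0, seed = 3)
  sim <- simulate_experiment(cfg)
  expect_true(all(sim$truth$lfc_stress == 0))
  expect_true(all(sim$truth$lfc_interaction == 0))
  expect_true(all(sim$truth$lfc_treatment == 0))
  m <- as.matrix(sim$counts[, -1])
  expect_true(all(m >= 0))
  expect_true(all(m == round(m)))
  expect_equal(nrow(sim$samples), sum(cfg$groups$n))
  # library sizes within 3 sd of the configured lognormal
  lib <- colSums(m)
  expect_true(all(abs(log(lib) - log(2e6)) < 3 * 0.15 + 0.5))
})

test_that("identical config and seed give bit-identical output", {
  cfg <- factorial_config(n_genes = 150, seed = 11)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  c <- simulate_experiment(factorial_config(n_genes = 150, seed = 12))
  expect_false(identical(a$counts, c$counts))
})

test_that("simulated moments recover the configured dispersion", {
  # fixed library sizes isolate the NB mean-variance structure
  cfg <- two_group_config(n_genes = 400, n = 50, phi = 0.05, seed = 5,
                          lib_sdlog = 0)
  sim <- simulate_experiment(cfg)
  m <- as.matrix(sim$counts[, -1])
  mm <- m[, sim$samples$stress == "control"]
  mu <- rowMeans(mm)
  v <- apply(mm, 1, var)
  phi_hat <- (v - mu) / mu^2
  sel <- mu > 50
  frac_ok <- mean(abs(phi_hat[sel] - 0.05) / 0.05 < 0.5)
  expect_gt(frac_ok, 0.9)
})

test_that("group means converge to design-implied means as n grows", {
  cfg <- two_group_config(n_genes = 300, n = 500, phi = 0.05, seed = 9,
                          frac_stress_de = 0.2, lib_sdlog = 0)
  sim <- simulate_experiment(cfg)
  m <- as.matrix(sim$counts[, -1])
  normalizer <- sum(2^sim$truth$baseline_log2_mean)
  implied_ctrl <- 2e6 * 2^sim$truth$baseline_log2_mean / normalizer
  implied_strs <- implied_ctrl * 2^sim$truth$lfc_stress
  stress <- sim$samples$stress == "stress"
  sel <- implied_ctrl > 20
  rel <- c(
    abs(rowMeans(m[sel, !stress]) - implied_ctrl[sel]) / implied_ctrl[sel],
    abs(rowMeans(m[sel, stress]) - implied_strs[sel]) / implied_strs[sel]
  )
  expect_lt(stats::quantile(rel, 0.95), 0.05)
})

test_that("invalid configs are rejected", {
  expect_error(sim_config(n_genes = 0), "positive")
  expect_error(sim_config(frac_stress_de = 1.2), "proportions")
  expect_error(sim_config(groups = tibble::tibble(stress = "a", n = 1)), "n >= 2")
})

test_that("multi-experiment simulation plants exactly the consistent genes", {
  cfgs <- lapply(1:3, function(i) two_group_config(n_genes = 400, n = 5,
                                                   frac_stress_de = 0.1, seed = i))
  sim <- simulate_multi_experiment(cfgs, shared_consistent_genes = 10, seed = 42)
  expect_length(sim$consistent_genes, 10)
  de_all <- sim$truth |>
    dplyr::summarise(all_de = all(de_response), .by = gene_id) |>
    dplyr::filter(all_de)
  expect_setequal(de_all$gene_id, sim$consistent_genes)
  # planted genes exceed the configured minimum effect everywhere
  planted <- sim$truth[sim$truth$gene_id %in% sim$consistent_genes, ]
  expect_true(all(abs(planted$lfc_response) >= 1))
  # same sign across experiments
  sgn <- planted |>
    dplyr::summarise(ns = dplyr::n_distinct(sign(lfc_response)), .by = gene_id)
  expect_true(all(sgn$ns == 1))
})

test_that("multi-experiment DE sets are independent when nothing is shared", {
  cfgs <- lapply(1:2, function(i) two_group_config(n_genes = 300, n = 5,
                                                   frac_stress_de = 0.1, seed = i))
  sim <- simulate_multi_experiment(cfgs, shared_consistent_genes = 0, seed = 7)
  expect_length(sim$consistent_genes, 0)
  wide <- tidyr::pivot_wider(sim$truth[, c("experiment", "gene_id", "de_response")],
                             names_from = experiment, values_from = de_response)
  expect_false(identical(wide[[2]], wide[[3]]))
  expect_error(
    simulate_multi_experiment(list(two_group_config(n_genes = 10),
                                   two_group_config(n_genes = 20)), seed = 1),
    "n_genes"
  )
})

test_that("p-value table simulator respects its distributional contract", {
  tab <- simulate_pvalue_table(400, 3, planted = 1:5, alpha_planted = 0.05, seed = 2)
  pm <- as.matrix(tab[, -1])
  expect_true(all(pm > 0 & pm <= 1))
  expect_lt(median(pm[1:5, ]), 0.05) # planted concentrate near zero
  expect_error(simulate_pvalue_table(10, 2, alpha_planted = 0), "positive")
  expect_error(simulate_pvalue_table(10, 2, planted = 11), "universe")
  expect_identical(tab, simulate_pvalue_table(400, 3, planted = 1:5,
                                              alpha_planted = 0.05, seed = 2))

  # null columns look uniform: KS at 0.01 rarely rejects
  rejections <- vapply(1:60, function(s) {
    p0 <- simulate_pvalue_table(300, 1, seed = s)
    suppressWarnings(stats::ks.test(p0$analysis1, "punif")$p.value) < 0.01
  }, logical(1))
  expect_gte(mean(!rejections), 0.95)
})
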