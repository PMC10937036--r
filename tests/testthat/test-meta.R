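test_that("surrogate variables recover a planted batch and stay orthonormal", {
  # batch crossed with (orthogonal to) the biological design
  cfg <- sim_config(
    n_genes = 800,
    groups = tibble::tibble(stress = rep(c("control", "stress"), 2),
                            batch = rep(c("b1", "b2"), each = 2), n = 5),
    dispersion = c(a = 0, b = 0.05, sdlog = 0),
    lib_size = c(median = 2e6, sdlog = 0.1),
    baseline_logmean = c(location = 6, scale = 1.5),
    frac_stress_de = 0.1, seed = 71
  )
  sim <- simulate_experiment(cfg)
  counts <- filter_low_expression(sim$counts, sim$samples)
  nf <- tmm_factors(counts)
  vst <- variance_stabilize(counts, nf)
  sv <- estimate_surrogate_variables(vst, sim$samples, ~stress, n_sv = 2)
  svm <- as.matrix(sv[, -1])
  expect_equal(crossprod(svm), diag(2), tolerance = 1e-8, ignore_attr = TRUE)
  batch_ind <- as.numeric(sim$samples$batch == "b2")
  expect_gte(abs(cor(svm[, 1], batch_ind)), 0.9)

  # expression exactly in the design space -> no residual structure
  X <- build_design(sim$samples, ~stress)
  flat <- X %*% matrix(c(5, 1), ncol = 1)
  expr0 <- tibble::as_tibble(as.data.frame(
    matrix(rep(t(flat), 3), nrow = 3, byrow = TRUE,
           dimnames = list(paste0("g", 1:3), sim$samples$sample_id))
  ), rownames = "gene_id")
  expect_error(estimate_surrogate_variables(expr0, sim$samples, ~stress, n_sv = 1),
               "n_sv = 0")
  expect_error(estimate_surrogate_variables(vst, sim$samples, ~stress,
                                            n_sv = nrow(sim$samples)), "n_sv")
})

test_that("parallel analysis counts surrogate variables sensibly", {
  # equal library sizes: residuals are pure exchangeable noise
  zeros <- vapply(1:10, function(s) {
    sim <- simulate_experiment(two_group_config(n_genes = 300, n = 6,
                                                phi = 0.05, seed = 73 + s,
                                                lib_sdlog = 0))
    vst <- variance_stabilize(sim$counts, tmm_factors(sim$counts))
    num_sv(vst, sim$samples, ~stress, seed = s)
  }, numeric(1))
  expect_gte(mean(zeros == 0), 0.9)

  cfg_batch <- sim_config(
    n_genes = 300,
    groups = tibble::tibble(stress = rep(c("control", "stress"), 2),
                            batch = rep(c("b1", "b2"), each = 2), n = 5),
    dispersion = c(a = 0, b = 0.05, sdlog = 0),
    lib_size = c(median = 2e6, sdlog = 0.1),
    baseline_logmean = c(location = 6, scale = 1.5),
    batch_sdlog2 = 0.5, seed = 75
  )
  simb <- simulate_experiment(cfg_batch)
  vstb <- variance_stabilize(simb$counts, tmm_factors(simb$counts))
  nb <- num_sv(vstb, simb$samples, ~stress, seed = 2)
  expect_gte(nb, 1)
  expect_identical(nb, num_sv(vstb, simb$samples, ~stress, seed = 2))
})

test_that("cumulative rank reproduces hand examples and the oracle", {
  # hand-computable 3 genes x 2 analyses
  ptbl <- tibble::tibble(gene_id = c("gA", "gB", "gC"),
                         a1 = c(0.001, 0.01, 0.9), a2 = c(0.5, 0.002, 0.9))
  cr <- cumulative_rank(ptbl)
  expect_equal(cr$cumulative_rank[match(c("gA", "gB", "gC"), cr$gene_id)],
               c(3, 3, 6))
  expect_equal(cr$gene_id[1:2], c("gA", "gB")) # ties broken lexicographically
  expect_equal(cr$log10_cumulative_rank, log10(cr$cumulative_rank))

  # a gene ranked first everywhere gets cumulative rank K and tops the table
  tab <- simulate_pvalue_table(50, 4, planted = 7, alpha_planted = 1e-6, seed = 9)
  cr2 <- cumulative_rank(tab)
  expect_equal(cr2$gene_id[1], "gene00007")
  expect_equal(cr2$cumulative_rank[1], 4)

  # random table with injected ties equals the sort-and-sum oracle
  tab3 <- simulate_pvalue_table(200, 3, seed = 10)
  tab3$analysis1[5:10] <- 0.42 # forced ties
  cr3 <- cumulative_rank(tab3)
  oracle <- cumrank_oracle(tab3)
  expect_equal(cr3$gene_id, oracle$gene_id)
  expect_equal(cr3$cumulative_rank, oracle$cumulative_rank)

  expect_error(cumulative_rank(tab3[, 1:2]), "two analyses")
})

test_that("cumulative rank is invariant to analysis order and monotone p transforms", {
  tab <- simulate_pvalue_table(150, 3, planted = 1:5, alpha_planted = 0.01, seed = 12)
  analyses <- lapply(setdiff(names(tab), "gene_id"), function(n) {
    tibble::tibble(gene_id = tab$gene_id, p_value = tab[[n]])
  })
  names(analyses) <- setdiff(names(tab), "gene_id")
  a <- cumulative_rank(analyses)
  b <- cumulative_rank(rev(analyses))
  expect_equal(a$gene_id, b$gene_id)
  expect_equal(a$cumulative_rank, b$cumulative_rank)

  # strictly monotone transform of p-values changes nothing
  analyses_t <- analyses
  analyses_t[[2]]$p_value <- sqrt(analyses_t[[2]]$p_value)
  expect_equal(cumulative_rank(analyses_t)$cumulative_rank, a$cumulative_rank)
})

test_that("combined-response analysis recovers planted consistent genes", {
  cfgs <- lapply(1:3, function(i) {
    two_group_config(n_genes = 800, n = 6, phi = 0.05, seed = 80 + i,
                     frac_stress_de = 0.05)
  })
  sim <- simulate_multi_experiment(cfgs, shared_consistent_genes = 10, seed = 81)
  labels <- stats::setNames(
    rep(list(c(control = "control", stress = "response")), 3),
    names(sim$experiments)
  )
  res <- combined_response_analysis(sim, labels)
  hits <- res$gene_id[res$fdr < 0.05]
  found <- intersect(sim$consistent_genes, hits)
  expect_gte(length(found), 8)

  # disjoint gene universes are an error
  e1 <- sim$experiments[[1]]
  e2 <- sim$experiments[[2]]
  e2$counts$gene_id <- paste0("other_", e2$counts$gene_id)
  expect_error(merge_experiments <- combined_response_analysis(
    list(a = e1, b = e2), labels = list(a = labels[[1]], b = labels[[2]])
  ), "share no gene")

  # an experiment mapped to a single response level is an error
  labels_bad <- labels
  labels_bad[[1]] <- c(control = "control", stress = "control")
  expect_error(combined_response_analysis(sim, labels_bad), "one response level")
})

test_that("sex meta-analysis separates baseline sex effects from interactions", {
  cfgs <- lapply(1:2, function(i) {
    sex_config(n_genes = 600, n = 6, seed = 90 + i, frac_stress_de = 0.15,
               frac_sex_baseline_de = 0.1)
  })
  sim <- simulate_multi_experiment(cfgs, shared_consistent_genes = 0, seed = 91)
  res <- sex_interaction_meta(sim)
  expect_s3_class(res, "nrx_cfdr")
  expect_true("interaction_log2fc_shrunk" %in% names(res))

  # no planted interaction: no or almost no interaction discoveries
  expect_lte(sum(res$interaction_fdr < 0.05, na.rm = TRUE), 1)

  # baseline sex-DE genes show up in the sex main effect, not the interaction
  truth1 <- sim$experiments[[1]]$truth
  sex_genes <- truth1$gene_id[truth1$de_sex]
  merged <- merge_experiments(sim)
  s <- merged$samples
  s$filter_group <- interaction(s$experiment, s$stress, s$sex, drop = TRUE)
  counts <- filter_low_expression(merged$counts, min_cpm = 1,
                                  min_samples = min(table(s$filter_group)))
  nf <- tmm_factors(counts)
  common <- estimate_common_dispersion(counts, s, ~ stress * sex, nf)
  disp <- estimate_tagwise_dispersion(counts, s, ~ stress * sex, nf, common)
  fit <- fit_glm(counts, s, ~ stress * sex, nf, disp)
  sex_main <- ql_ftest(fit, "sexM")
  de_sex_found <- sex_main$gene_id[sex_main$fdr < 0.05]
  # most detected sex-main genes are truly sex-DE at baseline in experiment 1
  overlap <- mean(de_sex_found %in% sex_genes)
  expect_gte(overlap, 0.6)
  # and recovered interaction discoveries do not pile up on them
  int_hits <- res$gene_id[which(res$interaction_fdr < 0.05)]
  expect_lte(length(intersect(int_hits, sex_genes)), 1)

  # single-sex input is rejected
  ss <- sim$experiments
  ss[[1]]$samples$sex <- "F"
  expect_error(sex_interaction_meta(ss), "single sex")
})
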