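# Shared fixtures: all data are generated in code, sized for fast tests.

# two-group design, constant dispersion model (a = 0, sdlog = 0 gives every
# gene exactly dispersion `phi`)
two_group_config <- function(n_genes = 500, n = 6, phi = 0.1, seed = 1,
                             frac_stress_de = 0, lib_sdlog = 0.1,
                             disp_sdlog = 0, ...) {
  sim_config(
    n_genes = n_genes,
    groups = tibble::tibble(stress = c("control", "stress"), n = n),
    dispersion = c(a = 0, b = phi, sdlog = disp_sdlog),
    lib_size = c(median = 2e6, sdlog = lib_sdlog),
    baseline_logmean = c(location = 6, scale = 1.5),
    frac_stress_de = frac_stress_de,
    seed = seed, ...
  )
}

factorial_config <- function(n_genes = 1000, n = 6, seed = 1, ...) {
  sim_config(
    n_genes = n_genes,
    groups = tibble::tibble(
      stress = rep(c("control", "stress"), 2),
      treatment = rep(c("vehicle", "propranolol"), each = 2),
      n = n
    ),
    lib_size = c(median = 2e6, sdlog = 0.15),
    baseline_logmean = c(location = 6, scale = 1.5),
    seed = seed, ...
  )
}

sex_config <- function(n_genes = 800, n = 6, seed = 1, ...) {
  sim_config(
    n_genes = n_genes,
    groups = tibble::tibble(
      stress = rep(c("control", "stress"), 2),
      sex = rep(c("F", "M"), each = 2),
      n = n
    ),
    lib_size = c(median = 2e6, sdlog = 0.15),
    baseline_logmean = c(location = 6, scale = 1.5),
    seed = seed, ...
  )
}

# small deterministic count tibble
toy_counts <- function() {
  tibble::tibble(
    gene_id = c("geneA", "geneB"),
    s1 = c(5, 0), s2 = c(3, 12)
  )
}

# independent quadratic-time BH oracle: q_i = min over j with p_j >= p_i of
# p_j * m / #(p <= p_j), capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    cand <- vapply(p[p >= pi], function(pj) pj * m / sum(p <= pj), numeric(1))
    min(1, min(cand))
  }, numeric(1))
}

# literal transcription of the TMM definition, independent of the package's
# internal code paths
tmm_oracle <- function(m, trim_M = 0.30, trim_A = 0.05) {
  lib <- colSums(m)
  f75 <- apply(m, 2, function(x) unname(quantile(x, 0.75))) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- rep(1, ncol(m))
  for (s in seq_len(ncol(m))) {
    if (s == ref) next
    ok <- m[, s] > 0 & m[, ref] > 0
    ys <- m[ok, s]; yr <- m[ok, ref]
    Ns <- lib[s]; Nr <- lib[ref]
    M <- log2((ys / Ns) / (yr / Nr))
    A <- 0.5 * log2((ys / Ns) * (yr / Nr))
    v <- 1 / ys - 1 / Ns + 1 / yr - 1 / Nr
    k <- length(M)
    keepM <- order(M)[(floor(k * trim_M) + 1):(k - floor(k * trim_M))]
    keepA <- order(A)[(floor(k * trim_A) + 1):(k - floor(k * trim_A))]
    keep <- intersect(keepM, keepA)
    fac[s] <- 2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  }
  fac / exp(mean(log(fac)))
}

# exhaustive conditional doubletail oracle for the exact test (small totals):
# works directly on unnormalized joint probabilities
exact_oracle <- function(s1, s2, n1, n2, phi) {
  t <- s1 + s2
  if (t == 0) return(1)
  mhat <- t / (n1 + n2)
  joint <- vapply(0:t, function(x) {
    dnbinom(x, size = n1 / phi, mu = n1 * mhat) *
      dnbinom(t - x, size = n2 / phi, mu = n2 * mhat)
  }, numeric(1))
  pobs <- joint[s1 + 1]
  sum(joint[joint <= pobs * (1 + 1e-10)]) / sum(joint)
}

# sort-and-sum cumulative-rank oracle over a wide p-value tibble
cumrank_oracle <- function(ptbl) {
  pm <- as.matrix(ptbl[, -1])
  ranks <- apply(pm, 2, rank) # average ranks on ties by default
  cum <- rowSums(ranks)
  ord <- order(cum, ptbl$gene_id)
  tibble::tibble(gene_id = ptbl$gene_id[ord], cumulative_rank = cum[ord])
}

# standard QL flow: the QL fit pairs with the common dispersion
run_standard_dge <- function(sim, design, coef) {
  counts <- filter_low_expression(sim$counts, sim$samples)
  nf <- tmm_factors(counts)
  common <- estimate_common_dispersion(counts, sim$samples, design, nf)
  fit <- fit_glm(counts, sim$samples, design, nf, common)
  list(fit = fit, res = ql_ftest(fit, coef), counts = counts, nf = nf,
       common = common)
}

write_pipeline_config <- function(dir, n_genes = 500) {
  cfg <- list(
    seed = 33,
    stages = c("simulate", "dge", "rank", "report"),
    simulate = list(
      shared_consistent_genes = 8,
      min_consistent_lfc = 1.5,
      experiments = lapply(1:2, function(i) list(
        name = paste0("exp", i),
        n_genes = n_genes,
        groups = list(list(stress = "control", n = 6),
                      list(stress = "stress", n = 6)),
        dispersion = list(a = 0, b = 0.05, sdlog = 0),
        lib_size = list(median = 1e6, sdlog = 0.1),
        baseline_logmean = list(location = 6, scale = 1.5),
        frac_stress_de = 0.05
      ))
    ),
    dge = list(analyses = lapply(1:2, function(i) list(
      name = paste0("exp", i, "_stress"),
      experiment = paste0("exp", i),
      test = "ql", design = "stress", coef = "stressstress"
    ))),
    rank = list(analyses = c("exp1_stress", "exp2_stress")),
    report = list(volcano = "exp1_stress", top_n = 10)
  )
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path)
  path
}
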