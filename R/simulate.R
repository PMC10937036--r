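#' Simulation configuration for factorial RNA-seq experiments
#'
#' Defines one synthetic bulk RNA-seq experiment: a negative-binomial count
#' model with per-gene baselines and dispersions, a factorial sample layout,
#' and the effect pattern the downstream analyses are designed to detect.
#' Defaults emulate a stress x treatment design on hippocampal tissue:
#' 14,000 expressed genes, n = 6 animals per group, roughly 20 million reads
#' per sample, ten percent of genes stress-responsive at |log2FC| around 1,
#' half of those blocked by the drug (the interaction coefficient cancels
#' the stress effect exactly), sex affecting baseline expression only, and
#' the drug doing nothing at baseline.
#'
#' @param n_genes Number of genes.
#' @param groups Data frame of factor columns plus an `n` column giving the
#'   per-group sample size. Factor columns are taken in the order given; the
#'   first row's levels act as reference levels. Recognized effect-bearing
#'   columns: `stress`, `treatment`, `sex`, `batch`.
#' @param baseline_logmean `c(location, scale)` of the normal distribution of
#'   per-gene baseline log2 relative expression.
#' @param dispersion `c(a, b, sdlog)`: per-gene dispersion `a / mean + b`
#'   multiplied by lognormal noise with log-sd `sdlog`; variance of counts is
#'   `mu + phi * mu^2`.
#' @param lib_size `c(median, sdlog)` of the lognormal library-size
#'   distribution (reads per sample).
#' @param frac_stress_de Proportion of genes with a stress main effect.
#' @param frac_blocked Proportion of stress-responsive genes whose
#'   stress:treatment interaction exactly cancels the stress effect.
#' @param effect_size `c(mean, sd, prob_up)`: |log2FC| is `|N(mean, sd)|`,
#'   positive sign with probability `prob_up`.
#' @param frac_sex_baseline_de Proportion of genes with a baseline sex effect.
#' @param frac_treatment_de Proportion of genes with a treatment effect at
#'   baseline (default 0: the drug alone changes nothing).
#' @param frac_stress_sex_de Proportion of stress-responsive genes whose
#'   response is additionally modulated by sex (default 0: the stress
#'   response is sex-independent, which is the pattern being emulated;
#'   non-zero values plant a true stress:sex interaction for power checks).
#' @param batch_sdlog2 SD of per-batch per-gene log2 shifts (applied to
#'   non-reference batch levels, and to non-reference experiments in
#'   [simulate_multi_experiment()]).
#' @param seed Integer seed; identical config + seed gives bit-identical data.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 14000,
                       groups = default_sim_groups(),
                       baseline_logmean = c(location = 4, scale = 2),
                       dispersion = c(a = 1, b = 0.05, sdlog = 0.3),
                       lib_size = c(median = 2e7, sdlog = 0.25),
                       frac_stress_de = 0.10,
                       frac_blocked = 0.50,
                       effect_size = c(mean = 1, sd = 0.3, prob_up = 0.5),
                       frac_sex_baseline_de = 0.10,
                       frac_treatment_de = 0,
                       frac_stress_sex_de = 0,
                       batch_sdlog2 = 0.3,
                       seed = 1) {
  groups <- tibble::as_tibble(groups)
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 1) {
    abort("`n_genes` must be a positive count.")
  }
  if (!"n" %in% names(groups) || ncol(groups) < 2) {
    abort("`groups` needs at least one factor column and an `n` column.")
  }
  if (any(groups$n < 2)) abort("Each group needs n >= 2 samples.")
  props <- c(frac_stress_de, frac_blocked, frac_sex_baseline_de,
             frac_treatment_de, frac_stress_sex_de)
  if (any(props < 0 | props > 1)) abort("All proportions must lie in [0, 1].")
  if (dispersion[["a"]] < 0 || dispersion[["b"]] <= 0 || dispersion[["sdlog"]] < 0) {
    abort("Dispersion model needs a >= 0, b > 0, sdlog >= 0.")
  }
  if (lib_size[["median"]] <= 0) abort("Library-size median must be positive.")
  if (missing(seed) && is.null(seed)) abort("`seed` is mandatory.")
  structure(list(
    n_genes = as.integer(n_genes), groups = groups,
    baseline_logmean = baseline_logmean, dispersion = dispersion,
    lib_size = lib_size, frac_stress_de = frac_stress_de,
    frac_blocked = frac_blocked, effect_size = effect_size,
    frac_sex_baseline_de = frac_sex_baseline_de,
    frac_treatment_de = frac_treatment_de,
    frac_stress_sex_de = frac_stress_sex_de,
    batch_sdlog2 = batch_sdlog2, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_sim_groups <- function() {
  tibble::tibble(
    stress = rep(c("control", "stress"), 2),
    treatment = rep(c("vehicle", "propranolol"), each = 2),
    n = 6L
  )
}

sign_draw <- function(k, prob_up) {
  ifelse(runif(k) < prob_up, 1, -1)
}

#' Simulate one factorial RNA-seq experiment with ground truth
#'
#' Draws counts gene-by-sample from `NB(mean, phi)` where
#' `mean = libsize * 2^(baseline + design-weighted log2 effects) / normalizer`
#' and the normalizer is the total baseline weight, so realized library sizes
#' track the configured distribution.
#'
#' @param config A [sim_config()].
#' @param .forced_response,.exclude_de,.extra_log2_shift Internal hooks used
#'   by [simulate_multi_experiment()] to plant consistent responder genes,
#'   keep gene sets disjoint, and add per-experiment batch shifts.
#'
#' @return A list with `counts` (tibble: `gene_id` + samples), `samples`
#'   (tibble of per-sample factors; factor columns carry their reference
#'   level first), and `truth` (per-gene baseline, dispersion, per-coefficient
#'   log2FC and DE flags).
#' @export
simulate_experiment <- function(config, .forced_response = NULL,
                                .exclude_de = integer(0),
                                .extra_log2_shift = NULL) {
  if (!inherits(config, "sim_config")) abort("`config` must come from sim_config().")
  G <- config$n_genes
  grp <- config$groups
  fac_cols <- setdiff(names(grp), "n")

  with_seed(config$seed, {
    gene_id <- sprintf("gene%05d", seq_len(G))
    baseline <- rnorm(G, config$baseline_logmean[[1]], config$baseline_logmean[[2]])
    w <- 2^baseline
    normalizer <- sum(w)
    mu_ref <- config$lib_size[["median"]] * w / normalizer
    phi <- (config$dispersion[["a"]] / mu_ref + config$dispersion[["b"]]) *
      rlnorm(G, 0, config$dispersion[["sdlog"]])

    # sample layout
    samples <- grp[rep(seq_len(nrow(grp)), grp$n), fac_cols, drop = FALSE]
    S <- nrow(samples)
    samples$sample_id <- sprintf("s%03d", seq_len(S))
    for (fc in fac_cols) {
      samples[[fc]] <- factor(samples[[fc]], levels = unique(grp[[fc]]))
    }
    samples$group <- interaction(samples[fac_cols], sep = ".", drop = TRUE)
    samples <- tibble::as_tibble(samples[, c("sample_id", fac_cols, "group")])
    lib <- rlnorm(S, log(config$lib_size[["median"]]), config$lib_size[["sdlog"]])

    es <- config$effect_size
    eligible <- setdiff(seq_len(G), .exclude_de)
    draw_set <- function(frac) sort(sample(eligible, round(frac * length(eligible))))

    lfc_stress <- lfc_treat <- lfc_inter <- lfc_sex <- numeric(G)
    stress_idx <- integer(0)
    if ("stress" %in% fac_cols) {
      stress_idx <- draw_set(config$frac_stress_de)
      lfc_stress[stress_idx] <- sign_draw(length(stress_idx), es[["prob_up"]]) *
        abs(rnorm(length(stress_idx), es[["mean"]], es[["sd"]]))
      if (!is.null(.forced_response)) {
        lfc_stress[.forced_response$genes] <- .forced_response$lfc
        stress_idx <- sort(union(stress_idx, .forced_response$genes))
      }
    }
    blocked_idx <- integer(0)
    if ("treatment" %in% fac_cols && length(stress_idx) > 0) {
      blocked_idx <- sort(sample(stress_idx, round(config$frac_blocked * length(stress_idx))))
      lfc_inter[blocked_idx] <- -lfc_stress[blocked_idx]
      treat_idx <- draw_set(config$frac_treatment_de)
      lfc_treat[treat_idx] <- sign_draw(length(treat_idx), es[["prob_up"]]) *
        abs(rnorm(length(treat_idx), es[["mean"]], es[["sd"]]))
    }
    lfc_stress_sex <- numeric(G)
    if ("sex" %in% fac_cols) {
      sex_idx <- draw_set(config$frac_sex_baseline_de)
      lfc_sex[sex_idx] <- sign_draw(length(sex_idx), es[["prob_up"]]) *
        abs(rnorm(length(sex_idx), es[["mean"]], es[["sd"]]))
      if (length(stress_idx) > 0 && config$frac_stress_sex_de > 0) {
        ss_idx <- sort(sample(stress_idx,
                              round(config$frac_stress_sex_de * length(stress_idx))))
        lfc_stress_sex[ss_idx] <- sign_draw(length(ss_idx), es[["prob_up"]]) *
          abs(rnorm(length(ss_idx), es[["mean"]], es[["sd"]]))
      }
    }
    batch_shift <- NULL
    if ("batch" %in% fac_cols && nlevels(samples$batch) > 1) {
      nb <- nlevels(samples$batch) - 1
      batch_shift <- matrix(rnorm(G * nb, 0, config$batch_sdlog2), G, nb)
      colnames(batch_shift) <- levels(samples$batch)[-1]
    }

    # per-sample log2 means
    log2mu <- matrix(baseline, G, S)
    ind <- function(col) as.integer(samples[[col]]) > 1
    if ("stress" %in% fac_cols) log2mu <- log2mu + outer(lfc_stress, ind("stress"))
    if ("treatment" %in% fac_cols) {
      log2mu <- log2mu + outer(lfc_treat, ind("treatment")) +
        outer(lfc_inter, ind("stress") & ind("treatment"))
    }
    if ("sex" %in% fac_cols) {
      log2mu <- log2mu + outer(lfc_sex, ind("sex")) +
        outer(lfc_stress_sex, ind("stress") & ind("sex"))
    }
    if (!is.null(batch_shift)) {
      bl <- as.character(samples$batch)
      for (b in colnames(batch_shift)) {
        log2mu[, bl == b] <- log2mu[, bl == b] + batch_shift[, b]
      }
    }
    if (!is.null(.extra_log2_shift)) log2mu <- log2mu + .extra_log2_shift

    mu <- sweep(2^log2mu / normalizer, 2, lib, `*`)
    counts <- matrix(rnbinom(G * S, mu = mu, size = rep(1 / phi, S)), G, S,
                     dimnames = list(gene_id, samples$sample_id))

    truth <- tibble::tibble(
      gene_id = gene_id,
      baseline_log2_mean = baseline,
      dispersion = phi,
      lfc_stress = lfc_stress,
      lfc_treatment = lfc_treat,
      lfc_interaction = lfc_inter,
      lfc_sex = lfc_sex,
      lfc_stress_sex = lfc_stress_sex,
      lfc_batch = if (is.null(batch_shift)) 0 else batch_shift[, 1],
      de_stress = lfc_stress != 0,
      de_treatment = lfc_treat != 0,
      de_interaction = lfc_inter != 0,
      de_sex = lfc_sex != 0,
      de_stress_sex = lfc_stress_sex != 0
    )
    list(counts = as_count_tbl(counts), samples = samples, truth = truth)
  })
}

#' Simulate several experiments sharing a set of consistent responder genes
#'
#' Generates one experiment per config. `shared_consistent_genes` genes are
#' planted with a stress/response effect in every experiment (same sign per
#' gene throughout, magnitude at least `min_consistent_lfc`); all other DE
#' genes are drawn independently per experiment, with the last experiment's
#' draw excluding any gene that happened to respond in all earlier ones, so
#' the planted set is exactly the set of genes responsive everywhere.
#' Experiments after the first also receive per-gene log2 batch shifts drawn
#' with each config's `batch_sdlog2`.
#'
#' @param configs List (optionally named) of [sim_config()]s with equal
#'   `n_genes`.
#' @param shared_consistent_genes Number of planted consistent genes.
#' @param seed Integer seed controlling gene selection, per-experiment seeds,
#'   and batch shifts.
#' @param min_consistent_lfc Minimum |log2FC| of planted genes per experiment.
#'
#' @return List with `experiments` (named list of `counts`/`samples`/`truth`),
#'   `truth` (long tibble: experiment, gene_id, lfc_response, de_response),
#'   and `consistent_genes` (character vector of planted gene ids).
#' @export
simulate_multi_experiment <- function(configs, shared_consistent_genes = 0,
                                      seed = 1, min_consistent_lfc = 1) {
  if (length(configs) < 2) abort("Need at least two configs.")
  ng <- vapply(configs, function(cf) cf$n_genes, integer(1))
  if (length(unique(ng)) != 1) abort("All configs must share `n_genes`.")
  G <- ng[[1]]
  if (shared_consistent_genes > G) abort("More consistent genes than genes.")
  K <- length(configs)
  nm <- names(configs) %||% paste0("exp", seq_len(K))
  nm[nm == ""] <- paste0("exp", which(nm == ""))

  plan <- with_seed(seed, {
    idx <- sort(sample.int(G, shared_consistent_genes))
    es <- configs[[1]]$effect_size
    sgn <- sign_draw(length(idx), es[["prob_up"]])
    lfcs <- lapply(seq_len(K), function(i) {
      sgn * (min_consistent_lfc + abs(rnorm(length(idx), 0, es[["sd"]])))
    })
    shifts <- lapply(seq_len(K), function(i) {
      if (i == 1) NULL else rnorm(G, 0, configs[[i]]$batch_sdlog2)
    })
    list(idx = idx, lfcs = lfcs, shifts = shifts,
         seeds = sample.int(.Machine$integer.max - 1, K))
  })

  experiments <- vector("list", K)
  de_all_prev <- NULL
  for (i in seq_len(K)) {
    cf <- configs[[i]]
    cf$seed <- plan$seeds[i]
    exclude <- plan$idx
    if (i == K && !is.null(de_all_prev)) exclude <- union(exclude, de_all_prev)
    forced <- if (shared_consistent_genes > 0) {
      list(genes = plan$idx, lfc = plan$lfcs[[i]])
    }
    ex <- simulate_experiment(cf, .forced_response = forced,
                              .exclude_de = exclude,
                              .extra_log2_shift = plan$shifts[[i]])
    ex$samples$experiment <- nm[i]
    ex$samples$sample_id <- paste(nm[i], ex$samples$sample_id, sep = "_")
    names(ex$counts)[-1] <- ex$samples$sample_id
    experiments[[i]] <- ex
    de_i <- which(ex$truth$de_stress)
    de_ind <- setdiff(de_i, plan$idx)
    de_all_prev <- if (i == 1) de_ind else intersect(de_all_prev, de_ind)
  }
  names(experiments) <- nm

  truth <- purrr::map2_dfr(experiments, nm, function(ex, n) {
    tibble::tibble(experiment = n, gene_id = ex$truth$gene_id,
                   lfc_response = ex$truth$lfc_stress,
                   de_response = ex$truth$de_stress)
  })
  gene_ids <- experiments[[1]]$truth$gene_id
  list(experiments = experiments, truth = truth,
       consistent_genes = gene_ids[plan$idx])
}

#' Simulate a gene-by-analysis p-value table
#'
#' Null entries are Uniform(0, 1); planted genes get Beta(`alpha_planted`, 1)
#' p-values in every analysis (`alpha_planted < 1` concentrates them near 0).
#' Used to exercise rank aggregation without running a full DGE analysis.
#'
#' @param n_genes,n_analyses Table dimensions.
#' @param planted Integer indices of planted genes.
#' @param alpha_planted Beta shape; must be positive. 1 gives uniform, i.e.
#'   planted genes indistinguishable from null.
#' @param seed Integer seed.
#' @return Tibble with `gene_id` and one p-value column per analysis; all
#'   entries in (0, 1].
#' @export
simulate_pvalue_table <- function(n_genes, n_analyses, planted = integer(0),
                                  alpha_planted = 0.001, seed = 1) {
  if (alpha_planted <= 0) abort("`alpha_planted` must be positive.")
  if (length(planted) > 0 && (min(planted) < 1 || max(planted) > n_genes)) {
    abort("`planted` indices must lie in the gene universe.")
  }
  with_seed(seed, {
    p <- matrix(runif(n_genes * n_analyses), n_genes, n_analyses)
    if (length(planted) > 0) {
      p[planted, ] <- rbeta(length(planted) * n_analyses, alpha_planted, 1)
    }
    p <- pmax(p, 1e-300) # keep support in (0, 1]
    colnames(p) <- paste0("analysis", seq_len(n_analyses))
    dplyr::bind_cols(tibble::tibble(gene_id = sprintf("gene%05d", seq_len(n_genes))),
                     tibble::as_tibble(p))
  })
}
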