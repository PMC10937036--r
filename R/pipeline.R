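#' Run the full analysis pipeline from a YAML config
#'
#' Stages (`simulate`, `dge`, `meta`, `rank`, `report`) execute in dependency
#' order; every intermediate table is written as TSV under `out_dir`,
#' together with a machine-readable `run_log.json` (package version, config
#' hash, seed, stages). Outputs contain no timestamps, so rerunning with an
#' identical config reproduces them bit-exactly.
#'
#' Config schema (YAML):
#' \preformatted{
#' seed: 42
#' stages: [simulate, dge, rank, report]
#' simulate:
#'   shared_consistent_genes: 10
#'   experiments:
#'     - {name: exp1, n_genes: 2000,
#'        groups: [{stress: control, n: 6}, {stress: stress, n: 6}]}
#'     - {name: exp2, ...}
#' inputs:            # alternative to simulate: load TSVs
#'   experiments:
#'     - {name: exp1, counts: path.tsv, samples: path.tsv}
#' dge:
#'   analyses:
#'     - {name: exp1_response, experiment: exp1, test: ql,
#'        design: "stress", coef: stressstress}
#'     - {name: exp1_exact, experiment: exp1, test: exact, group: stress}
#'     - {name: exp1_inter, experiment: exp1, test: ql,
#'        design: "stress*treatment", coef: stressstress,
#'        interaction: {coef: "stressstress:treatmentpropranolol"}}
#' meta:
#'   type: combined_response
#'   labels: {exp1: {control: control, stress: response}, ...}
#' rank: {analyses: [exp1_response, exp2_response]}
#' report: {volcano: [exp1_response], fdr_threshold: 0.05, top_n: 10}
#' }
#'
#' @param config_path Path to the YAML config.
#' @param out_dir Output directory (defaults to `out_dir` in the config).
#' @param seed Optional override of the config seed.
#' @param stages Optional subset of stages to run (still in pipeline order).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config_path, out_dir = NULL, seed = NULL,
                         stages = NULL) {
  if (!file.exists(config_path)) abort(sprintf("Config not found: %s", config_path))
  cfg <- yaml::read_yaml(config_path)
  seed <- seed %||% cfg$seed %||% abort("Config needs a `seed` (or pass one).")
  out_dir <- out_dir %||% cfg$out_dir %||% abort("Give `out_dir` (config or argument).")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  all_stages <- c("simulate", "dge", "meta", "rank", "report")
  want <- stages %||% cfg$stages %||% intersect(all_stages, names(cfg))
  unknown <- setdiff(want, all_stages)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown stage(s) in config `stages`: %s",
                  paste(unknown, collapse = ", ")))
  }
  want <- all_stages[all_stages %in% want]
  state <- list(experiments = NULL, dge = list(), meta = NULL, rank = NULL)

  if ("simulate" %in% want) {
    state$experiments <- pipeline_simulate(cfg, seed, out_dir)
  } else if (!is.null(cfg$inputs)) {
    state$experiments <- pipeline_load_inputs(cfg)
  }

  if ("dge" %in% want) {
    if (is.null(state$experiments)) abort("`dge` stage needs `simulate` or `inputs`.")
    state$dge <- pipeline_dge(cfg, state$experiments, out_dir)
  }
  if ("meta" %in% want) {
    if (is.null(state$experiments)) abort("`meta` stage needs `simulate` or `inputs`.")
    state$meta <- pipeline_meta(cfg, state$experiments, seed, out_dir)
  }
  if ("rank" %in% want) {
    sel <- cfg$rank$analyses %||% names(state$dge)
    missing <- setdiff(sel, names(state$dge))
    if (length(missing) > 0) {
      abort(sprintf("`rank.analyses` references unknown analyses: %s",
                    paste(missing, collapse = ", ")))
    }
    state$rank <- cumulative_rank(state$dge[sel])
    readr::write_tsv(state$rank, file.path(out_dir, "cumulative_rank.tsv"),
                     progress = FALSE)
  }
  if ("report" %in% want) {
    pipeline_report(cfg, state, out_dir)
  }

  log <- list(
    tool = "noradex",
    version = as.character(utils::packageVersion("noradex")),
    config = basename(config_path),
    config_md5 = unname(tools::md5sum(config_path)),
    seed = seed,
    stages = want
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(state)
}

parse_sim_config <- function(spec, seed) {
  groups <- lapply(spec$groups, function(g) {
    # YAML 1.1 parses a bare `n` key as boolean FALSE; undo that
    names(g)[names(g) %in% c("FALSE", "n")] <- "n"
    tibble::as_tibble(g)
  })
  spec$groups <- dplyr::bind_rows(groups)
  spec$name <- NULL
  for (fld in c("baseline_logmean", "dispersion", "lib_size", "effect_size")) {
    if (!is.null(spec[[fld]])) {
      v <- unlist(spec[[fld]])
      spec[[fld]] <- stats::setNames(as.numeric(v), names(v))
    }
  }
  spec$seed <- spec$seed %||% seed
  do.call(sim_config, spec)
}

pipeline_simulate <- function(cfg, seed, out_dir) {
  sc <- cfg$simulate %||% abort("Missing `simulate` section.")
  specs <- sc$experiments %||% abort("`simulate.experiments` is required.")
  nm <- vapply(specs, function(s) s$name %||% "", character(1))
  nm[nm == ""] <- paste0("exp", which(nm == ""))
  configs <- lapply(seq_along(specs), function(i) {
    parse_sim_config(specs[[i]], seed = seed + i)
  })
  names(configs) <- nm
  if (length(configs) >= 2) {
    sim <- simulate_multi_experiment(
      configs, shared_consistent_genes = sc$shared_consistent_genes %||% 0,
      seed = seed, min_consistent_lfc = sc$min_consistent_lfc %||% 1
    )
    exps <- sim$experiments
    readr::write_tsv(sim$truth, file.path(out_dir, "truth_long.tsv"),
                     progress = FALSE)
    writeLines(sim$consistent_genes, file.path(out_dir, "consistent_genes.txt"))
  } else {
    exps <- stats::setNames(list(simulate_experiment(configs[[1]])), nm)
  }
  for (n in names(exps)) {
    write_counts(exps[[n]]$counts, file.path(out_dir, paste0(n, "_counts.tsv")))
    write_sample_table(exps[[n]]$samples, file.path(out_dir, paste0(n, "_samples.tsv")))
    readr::write_tsv(exps[[n]]$truth, file.path(out_dir, paste0(n, "_truth.tsv")),
                     progress = FALSE)
  }
  exps
}

pipeline_load_inputs <- function(cfg) {
  specs <- cfg$inputs$experiments %||% abort("`inputs.experiments` is required.")
  exps <- lapply(specs, function(s) {
    list(counts = read_counts(s$counts), samples = read_sample_table(s$samples))
  })
  names(exps) <- vapply(specs, function(s) s$name, character(1))
  exps
}

pipeline_dge <- function(cfg, exps, out_dir) {
  specs <- cfg$dge$analyses %||% abort("`dge.analyses` is required.")
  out <- list()
  for (an in specs) {
    nm <- an$name %||% abort("Every `dge.analyses` entry needs a `name`.")
    ex <- exps[[an$experiment %||% abort(sprintf("Analysis `%s` needs `experiment`.", nm))]]
    if (is.null(ex)) abort(sprintf("Analysis `%s`: unknown experiment `%s`.",
                                   nm, an$experiment))
    counts <- filter_low_expression(ex$counts, ex$samples,
                                    min_cpm = an$min_cpm %||% 1)
    nf <- tmm_factors(counts)
    type <- an$test %||% "ql"
    if (type == "exact") {
      grp <- an$group %||% abort(sprintf("Analysis `%s` (exact) needs `group`.", nm))
      common <- estimate_common_dispersion(counts, ex$samples,
                                           paste0("`", grp, "`"), nf)
      disp <- estimate_tagwise_dispersion(counts, ex$samples,
                                          paste0("`", grp, "`"), nf, common)
      res <- exact_test(counts, ex$samples, grp, nf, disp)
    } else if (type == "ql") {
      design <- an$design %||% abort(sprintf("Analysis `%s` needs `design`.", nm))
      common <- estimate_common_dispersion(counts, ex$samples, design, nf)
      fit <- fit_glm(counts, ex$samples, design, nf, common)
      res <- ql_ftest(fit, an$coef %||% abort(sprintf("Analysis `%s` needs `coef`.", nm)))
      if (!is.null(an$interaction)) {
        inter <- ql_ftest(fit, an$interaction$coef)
        cf <- conditional_interaction_fdr(res, inter,
                                          alpha_main = an$interaction$alpha_main %||% 0.05)
        readr::write_tsv(cf, file.path(out_dir, paste0(nm, "_conditional_fdr.tsv")),
                         progress = FALSE)
      }
    } else {
      abort(sprintf("Analysis `%s`: unknown test type `%s`.", nm, type))
    }
    readr::write_tsv(res, file.path(out_dir, paste0(nm, "_dge.tsv")),
                     progress = FALSE)
    out[[nm]] <- res
  }
  out
}

pipeline_meta <- function(cfg, exps, seed, out_dir) {
  mc <- cfg$meta %||% abort("Missing `meta` section.")
  type <- mc$type %||% "combined_response"
  if (type == "combined_response") {
    labels <- lapply(mc$labels, function(x) unlist(x))
    res <- combined_response_analysis(exps, labels,
                                      n_sv = mc$n_sv, sv_seed = seed)
    readr::write_tsv(res, file.path(out_dir, "meta_combined_response.tsv"),
                     progress = FALSE)
  } else if (type == "sex_interaction") {
    res <- sex_interaction_meta(exps, n_sv = mc$n_sv, sv_seed = seed,
                                alpha_main = mc$alpha_main %||% 0.05)
    readr::write_tsv(res, file.path(out_dir, "meta_sex_interaction.tsv"),
                     progress = FALSE)
  } else {
    abort(sprintf("Unknown meta type `%s`.", type))
  }
  res
}

pipeline_report <- function(cfg, state, out_dir) {
  rc <- cfg$report %||% list()
  thr <- rc$fdr_threshold %||% 0.05
  for (nm in rc$volcano %||% names(state$dge)) {
    if (is.null(state$dge[[nm]])) {
      abort(sprintf("`report.volcano` references unknown analysis `%s`.", nm))
    }
    readr::write_tsv(volcano_table(state$dge[[nm]], fdr_threshold = thr),
                     file.path(out_dir, paste0(nm, "_volcano.tsv")),
                     progress = FALSE)
  }
  if (!is.null(state$rank)) {
    top <- utils::head(state$rank, rc$top_n %||% 10)
    readr::write_tsv(top, file.path(out_dir, "top_genes.tsv"), progress = FALSE)
  }
  invisible(NULL)
}
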