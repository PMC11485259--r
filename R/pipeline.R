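# End-to-end orchestration: simulate -> derive -> score -> reduce ->
# associate -> network, with config, logging and a machine-readable bundle.

#' Default pipeline configuration
#'
#' Returns the named configuration list for a preset scenario. Presets state
#' the simulated world (sizes, effect scales, thresholds); thresholds are
#' validated by [run_pipeline()].
#'
#' @param preset one of `"divas-like"`, `"epic-like"`, `"nhs-like"`,
#'   `"predimed-like"`.
#' @param seed master seed; per-stage child seeds derive from it.
#' @param out_dir artifact directory (`NULL` for none).
#' @return named list (a `RunConfig`).
#' @export
default_config <- function(preset = "divas-like", seed = 1, out_dir = NULL) {
  base <- list(
    preset = preset, seed = seed, out_dir = out_dir,
    p = 111, n_affected = 45, graph_density = 0.05, effect_scale = 0.5,
    n_per_arm = c(65, 130),
    cohort_n = 4000, followup_years = 10, subcohort_fraction = 0.3,
    fdr_level = 0.05, alpha_ci = 0.01, netcoupler_p = 0.05,
    max_missing_fraction = 0.70,
    covariate_sets = list(
      MV = c("age", "sex", "bmi"),
      minimal = c("age", "sex")
    )
  )
  switch(preset,
    "divas-like" = base,
    "epic-like" = utils::modifyList(base, list(cohort_n = 26437,
                                               subcohort_fraction = 1262 / 26437)),
    "nhs-like" = utils::modifyList(base, list(cohort_n = 6000,
                                              subcohort_fraction = 0.25)),
    "predimed-like" = utils::modifyList(base, list(cohort_n = 700,
                                                   subcohort_fraction = 0.6)),
    stop(sprintf("unknown preset '%s'", preset))
  )
}

validate_config <- function(config) {
  with(config, {
    stopifnot(fdr_level > 0, fdr_level < 1, alpha_ci > 0, alpha_ci < 1,
              netcoupler_p > 0, netcoupler_p < 1,
              max_missing_fraction >= 0, max_missing_fraction <= 1,
              p >= 1, n_affected >= 0, n_affected <= p)
  })
  invisible(config)
}

stage_msg <- function(log, stage, text) {
  entry <- sprintf("[%s] %s", stage, text)
  c(log, entry)
}

#' Run the full score-derivation and association pipeline
#'
#' Stages: (1) ground truth + trial simulation; (2) per-lipid diet effects
#' and FDR selection; (3) score build and standardization to the
#' intervention contrast; (4) cohort simulation, case-cohort draw, Prentice
#' Cox association; (5) conditional-independence network, Louvain clusters
#' and cluster-score associations. Reruns with the same config are
#' bit-identical; artifacts (TSV/JSON) are written when `out_dir` is set,
#' and on a stage failure partial artifacts persist and the stage is named.
#'
#' @param config a `RunConfig` list from [default_config()] (or a path to a
#'   JSON config file).
#' @return a results bundle list with per-stage outputs, run log, and config
#'   hash.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("missing input path: %s", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    config$n_per_arm <- as.numeric(config$n_per_arm)
  }
  validate_config(config)
  seed <- config$seed
  log <- character(0)
  out_dir <- config$out_dir
  # JSON round trips may turn a NULL out_dir into an empty container
  if (!is.character(out_dir) || length(out_dir) != 1L || !nzchar(out_dir)) {
    out_dir <- NULL
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  art <- function(name) if (is.null(out_dir)) NULL else file.path(out_dir, name)
  bundle <- list(config = config, config_hash = config_hash(config))

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) {
        writeLines(log, file.path(out_dir, "run_log.txt"))
      }
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # stage 1: simulate
  gt <- run_stage("simulate", generate_ground_truth(
    p = config$p, n_affected = config$n_affected,
    graph_density = config$graph_density, effect_scale = config$effect_scale,
    seed = derive_seed(seed, "ground_truth")))
  trial <- run_stage("simulate", simulate_trial(
    gt, n_per_arm = config$n_per_arm, seed = derive_seed(seed, "trial")))
  log <- stage_msg(log, "simulate", sprintf("p=%d, trial n=%d", gt$p,
                                            nrow(trial$subjects)))

  # stage 2: derive effects
  effects <- run_stage("derive-effects",
                       estimate_diet_effects(trial, fdr_level = config$fdr_level))
  log <- stage_msg(log, "derive-effects",
                   sprintf("%d/%d selected", sum(effects$selected), nrow(effects)))

  # stage 3: build + standardize score
  def <- run_stage("build-score", {
    d0 <- select_components(effects, level = config$fdr_level)
    standardize_to_contrast(d0, trial)
  })
  log <- stage_msg(log, "build-score", sprintf("s = %.4g", def$s))

  # stage 4: cohort association
  assoc <- run_stage("associate", {
    cohort <- simulate_cohort(gt, n = config$cohort_n,
                              followup_years = config$followup_years,
                              score_def = def,
                              seed = derive_seed(seed, "cohort"))
    cohort$subjects$score <- compute_score(cohort$lipids, def)
    cc <- draw_case_cohort(cohort, config$subcohort_fraction,
                           seed = derive_seed(seed, "case_cohort"))
    hr <- fit_prentice_cox(cc, exposure = "score",
                           covariates = config$covariate_sets$MV)
    list(cohort = cohort, case_cohort = cc, hazard = hr)
  })
  log <- stage_msg(log, "associate",
                   sprintf("HR per contrast unit = %.3f (events %d)",
                           assoc$hazard$hr, assoc$hazard$n_events))

  # stage 5: network + clusters
  net <- run_stage("network", {
    sel_vars <- def$variables
    sub_m <- assoc$cohort$lipids$values[assoc$case_cohort$id[assoc$case_cohort$subcohort],
                                        sel_vars, drop = FALSE]
    g <- pc_skeleton(sub_m, alpha = config$alpha_ci)
    cl <- louvain_clusters(g, seed = derive_seed(seed, "louvain"))
    cs <- cluster_scores(assoc$cohort$lipids, def, cl)
    list(graph = g, clusters = cl, cluster_scores = cs)
  })
  log <- stage_msg(log, "network",
                   sprintf("%d edges, %d clusters", sum(net$graph$adj) / 2,
                           length(unique(net$clusters$membership))))

  bundle$ground_truth <- gt
  bundle$trial <- trial
  bundle$effects <- effects
  bundle$score_definition <- def
  bundle$association <- assoc
  bundle$network <- net
  bundle$log <- log

  if (!is.null(out_dir)) {
    utils::write.table(effects, art("effect_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_score_definition(def, art("score_definition.json"))
    write_lipid_matrix(trial$post, art("trial_post.tsv"))
    utils::write.table(assoc$case_cohort, art("case_cohort.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_network(net$graph, art("network"))
    utils::write.table(
      data.frame(node = names(net$clusters$membership),
                 cluster = as.integer(net$clusters$membership)),
      art("clusters.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(config = config, config_hash = bundle$config_hash,
           seed = seed,
           hazard = list(hr = assoc$hazard$hr,
                         ci = c(assoc$hazard$ci_lower, assoc$hazard$ci_upper)),
           n_selected = sum(effects$selected)),
      art("results.json"), auto_unbox = TRUE, digits = NA)
    writeLines(log, art("run_log.txt"))
  }
  bundle
}

#' Command-line interface
#'
#' Thin dispatcher for scripted use; subcommands:
#' \itemize{
#'   \item `simulate --preset <name> --seed <int> --out <dir>`: run the
#'     simulation stages and write the artifact bundle;
#'   \item `score --matrix <tsv> --definition <json> --out <tsv>`: per-sample
#'     scores from a matrix and a score definition;
#'   \item `pipeline --preset <name> --seed <int> --out <dir>`: full run.
#' }
#'
#' @param args character vector (default `commandArgs(trailingOnly = TRUE)`).
#' @return invisibly, the result of the dispatched command.
#' @export
mls_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) stop("usage: <simulate|score|pipeline> [--flag value ...]")
  cmd <- args[1]
  flags <- list()
  rest <- args[-1]
  while (length(rest) >= 2) {
    if (!startsWith(rest[1], "--")) stop(sprintf("unexpected argument '%s'", rest[1]))
    flags[[sub("^--", "", rest[1])]] <- rest[2]
    rest <- rest[-(1:2)]
  }
  switch(cmd,
    simulate = ,
    pipeline = {
      cfg <- default_config(preset = flags$preset %||% "divas-like",
                            seed = as.integer(flags$seed %||% "1"),
                            out_dir = flags$out)
      invisible(run_pipeline(cfg))
    },
    score = {
      m <- read_lipid_matrix(flags$matrix)
      def <- read_score_definition(flags$definition)
      sc <- compute_score(m, def)
      out <- data.frame(sample = names(sc), score = sc)
      utils::write.table(out, flags$out %||% stdout(), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      invisible(sc)
    },
    stop(sprintf("unknown subcommand '%s'", cmd))
  )
}
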