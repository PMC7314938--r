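#' Configuration for the full two-stage pipeline
#'
#' Exactly one of `paths` (real delimited inputs) or `synthetic` (a
#' [synthetic_spec()]) must be supplied. The selection rule is the
#' "hand-off" knob between the cheap MMI filter and the expensive network
#' stage: loosen it (smaller `q`) to pass more variables to the network.
#'
#' @param paths named list with `S`, `E`, `M` (matrix TSVs) and `clinical`.
#' @param synthetic a [synthetic_spec()].
#' @param outcome `"tumor_status"` or `"survival2y"` (used with `paths`).
#' @param mmi an [mmi_config()].
#' @param selection_rule `"cdf_quantile"` or `"mmi_threshold"`.
#' @param selection_parameter quantile q or threshold t (default 0.995).
#' @param score a [score_config()].
#' @param mn_radius Markov neighborhood radius (1 or 2).
#' @param alpha,min_count post-hoc test parameters.
#' @param out_dir artifact directory.
#' @param seed master seed for seeded stages.
#' @export
pipeline_config <- function(paths = NULL, synthetic = NULL,
                            outcome = c("tumor_status", "survival2y"),
                            mmi = mmi_config(),
                            selection_rule = c("cdf_quantile",
                                               "mmi_threshold"),
                            selection_parameter = 0.995,
                            score = score_config(),
                            mn_radius = 1L, alpha = 0.05, min_count = 5L,
                            out_dir = tempfile("mmibn_run_"), seed = 1L) {
  if (is.null(paths) == is.null(synthetic))
    stopf("exactly one of 'paths' or 'synthetic' must be given")
  structure(list(paths = paths, synthetic = synthetic,
                 outcome = match.arg(outcome), mmi = mmi,
                 selection_rule = match.arg(selection_rule),
                 selection_parameter = selection_parameter,
                 score = score, mn_radius = as.integer(mn_radius),
                 alpha = alpha, min_count = as.integer(min_count),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

load_pipeline_dataset <- function(cfg) {
  if (!is.null(cfg$synthetic)) return(generate_multiomics(cfg$synthetic)$dataset)
  S <- read_modality(cfg$paths$S, "S")
  E <- read_modality(cfg$paths$E, "E")
  M <- read_modality(cfg$paths$M, "M")
  clin <- read_clinical(cfg$paths$clinical)
  outcome <- if (cfg$outcome == "tumor_status") encode_tumor_status(clin)
             else dichotomize_survival(clin)
  assemble_dataset(S, E, M, outcome)
}

#' Run the full two-stage analysis
#'
#' Executes: dataset assembly (or synthesis), MMI ranking, gene selection,
#' S/E/M node expansion with maximum-entropy binning, BN structure
#' learning, Markov-neighborhood extraction and the post-hoc test report.
#' Each stage writes its artifact to `cfg$out_dir`, stamped with the
#' configuration hash so intermediates from different runs cannot be
#' silently mixed.
#'
#' @param cfg a [pipeline_config()].
#' @return list of artifact paths plus the in-memory results, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg[setdiff(names(cfg), "out_dir")])
  t0 <- proc.time()[["elapsed"]]
  stages <- list()
  tick <- function(stage) {
    stages[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    message(sprintf("[mmibn] %-12s done at %7.2fs", stage, stages[[stage]]))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  ds <- run_stage("input", load_pipeline_dataset(cfg)); tick("input")
  tab <- run_stage("rank", rank_genes(ds, cfg$mmi)); tick("rank")
  sel <- run_stage("select",
    if (cfg$selection_rule == "cdf_quantile")
      select_top_cdf(tab, cfg$selection_parameter)
    else select_by_threshold(tab, cfg$selection_parameter))
  tick("select")
  dd <- run_stage("discretize",
                  discretize_dataset(ds, sel$selected_genes)); tick("discretize")
  model <- run_stage("learn", learn_structure(dd, cfg$score)); tick("learn")
  mn <- run_stage("mn", extract_mn(model, ds$outcome_name, cfg$mn_radius))
  tick("mn")
  report <- run_stage("posthoc",
                      posthoc_table(ds, mn, cfg$alpha, cfg$min_count))
  tick("posthoc")

  paths <- list(
    rank_table = file.path(cfg$out_dir, "rank_table.tsv"),
    selection = file.path(cfg$out_dir, "selection.txt"),
    discretized = file.path(cfg$out_dir, "discretized.tsv"),
    bn_json = file.path(cfg$out_dir, "bn.json"),
    bn_dot = file.path(cfg$out_dir, "bn.dot"),
    mn_dot = file.path(cfg$out_dir, "mn.dot"),
    posthoc = file.path(cfg$out_dir, "posthoc.tsv"),
    run_log = file.path(cfg$out_dir, "run_log.json"))
  write_rank_table(tab, paths$rank_table)
  writeLines(sel$selected_genes, paths$selection)
  write_discretized(dd, paths$discretized)
  write_bn_json(model, paths$bn_json)
  export_dot(model, paths$bn_dot)
  export_dot(mn, paths$mn_dot, name = "mn")
  write_posthoc(report, paths$posthoc)
  jsonlite::write_json(
    list(config_hash = hash, seed = cfg$seed,
         package_version = as.character(utils::packageVersion("mmibn")),
         r_version = R.version.string,
         n_genes = length(ds$genes), n_samples = length(ds$samples),
         n_selected = length(sel$selected_genes),
         n_bn_nodes = length(model$nodes), n_edges = nrow(model$edges),
         stage_seconds = stages),
    paths$run_log, auto_unbox = TRUE, digits = NA)

  invisible(list(paths = paths, config_hash = hash, dataset = ds,
                 rank_table = tab, selection = sel, discretized = dd,
                 model = model, mn = mn, posthoc = report))
}

#' Verify that an artifact was produced by a given configuration
#'
#' @param run_log_path path to a `run_log.json`.
#' @param cfg the `pipeline_config` to check against.
#' @export
check_artifact_config <- function(run_log_path, cfg) {
  log <- jsonlite::read_json(run_log_path)
  expect <- config_hash(cfg[setdiff(names(cfg), "out_dir")])
  if (!identical(log$config_hash, expect))
    stopf("artifact config hash %s does not match configuration %s",
          log$config_hash, expect)
  invisible(TRUE)
}

#' Read a declarative pipeline configuration (JSON)
#'
#' Keys mirror the arguments of [pipeline_config()]; `mmi`, `score` and
#' `synthetic` are nested objects passed to their constructors.
#'
#' @param path JSON file path.
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(j$paths)) args$paths <- as.list(j$paths)
  if (!is.null(j$synthetic)) args$synthetic <- do.call(synthetic_spec,
                                                       as.list(j$synthetic))
  for (k in c("outcome", "selection_rule", "selection_parameter",
              "mn_radius", "alpha", "min_count", "out_dir", "seed"))
    if (!is.null(j[[k]])) args[[k]] <- j[[k]]
  if (!is.null(j$mmi)) args$mmi <- do.call(mmi_config, as.list(j$mmi))
  if (!is.null(j$score)) args$score <- do.call(score_config, as.list(j$score))
  do.call(pipeline_config, args)
}
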