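# Declarative end-to-end runs: a single YAML config drives simulate/read ->
# train -> predict -> interpret, with every output stamped with the config
# hash, seed and package version.

.runconfig_schema <- list(
  top = c("task", "seed", "data", "model", "output", "allow_missing"),
  data = c("dir", "simulate"))

#' Read and validate a pipeline configuration
#'
#' The config is a YAML file with keys `task`, `seed`, `data` (either `dir`,
#' a cohort directory written by [writeCohort()], or `simulate`, a block of
#' [syntheticConfig()] fields), optional `model` (any [trainConfig()] fields),
#' `output` (directory) and `allow_missing` (modalities absent at inference).
#' Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return validated list of class `RunConfig`.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .runconfig_schema$top)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$task) || !cfg$task %in% c("classification", "survival"))
    stop("config needs task: classification or survival")
  if (is.null(cfg$data) ||
      !length(intersect(names(cfg$data), .runconfig_schema$data)))
    stop("config needs data: dir or data: simulate")
  unknown_d <- setdiff(names(cfg$data), .runconfig_schema$data)
  if (length(unknown_d))
    stop("unknown data key(s): ", paste(unknown_d, collapse = ", "))
  if (!is.null(cfg$model)) {
    bad <- setdiff(names(cfg$model), names(formals(trainConfig)))
    if (length(bad))
      stop("unknown model key(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$output)) cfg$output <- "pathmoe_run"
  class(cfg) <- "RunConfig"
  cfg
}

.log_stage <- function(stage, t0, ...) {
  message(sprintf("[pathMoE] %-10s %6.1fs %s", stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  paste(..., collapse = " ")))
}

#' Run the full pipeline from a declarative config
#'
#' Stages: load or simulate the cohort, train the multiphase model, predict
#' on the held-out test split (optionally with modalities removed), write the
#' interpretation report. Every output directory carries `run_info.json` with
#' the config hash, seed and package version; rerunning with the same config
#' and seed reproduces every artifact.
#'
#' @param config path to a YAML config, or a [readRunConfig()] result.
#' @param out_dir overrides the config's output directory.
#' @return (invisibly) list with the trained model, predictions, report and
#'   output paths.
#' @export
runPipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "RunConfig"))
  out <- out_dir %||% config$output
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  cohort <- if (!is.null(config$data$dir)) {
    readCohort(config$data$dir)
  } else {
    sim_args <- config$data$simulate
    sim_args$task <- config$task
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    generateCohort(do.call(syntheticConfig, sim_args))
  }
  if (cohortTask(cohort) != config$task)
    stop("cohort task '", cohortTask(cohort), "' does not match config task")
  .log_stage("data", t0, nrow(cohortOutcome(cohort)), "patients")

  margs <- config$model %||% list()
  margs$task <- config$task
  if (is.null(margs$seed)) margs$seed <- config$seed
  tcfg <- do.call(trainConfig, margs)
  model <- trainModel(cohort, tcfg)
  .log_stage("train", t0, "best epoch", model@meta$best_epoch)

  test <- modelSplit(model)$test
  missing <- intersect(config$allow_missing %||% character(0),
                       c("wsi", model@meta$sources))
  pred <- predictModel(model, cohort, rows = test, missing = missing)
  oc <- cohortOutcome(cohort)[test, ]
  metrics <- if (config$task == "classification") {
    pos <- model@meta$class_levels[length(model@meta$class_levels)]
    list(test_auc = aucScore(oc$label == pos, pred$scores[, pos]))
  } else {
    list(test_cindex = concordanceIndex(pred$scores, oc$time, oc$event))
  }
  ptab <- if (config$task == "classification") {
    data.frame(sample_id = pred$sample_ids, pred$scores,
               predicted = colnames(pred$scores)[max.col(pred$scores)])
  } else {
    data.frame(sample_id = pred$sample_ids, risk = as.numeric(pred$scores))
  }
  utils::write.table(ptab, file.path(out, "predictions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(trainHistory(model), file.path(out, "history.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .log_stage("predict", t0, names(metrics), round(unlist(metrics), 4))

  report <- interpretModel(model, cohort, rows = test)
  utils::write.table(geneTable(report), file.path(out, "gene_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pathwayTable(report), file.path(out, "pathway_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(cohort_mean = as.data.frame(interactionScores(report)),
         by_patient = lapply(report@misByPatient, as.data.frame)),
    file.path(out, "mis.json"), auto_unbox = TRUE, digits = 10)
  .log_stage("interpret", t0, nrow(pathwayTable(report)), "pathways")

  info <- list(schema_version = "1.0",
               package_version = as.character(utils::packageVersion("pathMoE")),
               config_hash = configHash(unclass(config)),
               seed = config$seed, task = config$task,
               metrics = metrics, missing_modalities = missing,
               finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(info, file.path(out, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(model = model, predictions = pred, report = report,
                 metrics = metrics, out_dir = out))
}
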