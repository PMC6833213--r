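## The pipeline surface behind the command-line tool: simulate -> fit ->
## estimate -> evaluate, all exchanging the package's CSV/JSON formats.
## Every run writes its fully resolved configuration next to the outputs so
## results stay reproducible from the files alone.

resolveDefault <- function(config, field, default) {
  if (is.null(config[[field]])) default else config[[field]]
}

writeResolvedConfig <- function(config, command, mainOutput) {
  path <- file.path(dirname(mainOutput),
                    paste0(command, "_resolved_config.json"))
  config <- config[!vapply(config, is.null, logical(1))]
  jsonlite::write_json(c(list(command = command), config), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  invisible(path)
}

#' Run one pipeline command
#'
#' Programmatic equivalent of the `coursense` command-line tool
#' (`inst/scripts/coursense`).  Supported commands and their `config`
#' entries (all file paths; defaults in parentheses):
#'
#' * `simulate`: `out_dir`; optional simulator settings `seed` (1),
#'   `our_noise_cv` (0.02), `dcw_noise_cv` (0.05), `t_end` (20),
#'   `induction_time` (10), `beta_mode` ("biomass").  Writes `truth.csv`,
#'   `our.csv`, `dcw.csv`.
#' * `fit`: `our_csv`, `dcw_csv` (equal-length vectors, one entry per
#'   experiment), `out_json`; optional `k_exp` (0.4), `degree` (2),
#'   `induction_time` (absent: activation-time search), `x0` (taken from a
#'   `t = 0` row of the DCW file when present), `candidates`.
#' * `estimate`: `params_json`, `input_csv`, `out_csv`; optional `column`
#'   ("our" or "cour", default "our"), `x0` or `od` with `od_factor` (0.4).
#' * `evaluate`: `trajectory_csv`, `dcw_csv`, `out_json`; optional
#'   `feed_start` (0), `x0`.
#'
#' @param command one of `"simulate"`, `"fit"`, `"estimate"`, `"evaluate"`.
#' @param config named list of inputs (see above).
#' @return list of produced outputs, invisibly (with the written file paths
#'   in `$paths`).
#' @export
runPipeline <- function(command = c("simulate", "fit", "estimate", "evaluate"),
                        config = list()) {
  command <- match.arg(command)
  out <- switch(command,
                simulate = pipelineSimulate(config),
                fit = pipelineFit(config),
                estimate = pipelineEstimate(config),
                evaluate = pipelineEvaluate(config))
  invisible(out)
}

pipelineSimulate <- function(config) {
  outDir <- resolveDefault(config, "out_dir", ".")
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  simConfig <- simulationConfig(
    seed = resolveDefault(config, "seed", 1L),
    ourNoiseCv = resolveDefault(config, "our_noise_cv", 0.02),
    dcwNoiseCv = resolveDefault(config, "dcw_noise_cv", 0.05),
    tEnd = resolveDefault(config, "t_end", 20),
    inductionTime = resolveDefault(config, "induction_time", 10),
    betaMode = resolveDefault(config, "beta_mode", "biomass"),
    offlineInterval = resolveDefault(config, "offline_interval", 1),
    onlineInterval = resolveDefault(config, "online_interval", 1 / 60))
  experiment <- addNoise(simulateCulture(simConfig))
  paths <- c(truth = file.path(outDir, "truth.csv"),
             our = file.path(outDir, "our.csv"),
             dcw = file.path(outDir, "dcw.csv"))
  writeTimeseriesCsv(experiment@truth, paths["truth"])
  series <- experiment@observedOurSeries
  writeTimeseriesCsv(data.frame(time_h = series@times, our = series@our,
                                cour = series@cour), paths["our"])
  ds <- experiment@offlineDataset
  writeTimeseriesCsv(data.frame(time_h = c(0, ds@sampleTimes),
                                dcw_g_per_l = c(ds@x0, ds@biomass)),
                     paths["dcw"])
  resolved <- simConfig[setdiff(names(simConfig), "maintenanceTrue")]
  cfgPath <- writeResolvedConfig(resolved, "simulate", paths["truth"])
  list(experiment = experiment, paths = c(paths, config = cfgPath))
}

## A DCW file may carry the inoculation value as a t = 0 row; that row
## becomes x0 and the remaining rows the offline samples.
readOfflineCsv <- function(path, x0 = NULL, inductionTime = NA_real_,
                           label = NULL) {
  df <- readTimeseriesCsv(path, columns = c("time_h", "dcw_g_per_l"))
  if (is.null(label)) label <- basename(path)
  if (df$time_h[1L] == 0) {
    if (is.null(x0)) x0 <- df$dcw_g_per_l[1L]
    df <- df[-1L, , drop = FALSE]
  }
  if (is.null(x0))
    stopInvalidInput("%s: no t = 0 row and no x0 supplied", path)
  offlineDataset(df$time_h, df$dcw_g_per_l, x0 = x0,
                 inductionTime = inductionTime, label = label)
}

pipelineFit <- function(config) {
  ourCsv <- config$our_csv
  dcwCsv <- config$dcw_csv
  outJson <- resolveDefault(config, "out_json", "strain_parameters.json")
  if (is.null(ourCsv) || is.null(dcwCsv) || length(ourCsv) != length(dcwCsv))
    stopInvalidInput("fit needs equal-length our_csv and dcw_csv path vectors")
  inductionTime <- resolveDefault(config, "induction_time", NA_real_)
  experiments <- lapply(seq_along(ourCsv), function(i) {
    df <- readTimeseriesCsv(ourCsv[i], columns = c("time_h", "our"))
    list(offline = readOfflineCsv(dcwCsv[i], x0 = config$x0,
                                  inductionTime = inductionTime),
         our = ourSeries(df$time_h, our = df$our))
  })
  fit <- fitStrain(experiments,
                   kExp = resolveDefault(config, "k_exp", 0.4),
                   degree = resolveDefault(config, "degree", 2L),
                   candidates = config$candidates,
                   strainLabel = resolveDefault(config, "strain_label", "strain"))
  writeStrainParameters(fit@strainParameters, outJson)
  cfgPath <- writeResolvedConfig(
    list(our_csv = ourCsv, dcw_csv = dcwCsv, out_json = outJson,
         k_exp = resolveDefault(config, "k_exp", 0.4),
         degree = resolveDefault(config, "degree", 2L),
         induction_time = inductionTime, flags = fit@flags),
    "fit", outJson)
  list(fit = fit, paths = c(params = outJson, config = cfgPath))
}

pipelineEstimate <- function(config) {
  params <- readStrainParameters(config$params_json)
  column <- match.arg(resolveDefault(config, "column", "our"), c("our", "cour"))
  outCsv <- resolveDefault(config, "out_csv", "trajectory.csv")
  df <- readTimeseriesCsv(config$input_csv, columns = c("time_h", column))
  series <- if (column == "cour")
    ourSeries(df$time_h, cour = df$cour)
  else
    ourSeries(df$time_h, our = df$our)
  x0 <- config$x0
  if (is.null(x0)) {
    if (is.null(config$od))
      stopInvalidInput("estimate needs x0 or od")
    x0 <- odToDcw(config$od, resolveDefault(config, "od_factor", 0.4))
  }
  trajectory <- estimateTrajectory(params, series, x0 = x0)
  writeTrajectoryCsv(trajectory, outCsv)
  cfgPath <- writeResolvedConfig(
    list(params_json = config$params_json, input_csv = config$input_csv,
         out_csv = outCsv, column = column, x0 = x0),
    "estimate", outCsv)
  list(trajectory = trajectory, paths = c(trajectory = outCsv, config = cfgPath))
}

pipelineEvaluate <- function(config) {
  trajectory <- readTrajectoryCsv(config$trajectory_csv)
  offline <- readOfflineCsv(config$dcw_csv, x0 = config$x0)
  feedStart <- resolveDefault(config, "feed_start", 0)
  outJson <- resolveDefault(config, "out_json", "evaluation.json")
  report <- evaluateEstimation(trajectory, offline, feedStart = feedStart)
  jsonlite::write_json(report, outJson, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  cfgPath <- writeResolvedConfig(
    list(trajectory_csv = config$trajectory_csv, dcw_csv = config$dcw_csv,
         feed_start = feedStart, out_json = outJson),
    "evaluate", outJson)
  list(report = report, paths = c(report = outJson, config = cfgPath))
}
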