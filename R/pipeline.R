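#' Pipeline run configuration
#'
#' Bundles every setting of a simulate-smooth-detect-model run. Fully
#' serializable; [run_pipeline()] writes it into the run manifest together
#' with the package version and seed.
#'
#' @param simulation a [simulation_config()] (the `seed` argument overrides
#'   its seed).
#' @param outdir output directory.
#' @param resolution isochronal grid spacing, minutes.
#' @param k,lambda_selection,scale smoothing settings
#'   (see [fit_growth_smoothers()]).
#' @param min_prominence,min_separation peak-calling settings
#'   (see [detect_peaks()]).
#' @param weights_mode uncertainty-weighting mode for the linear models.
#' @param hgam_k,hgam_fs_k basis dimensions for the hierarchical GAMs.
#' @param run_hgam fit the hierarchical GAMs (the slowest stage).
#' @param calibration_pairs optional paired machine/manual data frame for
#'   [calibration_regression()]; when `NULL` that stage is skipped.
#' @param seed integer seed for the whole run.
#' @export
run_config <- function(simulation = simulation_config(),
                       outdir = tempfile("copegrow_run_"),
                       resolution = 72,
                       k = 40, lambda_selection = "REML", scale = "mm",
                       min_prominence = NULL, min_separation = 720,
                       weights_mode = "inverse",
                       hgam_k = 10, hgam_fs_k = 6, run_hgam = TRUE,
                       calibration_pairs = NULL,
                       seed = simulation$seed) {
  simulation$seed <- as.integer(seed)
  structure(list(simulation = simulation, outdir = outdir,
                 resolution = resolution, k = k,
                 lambda_selection = lambda_selection, scale = scale,
                 min_prominence = min_prominence,
                 min_separation = min_separation,
                 weights_mode = weights_mode,
                 hgam_k = hgam_k, hgam_fs_k = hgam_fs_k,
                 run_hgam = run_hgam,
                 calibration_pairs = calibration_pairs,
                 seed = as.integer(seed)),
            class = "run_config")
}

write_stage <- function(outdir, name, df) {
  utils::write.csv(df, file.path(outdir, paste0(name, ".csv")), row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Simulates an experiment, fits the per-individual growth smoothers,
#' derives isochronal predictions and growth increments, detects moult
#' events, screens the N6-to-C1 transitions, fits the transition-time,
#' moult-duration, endpoint-size (all and matured-only) and hierarchical
#' GAM models, and writes every stage's output plus a YAML manifest to the
#' run directory. A stage failure aborts with the stage name.
#'
#' @param config a [run_config()].
#' @return Object of class `pipeline_run` (list of all stage results, with
#'   `outdir`), invisibly printable.
#' @export
run_pipeline <- function(config = run_config()) {
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("copegrow")),
    seed = config$seed,
    resolution = config$resolution,
    smoothing = list(k = config$k, lambda_selection = config$lambda_selection,
                     scale = config$scale),
    peaks = list(min_prominence = config$min_prominence,
                 min_separation = config$min_separation),
    weights_mode = config$weights_mode,
    simulation = list(n_clutches = config$simulation$n_clutches,
                      individuals_per_clutch = config$simulation$individuals_per_clutch,
                      experiment_duration = config$simulation$experiment_duration,
                      frame_interval = config$simulation$frame_interval,
                      copper_delay_log = config$simulation$copper_delay_log,
                      dropout = config$simulation$dropout))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))

  sim <- stage("simulate", simulate_experiment(config$simulation))
  dataset <- as_dataset(sim)
  write_stage(outdir, "individuals", dataset$individuals)
  write_stage(outdir, "windows", dataset$windows)
  yaml::write_yaml(list(n_individuals = nrow(dataset$individuals),
                        n_analyzable = n_analyzable(dataset),
                        mean_usable = mean(dataset$windows$n_usable)),
                   file.path(outdir, "dataset_summary.yaml"))

  smoothers <- stage("smooth", suppressWarnings(
    fit_growth_smoothers(dataset, k = config$k,
                         lambda_selection = config$lambda_selection,
                         scale = config$scale)))
  write_stage(outdir, "smoother_diagnostics", check_fit(smoothers))
  pred <- stage("predict", suppressWarnings(
    predict_isochronal(smoothers, config$resolution)))
  write_stage(outdir, "predictions", pred)
  inc <- stage("increments", growth_increments(pred))
  write_stage(outdir, "increments", inc)

  events <- stage("detect", detect_peaks(inc,
                                         min_prominence = config$min_prominence,
                                         min_separation = config$min_separation))
  write_stage(outdir, "moult_events", events)
  transitions <- stage("screen", screen_c1_transition(sim$frame_log))
  write_stage(outdir, "c1_transitions", transitions)
  durations <- stage("duration", moult_duration(sim$frame_log,
                                                config$simulation$frame_interval))
  write_stage(outdir, "moult_durations", durations)

  avg_inc <- stage("average_increments",
                   average_increments_by_treatment(inc, dataset$individuals,
                                                   config$resolution))
  write_stage(outdir, "treatment_increment_curves", avg_inc)

  analyzable <- dataset$individuals[dataset$individuals$end_status != "lost", ]
  models <- list()
  models$transition <- stage("transition_model",
    transition_time_model(transitions, analyzable,
                          weights_mode = config$weights_mode))
  models$transition_sex <- tryCatch(
    transition_time_model(transitions, analyzable, include_sex = TRUE,
                          weights_mode = config$weights_mode),
    error = function(e) NULL)
  models$duration <- stage("duration_model",
    moult_duration_model(transitions, analyzable,
                         frame_interval = config$simulation$frame_interval,
                         weights_mode = config$weights_mode))
  models$endpoint <- stage("endpoint_model",
    suppressWarnings(endpoint_size_model(dataset)))
  models$endpoint_matured <- tryCatch(
    suppressWarnings(endpoint_size_model(dataset, matured_only = TRUE)),
    error = function(e) NULL)
  for (nm in names(models)) {
    if (is.null(models[[nm]])) next
    write_stage(outdir, paste0("model_", nm), as_coef_table(models[[nm]]))
  }

  hgams <- list()
  if (isTRUE(config$run_hgam)) {
    hgams$length <- stage("hgam_length", suppressMessages(
      hgam_length_model(dataset, k = config$hgam_k, fs_k = config$hgam_fs_k)))
    write_stage(outdir, "model_hgam_length", parametric_terms(hgams$length))
    write_stage(outdir, "treatment_length_curves",
                treatment_curves(hgams$length, config$resolution))
    hgams$increment <- stage("hgam_increment", suppressMessages(
      hgam_increment_model(inc, dataset$individuals,
                           k = config$hgam_k, fs_k = config$hgam_fs_k)))
    write_stage(outdir, "model_hgam_increment", parametric_terms(hgams$increment))
  }

  calibration <- NULL
  if (!is.null(config$calibration_pairs)) {
    calibration <- stage("calibration",
                         calibration_regression(config$calibration_pairs))
    write_stage(outdir, "model_calibration",
                data.frame(term = c("(Intercept)", "manual_mm"),
                           estimate = c(calibration$intercept, calibration$slope),
                           std_error = c(NA, calibration$se)))
  }

  structure(list(outdir = outdir, config = config, experiment = sim,
                 dataset = dataset, smoothers = smoothers,
                 predictions = pred, increments = inc, events = events,
                 transitions = transitions, durations = durations,
                 treatment_increments = avg_inc, models = models,
                 hgams = hgams, calibration = calibration),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("Pipeline run in %s\n", x$outdir))
  cat(sprintf("  %d analyzable individuals; %d smoothed; %d moult events; %d transitions observed\n",
              n_analyzable(x$dataset), length(x$smoothers$fits),
              nrow(x$events), sum(x$transitions$status == "observed")))
  invisible(x)
}

md_table <- function(df, digits = 4) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  rows <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  paste(c(header, sep, rows), collapse = "\n")
}

#' Collate a run directory into a human-readable report
#'
#' Writes `report.md` in the run directory: the echoed configuration, the
#' dataset summary, and every model coefficient table found. Missing stage
#' outputs are listed as absent rather than failing.
#'
#' @param outdir a completed [run_pipeline()] directory.
#' @return Path to the report, invisibly.
#' @export
make_report <- function(outdir) {
  lines <- c("# Copepod growth pipeline report", "")
  man_path <- file.path(outdir, "manifest.yaml")
  if (file.exists(man_path)) {
    man <- yaml::read_yaml(man_path)
    lines <- c(lines, "## Configuration", "",
               paste0("```yaml\n", yaml::as.yaml(man), "```"), "")
  }
  sum_path <- file.path(outdir, "dataset_summary.yaml")
  if (file.exists(sum_path)) {
    s <- yaml::read_yaml(sum_path)
    lines <- c(lines, "## Dataset", "",
               sprintf("- individuals: %s", s$n_individuals),
               sprintf("- analyzable: %s", s$n_analyzable),
               sprintf("- mean usable measurements per individual: %.1f",
                       s$mean_usable), "")
  }
  tables <- c(transition = "Transition time (log days)",
              transition_sex = "Transition time, matured individuals (sex model)",
              duration = "Moult duration (sqrt minutes)",
              endpoint = "Final size, all individuals (log mm)",
              endpoint_matured = "Final size, matured individuals (log mm)",
              hgam_length = "Hierarchical GAM: length",
              hgam_increment = "Hierarchical GAM: growth increments",
              calibration = "Machine ~ manual calibration")
  lines <- c(lines, "## Model coefficient tables", "")
  for (nm in names(tables)) {
    path <- file.path(outdir, paste0("model_", nm, ".csv"))
    lines <- c(lines, paste("###", tables[[nm]]), "")
    if (file.exists(path)) {
      lines <- c(lines, md_table(utils::read.csv(path)), "")
    } else {
      lines <- c(lines, "*absent*", "")
    }
  }
  report <- file.path(outdir, "report.md")
  writeLines(lines, report)
  invisible(report)
}
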