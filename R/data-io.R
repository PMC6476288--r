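#' Write a synthetic experiment to disk
#'
#' One comma-delimited measurement file per individual (columns
#' `frame_index`, `time_min`, `length_mm`, `usable`), a linking table
#' (`individual_id`, `file`, `clutch_id`, `copper`, `cue`, `birth_time_min`,
#' `sex`, `end_status`), a ground-truth file, and a YAML run manifest
#' recording paths and the seed.
#'
#' @param experiment a [simulate_experiment()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(experiment, dir) {
  meas_dir <- file.path(dir, "measurements")
  dir.create(meas_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- experiment$individuals$individual_id
  files <- sprintf("measurements/%s.csv", ids)
  for (i in seq_along(ids)) {
    m <- experiment$measurements[experiment$measurements$individual_id == ids[i],
                                 c("frame_index", "time_min", "length_mm", "usable")]
    utils::write.csv(m, file.path(dir, files[i]), row.names = FALSE)
  }
  linking <- cbind(individual_id = ids, file = files,
                   experiment$individuals[, c("clutch_id", "copper", "cue",
                                              "birth_time_min", "sex", "end_status")])
  utils::write.csv(linking, file.path(dir, "linking.csv"), row.names = FALSE)
  utils::write.csv(experiment$truth$moults, file.path(dir, "truth_moults.csv"),
                   row.names = FALSE)
  utils::write.csv(experiment$truth$individuals,
                   file.path(dir, "truth_individuals.csv"), row.names = FALSE)
  yaml::write_yaml(list(
    seed = experiment$config$seed,
    n_individuals = length(ids),
    linking = "linking.csv",
    measurement_files = as.character(files),
    truth = c("truth_moults.csv", "truth_individuals.csv"),
    frame_interval = experiment$config$frame_interval
  ), file.path(dir, "manifest.yaml"))
  invisible(dir)
}

read_table_dialect <- function(path, dialect = c("auto", "comma", "tab")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    first <- readLines(path, n = 1L)
    dialect <- if (grepl("\t", first)) "tab" else "comma"
  }
  utils::read.delim(path, sep = if (dialect == "tab") "\t" else ",",
                    stringsAsFactors = FALSE)
}

#' Read and validate a measurement dataset
#'
#' Joins per-individual measurement files with the treatment linking table,
#' validates them, and computes each individual's observation window as
#' \[first usable time, last usable time\]. Unusable rows are retained but
#' flagged. Comma-delimited by default; a tab-delimited variant is accepted
#' via `dialect`.
#'
#' @param measurements_path directory against which the linking table's
#'   `file` column is resolved.
#' @param linking_path path to the linking table.
#' @param dialect `"auto"`, `"comma"` or `"tab"`.
#' @return Object of class `copepod_dataset`: list with `individuals`,
#'   `measurements` (all rows, flagged), and `windows` (per analyzable
#'   individual: `window_start`, `window_end`, `n_usable`).
#' @export
read_dataset <- function(measurements_path,
                         linking_path = file.path(measurements_path, "linking.csv"),
                         dialect = c("auto", "comma", "tab")) {
  dialect <- match.arg(dialect)
  if (!file.exists(linking_path)) stopf("linking table not found: %s", linking_path)
  linking <- read_table_dialect(linking_path, dialect)
  req <- c("individual_id", "file", "clutch_id", "copper", "cue")
  missing_cols <- setdiff(req, names(linking))
  if (length(missing_cols))
    stopf("linking table lacks columns: %s", paste(missing_cols, collapse = ", "))
  dup <- linking$individual_id[duplicated(linking$individual_id)]
  if (length(dup))
    stopf("duplicate individual_id in linking table: %s",
          paste(unique(dup), collapse = ", "))

  meas <- vector("list", nrow(linking))
  for (i in seq_len(nrow(linking))) {
    path <- file.path(measurements_path, linking$file[i])
    if (!file.exists(path))
      stopf("measurement file missing for individual '%s': %s",
            linking$individual_id[i], path)
    m <- read_table_dialect(path, dialect)
    m$individual_id <- linking$individual_id[i]
    meas[[i]] <- m
  }
  measurements <- do.call(rbind, meas)
  measurements$usable <- as.logical(measurements$usable)
  if (!is.numeric(measurements$length_mm))
    stopf("non-numeric length values in rows: %s",
          paste(utils::head(which(!grepl("^[-0-9.eE+]*$",
                                         as.character(measurements$length_mm))), 10),
                collapse = ", "))
  bad_time <- which(measurements$time_min < 0)
  if (length(bad_time))
    stopf("negative measurement times in rows: %s (individuals %s)",
          paste(utils::head(bad_time, 10), collapse = ", "),
          paste(unique(measurements$individual_id[utils::head(bad_time, 10)]),
                collapse = ", "))
  bad_len <- which(measurements$usable & (!is.finite(measurements$length_mm) |
                                            measurements$length_mm <= 0))
  if (length(bad_len))
    stopf("usable rows with missing/non-positive length: rows %s",
          paste(utils::head(bad_len, 10), collapse = ", "))

  linking$copper <- as.logical(linking$copper)
  linking$cue <- as.logical(linking$cue)
  new_copepod_dataset(linking[, setdiff(names(linking), "file")], measurements)
}

#' Construct an analysis dataset from in-memory tables
#'
#' Assembles a `copepod_dataset` from an individuals table and a
#' measurement table, computing per-individual observation windows from the
#' usable records.
#'
#' @param individuals data frame with at least `individual_id`; treatment
#'   columns (`clutch_id`, `copper`, `cue`, `sex`, `end_status`) as needed
#'   by downstream models.
#' @param measurements data frame with `individual_id`, `time_min`,
#'   `length_mm`, `usable`.
#' @export
copepod_dataset <- function(individuals, measurements) {
  stopifnot(is.data.frame(individuals), is.data.frame(measurements),
            all(c("individual_id", "time_min", "length_mm", "usable") %in%
                  names(measurements)))
  new_copepod_dataset(individuals, measurements)
}

new_copepod_dataset <- function(individuals, measurements) {
  usable <- measurements[measurements$usable, ]
  windows <- do.call(rbind, lapply(split(usable, usable$individual_id), function(m)
    data.frame(individual_id = m$individual_id[1],
               window_start = min(m$time_min),
               window_end = max(m$time_min),
               n_usable = nrow(m),
               stringsAsFactors = FALSE)))
  rownames(windows) <- NULL
  structure(list(individuals = individuals, measurements = measurements,
                 windows = windows),
            class = "copepod_dataset")
}

#' Convert a synthetic experiment into an analysis dataset
#'
#' In-memory equivalent of [write_dataset()] + [read_dataset()].
#' @param experiment a [simulate_experiment()] result.
#' @return A `copepod_dataset`.
#' @export
as_dataset <- function(experiment) {
  new_copepod_dataset(experiment$individuals, experiment$measurements)
}

#' @export
print.copepod_dataset <- function(x, ...) {
  n_ana <- n_analyzable(x)
  cat(sprintf("Copepod dataset: %d individuals (%d analyzable)\n",
              nrow(x$individuals), n_ana))
  cat(sprintf("  %d measurement rows, %d usable; mean usable per analyzable individual %.1f\n",
              nrow(x$measurements), sum(x$measurements$usable),
              if (n_ana) sum(x$measurements$usable) / n_ana else NA))
  invisible(x)
}

#' Number of analyzable individuals
#'
#' Individuals with at least one usable measurement and not recorded lost.
#' @param dataset a `copepod_dataset`.
#' @export
n_analyzable <- function(dataset) {
  has_usable <- dataset$individuals$individual_id %in% dataset$windows$individual_id
  not_lost <- if ("end_status" %in% names(dataset$individuals))
    dataset$individuals$end_status != "lost" else TRUE
  sum(has_usable & not_lost)
}

#' Daily averages of usable machine lengths
#'
#' One mean per (individual, day), with day `k` the half-open interval
#' \[1440k, 1440(k+1)) minutes of age. Days without usable measurements are
#' absent, not zero.
#'
#' @param measurements data frame with `individual_id`, `time_min`,
#'   `length_mm`, `usable` (a `copepod_dataset$measurements` works).
#' @return Data frame with `individual_id`, `day`, `mean_length_mm`, `n`.
#' @export
daily_average <- function(measurements) {
  m <- measurements[measurements$usable, ]
  if (!nrow(m))
    return(data.frame(individual_id = character(), day = integer(),
                      mean_length_mm = numeric(), n = integer()))
  day <- floor(m$time_min / MIN_PER_DAY)
  agg <- stats::aggregate(m$length_mm,
                          by = list(individual_id = m$individual_id, day = day),
                          FUN = mean)
  cnt <- stats::aggregate(m$length_mm,
                          by = list(individual_id = m$individual_id, day = day),
                          FUN = length)
  out <- data.frame(individual_id = agg$individual_id, day = as.integer(agg$day),
                    mean_length_mm = agg$x, n = as.integer(cnt$x),
                    stringsAsFactors = FALSE)
  out[order(out$individual_id, out$day), , drop = FALSE]
}
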