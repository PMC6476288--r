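# Shared fixtures, built in code.

# Small, fast experiment: 3 clutches x 4 individuals over 8 days at a
# 144-min frame interval.
small_config <- function(seed = 1L, ...) {
  simulation_config(n_clutches = 3, individuals_per_clutch = 4,
                    experiment_duration = 8 * 1440, frame_interval = 144,
                    dropout = 0, seed = seed, ...)
}

# Noise-free, fully detected observation process: the moult-detection oracle
# conditions (measurement noise, machine bias, birth-time error, frame loss
# and detection dropout all switched off).
oracle_config <- function(seed = 42L, n_clutches = 5,
                          individuals_per_clutch = 10, ...) {
  simulation_config(n_clutches = n_clutches,
                    individuals_per_clutch = individuals_per_clutch,
                    dropout = 0, measurement_cv = 0, machine_bias = 1,
                    birth_jitter_min = 0,
                    detection_by_stage = stats::setNames(rep(1, 12), STAGE_NAMES),
                    unusable_episode_rate = 0, seed = seed, ...)
}

# One default-scale experiment shared across tests (computed once).
default_experiment_cache <- new.env()
default_experiment <- function() {
  if (is.null(default_experiment_cache$ex))
    default_experiment_cache$ex <- simulate_experiment(simulation_config())
  default_experiment_cache$ex
}

# Match detected events to true moult times: for each true stage-entry time
# inside an individual's observation window, is there an event within `tol`
# minutes; and how many events match no true moult.
match_moults <- function(events, truth_moults, windows, tol = 72) {
  detected <- 0L; missed <- 0L; spurious <- 0L; total <- 0L
  for (id in windows$individual_id) {
    w <- windows[windows$individual_id == id, ]
    tm <- truth_moults[truth_moults$individual_id == id &
                         truth_moults$stage != "N1", ]
    tm <- tm$entry_time_min[tm$entry_time_min > w$window_start &
                              tm$entry_time_min <= w$window_end]
    e <- events$event_time_min[events$individual_id == id]
    total <- total + length(tm)
    for (t in tm) {
      if (any(abs(e - t) <= tol)) detected <- detected + 1L
      else missed <- missed + 1L
    }
    if (length(e))
      spurious <- spurious + sum(vapply(e, function(x)
        !any(abs(tm - x) <= tol), logical(1)))
  }
  list(total = total, detected = detected, missed = missed,
       spurious = spurious)
}

# Run the smoothing -> increments part of the pipeline on a dataset.
increments_pipeline <- function(dataset, k = 40, resolution = 72, sp = NULL) {
  sm <- suppressWarnings(fit_growth_smoothers(dataset, k = k, sp = sp))
  pred <- suppressWarnings(predict_isochronal(sm, resolution))
  list(smoothers = sm, predictions = pred,
       increments = growth_increments(pred))
}
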