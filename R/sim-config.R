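#' Developmental stage labels
#'
#' Twelve stages: six naupliar (N1--N6), five copepodite (C1--C5), adult.
#' @export
STAGE_NAMES <- c("N1", "N2", "N3", "N4", "N5", "N6",
                 "C1", "C2", "C3", "C4", "C5", "adult")

#' Simulation configuration for a synthetic imaging experiment
#'
#' Builds and validates the configuration of the stage-structured growth and
#' observation simulator. Defaults describe a 13-day experiment on 72
#' individuals from nine clutches in a 2x2 copper x predator-cue design,
#' imaged approximately hourly (one frame per 72 minutes), with
#' stage-dependent probability that a frame yields a usable length
#' measurement, episodic runs of unusable frames (water changes,
#' misalignments), multiplicative machine measurement bias, and a motionless
#' period preceding the naupliar-to-copepodite (N6 to C1) metamorphosis.
#'
#' Development is stage-structured: each individual's stage durations are
#' log-normal around the configured means, scaled by clutch, individual and
#' treatment factors. Copper multiplies the durations of all stages after N2
#' by a factor chosen so that the expected log N6-to-C1 transition time
#' shifts by exactly `copper_delay_log`; the copper x cue interaction adds
#' `cue_copper_interaction` (log scale) to copepodite-stage durations only.
#'
#' @param n_clutches number of clutches (maternal broods).
#' @param individuals_per_clutch individuals incubated per clutch.
#' @param treatments data frame with logical columns `copper` and `cue`, one
#'   row per treatment arm, cycled over individuals within each clutch.
#' @param experiment_duration total duration in minutes.
#' @param frame_interval minutes between scheduled frames.
#' @param stage_lengths named numeric of true body length (mm) per stage,
#'   strictly increasing over the 12 stages.
#' @param stage_durations named numeric of mean stage durations in days for
#'   the 11 pre-adult stages. The naupliar durations sum to the control
#'   geometric-mean N6-to-C1 transition time.
#' @param copper_delay_log additive copper effect on the expected log
#'   N6-to-C1 transition time.
#' @param cue_copper_interaction additional log-scale delay applied to
#'   copepodite-stage durations when copper and predator cue are combined.
#' @param copper_length_log additive copper effect on log true length
#'   (0 by default: in the default conditions the apparent length deficit
#'   under copper emerges from developmental delay alone).
#' @param sex_length_log additive male effect on log length of copepodite
#'   and adult stages.
#' @param clutch_sd_log_time,clutch_sd_log_length SDs of clutch random
#'   effects on log stage durations and log stage lengths.
#' @param clutch_copper_interaction_sd SD of the clutch-specific copper
#'   sensitivity of the motion-free moult duration (log scale).
#' @param copper_motionfree_log mean copper effect on log motion-free
#'   duration.
#' @param individual_sd_log_time,individual_sd_log_length SDs of
#'   individual-level random effects (log scale, shared across stages).
#' @param stage_sd_log SD of independent per-stage duration noise (log).
#' @param measurement_cv relative SD of observed length noise.
#' @param machine_bias multiplicative bias of machine lengths relative to
#'   true length (automated estimates run large).
#' @param detection_by_stage named numeric in \[0, 1\]: probability that a
#'   scheduled frame yields a usable length, per stage. Defaults decrease
#'   after C1 (nauplii are benthic and easy to image; older stages swim).
#' @param unusable_episode_rate expected unusable-frame episodes per day.
#' @param unusable_episode_length mean episode length in frames (geometric).
#' @param motionfree_duration_dist list with `meanlog`, `sdlog`, `min`,
#'   `max` (minutes): log-normal motionless period before the C1 moult,
#'   truncated to its support.
#' @param birth_jitter_min half-width (minutes) of the uniform recorded
#'   birth-time error.
#' @param dropout number of individuals lost to handling/misalignment (no
#'   usable frames; excluded from analysis).
#' @param seed integer RNG seed; identical configurations produce identical
#'   datasets.
#'
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_clutches = 9,
                              individuals_per_clutch = 8,
                              treatments = default_treatments(),
                              experiment_duration = 13 * MIN_PER_DAY,
                              frame_interval = 72,
                              stage_lengths = default_stage_lengths(),
                              stage_durations = default_stage_durations(),
                              copper_delay_log = 0.14,
                              cue_copper_interaction = 0.20,
                              copper_length_log = 0,
                              sex_length_log = 0.04,
                              clutch_sd_log_time = 0.05,
                              clutch_sd_log_length = 0.08,
                              clutch_copper_interaction_sd = 0.40,
                              copper_motionfree_log = 0.10,
                              individual_sd_log_time = 0.10,
                              individual_sd_log_length = 0.04,
                              stage_sd_log = 0.08,
                              measurement_cv = 0.05,
                              machine_bias = 1.10,
                              detection_by_stage = default_detection(),
                              unusable_episode_rate = 0.6,
                              unusable_episode_length = 2,
                              motionfree_duration_dist = list(
                                meanlog = log(160), sdlog = 0.45,
                                min = 72, max = 450),
                              birth_jitter_min = 30,
                              dropout = 3,
                              seed = 1L) {
  cfg <- list(
    n_clutches = as.integer(n_clutches),
    individuals_per_clutch = as.integer(individuals_per_clutch),
    treatments = as.data.frame(treatments),
    experiment_duration = experiment_duration,
    frame_interval = frame_interval,
    stage_lengths = stage_lengths,
    stage_durations = stage_durations,
    copper_delay_log = copper_delay_log,
    cue_copper_interaction = cue_copper_interaction,
    copper_length_log = copper_length_log,
    sex_length_log = sex_length_log,
    clutch_sd_log_time = clutch_sd_log_time,
    clutch_sd_log_length = clutch_sd_log_length,
    clutch_copper_interaction_sd = clutch_copper_interaction_sd,
    copper_motionfree_log = copper_motionfree_log,
    individual_sd_log_time = individual_sd_log_time,
    individual_sd_log_length = individual_sd_log_length,
    stage_sd_log = stage_sd_log,
    measurement_cv = measurement_cv,
    machine_bias = machine_bias,
    detection_by_stage = detection_by_stage,
    unusable_episode_rate = unusable_episode_rate,
    unusable_episode_length = unusable_episode_length,
    motionfree_duration_dist = motionfree_duration_dist,
    birth_jitter_min = birth_jitter_min,
    dropout = as.integer(dropout),
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_config(cfg)
  cfg
}

#' @rdname simulation_config
#' @export
default_treatments <- function() {
  data.frame(copper = c(FALSE, TRUE, FALSE, TRUE),
             cue = c(FALSE, FALSE, TRUE, TRUE))
}

#' @rdname simulation_config
#' @export
default_stage_lengths <- function() {
  stats::setNames(
    c(0.100, 0.125, 0.155, 0.190, 0.230, 0.280,
      0.340, 0.420, 0.500, 0.600, 0.710, 0.850),
    STAGE_NAMES)
}

#' @rdname simulation_config
#' @export
default_stage_durations <- function() {
  # Naupliar durations sum to 5.42 d: geometric-mean control N6->C1
  # transition of exp(1.69) days.
  stats::setNames(
    c(0.75, 0.80, 0.90, 0.95, 1.00, 1.02,
      0.95, 1.05, 1.10, 1.20, 1.30),
    STAGE_NAMES[1:11])
}

#' @rdname simulation_config
#' @export
default_detection <- function() {
  stats::setNames(
    c(rep(0.93, 6), rep(0.52, 5), 0.40),
    STAGE_NAMES)
}

validate_config <- function(cfg) {
  if (!all(c("copper", "cue") %in% names(cfg$treatments)))
    stopf("treatments must have logical columns 'copper' and 'cue'")
  if (length(cfg$stage_lengths) != 12L || any(diff(cfg$stage_lengths) <= 0))
    stopf("stage_lengths must be 12 strictly increasing values")
  if (length(cfg$stage_durations) != 11L || any(!is.finite(cfg$stage_durations)) ||
      any(cfg$stage_durations <= 0))
    stopf("stage_durations must be 11 positive finite values")
  if (length(cfg$detection_by_stage) != 12L ||
      any(cfg$detection_by_stage < 0) || any(cfg$detection_by_stage > 1))
    stopf("detection_by_stage must be 12 probabilities in [0, 1]")
  if (cfg$frame_interval <= 0) stopf("frame_interval must be positive")
  if (cfg$experiment_duration <= 0) stopf("experiment_duration must be positive")
  mf <- cfg$motionfree_duration_dist
  if (!all(c("meanlog", "sdlog", "min", "max") %in% names(mf)))
    stopf("motionfree_duration_dist needs meanlog, sdlog, min, max")
  if (mf$min <= 0 || mf$max < mf$min)
    stopf("motionfree_duration_dist support must satisfy 0 < min <= max")
  sds <- c(cfg$clutch_sd_log_time, cfg$clutch_sd_log_length,
           cfg$clutch_copper_interaction_sd, cfg$individual_sd_log_time,
           cfg$individual_sd_log_length, cfg$stage_sd_log,
           cfg$measurement_cv)
  if (any(sds < 0)) stopf("all SDs must be non-negative")
  if (cfg$machine_bias <= 0) stopf("machine_bias must be positive")
  # the copper stage multiplier must stay positive
  if (copper_stage_multiplier(cfg) <= 0)
    stopf("copper_delay_log incompatible with stage_durations (non-positive multiplier)")
  invisible(cfg)
}

# Multiplier applied to durations of all stages after N2 under copper, solved
# so that log(sum of mean naupliar durations) shifts by exactly
# copper_delay_log: the expected log N6->C1 transition time moves by that
# amount because clutch/individual factors scale both arms identically.
copper_stage_multiplier <- function(cfg) {
  mu <- cfg$stage_durations
  s_all <- sum(mu[1:6])
  s_12 <- sum(mu[1:2])
  s_36 <- sum(mu[3:6])
  (exp(cfg$copper_delay_log) * s_all - s_12) / s_36
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  %d clutches x %d individuals = %d total; %d treatment arms\n",
              x$n_clutches, x$individuals_per_clutch,
              x$n_clutches * x$individuals_per_clutch, nrow(x$treatments)))
  cat(sprintf("  %.1f days at one frame per %g min (%d frames)\n",
              x$experiment_duration / MIN_PER_DAY, x$frame_interval,
              n_scheduled_frames(x)))
  cat(sprintf("  copper delay (log N6->C1 time): %g; cue x copper (copepodite): %g\n",
              x$copper_delay_log, x$cue_copper_interaction))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

n_scheduled_frames <- function(cfg) {
  as.integer(floor(cfg$experiment_duration / cfg$frame_interval))
}
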