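#' Draw clutch-level random effects
#'
#' One independent RNG substream per clutch, so effects are reproducible and
#' unaffected by how many individuals are simulated.
#'
#' @param config a [simulation_config()].
#' @param clutch_ids character vector of clutch labels.
#' @return Data frame with columns `clutch_id`, `log_time` (effect on log
#'   stage durations), `log_length` (effect on log stage lengths) and
#'   `copper_moult` (clutch-specific copper sensitivity of the motion-free
#'   moult duration, log scale).
#' @export
draw_clutch_effects <- function(config, clutch_ids = clutch_labels(config)) {
  eff <- lapply(clutch_ids, function(cl) {
    with_seed(rng_substream(config$seed, "clutch", cl), {
      data.frame(clutch_id = cl,
                 log_time = stats::rnorm(1, 0, config$clutch_sd_log_time),
                 log_length = stats::rnorm(1, 0, config$clutch_sd_log_length),
                 copper_moult = stats::rnorm(1, 0, config$clutch_copper_interaction_sd))
    })
  })
  do.call(rbind, eff)
}

#' Clutch labels for a configuration
#'
#' Uses the conventional brood labels (D1--D3, S1--S6) when nine or fewer
#' clutches are configured.
#' @param config a [simulation_config()].
#' @export
clutch_labels <- function(config) {
  std <- c("D1", "D2", "D3", "S1", "S2", "S3", "S4", "S5", "S6")
  n <- config$n_clutches
  if (n <= length(std)) std[seq_len(n)] else sprintf("C%02d", seq_len(n))
}

#' Simulate one individual's true developmental trajectory
#'
#' Stage-entry times are cumulative sums of log-normal stage durations,
#' scaled by clutch, individual and treatment factors. Copper multiplies the
#' durations of all post-N2 stages so the expected log N6-to-C1 transition
#' time shifts by `copper_delay_log`; the copper-with-cue combination adds
#' further delay to the copepodite stages only. The true length path is a
#' non-decreasing step function over stages.
#'
#' @param config a [simulation_config()].
#' @param individual_id character id; also names the RNG substream.
#' @param clutch_id clutch label present in `clutch_effects`.
#' @param clutch_effects data frame from [draw_clutch_effects()].
#' @param treatment list or one-row data frame with logical `copper`, `cue`.
#' @return An object of class `true_trajectory`: a list with `individual_id`,
#'   `clutch_id`, `copper`, `cue`, `moult_times` (minutes, entry times of the
#'   12 stages; stage 1 entered at birth), `stage_lengths` (true mm per
#'   stage), `maturation_time` (minutes, `NA` if the adult stage was not
#'   reached within the experiment), `sex` (`"F"`, `"M"`, or `"copepodite"`
#'   when maturation is censored), `sex_latent`, `motionfree_min` (drawn
#'   motionless period before the C1 moult) and `birth_jitter` (recorded
#'   birth-time error, minutes).
#' @export
simulate_individual <- function(config, individual_id, clutch_id,
                                clutch_effects = draw_clutch_effects(config),
                                treatment = list(copper = FALSE, cue = FALSE)) {
  ce <- clutch_effects[clutch_effects$clutch_id == clutch_id, , drop = FALSE]
  if (nrow(ce) != 1L) stopf("clutch '%s' not found in clutch_effects", clutch_id)
  copper <- isTRUE(as.logical(treatment$copper))
  cue <- isTRUE(as.logical(treatment$cue))

  with_seed(rng_substream(config$seed, "ind", individual_id), {
    sex_latent <- if (stats::runif(1) < 0.5) "F" else "M"
    ind_time <- stats::rnorm(1, 0, config$individual_sd_log_time)
    ind_len <- stats::rnorm(1, 0, config$individual_sd_log_length)
    eps <- stats::rnorm(11, 0, config$stage_sd_log)
    z_mf <- stats::rnorm(1)
    birth_jitter <- stats::runif(1, -config$birth_jitter_min,
                                 config$birth_jitter_min)
  })

  mult <- rep(1, 11)
  if (copper) {
    mult[3:11] <- mult[3:11] * copper_stage_multiplier(config)
    if (cue) mult[7:11] <- mult[7:11] * exp(config$cue_copper_interaction)
  }
  durations_days <- config$stage_durations * mult *
    exp(ce$log_time + ind_time + eps)
  if (any(!is.finite(durations_days)) || any(durations_days <= 0))
    stopf("non-finite or non-positive stage durations for '%s': check configuration",
          individual_id)

  moult_times <- c(0, cumsum(durations_days) * MIN_PER_DAY)
  names(moult_times) <- STAGE_NAMES
  maturation_time <- if (moult_times["adult"] <= config$experiment_duration)
    unname(moult_times["adult"]) else NA_real_

  len_fac <- exp(ce$log_length + ind_len +
                   (if (copper) config$copper_length_log else 0))
  lengths <- config$stage_lengths * len_fac
  if (sex_latent == "M")
    lengths[7:12] <- lengths[7:12] * exp(config$sex_length_log)

  mf <- config$motionfree_duration_dist
  motionfree_min <- exp(mf$meanlog +
                          (if (copper) config$copper_motionfree_log + ce$copper_moult else 0) +
                          mf$sdlog * z_mf)
  motionfree_min <- min(max(motionfree_min, mf$min), mf$max)

  structure(list(
    individual_id = individual_id,
    clutch_id = clutch_id,
    copper = copper,
    cue = cue,
    moult_times = moult_times,
    stage_lengths = lengths,
    maturation_time = maturation_time,
    sex = if (is.na(maturation_time)) "copepodite" else sex_latent,
    sex_latent = sex_latent,
    motionfree_min = motionfree_min,
    birth_jitter = birth_jitter
  ), class = "true_trajectory")
}

#' True body length at given times
#'
#' Evaluates a trajectory's step-function length path.
#' @param traj a `true_trajectory`.
#' @param times numeric vector of minutes since birth.
#' @return numeric vector of true lengths (mm).
#' @export
true_length_at <- function(traj, times) {
  stage <- findInterval(times, traj$moult_times)
  stage[stage < 1L] <- 1L
  stage[stage > 12L] <- 12L
  unname(traj$stage_lengths[stage])
}

#' @export
print.true_trajectory <- function(x, ...) {
  cat(sprintf("True trajectory %s (clutch %s, copper=%s, cue=%s)\n",
              x$individual_id, x$clutch_id, x$copper, x$cue))
  cat(sprintf("  N6->C1 at %.0f min (%.2f d); maturation: %s; sex: %s\n",
              x$moult_times["C1"], x$moult_times["C1"] / MIN_PER_DAY,
              if (is.na(x$maturation_time)) "censored"
              else sprintf("%.2f d", x$maturation_time / MIN_PER_DAY),
              x$sex))
  invisible(x)
}
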