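#' Simulate a complete synthetic imaging experiment
#'
#' Generates the full dataset the analysis pipeline consumes: an individuals
#' (linking) table with clutch, treatment, recorded birth time and end
#' status; stacked per-frame measurement records; the frame log; and the
#' ground-truth trajectories for recovery tests. Treatments are assigned in
#' balance within each clutch (with a rotating offset across clutches so no
#' treatment is confounded with within-clutch position); a warning is issued
#' when the total number of individuals is not divisible by the number of
#' treatment arms. `dropout` individuals are marked `lost` and yield no
#' usable frames.
#'
#' @param config a [simulation_config()].
#' @return Object of class `synthetic_experiment`: list with `individuals`,
#'   `measurements`, `frame_log`, `truth` (list: `individuals` with latent
#'   sex, maturation and motion-free truth; `moults` with per-stage entry
#'   times and true lengths), `clutch_effects`, and `config`.
#' @export
simulate_experiment <- function(config = simulation_config()) {
  validate_config(config)
  n_treat <- nrow(config$treatments)
  total <- config$n_clutches * config$individuals_per_clutch
  if (total %% n_treat != 0L)
    warnf("%d individuals not divisible by %d treatments: assignment is near-balanced",
          total, n_treat)
  clutches <- clutch_labels(config)
  ce <- draw_clutch_effects(config, clutches)

  lost_idx <- integer(0)
  if (config$dropout > 0L) {
    lost_idx <- with_seed(rng_substream(config$seed, "dropout"),
                          sample.int(total, min(config$dropout, total)))
  }

  individuals <- list(); measurements <- list(); frame_logs <- list()
  truth_ind <- list(); truth_moults <- list()
  idx <- 0L
  for (ci in seq_along(clutches)) {
    treat_order <- ((seq_len(config$individuals_per_clutch) - 1L + (ci - 1L)) %%
                      n_treat) + 1L
    for (wi in seq_len(config$individuals_per_clutch)) {
      idx <- idx + 1L
      id <- sprintf("%s-%02d", clutches[ci], wi)
      trt <- config$treatments[treat_order[wi], ]
      traj <- simulate_individual(config, id, clutches[ci], ce, trt)
      obs <- simulate_observations(traj, config)
      lost <- idx %in% lost_idx
      if (lost) {
        obs$measurements$usable <- FALSE
        obs$measurements$length_mm <- NA_real_
        obs$frame_log$usable <- FALSE
        obs$frame_log$copepodite_visible <- FALSE
      }
      end_status <- if (lost) "lost"
        else if (!is.na(traj$maturation_time)) "matured" else "copepodite"
      individuals[[idx]] <- data.frame(
        individual_id = id,
        clutch_id = clutches[ci],
        copper = isTRUE(trt$copper),
        cue = isTRUE(trt$cue),
        birth_time_min = traj$birth_jitter,
        sex = if (lost) NA_character_ else traj$sex,
        end_status = end_status,
        stringsAsFactors = FALSE)
      measurements[[idx]] <- obs$measurements
      frame_logs[[idx]] <- obs$frame_log
      truth_ind[[idx]] <- data.frame(
        individual_id = id,
        sex_latent = traj$sex_latent,
        maturation_time_min = traj$maturation_time,
        motionfree_min = traj$motionfree_min,
        birth_jitter_min = traj$birth_jitter,
        stringsAsFactors = FALSE)
      truth_moults[[idx]] <- data.frame(
        individual_id = id,
        stage = STAGE_NAMES,
        entry_time_min = unname(traj$moult_times),
        true_length_mm = unname(traj$stage_lengths),
        stringsAsFactors = FALSE)
    }
  }

  structure(list(
    individuals = do.call(rbind, individuals),
    measurements = do.call(rbind, measurements),
    frame_log = do.call(rbind, frame_logs),
    truth = list(individuals = do.call(rbind, truth_ind),
                 moults = do.call(rbind, truth_moults)),
    clutch_effects = ce,
    config = config
  ), class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  usable <- tapply(x$measurements$usable, x$measurements$individual_id, sum)
  analyzable <- x$individuals$end_status != "lost"
  cat(sprintf("Synthetic experiment: %d individuals (%d analyzable), %d clutches\n",
              nrow(x$individuals), sum(analyzable),
              length(unique(x$individuals$clutch_id))))
  cat(sprintf("  %d scheduled frames per individual; mean usable %.1f (analyzable only)\n",
              n_scheduled_frames(x$config),
              mean(usable[x$individuals$individual_id[analyzable]])))
  cat(sprintf("  end status: %s\n",
              paste(sprintf("%s=%d", names(table(x$individuals$end_status)),
                            table(x$individuals$end_status)), collapse = ", ")))
  invisible(x)
}

#' Simulate paired machine and microscope length measurements
#'
#' Generates the paired daily data used to exercise the machine-versus-manual
#' calibration regression: per (individual, day) a manual microscope length
#' along a growth ramp and a machine length `intercept + slope * manual +
#' individual offset + noise`.
#'
#' @param n_individuals number of individuals.
#' @param days days of paired measurements per individual.
#' @param slope,intercept true calibration line.
#' @param sd_individual SD of individual-level random intercepts (mm).
#' @param sd_resid residual SD (mm).
#' @param seed RNG seed.
#' @return Data frame with `individual_id`, `day`, `manual_mm`, `machine_mm`.
#' @export
simulate_calibration_pairs <- function(n_individuals = 30, days = 10,
                                       slope = 0.90, intercept = 0.05,
                                       sd_individual = 0.02, sd_resid = 0.03,
                                       seed = 1L) {
  with_seed(rng_substream(seed, "calibration"), {
    b <- stats::rnorm(n_individuals, 0, sd_individual)
    out <- lapply(seq_len(n_individuals), function(i) {
      manual <- seq(0.12, 0.80, length.out = days) *
        exp(stats::rnorm(days, 0, 0.05))
      data.frame(individual_id = sprintf("ind%03d", i),
                 day = seq_len(days) - 1L,
                 manual_mm = manual,
                 machine_mm = intercept + slope * manual + b[i] +
                   stats::rnorm(days, 0, sd_resid),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
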