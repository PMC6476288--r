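#' Simulate the observation process for one trajectory
#'
#' Emulates the automated imaging platform: one scheduled frame per
#' `frame_interval` minutes over the experiment. A frame is unusable during
#' episodic runs (water changes, camera misalignment); an otherwise usable
#' frame yields a length with stage-dependent probability (young benthic
#' stages image well, older stages swim in the water column). Usable frames
#' carry `machine_bias * true length * (1 + noise)`. Recorded ages carry the
#' individual's birth-time error. The frame log flags, per frame, usability,
#' whether a copepodite is visible, and whether the animal is motionless
#' (during the drawn pre-C1 window, including the first frame in which the
#' copepodite is seen in the same position).
#'
#' @param traj a [simulate_individual()] trajectory.
#' @param config the [simulation_config()] used to create it.
#' @return List with `measurements` (data frame: `individual_id`,
#'   `frame_index`, `time_min` recorded age, `length_mm` (`NA` when
#'   unusable), `usable`) and `frame_log` (adds `stage`,
#'   `copepodite_visible`, `motion_free`).
#' @export
simulate_observations <- function(traj, config) {
  n <- n_scheduled_frames(config)
  t_true <- config$frame_interval * seq_len(n)
  stage_idx <- findInterval(t_true, traj$moult_times)
  stage_idx[stage_idx < 1L] <- 1L
  stage_idx[stage_idx > 12L] <- 12L

  with_seed(rng_substream(config$seed, "obs", traj$individual_id), {
    # episodic unusable frames
    in_episode <- logical(n)
    p_start <- min(1, config$unusable_episode_rate * config$frame_interval / MIN_PER_DAY)
    i <- 1L
    while (i <= n) {
      if (stats::runif(1) < p_start) {
        len <- stats::rgeom(1, 1 / config$unusable_episode_length) + 1L
        in_episode[i:min(n, i + len - 1L)] <- TRUE
        i <- i + len
      } else {
        i <- i + 1L
      }
    }
    detected <- stats::runif(n) < config$detection_by_stage[stage_idx]
    noise <- stats::rnorm(n, 0, config$measurement_cv)
  })

  usable <- !in_episode & detected
  length_mm <- rep(NA_real_, n)
  length_mm[usable] <- config$machine_bias *
    true_length_at(traj, t_true[usable]) * (1 + noise[usable])

  # motionless window preceding the C1 moult. The freshly moulted copepodite
  # stays put until it is first seen: the window runs from k frames before C1
  # entry up to the first usable frame at or after it (the screening
  # convention counts the first picture showing the copepodite in the same
  # position), or the entry frame itself when no later frame is usable.
  motion_free <- logical(n)
  t_c1 <- unname(traj$moult_times["C1"])
  if (t_c1 <= max(t_true)) {
    j0 <- which(t_true >= t_c1)[1]
    j_vis <- which(usable & t_true >= t_c1)[1]
    if (is.na(j_vis)) j_vis <- j0
    k <- max(1L, as.integer(round(traj$motionfree_min / config$frame_interval)))
    motion_free[max(1L, j0 - k + 1L):j_vis] <- TRUE
  }

  time_rec <- t_true - traj$birth_jitter
  measurements <- data.frame(
    individual_id = traj$individual_id,
    frame_index = seq_len(n),
    time_min = time_rec,
    length_mm = length_mm,
    usable = usable,
    stringsAsFactors = FALSE
  )
  frame_log <- data.frame(
    individual_id = traj$individual_id,
    frame_index = seq_len(n),
    time_min = time_rec,
    stage = STAGE_NAMES[stage_idx],
    usable = usable,
    copepodite_visible = usable & stage_idx >= 7L,
    motion_free = motion_free,
    stringsAsFactors = FALSE
  )
  list(measurements = measurements, frame_log = frame_log)
}
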