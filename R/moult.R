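# Topographic prominence of local maxima in a numeric series: for each peak,
# the drop from the peak to the higher of the two lowest points separating it
# from higher terrain. A side that runs into the series end without meeting
# higher terrain imposes no key (the observation window's cut is not
# terrain); a peak truncated at the window edge keeps its full prominence
# from the other side.
peak_prominence <- function(x) {
  n <- length(x)
  # A peak must rise out of preceding terrain: the first sample is never a
  # peak (a series that starts mid-decline shows no onset), while a rise
  # into the final sample is (a moult truncated by the window end).
  is_peak <- which(vapply(seq_len(n), function(i) {
    left_ok <- i > 1L && x[i] > x[i - 1L]
    right_ok <- i == n || x[i] >= x[i + 1L]
    left_ok && right_ok
  }, logical(1)))
  prom <- vapply(is_peak, function(i) {
    left_min <- x[i]
    left_bounded <- FALSE
    j <- i
    while (j > 1L) {
      j <- j - 1L
      if (x[j] > x[i]) { left_bounded <- TRUE; break }
      left_min <- min(left_min, x[j])
    }
    right_min <- x[i]
    right_bounded <- FALSE
    j <- i
    while (j < n) {
      j <- j + 1L
      if (x[j] > x[i]) { right_bounded <- TRUE; break }
      right_min <- min(right_min, x[j])
    }
    key <- if (left_bounded && right_bounded) max(left_min, right_min)
      else if (left_bounded) left_min
      else if (right_bounded) right_min
      else min(left_min, right_min)
    x[i] - key
  }, numeric(1))
  list(index = is_peak, prominence = prom)
}

#' Detect moult events as growth-increment peaks
#'
#' Local maxima of the increment series with topographic prominence at least
#' `min_prominence`; maxima closer together than `min_separation` are merged
#' keeping the larger (ties broken to the earlier one -- a moult is an onset
#' event). The default prominence threshold is half the median positive
#' increment of the series (restricted to times before `naupliar_until` when
#' supplied, approximating the naupliar phase), with an absolute floor of
#' `prominence_floor` mm so numerical dust in near-noiseless series never
#' qualifies.
#'
#' @param increments a [growth_increments()] data frame (one or many
#'   individuals).
#' @param min_prominence minimum prominence (mm per step); `NULL` for the
#'   per-individual default.
#' @param min_separation minimum time between events, minutes.
#' @param naupliar_until optional named numeric (individual_id -> minutes):
#'   restrict the default-prominence baseline to increments before this time.
#' @param prominence_floor absolute lower bound on the default threshold.
#' @return Data frame of events: `individual_id`, `event_time_min` (right
#'   endpoint of the increment interval), `amplitude_mm`, `rank`.
#' @export
detect_peaks <- function(increments, min_prominence = NULL,
                         min_separation = 720,
                         naupliar_until = NULL,
                         prominence_floor = 0.004) {
  out <- lapply(split(increments, increments$individual_id), function(s) {
    s <- s[order(s$time_min), ]
    x <- s$increment_mm
    if (!length(x)) return(NULL)
    thr <- min_prominence
    if (is.null(thr)) {
      base <- x
      lim <- naupliar_until[[s$individual_id[1]]]
      if (!is.null(lim) && !is.na(lim)) base <- x[s$time_min <= lim]
      pos <- base[base > 0]
      thr <- max(0.5 * (if (length(pos)) stats::median(pos) else 0),
                 prominence_floor)
    }
    pk <- peak_prominence(x)
    keep <- pk$prominence >= thr & x[pk$index] > 0
    idx <- pk$index[keep]
    if (!length(idx)) return(NULL)
    # merge close maxima: greedy by height (ties -> earlier)
    ord <- idx[order(-x[idx], s$time_min[idx])]
    accepted <- integer(0)
    for (i in ord) {
      if (!length(accepted) ||
          all(abs(s$time_min[i] - s$time_min[accepted]) >= min_separation))
        accepted <- c(accepted, i)
    }
    accepted <- sort(accepted)
    data.frame(individual_id = s$individual_id[1],
               event_time_min = s$time_min[accepted],
               amplitude_mm = x[accepted],
               rank = seq_along(accepted),
               stringsAsFactors = FALSE)
  })
  out <- rbind_rows(out)
  if (is.null(out))
    out <- data.frame(individual_id = character(), event_time_min = numeric(),
                      amplitude_mm = numeric(), rank = integer())
  out
}

#' Screen frame logs for the naupliar-to-copepodite transition
#'
#' Emulates the manual screening of images for the first occurrence of the
#' copepodite stage. The transition time is the time of the first
#' copepodite-visible frame; the number of 'uncertain' frames is the run
#' length of unusable frames immediately preceding it (frames in which the
#' stage could not be judged); the motion-free count is the run of
#' motionless frames ending at, and including, the first copepodite frame.
#' Individuals with no copepodite-visible frame are returned censored.
#'
#' @param frame_log data frame with `individual_id`, `frame_index`,
#'   `time_min`, `usable`, `copepodite_visible`, `motion_free`.
#' @return Data frame: `individual_id`, `status` (`"observed"` or
#'   `"censored"`), `transition_time_min`, `n_uncertain_frames`,
#'   `motion_free_frames`.
#' @export
screen_c1_transition <- function(frame_log) {
  rows <- lapply(split(frame_log, frame_log$individual_id), function(fl) {
    fl <- fl[order(fl$frame_index), ]
    j <- which(fl$copepodite_visible)[1]
    if (is.na(j)) {
      return(data.frame(individual_id = fl$individual_id[1],
                        status = "censored",
                        transition_time_min = NA_real_,
                        n_uncertain_frames = NA_integer_,
                        motion_free_frames = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    n_unc <- 0L
    i <- j - 1L
    while (i >= 1L && !fl$usable[i]) {
      n_unc <- n_unc + 1L
      i <- i - 1L
    }
    mf <- 0L
    i <- j
    while (i >= 1L && isTRUE(fl$motion_free[i])) {
      mf <- mf + 1L
      i <- i - 1L
    }
    data.frame(individual_id = fl$individual_id[1],
               status = "observed",
               transition_time_min = fl$time_min[j],
               n_uncertain_frames = n_unc,
               motion_free_frames = mf,
               stringsAsFactors = FALSE)
  })
  rbind_rows(rows)
}

#' Moult duration from motion-free frames
#'
#' Duration of the N6-to-C1 moult: the number of consecutive motion-free
#' frames (including the first frame in which the copepodite is detected in
#' the same position) times the frame interval. With no motion-free frame
#' detected the duration is censored below at one frame interval -- the
#' observable minimum. Individuals without an observed transition carry no
#' duration.
#'
#' @param frame_log as for [screen_c1_transition()].
#' @param frame_interval minutes between frames.
#' @return Data frame: `individual_id`, `duration_status` (`"observed"`,
#'   `"censored_below"`, `"censored"`), `motion_free_frames`,
#'   `duration_min`.
#' @export
moult_duration <- function(frame_log, frame_interval = 72) {
  tr <- screen_c1_transition(frame_log)
  status <- ifelse(tr$status == "censored", "censored",
                   ifelse(tr$motion_free_frames == 0L, "censored_below",
                          "observed"))
  duration <- ifelse(tr$status == "censored", NA_real_,
                     pmax(tr$motion_free_frames, 1L) * frame_interval)
  data.frame(individual_id = tr$individual_id,
             duration_status = status,
             motion_free_frames = tr$motion_free_frames,
             duration_min = duration,
             stringsAsFactors = FALSE)
}

#' Treatment-averaged growth-increment curves
#'
#' Re-bins individual increment series (whose grids are anchored at each
#' individual's first usable time) onto common fixed-width bins from birth
#' and averages over the individuals present in each bin, per treatment
#' combination. Empty bins are absent, not zero. A lower averaged peak
#' indicates larger between-individual variability in transition timing.
#'
#' @param increments a [growth_increments()] data frame.
#' @param individuals data frame with `individual_id`, `copper`, `cue`.
#' @param resolution bin width in minutes.
#' @return Data frame: `copper`, `cue`, `treatment`, `time_min` (right bin
#'   edge), `mean_increment_mm`, `n`.
#' @export
average_increments_by_treatment <- function(increments, individuals,
                                            resolution = 72) {
  d <- merge(increments,
             individuals[, c("individual_id", "copper", "cue")],
             by = "individual_id")
  d$bin <- floor(d$time_min / resolution)
  agg <- stats::aggregate(d$increment_mm,
                          by = list(copper = d$copper, cue = d$cue, bin = d$bin),
                          FUN = mean)
  cnt <- stats::aggregate(d$increment_mm,
                          by = list(copper = d$copper, cue = d$cue, bin = d$bin),
                          FUN = length)
  out <- data.frame(copper = agg$copper, cue = agg$cue,
                    treatment = treatment_label(agg$copper, agg$cue),
                    time_min = (agg$bin + 1) * resolution,
                    mean_increment_mm = agg$x,
                    n = as.integer(cnt$x),
                    stringsAsFactors = FALSE)
  out[order(out$treatment, out$time_min), , drop = FALSE]
}

#' Treatment labels from copper / cue flags
#' @param copper,cue logical vectors.
#' @export
treatment_label <- function(copper, cue) {
  ifelse(copper & cue, "copper+cue",
         ifelse(copper, "copper", ifelse(cue, "cue", "control")))
}
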