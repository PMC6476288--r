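uncertainty_weights <- function(n_uncertain, mode = c("inverse", "literal")) {
  mode <- match.arg(mode)
  # Inverse weighting down-weights transitions preceded by many uncertain
  # frames (the statistically coherent reading); the literal mode uses the
  # raw uncertain-frame count as the weight, which up-weights the least
  # certain observations and silently drops the fully certain ones
  # (weight 0). Kept selectable; inverse is the default.
  if (mode == "inverse") 1 / (1 + n_uncertain) else as.numeric(n_uncertain)
}

prepare_transitions <- function(transitions, individuals) {
  tr <- transitions[transitions$status == "observed", , drop = FALSE]
  if (!nrow(tr)) stopf("no uncensored transitions to model")
  d <- merge(tr, individuals, by = "individual_id")
  d$clutch_id <- factor(d$clutch_id)
  d
}

#' Stressor effects on the N6-to-C1 transition time
#'
#' Weighted linear models of log transition time (days) with copper,
#' predator cue and clutch as predictors (all pairwise interactions in the
#' full model), AICc-selected and conditionally averaged. Observation
#' weights reflect the uncertain-frame count of each transition. With
#' `include_sex = TRUE` the data are restricted to matured individuals and
#' clutch is replaced by sex, mirroring the sex-specific variant.
#'
#' @param transitions a [screen_c1_transition()] data frame.
#' @param individuals data frame with `individual_id`, `clutch_id`,
#'   `copper`, `cue`, `sex`, `end_status`.
#' @param include_sex restrict to matured individuals and model sex.
#' @param weights_mode `"inverse"` (default, `1/(1+n_uncertain)`) or
#'   `"literal"` (raw count).
#' @param delta AICc window for model averaging.
#' @return An [select_and_average()] result with attributes `weights_mode`
#'   and `response`.
#' @export
transition_time_model <- function(transitions, individuals,
                                  include_sex = FALSE,
                                  weights_mode = c("inverse", "literal"),
                                  delta = 2) {
  weights_mode <- match.arg(weights_mode)
  d <- prepare_transitions(transitions, individuals)
  if (include_sex) {
    d <- d[d$end_status == "matured" & d$sex %in% c("F", "M"), , drop = FALSE]
    if (!nrow(d)) stopf("no matured individuals for the sex model")
    d$sex <- factor(d$sex, levels = c("F", "M"))
  }
  d$log_days <- log(d$transition_time_min / MIN_PER_DAY)
  w <- uncertainty_weights(d$n_uncertain_frames, weights_mode)
  terms <- if (include_sex)
    c("copper", "cue", "sex", "copper:cue", "copper:sex", "cue:sex")
  else
    c("copper", "cue", "clutch_id", "copper:cue", "copper:clutch_id",
      "cue:clutch_id")
  fits <- fit_candidate_lms("log_days", terms, d, w)
  out <- select_and_average(fits, delta)
  attr(out, "weights_mode") <- weights_mode
  attr(out, "response") <- "log(transition time, days)"
  out
}

#' Stressor and clutch effects on moult duration
#'
#' Weighted linear models of the square-root transformed motion-free moult
#' duration (minutes), with clutch, copper and cue as predictors and the
#' clutch-by-copper interaction estimable in the full model; AICc-selected
#' and conditionally averaged, with uncertain-frame weights.
#'
#' @inheritParams transition_time_model
#' @param frame_interval minutes between frames (sets the duration floor).
#' @export
moult_duration_model <- function(transitions, individuals,
                                 frame_interval = 72,
                                 weights_mode = c("inverse", "literal"),
                                 delta = 2) {
  weights_mode <- match.arg(weights_mode)
  d <- prepare_transitions(transitions, individuals)
  d$duration_min <- pmax(d$motion_free_frames, 1L) * frame_interval
  d$sqrt_duration <- sqrt(d$duration_min)
  w <- uncertainty_weights(d$n_uncertain_frames, weights_mode)
  terms <- c("copper", "cue", "clutch_id", "copper:cue",
             "copper:clutch_id", "cue:clutch_id")
  fits <- fit_candidate_lms("sqrt_duration", terms, d, w)
  out <- select_and_average(fits, delta)
  attr(out, "weights_mode") <- weights_mode
  attr(out, "response") <- "sqrt(moult duration, min)"
  out
}

#' Stressor effects on final body size
#'
#' Restricts the data to usable measurements from the last experimental day,
#' averages them per individual, and models the log mean length with copper,
#' cue and clutch (plus sex when `matured_only`), AICc-selected and
#' conditionally averaged. Individuals without a last-day record are
#' excluded with a warning.
#'
#' @param dataset a `copepod_dataset` (or `synthetic_experiment`).
#' @param matured_only restrict to matured individuals and add sex.
#' @param delta AICc window.
#' @export
endpoint_size_model <- function(dataset, matured_only = FALSE, delta = 2) {
  if (inherits(dataset, "synthetic_experiment")) dataset <- as_dataset(dataset)
  m <- dataset$measurements[dataset$measurements$usable, ]
  # the experiment's last day: the final 1440 minutes before the latest
  # usable record (individual ages differ by the small birth-time error, so
  # a calendar-day bin would be ragged at the end)
  md <- m[m$time_min > max(m$time_min) - MIN_PER_DAY, ]
  mean_len <- tapply(md$length_mm, md$individual_id, mean)
  ind <- dataset$individuals
  if ("end_status" %in% names(ind)) ind <- ind[ind$end_status != "lost", ]
  absent <- setdiff(ind$individual_id, names(mean_len))
  if (length(absent))
    warnf("%d individual(s) without last-day measurements excluded: %s",
          length(absent), paste(utils::head(absent, 5), collapse = ", "))
  d <- merge(ind, data.frame(individual_id = names(mean_len),
                             mean_len = as.numeric(mean_len),
                             stringsAsFactors = FALSE),
             by = "individual_id")
  if (matured_only) {
    d <- d[d$end_status == "matured" & d$sex %in% c("F", "M"), , drop = FALSE]
    if (!nrow(d)) stopf("no matured individuals for the endpoint sex model")
    d$sex <- factor(d$sex, levels = c("F", "M"))
  }
  d$clutch_id <- factor(d$clutch_id)
  d$log_len <- log(d$mean_len)
  terms <- c("copper", "cue", "clutch_id", "copper:cue",
             if (matured_only) "sex")
  fits <- fit_candidate_lms("log_len", terms, d)
  out <- select_and_average(fits, delta)
  attr(out, "response") <- "log(mean last-day length, mm)"
  out
}

#' Machine-versus-manual length calibration
#'
#' Mixed-effects regression of daily machine length means on paired manual
#' microscope lengths, with an individual-level random intercept to account
#' for repeated measures. Optionally adds treatment fixed effects to test
#' whether treatments influence the relationship.
#'
#' @param pairs data frame with `individual_id`, `manual_mm`, `machine_mm`
#'   (and `copper`, `cue` when `include_treatment`).
#' @param include_treatment add copper and cue fixed effects.
#' @return Object of class `calibration_fit`: list with `slope`, `se`,
#'   `intercept`, `fit` (the `lmerMod`).
#' @export
calibration_regression <- function(pairs, include_treatment = FALSE) {
  if (length(unique(pairs$individual_id)) < 2L)
    stopf("calibration requires at least 2 individuals")
  rhs <- "manual_mm + (1 | individual_id)"
  if (include_treatment) rhs <- paste("copper + cue +", rhs)
  fit <- lme4::lmer(stats::as.formula(paste("machine_mm ~", rhs)),
                    data = pairs, REML = TRUE)
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  structure(list(slope = unname(fe["manual_mm"]),
                 se = unname(se[names(fe) == "manual_mm"]),
                 intercept = unname(fe["(Intercept)"]),
                 fit = fit),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Machine ~ manual calibration: slope %.3f (SE %.3f), intercept %.3f\n",
              x$slope, x$se, x$intercept))
  invisible(x)
}
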