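hgam_prepare <- function(measurements, individuals, min_cell) {
  d <- merge(measurements[measurements$usable, , drop = FALSE],
             individuals[, c("individual_id", "clutch_id", "copper", "cue")],
             by = "individual_id")
  d$age <- d$time_min
  d$well <- factor(d$individual_id)
  d$clutch_id <- factor(d$clutch_id)
  d$treat <- treatment_label(d$copper, d$cue)
  cell <- paste(d$treat, d$clutch_id, sep = ".")
  per_cell <- tapply(d$individual_id, cell, function(x) length(unique(x)))
  small <- names(per_cell)[per_cell < min_cell]
  if (length(small))
    message(sprintf("%d treatment x clutch cell(s) below %d individuals absorbed into treatment-level smooths",
                    length(small), min_cell))
  grp <- ifelse(cell %in% small, d$treat, cell)
  d$grp <- factor(grp)
  d
}

hgam_formula <- function(response, k, fs_k, include_individual) {
  rhs <- sprintf("clutch_id + copper + cue + s(age, by = grp, k = %d, bs = \"ps\")", k)
  if (include_individual)
    rhs <- paste0(rhs, sprintf(" + s(age, well, bs = \"fs\", m = 1, k = %d)", fs_k))
  stats::as.formula(paste(response, "~", rhs))
}

hgam_fit <- function(d, response, k, fs_k, include_individual, method, use_bam) {
  f <- hgam_formula(response, k, fs_k, include_individual)
  if (use_bam)
    mgcv::bam(f, data = d, method = "fREML", discrete = TRUE)
  else
    mgcv::gam(f, data = d, method = method)
}

#' Hierarchical GAM for length over age
#'
#' Models log body length as parametric clutch, copper and cue offsets plus
#' one smooth age curve per treatment-by-clutch combination and
#' per-individual deviation smooths (a factor smooth with first-order
#' penalty and shared smoothing -- a functional random effect). Treatment x
#' clutch cells with fewer than `min_cell` individuals are absorbed into
#' treatment-level smooths with a message.
#'
#' @param dataset a `copepod_dataset` (or `synthetic_experiment`).
#' @param k basis dimension of the group smooths.
#' @param fs_k basis dimension of the per-individual factor smooths.
#' @param min_cell minimum individuals per treatment x clutch cell.
#' @param include_individual include the per-individual deviation smooths
#'   (disable only for nested-model comparisons).
#' @param method smoothing selection criterion for `mgcv::gam`.
#' @param use_bam fit with `mgcv::bam(discrete = TRUE)` for large data.
#' @return Object of class `hgam_fit`: list with `fit`, `data`, `response`.
#' @export
hgam_length_model <- function(dataset, k = 40, fs_k = min(k, 10),
                              min_cell = 3, include_individual = TRUE,
                              method = "REML", use_bam = FALSE) {
  if (inherits(dataset, "synthetic_experiment")) dataset <- as_dataset(dataset)
  d <- hgam_prepare(dataset$measurements, dataset$individuals, min_cell)
  d$log_length <- log(d$length_mm)
  fit <- hgam_fit(d, "log_length", k, fs_k, include_individual, method, use_bam)
  structure(list(fit = fit, data = d, response = "log(length, mm)"),
            class = "hgam_fit")
}

#' Hierarchical GAM for growth increments over age
#'
#' Same structure as [hgam_length_model()] with the isochronal growth
#' increment (mm per step, negatives retained) as response.
#'
#' @param increments a [growth_increments()] data frame.
#' @param individuals data frame with `individual_id`, `clutch_id`,
#'   `copper`, `cue`.
#' @inheritParams hgam_length_model
#' @export
hgam_increment_model <- function(increments, individuals, k = 40,
                                 fs_k = min(k, 10), min_cell = 3,
                                 include_individual = TRUE,
                                 method = "REML", use_bam = FALSE) {
  inc <- increments
  inc$usable <- TRUE
  d <- hgam_prepare(inc, individuals, min_cell)
  fit <- hgam_fit(d, "increment_mm", k, fs_k, include_individual, method, use_bam)
  structure(list(fit = fit, data = d, response = "growth increment (mm / step)"),
            class = "hgam_fit")
}

#' @export
print.hgam_fit <- function(x, ...) {
  cat(sprintf("Hierarchical GAM: %s, %d obs, %d individuals, %d group smooths\n",
              x$response, nrow(x$data), nlevels(x$data$well),
              nlevels(x$data$grp)))
  print(parametric_terms(x))
  invisible(x)
}

#' Parametric coefficient table of a hierarchical GAM
#' @param x an `hgam_fit`.
#' @return Data frame: `term`, `estimate`, `std_error`, `t_value`,
#'   `p_value`.
#' @export
parametric_terms <- function(x) {
  pt <- summary(x$fit)$p.table
  data.frame(term = rownames(pt), estimate = pt[, 1], std_error = pt[, 2],
             t_value = pt[, 3], p_value = pt[, 4],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Treatment-averaged fitted curves from a hierarchical GAM
#'
#' Averages the model's fitted values over individuals per treatment and
#' time bin (the bold per-treatment curves over the faint individual
#' trajectories).
#'
#' @param x an `hgam_fit`.
#' @param resolution bin width in minutes.
#' @return Data frame: `treatment`, `time_min`, `mean_fitted`, `n`.
#' @export
treatment_curves <- function(x, resolution = 72) {
  d <- x$data
  d$fitted <- as.numeric(stats::fitted(x$fit))
  d$bin <- floor(d$age / resolution)
  agg <- stats::aggregate(d$fitted, by = list(treatment = d$treat, bin = d$bin),
                          FUN = mean)
  cnt <- stats::aggregate(d$fitted, by = list(treatment = d$treat, bin = d$bin),
                          FUN = length)
  out <- data.frame(treatment = agg$treatment,
                    time_min = (agg$bin + 1) * resolution,
                    mean_fitted = agg$x, n = as.integer(cnt$x),
                    stringsAsFactors = FALSE)
  out[order(out$treatment, out$time_min), , drop = FALSE]
}
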