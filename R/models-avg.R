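#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2*loglik + 2k + 2k(k+1)/(n-k-1)` with `k` the number of
#' estimated parameters including the residual scale. When `n <= k + 1` the
#' correction is undefined and `Inf` is returned with a warning (the model
#' is effectively excluded from selection).
#'
#' @param loglik model log-likelihood.
#' @param n_params number of estimated parameters, including the scale.
#' @param n_obs number of observations.
#' @export
aicc <- function(loglik, n_params, n_obs) {
  if (n_obs <= n_params + 1) {
    warnf("AICc undefined for n = %g, k = %g (n <= k + 1): returning Inf",
          n_obs, n_params)
    return(Inf)
  }
  -2 * loglik + 2 * n_params + 2 * n_params * (n_params + 1) / (n_obs - n_params - 1)
}

aicc_fit <- function(fit) {
  ll <- stats::logLik(fit)
  aicc(as.numeric(ll), attr(ll, "df"), stats::nobs(fit))
}

# All term subsets of a full fixed-effect structure that respect marginality
# (an interaction never appears without all its marginal main effects).
# `terms` is a character vector; interactions use ":".
candidate_term_sets <- function(terms) {
  m <- length(terms)
  parents <- lapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (length(parts) == 1L) character(0) else parts
  })
  sets <- list()
  for (mask in 0:(2^m - 1)) {
    inc <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1L)))
    ok <- all(vapply(which(inc), function(i)
      all(parents[[i]] %in% terms[inc]), logical(1)))
    if (ok) sets[[length(sets) + 1L]] <- terms[inc]
  }
  sets
}

# Fit every marginality-respecting candidate linear model.
fit_candidate_lms <- function(response, terms, data, weights = NULL) {
  sets <- candidate_term_sets(terms)
  data$.w <- if (is.null(weights)) rep(1, nrow(data)) else weights
  fits <- lapply(sets, function(s) {
    rhs <- if (length(s)) paste(s, collapse = " + ") else "1"
    f <- stats::as.formula(paste(response, "~", rhs))
    fit <- stats::lm(f, data = data, weights = .w)
    fit$call$formula <- f
    fit
  })
  names(fits) <- vapply(sets, function(s)
    if (length(s)) paste(s, collapse = " + ") else "(intercept)", "")
  fits
}

#' AICc model selection with conditional model averaging
#'
#' Ranks candidate models by AICc; all models within `delta` AICc units of
#' the best form the candidate set. Each coefficient is averaged
#' conditionally -- over only the member models that contain it -- with
#' Akaike weights renormalized within that subset; the unconditional
#' standard error folds in the between-model spread of the estimates.
#' z-values and p-values use the normal approximation. With a single member
#' model the output reduces to that model's estimates.
#'
#' @param models named list of fitted models supporting `logLik`, `nobs`
#'   and `summary()$coefficients` (e.g. `lm` fits).
#' @param delta AICc window defining the member set.
#' @return Object of class `averaged_estimates`: list with `coefficients`
#'   (data frame: `term`, `estimate`, `std_error`, `z_value`, `p_value`,
#'   `n_models`), `members` (model, AICc, delta, weight), `best`.
#' @export
select_and_average <- function(models, delta = 2) {
  if (!length(models)) stopf("empty candidate model set")
  if (is.null(names(models)))
    names(models) <- paste0("model", seq_along(models))
  aiccs <- vapply(models, aicc_fit, numeric(1))
  if (all(!is.finite(aiccs))) stopf("no candidate model has finite AICc")
  best <- which.min(aiccs)
  d <- aiccs - aiccs[best]
  member <- which(is.finite(d) & d < delta)
  w <- exp(-0.5 * d[member])
  w <- w / sum(w)

  coefs <- lapply(models[member], function(fit) summary(fit)$coefficients)
  terms <- unique(unlist(lapply(coefs, rownames)))
  rows <- lapply(terms, function(tm) {
    has <- vapply(coefs, function(cc) tm %in% rownames(cc), logical(1))
    wt <- w[has] / sum(w[has])
    b <- vapply(coefs[has], function(cc) cc[tm, 1], numeric(1))
    se <- vapply(coefs[has], function(cc) cc[tm, 2], numeric(1))
    est <- sum(wt * b)
    se_u <- sum(wt * sqrt(se^2 + (b - est)^2))
    z <- est / se_u
    data.frame(term = tm, estimate = est, std_error = se_u,
               z_value = z, p_value = 2 * stats::pnorm(-abs(z)),
               n_models = sum(has), stringsAsFactors = FALSE)
  })
  structure(list(
    coefficients = rbind_rows(rows),
    members = data.frame(model = names(models)[member],
                         AICc = aiccs[member], delta = d[member],
                         weight = w, stringsAsFactors = FALSE,
                         row.names = NULL),
    best = names(models)[best]
  ), class = "averaged_estimates")
}

#' @export
print.averaged_estimates <- function(x, ...) {
  cat(sprintf("Conditional model averages over %d model(s) (best: %s)\n",
              nrow(x$members), x$best))
  tab <- x$coefficients
  cat(sprintf("%-28s %9s %10s %8s %8s\n",
              "Factor", "Estimate", "Std. Error", "z", "p"))
  for (i in seq_len(nrow(tab)))
    cat(sprintf("%-28s %9.4f %10.4f %8.2f %8.4f\n",
                tab$term[i], tab$estimate[i], tab$std_error[i],
                tab$z_value[i], tab$p_value[i]))
  invisible(x)
}

#' Coefficient table in the standard export layout
#' @param x an `averaged_estimates` object.
#' @return Data frame with columns Factor, Estimate, Std.Error, z, p.
#' @export
as_coef_table <- function(x) {
  data.frame(Factor = x$coefficients$term,
             Estimate = x$coefficients$estimate,
             Std.Error = x$coefficients$std_error,
             z = x$coefficients$z_value,
             p = x$coefficients$p_value,
             stringsAsFactors = FALSE)
}
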