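test_that("AICc matches its closed form and collapses to AIC for large n", {
  expect_equal(aicc(0, 1, 10), 2 + 2 * 1 * 2 / 8)
  expect_lt(abs(aicc(-50, 3, 1e7) - (100 + 6)), 1e-5)
  expect_warning(v <- aicc(0, 9, 10), "Inf")
  expect_identical(v, Inf)

  set.seed(201)
  for (i in 1:100) {
    ll <- rnorm(1, -50, 20); k <- sample(1:8, 1); n <- k + 1 + sample(1:200, 1)
    aic <- -2 * ll + 2 * k
    correction <- (2 * k^2 + 2 * k) / (n - k - 1)
    expect_equal(aicc(ll, k, n), aic + correction, tolerance = 1e-12)
  }
})

test_that("candidate enumeration respects marginality", {
  sets <- copegrow:::candidate_term_sets(c("a", "b", "a:b"))
  expect_equal(length(sets), 5)  # {}, a, b, a+b, a+b+a:b
  has_int <- vapply(sets, function(s) "a:b" %in% s, logical(1))
  expect_true(all(vapply(sets[has_int], function(s)
    all(c("a", "b") %in% s), logical(1))))
})

test_that("a single member model is returned unchanged by averaging", {
  set.seed(202)
  d <- data.frame(y = rnorm(30), x = rnorm(30))
  fit <- lm(y ~ x, data = d)
  out <- select_and_average(list(only = fit))
  s <- summary(fit)$coefficients
  expect_equal(out$coefficients$estimate, unname(s[, 1]))
  expect_equal(out$coefficients$std_error, unname(s[, 2]))
})

test_that("conditional averaging of a term uses only the models containing it", {
  set.seed(203)
  d <- data.frame(x1 = rnorm(40), x2 = rnorm(40))
  d$y <- 1 + 0.5 * d$x1 + rnorm(40, 0, 0.5)
  m1 <- lm(y ~ x1, data = d)
  m2 <- lm(y ~ x1 + x2, data = d)
  out <- select_and_average(list(a = m1, b = m2), delta = Inf)
  # x2 appears only in m2: its conditional average is m2's estimate
  expect_equal(out$coefficients$estimate[out$coefficients$term == "x2"],
               unname(coef(m2)["x2"]))
})

test_that("selection and averaging match an independent brute-force enumeration", {
  set.seed(204)
  n <- 30
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$y <- 0.3 + 0.8 * d$x1 + 0.25 * d$x2 + rnorm(n, 0, 0.7)

  fits <- copegrow:::fit_candidate_lms("y", c("x1", "x2", "x3"), d)
  out <- select_and_average(fits, delta = 2)

  # --- independent oracle: explicit loops over all 8 subsets ---
  vars <- c("x1", "x2", "x3")
  oracle <- list()
  for (i in 0:7) {
    use <- vars[c(bitwAnd(i, 1) > 0, bitwAnd(i, 2) > 0, bitwAnd(i, 4) > 0)]
    f <- if (length(use)) reformulate(use, "y") else y ~ 1
    m <- lm(f, data = d)
    rss <- sum(resid(m)^2)
    p <- length(coef(m)) + 1  # + residual variance
    ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
    oracle[[i + 1]] <- list(fit = m,
                            aicc = -2 * ll + 2 * p + 2 * p * (p + 1) / (n - p - 1))
  }
  av <- vapply(oracle, function(o) o$aicc, numeric(1))
  keep <- which(av - min(av) < 2)
  w <- exp(-0.5 * (av[keep] - min(av[keep])))
  w <- w / sum(w)
  terms <- unique(unlist(lapply(oracle[keep], function(o) names(coef(o$fit)))))
  for (tm in terms) {
    has <- vapply(oracle[keep], function(o) tm %in% names(coef(o$fit)), logical(1))
    ww <- w[has] / sum(w[has])
    b <- vapply(oracle[keep][has], function(o) coef(o$fit)[[tm]], numeric(1))
    se <- vapply(oracle[keep][has], function(o)
      summary(o$fit)$coefficients[tm, 2], numeric(1))
    est <- sum(ww * b)
    se_u <- sum(ww * sqrt(se^2 + (b - est)^2))
    row <- out$coefficients[out$coefficients$term == tm, ]
    expect_equal(row$estimate, est, tolerance = 1e-10)
    expect_equal(row$std_error, se_u, tolerance = 1e-10)
  }
  expect_equal(nrow(out$members), length(keep))
})

test_that("weighting identities: equal weights match OLS, zero weights match deletion", {
  set.seed(205)
  d <- data.frame(x = rnorm(25))
  d$y <- 1 + 2 * d$x + rnorm(25, 0, 0.3)
  fw <- copegrow:::fit_candidate_lms("y", "x", d, weights = rep(2, 25))
  expect_equal(coef(fw$x), coef(lm(y ~ x, data = d)), tolerance = 1e-12)

  w0 <- rep(1, 25); w0[1:5] <- 0
  fz <- copegrow:::fit_candidate_lms("y", "x", d, weights = w0)
  fd <- lm(y ~ x, data = d[6:25, ])
  expect_equal(unname(coef(fz$x)), unname(coef(fd)), tolerance = 1e-12)
})

make_transitions <- function(times_min, n_uncertain = 0, frames = 3) {
  data.frame(individual_id = sprintf("t%02d", seq_along(times_min)),
             status = "observed", transition_time_min = times_min,
             n_uncertain_frames = rep_len(n_uncertain, length(times_min)),
             motion_free_frames = rep_len(frames, length(times_min)),
             stringsAsFactors = FALSE)
}

make_individuals <- function(n, clutches = 3) {
  g <- expand.grid(copper = c(FALSE, TRUE), cue = c(FALSE, TRUE),
                   clutch_id = paste0("K", seq_len(clutches)),
                   stringsAsFactors = FALSE)
  g <- g[rep_len(seq_len(nrow(g)), n), ]
  data.frame(individual_id = sprintf("t%02d", seq_len(n)),
             clutch_id = g$clutch_id,
             copper = g$copper,
             cue = g$cue,
             sex = rep_len(c("F", "M"), n),
             end_status = "matured",
             stringsAsFactors = FALSE)
}

test_that("transition model is equivariant under time rescaling", {
  set.seed(206)
  n <- 48
  ind <- make_individuals(n)
  t1 <- exp(log(7000) + 0.15 * ind$copper + rnorm(n, 0, 0.1))
  tr1 <- make_transitions(t1, n_uncertain = rpois(n, 1))
  tr2 <- tr1; tr2$transition_time_min <- tr1$transition_time_min * 2
  m1 <- transition_time_model(tr1, ind)
  m2 <- transition_time_model(tr2, ind)
  c1 <- m1$coefficients; c2 <- m2$coefficients
  expect_equal(c2$estimate[c2$term == "(Intercept)"],
               c1$estimate[c1$term == "(Intercept)"] + log(2), tolerance = 1e-9)
  expect_equal(c2$estimate[c2$term == "copperTRUE"],
               c1$estimate[c1$term == "copperTRUE"], tolerance = 1e-9)
})

test_that("constant uncertainty gives weight-scale-invariant estimates", {
  set.seed(207)
  n <- 40
  ind <- make_individuals(n)
  tt <- exp(log(7500) + 0.2 * ind$copper + rnorm(n, 0, 0.08))
  tr <- make_transitions(tt, n_uncertain = 2)
  # all weights constant: inverse (1/3) and literal (2) modes differ only by
  # a scale factor, which cannot change any estimate or the model ranking
  m_inv <- transition_time_model(tr, ind, weights_mode = "inverse")
  m_lit <- transition_time_model(tr, ind, weights_mode = "literal")
  expect_equal(m_inv$coefficients$estimate, m_lit$coefficients$estimate,
               tolerance = 1e-9)
  expect_equal(m_inv$coefficients$std_error, m_lit$coefficients$std_error,
               tolerance = 1e-9)
  expect_identical(m_inv$best, m_lit$best)
})

test_that("near-constant moult durations yield null treatment effects", {
  set.seed(208)
  n <- 36
  ind <- make_individuals(n)
  tr <- make_transitions(exp(rnorm(n, log(7500), 0.1)), frames = 3)
  tr$motion_free_frames <- 3L
  m <- suppressWarnings(moult_duration_model(tr, ind, frame_interval = 72))
  non_int <- m$coefficients[m$coefficients$term != "(Intercept)", ]
  if (nrow(non_int)) expect_lt(max(abs(non_int$estimate)), 1e-8)
  expect_equal(m$coefficients$estimate[m$coefficients$term == "(Intercept)"],
               sqrt(216), tolerance = 1e-8)
})

test_that("opposite clutch-specific copper effects on moult duration are recovered", {
  set.seed(209)
  n <- 60
  ind <- make_individuals(n, clutches = 2)
  # clutch K1: copper shortens the moult; clutch K2: copper prolongs it
  frames <- ifelse(ind$clutch_id == "K1", ifelse(ind$copper, 1, 3),
                   ifelse(ind$copper, 6, 3))
  frames <- pmax(1, frames + sample(-1:1, n, replace = TRUE) *
                   rbinom(n, 1, 0.3))
  tr <- make_transitions(exp(rnorm(n, log(7500), 0.1)), frames = frames)
  m <- moult_duration_model(tr, ind, frame_interval = 72)
  cc <- m$coefficients
  int <- cc[grepl("copperTRUE:clutch_idK2|clutch_idK2:copperTRUE", cc$term), ]
  expect_equal(nrow(int), 1)
  expect_gt(int$estimate, 0)  # K2 is prolonged relative to K1 under copper
  main <- cc[cc$term == "copperTRUE", ]
  expect_lt(main$estimate, 0)  # in the K1 reference, copper shortens
})

test_that("doubling all lengths shifts only the endpoint intercept, by log 2", {
  ex <- suppressWarnings(simulate_experiment(small_config(seed = 31)))
  ds <- as_dataset(ex)
  m1 <- suppressWarnings(endpoint_size_model(ds))
  ds2 <- ds
  ds2$measurements$length_mm <- ds2$measurements$length_mm * 2
  m2 <- suppressWarnings(endpoint_size_model(ds2))
  c1 <- m1$coefficients; c2 <- m2$coefficients
  expect_equal(c2$estimate[c2$term == "(Intercept)"],
               c1$estimate[c1$term == "(Intercept)"] + log(2), tolerance = 1e-9)
  shared <- setdiff(intersect(c1$term, c2$term), "(Intercept)")
  expect_equal(c2$estimate[match(shared, c2$term)],
               c1$estimate[match(shared, c1$term)], tolerance = 1e-9)
})

test_that("a configured male size advantage is recovered by the matured-only model", {
  cfg <- simulation_config(sex_length_log = 0.2, seed = 32)
  ds <- as_dataset(simulate_experiment(cfg))
  m <- suppressWarnings(endpoint_size_model(ds, matured_only = TRUE))
  cc <- m$coefficients[m$coefficients$term == "sexM", ]
  expect_equal(nrow(cc), 1)
  expect_lt(abs(cc$estimate - 0.2), 2 * cc$std_error)
})

test_that("copper's endpoint estimate attenuates when unmatured individuals are excluded", {
  ds <- as_dataset(default_experiment())
  m_all <- suppressWarnings(endpoint_size_model(ds))
  m_mat <- suppressWarnings(endpoint_size_model(ds, matured_only = TRUE))
  est <- function(m) {
    r <- m$coefficients[m$coefficients$term == "copperTRUE", ]
    if (nrow(r)) r$estimate else 0
  }
  expect_lt(est(m_all), 0)
  expect_lt(abs(est(m_mat)), abs(est(m_all)))
})

test_that("calibration regression recovers exact and simulated relationships", {
  set.seed(210)
  pairs0 <- data.frame(individual_id = rep(sprintf("i%d", 1:10), each = 8),
                       manual_mm = runif(80, 0.1, 0.8))
  pairs0$machine_mm <- pairs0$manual_mm + rnorm(80, 0, 1e-8)
  fit0 <- suppressWarnings(suppressMessages(calibration_regression(pairs0)))
  expect_equal(fit0$slope, 1, tolerance = 1e-4)
  expect_equal(fit0$intercept, 0, tolerance = 1e-4)

  pairs <- simulate_calibration_pairs(seed = 33)
  fit <- calibration_regression(pairs)
  expect_lt(abs(fit$slope - 0.90), 2 * fit$se)

  expect_error(calibration_regression(pairs[pairs$individual_id == "ind001", ]),
               "2 individuals")
})

test_that("the calibration slope is stable under permutation of individual labels", {
  pairs <- simulate_calibration_pairs(n_individuals = 20, days = 8, seed = 34)
  base <- calibration_regression(pairs)$slope
  set.seed(211)
  slopes <- replicate(30, {
    p <- pairs
    p$individual_id <- sample(p$individual_id)
    suppressWarnings(suppressMessages(calibration_regression(p)$slope))
  })
  expect_lt(abs(mean(slopes) - base), 3 * sd(slopes) / sqrt(30) + 0.01)
})

test_that("hierarchical GAM recovers a configured copper growth deficit", {
  cfg <- simulation_config(n_clutches = 3, individuals_per_clutch = 12,
                           experiment_duration = 9 * 1440,
                           frame_interval = 144, dropout = 0,
                           copper_delay_log = 0, copper_length_log = -0.11,
                           seed = 35)
  ds <- as_dataset(simulate_experiment(cfg))
  fit <- suppressMessages(hgam_length_model(ds, k = 8, fs_k = 5))
  pt <- parametric_terms(fit)
  cu <- pt[pt$term == "copperTRUE", ]
  expect_lt(cu$estimate, 0)
  expect_lt(abs(cu$estimate - (-0.11)), 2 * cu$std_error)
})

test_that("null simulations give null parametric treatment terms in both hierarchical GAMs", {
  cfg <- simulation_config(n_clutches = 3, individuals_per_clutch = 12,
                           experiment_duration = 9 * 1440,
                           frame_interval = 144, dropout = 0,
                           copper_delay_log = 0, cue_copper_interaction = 0,
                           seed = 36)
  ds <- as_dataset(simulate_experiment(cfg))
  fit <- suppressMessages(hgam_length_model(ds, k = 8, fs_k = 5))
  pt <- parametric_terms(fit)
  for (tm in c("copperTRUE", "cueTRUE")) {
    r <- pt[pt$term == tm, ]
    expect_lt(abs(r$estimate), 3 * r$std_error)
  }
  res <- increments_pipeline(ds, k = 20, resolution = 144)
  fit2 <- suppressMessages(hgam_increment_model(res$increments, ds$individuals,
                                                k = 8, fs_k = 5))
  pt2 <- parametric_terms(fit2)
  for (tm in c("copperTRUE", "cueTRUE")) {
    r <- pt2[pt2$term == tm, ]
    expect_lt(abs(r$estimate), 3 * r$std_error + 1e-3)
  }
})

test_that("per-individual deviation smooths improve the likelihood under heterogeneity", {
  cfg <- simulation_config(n_clutches = 3, individuals_per_clutch = 8,
                           experiment_duration = 8 * 1440,
                           frame_interval = 144, dropout = 0,
                           individual_sd_log_time = 0.15,
                           individual_sd_log_length = 0.08, seed = 37)
  ds <- as_dataset(simulate_experiment(cfg))
  with_ind <- suppressMessages(hgam_length_model(ds, k = 8, fs_k = 5))
  without <- suppressMessages(hgam_length_model(ds, k = 8, fs_k = 5,
                                                include_individual = FALSE))
  expect_gt(as.numeric(logLik(with_ind$fit)), as.numeric(logLik(without$fit)))
})
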