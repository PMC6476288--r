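linear_dataset <- function(times, a = 0.1, b = 5e-5, id = "lin") {
  copepod_dataset(
    data.frame(individual_id = id),
    data.frame(individual_id = id, time_min = times,
               length_mm = a + b * times, usable = TRUE))
}

test_that("noiseless linear data are reproduced exactly (penalty null space)", {
  ds <- linear_dataset(seq(0, 7200, by = 72))
  fit <- suppressWarnings(fit_growth_smoothers(ds, k = 20))
  pred <- predict_isochronal(fit, 72)
  expect_lt(max(abs(pred$length_mm - (0.1 + 5e-5 * pred$time_min))), 1e-8)
})

test_that("a cubic signal with tiny noise is recovered to 1e-3", {
  set.seed(101)
  t <- seq(0, 10000, length.out = 200)
  f <- function(x) 0.3 + 1e-4 * x - 1.5e-8 * x^2 + 8e-13 * x^3
  ds <- copepod_dataset(
    data.frame(individual_id = "cubic"),
    data.frame(individual_id = "cubic", time_min = t,
               length_mm = f(t) + rnorm(200, 0, 1e-6), usable = TRUE))
  fit <- fit_growth_smoothers(ds, k = 40)
  pred <- predict_isochronal(fit, 72)
  expect_lt(max(abs(pred$length_mm - f(pred$time_min))), 1e-3)
})

test_that("infinite smoothing degenerates to the least-squares line", {
  set.seed(102)
  t <- seq(0, 7200, by = 72)
  y <- 0.2 + 4e-5 * t + rnorm(length(t), 0, 0.01)
  ds <- copepod_dataset(
    data.frame(individual_id = "n"),
    data.frame(individual_id = "n", time_min = t, length_mm = y, usable = TRUE))
  fit <- fit_growth_smoothers(ds, k = 20, sp = 1e10)
  ols <- lm(y ~ t)
  expect_equal(sd(residuals(fit$fits$n)), sd(residuals(ols)), tolerance = 1e-3)
})

test_that("isochronal grids are anchored, exactly spaced, and clipped to the window", {
  ds <- linear_dataset(seq(0, 7200, by = 72), id = "g1")
  fit <- suppressWarnings(fit_growth_smoothers(ds, k = 15))
  p <- predict_isochronal(fit, 72)
  expect_equal(nrow(p), 101)
  expect_equal(unique(diff(p$time_min)), 72)
  expect_equal(p$time_min[1], 0)

  ds2 <- linear_dataset(seq(100, 7300, by = 60), id = "g2")
  fit2 <- suppressWarnings(fit_growth_smoothers(ds2, k = 15))
  p2 <- predict_isochronal(fit2, 72)
  expect_equal(p2$time_min[1], 100)
  expect_lte(max(p2$time_min), 7300)

  p3 <- predict_isochronal(fit2, 1440)
  expect_equal(nrow(p3), 6)
})

test_that("growth increments difference, retain negatives, and telescope exactly", {
  pred <- data.frame(individual_id = "c", time_min = c(0, 72, 144),
                     length_mm = c(0.30, 0.33, 0.32))
  inc <- growth_increments(pred)
  expect_equal(inc$increment_mm, c(0.03, -0.01))
  expect_equal(inc$time_min, c(72, 144))

  const <- data.frame(individual_id = "k", time_min = seq(0, 720, 72),
                      length_mm = rep(0.4, 11))
  expect_true(all(growth_increments(const)$increment_mm == 0))

  set.seed(103)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    p <- data.frame(individual_id = "r", time_min = seq(0, by = 72, length.out = n),
                    length_mm = cumsum(rnorm(n, 0.01, 0.02)) + 0.3)
    ic <- growth_increments(p)
    expect_equal(sum(ic$increment_mm), p$length_mm[n] - p$length_mm[1],
                 tolerance = 1e-12)
  }
})

test_that("simulated pipelines keep every prediction inside the observation window", {
  for (seed in 1:2) {
    ds <- as_dataset(suppressWarnings(simulate_experiment(small_config(seed = seed))))
    res <- increments_pipeline(ds, k = 20, resolution = 72)
    for (id in unique(res$predictions$individual_id)) {
      w <- ds$windows[ds$windows$individual_id == id, ]
      p <- res$predictions[res$predictions$individual_id == id, ]
      expect_gte(min(p$time_min), w$window_start)
      expect_lte(max(p$time_min), w$window_end)
      expect_equal(unique(round(diff(p$time_min), 9)), 72)
      ic <- res$increments[res$increments$individual_id == id, ]
      expect_equal(sum(ic$increment_mm),
                   p$length_mm[nrow(p)] - p$length_mm[1], tolerance = 1e-9)
    }
  }
})

test_that("prediction error decreases with sample size on a fixed signal", {
  f <- function(x) 0.3 + 0.25 * sin(x / 2000)
  mse <- sapply(c(40, 160), function(n) {
    mean(sapply(1:30, function(r) {
      set.seed(1000 + r)
      t <- seq(0, 10000, length.out = n)
      ds <- copepod_dataset(
        data.frame(individual_id = "s"),
        data.frame(individual_id = "s", time_min = t,
                   length_mm = f(t) + rnorm(n, 0, 0.02), usable = TRUE))
      fit <- fit_growth_smoothers(ds, k = 20)
      p <- predict_isochronal(fit, 250)
      mean((p$length_mm - f(p$time_min))^2)
    }))
  })
  expect_lt(mse[2], mse[1])
})

test_that("fit diagnostics flag exhausted bases and clean residuals", {
  set.seed(104)
  t <- seq(0, 10000, length.out = 150)
  # pure noise: the smooth should shrink towards its null space
  ds_noise <- copepod_dataset(
    data.frame(individual_id = "noise"),
    data.frame(individual_id = "noise", time_min = t,
               length_mm = 0.4 + rnorm(150, 0, 0.02), usable = TRUE))
  ck <- check_fit(fit_growth_smoothers(ds_noise, k = 20))
  expect_lt(ck$edf, 3)
  expect_false(ck$basis_flag)

  # a resolvable wiggle against an under-dimensioned basis with near-zero
  # noise drives the effective degrees of freedom to the basis limit
  ds_osc <- copepod_dataset(
    data.frame(individual_id = "osc"),
    data.frame(individual_id = "osc", time_min = t,
               length_mm = 0.4 + 0.1 * sin(2 * pi * 1.5 * t / 10000) +
                 rnorm(150, 0, 1e-4), usable = TRUE))
  ck2 <- check_fit(fit_growth_smoothers(ds_osc, k = 6))
  expect_true(ck2$basis_flag)

  # near-perfect fit: residual skew about zero
  ck3 <- check_fit(fit_growth_smoothers(ds_noise, k = 20))
  expect_lt(abs(ck3$resid_skew), 1)
})

test_that("individuals with too few usable records are excluded with a warning", {
  ds <- copepod_dataset(
    data.frame(individual_id = c("ok", "thin")),
    rbind(data.frame(individual_id = "ok", time_min = seq(0, 7200, 72),
                     length_mm = 0.3 + seq(0, 7200, 72) * 4e-5 +
                       rnorm(101, 0, 0.005), usable = TRUE),
          data.frame(individual_id = "thin", time_min = c(0, 72, 144),
                     length_mm = c(0.3, 0.31, 0.32), usable = TRUE)))
  expect_warning(fit <- fit_growth_smoothers(ds, k = 10), "thin")
  expect_named(fit$fits, "ok")
  expect_identical(fit$excluded, "thin")
})
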