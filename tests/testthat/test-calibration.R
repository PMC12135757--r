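test_that("exact linear data are fit exactly", {
  x <- c(1, 2, 5, 9)
  f <- quiet(fit_calibration(x, 2 * x + 1))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r2, 1)
  expect_equal(f$rmse, 0, tolerance = 1e-12)
})

test_that("three-point fit matches hand-derived normal equations", {
  f <- fit_calibration(c(1, 2, 3), c(1, 3, 4))
  expect_equal(f$slope, 1.5)
  expect_equal(f$intercept, -1 / 3)
  expect_equal(f$r2, 27 / 28)              # SSE = 1/6, SST = 14/3
  expect_equal(f$rmse, sqrt((1 / 6) / 3))  # sqrt(SSE/n) convention
  expect_identical(f$n_obs, 3L)
})

test_that("OLS agrees with the closed-form oracle on random instances", {
  set.seed(21)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    x <- runif(n, 0, 50)
    y <- runif(1, 1, 10) * x + rnorm(1, 0, 5) + rnorm(n, 0, 3)
    f <- fit_calibration(x, y)
    o <- ols_oracle(x, y)
    expect_equal(f$slope, o$slope, tolerance = 1e-10)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(f$r2, o$r2, tolerance = 1e-10)
    expect_equal(f$rmse, o$rmse, tolerance = 1e-10)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_calibration(1:2, 1:2), "at least 3")
  expect_error(fit_calibration(rep(1, 5), 1:5), "constant")
})

test_that("noise-free pipeline reproduces per-unit generating coefficients", {
  sim <- simulate_colocation(noiseless_config())
  fit <- quiet(calibrate_colocation(sim, "pm2_5"))
  expect_equal(fit$models$BB1$slope, 4.48, tolerance = 1e-6)
  expect_equal(fit$models$BB1$intercept, -5.17, tolerance = 1e-4)
  expect_equal(fit$models$BB3$slope, 3.60, tolerance = 1e-6)
  expect_gt(fit$models$BB1$r2, 1 - 1e-10)
})

test_that("universal fit equals a closed-form regression on the mean predictor", {
  sim <- simulate_colocation(noiseless_config())
  fit <- quiet(calibrate_colocation(sim, "pm2_5"))
  mi <- fit$matched
  xbar <- rowMeans(mi[, attr(mi, "units")])
  o <- ols_oracle(xbar, mi$teom_mean)
  expect_equal(fit$models$averaged$slope, o$slope, tolerance = 1e-10)
  expect_equal(fit$models$averaged$intercept, o$intercept, tolerance = 1e-10)
  # analytic limit: slope is the harmonic mean of the unit slopes
  betas <- c(4.48, 4.16, 3.60)
  expect_equal(fit$models$averaged$slope, 1 / mean(1 / betas), tolerance = 1e-6)
})

test_that("universal fit equals any per-unit fit when units are identical", {
  mi <- data.frame(teom_mean = c(10, 20, 40, 80),
                   A = c(2, 5, 10, 20), B = c(2, 5, 10, 20))
  attr(mi, "units") <- c("A", "B")
  attr(mi, "channel") <- "pm2_5"
  u <- quiet(fit_universal(mi))
  a <- quiet(fit_calibration(mi$A, mi$teom_mean))
  expect_equal(u$slope, a$slope)
  expect_equal(u$intercept, a$intercept)
  expect_identical(u$unit_id, "averaged")
})

test_that("applying a calibration is affine and self-consistent", {
  s <- mk_wearable(c(1, 5, 10, 20))
  m <- quiet(fit_calibration(c(1, 2, 5, 9), c(1, 2, 5, 9) * 4.07 - 3.82,
                             "averaged", "pm2_5"))
  out <- apply_calibration(m, s)
  expect_equal(out$data$pm2_5, 4.07 * c(1, 5, 10, 20) - 3.82)
  # identity model leaves the series untouched
  id <- quiet(fit_calibration(c(1, 2, 3), c(1, 2, 3)))
  id$size_fraction <- "pm2_5"
  expect_equal(apply_calibration(id, s)$data, s$data)

  # refit after correction: slope 1, intercept 0, for arbitrary noisy data
  set.seed(31)
  x <- runif(25, 1, 40)
  y <- 4.07 * x - 3.82 + rnorm(25, 0, 4)
  f1 <- fit_calibration(x, y)
  f2 <- fit_calibration(predict(f1, x), y)
  expect_equal(f2$slope, 1, tolerance = 1e-10)
  expect_equal(f2$intercept, 0, tolerance = 1e-8)
})

test_that("corrected window means are floored only at reporting", {
  m <- quiet(fit_calibration(c(1, 2, 5, 9), c(1, 2, 5, 9) * 4.07 - 3.82,
                             "averaged", "pm2_5"))
  s <- mk_wearable(rep(0, 240))
  # per-sample corrected values go negative and are preserved
  corr <- apply_calibration(m, s)
  expect_true(all(corr$data$pm2_5 < 0))
  # the reported window mean is floored at 0 (raw 0 -> -3.82 -> 0)
  w <- window_exposure(s, m, s$data$timestamp[1], "short")
  expect_equal(w$mean_conc, 0)
})

test_that("calibration JSON round-trips coefficients and diagnostics", {
  f <- fit_calibration(c(1, 2, 3, 5), c(1.2, 3.1, 3.9, 6.5), "BB2", "pm10")
  p <- withr::local_tempfile(fileext = ".json")
  calibration_to_json(f, p)
  j <- jsonlite::read_json(p)
  expect_identical(j$rmse_convention, "sse_over_n")
  g <- calibration_from_json(p)
  expect_equal(coef(g), coef(f))
  expect_equal(g$r2, f$r2)
  expect_equal(predict(g, 10), f$slope * 10 + f$intercept)
})

test_that("inter-unit CV pools per-interval CVs by root mean square", {
  mi <- data.frame(teom_mean = c(10, 10), A = c(9, 9), B = c(10, 10), C = c(11, 11))
  attr(mi, "units") <- c("A", "B", "C")
  expect_equal(interunit_cv(mi), 10)  # sd 1 / mean 10 in both intervals

  mi7 <- mi
  mi7[, c("A", "B", "C")] <- 7 * mi7[, c("A", "B", "C")]
  attr(mi7, "units") <- c("A", "B", "C")
  expect_equal(interunit_cv(mi7), interunit_cv(mi))  # scale invariance
})

test_that("inter-unit CV shrinks monotonically with unit heterogeneity", {
  base <- c(5, 10, 20, 40)
  cvs <- vapply(c(0.2, 0.1, 0.05, 0), function(d) {
    mi <- data.frame(teom_mean = base, A = base, B = base * (1 + d))
    attr(mi, "units") <- c("A", "B")
    interunit_cv(mi)
  }, numeric(1))
  expect_true(all(diff(cvs) < 1e-12))
  expect_equal(cvs[4], 0)
})

test_that("pairwise correlations: duplicates, anticorrelation, constants", {
  mi <- data.frame(teom_mean = c(1, 2, 3, 4),
                   A = c(1, 2, 3, 4), B = c(1, 2, 3, 4),
                   C = c(4, 3, 2, 1), D = rep(5, 4))
  attr(mi, "units") <- c("A", "B", "C", "D")
  r <- pairwise_correlations(mi)
  expect_equal(r["A", "B"], 1)
  expect_equal(r["A", "C"], -1)
  expect_true(is.na(r["A", "D"]))  # constant unit: undefined, reported missing
  expect_equal(r, t(r))
  expect_true(all(diag(r) == 1))
})

test_that("Shapiro-Wilk wrapper: domain, symmetry, null rate, power", {
  expect_error(shapiro_wilk(c(0, 1)), "3 <= n <= 5000")
  expect_gt(shapiro_wilk(c(-1, 0, 1))[["w"]], 0.99)

  set.seed(41)
  rej <- mean(replicate(1000, shapiro_wilk(rnorm(29))[["p"]] < 0.05))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)

  pow <- mean(replicate(200, shapiro_wilk(stats::rexp(50))[["p"]] < 0.05))
  expect_gte(pow, 0.95)
})

test_that("parameter recovery: mean universal slope is unbiased across seeds", {
  generating <- 1 / mean(1 / c(4.48, 4.16, 3.60))
  res <- vapply(1:200, function(s) {
    sim <- simulate_colocation(colocation_config(seed = 1000 + s))
    m <- quiet(calibrate_colocation(sim, "pm2_5"))$models$averaged
    ci <- stats::confint(m$fit)["x", ]
    c(slope = m$slope, cover = ci[1] <= generating && generating <= ci[2])
  }, numeric(2))
  expect_lt(abs(mean(res["slope", ]) - generating) / generating, 0.02)
  expect_gte(mean(res["cover", ]), 0.85)  # ~95% nominal coverage
  expect_lte(mean(res["cover", ]), 1.00)
})
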