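test_that("simulators are deterministic under a fixed seed", {
  a <- simulate_colocation(colocation_config(seed = 5))
  b <- simulate_colocation(colocation_config(seed = 5))
  c <- simulate_colocation(colocation_config(seed = 6))
  expect_identical(a$teom$pm2_5$data, b$teom$pm2_5$data)
  expect_identical(a$wearables$BB1$data, b$wearables$BB1$data)
  expect_false(identical(a$teom$pm2_5$data$value, c$teom$pm2_5$data$value))

  ta <- simulate_feed_trial(trial_config(n_horses = 3, seed = 5))
  tb <- simulate_feed_trial(trial_config(n_horses = 3, seed = 5))
  tc <- simulate_feed_trial(trial_config(n_horses = 3, seed = 6))
  expect_identical(ta$logs[[1]]$data, tb$logs[[1]]$data)
  expect_false(identical(ta$logs[[1]]$data$pm2_5, tc$logs[[1]]$data$pm2_5))
  # the simulators do not disturb the caller's RNG stream
  set.seed(99); x1 <- {simulate_colocation(colocation_config(seed = 1)); rnorm(1)}
  set.seed(99); x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("noise-free reference equals plateau truth on plateau interiors", {
  sim <- simulate_colocation(noiseless_config())
  teom <- sim$teom$pm2_5$data
  sched <- sim$truth$schedule
  for (i in seq_len(nrow(sched))) {
    inside <- teom$timestamp >= sched$start[i] + 60 &
      teom$timestamp < sched$end[i] - 60
    expect_equal(teom$value[inside], rep(sched$level_pm2_5[i], sum(inside)))
  }
})

test_that("default chamber concentrations span the intended working ranges", {
  sim <- simulate_colocation(colocation_config(seed = 12))
  lag_s <- sim$config$teom_lag_min * 60
  for (frac in c("pm2_5", "pm10")) {
    teom <- sim$teom[[frac]]$data
    sched <- sim$truth$schedule
    vals <- unlist(lapply(seq_len(nrow(sched)), function(i)
      teom$value[teom$timestamp >= sched$start[i] + lag_s + 60 &
                 teom$timestamp < sched$end[i] + lag_s - 60]))
    rng <- if (frac == "pm2_5") c(3.5, 163.3) else c(9.7, 2543)
    expect_true(all(vals >= rng[1] & vals <= rng[2]))
  }
})

test_that("simulated reference lags the comparison by exactly the configured delay", {
  for (k in c(0L, 2L, 4L)) {
    sim <- simulate_colocation(colocation_config(
      seed = 13, teom_lag_min = k,
      noise_cv = 0, teom_noise_cv = 0, comparison_noise_cv = 0))
    r <- resample_to_minutes(sim$teom$pm2_5)
    cmp <- resample_to_minutes(sim$comparison$pm2_5)
    expect_identical(estimate_lag(r, cmp)$lag_min, k)
  }
})

test_that("wearable records honour their invariants in both generators", {
  sim <- simulate_colocation(colocation_config(seed = 14))
  for (w in sim$wearables) expect_s3_class(w, "pm_series")  # ctor validates
  d <- sim$wearables$BB1$data
  expect_true(all(d$pm1 <= d$pm2_5 & d$pm2_5 <= d$pm10))
  expect_true(all(d$n_gt_0_3 >= d$n_gt_0_5 & d$n_gt_5_0 >= d$n_gt_10))

  tr <- simulate_feed_trial(trial_config(n_horses = 2, seed = 14))
  expect_identical(nrow(tr$metadata), 4L)
  d <- tr$logs[[1]]$data
  expect_true(all(d$pm1 <= d$pm2_5 & d$pm2_5 <= d$pm10))
})

test_that("trial generator emits 20 horse-days of 5760 records at defaults", {
  sim <- simulate_feed_trial(trial_config(seed = 15))
  expect_identical(nrow(sim$metadata), 20L)
  expect_identical(length(sim$logs), 20L)
  expect_true(all(vapply(sim$logs, function(s) nrow(s$data), 0L) == 5760L))
  expect_identical(sort(unique(sim$metadata$treatment)), c("dry", "soaked"))
  # dry always precedes soaked for each horse
  for (h in unique(sim$metadata$horse_id)) {
    md <- sim$metadata[sim$metadata$horse_id == h, ]
    expect_lt(md$date[md$treatment == "dry"], md$date[md$treatment == "soaked"])
  }
})

test_that("deterministic trial limit reproduces the group means exactly", {
  cfg <- trial_config(n_horses = 3, horse_sd_log = 0, resid_sd_log = 0,
                      noise_cv = 0, seed = 16)
  sim <- simulate_feed_trial(cfg)
  models <- exact_universal_models()
  ex <- trial_exposures(sim, models["pm2_5"])
  m8_dry <- ex$mean_conc[ex$treatment == "dry" & ex$window == "extended"]
  m20_dry <- ex$mean_conc[ex$treatment == "dry" & ex$window == "short"]
  expect_equal(m8_dry, rep(76, 3), tolerance = 1e-9)
  expect_equal(m20_dry, rep(160, 3), tolerance = 1e-9)
})

test_that("an infeasible post-feeding level triggers the floor warning", {
  gm <- default_group_means()
  gm$pm2_5$dry <- c(short = 24.5, extended = 1.05)  # L2 = 0.03 < 0.5
  w <- testthat::capture_warnings(
    simulate_feed_trial(trial_config(n_horses = 2, group_means = gm,
                                     horse_sd_log = 0, resid_sd_log = 0,
                                     seed = 17)))
  expect_true(any(grepl("floored at 0.5", w)))
})

test_that("simulated 8-h dry means converge to the generating geometric mean", {
  cfg <- trial_config(n_horses = 200, seed = 1)
  sim <- simulate_feed_trial(cfg)
  model <- exact_universal_models()$pm2_5
  md <- sim$metadata[sim$metadata$treatment == "dry", ]
  m8 <- vapply(seq_len(nrow(md)), function(i)
    window_exposure(sim$logs[[md$log_id[i]]], model, md$feed_time[i],
                    "extended")$mean_conc, numeric(1))
  gm <- exp(mean(log(m8)))
  expect_lt(abs(gm - 76) / 76, 0.05)
  # independent oracle: direct Monte-Carlo of the stated lognormal model
  set.seed(2)
  gm_mc <- exp(mean(log(76) + rnorm(200, 0, cfg$horse_sd_log) +
                 rnorm(200, 0, cfg$resid_sd_log)))
  expect_lt(abs(gm - gm_mc) / 76, 3 * sqrt(2) * 0.43 / sqrt(200))
})

test_that("simulation runs serialise with a traceable manifest", {
  dir <- withr::local_tempdir()
  sim <- simulate_feed_trial(trial_config(n_horses = 2, seed = 18))
  write_simulation(sim, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_identical(man$seed, 18L)
  expect_true(all(c("H01_dry.csv", "metadata.csv") %in% unlist(man$files)))
  r <- read_pm_log(file.path(dir, "H01_soaked.csv"), "wearable",
                   unit_id = "H01_soaked")
  expect_equal(r$data, sim$logs$H01_soaked$data)
  # same seed, fresh run: byte-identical log files
  dir2 <- withr::local_tempdir()
  write_simulation(simulate_feed_trial(trial_config(n_horses = 2, seed = 18)), dir2)
  expect_identical(readLines(file.path(dir, "H01_dry.csv")),
                   readLines(file.path(dir2, "H01_dry.csv")))
})

test_that("default configurations carry the published generating parameters", {
  cfgs <- default_configs(seed = 3)
  expect_equal(cfgs$colocation$unit_params$pm2_5$beta, c(4.48, 4.16, 3.60))
  expect_equal(cfgs$colocation$unit_params$pm10$beta, c(45.8, 44.6, 42.0))
  expect_equal(cfgs$trial$group_means$pm2_5$dry[["extended"]], 76)
  expect_equal(cfgs$trial$group_means$pm10$soaked[["short"]], 970)
  expect_identical(cfgs$colocation$teom_lag_min, 4)
  # configs validate against their own invariants
  expect_s3_class(validate_colocation_config <- cfgs$colocation, "colocation_config")
  expect_error(colocation_config(plateau_duration_min = 3), ">= 5")
  expect_error(trial_config(n_horses = 1), ">= 2")
})
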