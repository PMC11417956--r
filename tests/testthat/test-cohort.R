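test_that("cohort generation is deterministic in the seed and sized per config", {
  cfg <- cohort_config(seed = 3)
  a <- generate_cohort(cfg, n = 48)
  b <- generate_cohort(cfg, n = 48)
  expect_identical(a, b)
  d <- generate_cohort(cohort_config(seed = 4), n = 48)
  expect_false(identical(a$sex, d$sex) && identical(a$birthdate, d$birthdate))
  # default sizing emulates 22 F / 26 M
  expect_equal(sum(a$sex == "female"), 22)
  expect_equal(sum(a$sex == "male"), 26)
  expect_false(anyDuplicated(a$id) > 0)
})

test_that("empty cohort and invalid configuration are handled", {
  empty <- generate_cohort(cohort_config(), n = 0)
  expect_equal(nrow(empty), 0)
  expect_error(cohort_config(sex_ratio = 1.2), "sex_ratio")
  expect_error(cohort_config(day_cv = 0), "day_cv")
  expect_error(cohort_config(coupling = 2), "coupling")
  expect_error(cohort_config(fgv_curve_params = list(
    female = list(baseline = 0.004, height = 0.008, peak = 5.5, width = 2.5,
                  cessation = 25, ramp = 3),
    male = cohort_config()$fgv_curve_params$male)), "cessation")
})

test_that("growth-velocity curves have the documented sex-specific shapes", {
  grid <- seq(0, 20, by = 0.1)
  f <- mean_fgv_curve(grid, "female")
  m <- mean_fgv_curve(grid, "male")
  expect_true(all(f >= 0) && all(m >= 0))
  # female spurt peaks in the juvenile window, before the male decline onset
  argmax_f <- grid[which.max(f)]
  expect_gte(argmax_f, 4.5)
  expect_lte(argmax_f, 7)
  expect_lt(argmax_f, 11)
  # growth ceases at the cessation age by construction
  expect_lte(mean_fgv_curve(18, "female"), 1e-6)
  # males grow fast from the start and have declined by 15
  expect_gt(mean_fgv_curve(1, "male"), mean_fgv_curve(15, "male"))
  expect_error(mean_fgv_curve(21, "female"), "age")
  expect_error(mean_fgv_curve(-1, "male"), "age")
})

test_that("log CTX-I curves peak early and decline after age 10", {
  grid <- seq(0, 20, by = 0.1)
  cfg <- cohort_config()
  f <- mean_log_ctx_curve(grid, "female", cfg)
  m <- mean_log_ctx_curve(grid, "male", cfg)
  argmax_f <- grid[which.max(f)]
  expect_gte(argmax_f, 3)
  expect_lte(argmax_f, 5)
  expect_gt(f[grid == 10], f[grid == 20])
  expect_gt(m[grid == 10], m[grid == 20])
  # strict decline across [10, 20] under defaults
  expect_true(all(diff(f[grid >= 10]) < 0))
  expect_true(all(diff(m[grid >= 10]) < 0))
})

test_that("coupling ties the female CTX-I curve to growth velocity", {
  grid <- seq(0, 20, by = 0.1)
  cfg1 <- cohort_config(coupling = 1)
  rho <- cor(mean_fgv_curve(grid, "female"),
             exp(mean_log_ctx_curve(grid, "female", cfg1)),
             method = "spearman")
  expect_gt(rho, 0.8)
  # coupling = 0 makes the female curve independent of the growth parameters
  cfg0a <- cohort_config(coupling = 0)
  alt_fgv <- cohort_config()$fgv_curve_params
  alt_fgv$female$peak <- 9
  alt_fgv$female$height <- 0.002
  cfg0b <- cohort_config(coupling = 0, fgv_curve_params = alt_fgv)
  expect_identical(mean_log_ctx_curve(grid, "female", cfg0a),
                   mean_log_ctx_curve(grid, "female", cfg0b))
})

test_that("noiseless forearm series reproduces the curve's interval averages", {
  ind <- list(id = "x", sex = "female", birthdate = as.Date("2005-06-01"))
  sched <- ind$birthdate + c(400, 900, 1500, 2600, 4000)
  meas <- simulate_forearm_series(ind, sched, noise_sd = 0)
  vel <- compute_velocities(meas, ind$birthdate)
  for (k in seq_len(nrow(vel))) {
    a1 <- as.numeric(sched[k] - ind$birthdate) / 365.25
    a2 <- as.numeric(sched[k + 1] - ind$birthdate) / 365.25
    avg <- integrate(function(a) mean_fgv_curve(a, "female"), a1, a2,
                     rel.tol = 1e-12)$value / (a2 - a1)
    expect_equal(vel$fgv[k], avg, tolerance = 1e-9)
  }
})

test_that("forearm noise produces a small-magnitude negative minority of velocities", {
  cfg <- cohort_config(seed = 9)
  ind <- list(id = "x", sex = "male", birthdate = as.Date("2004-01-01"),
              growth_log_factor = 0)
  vels <- c()
  with_seed <- ctxgrowth:::with_seed
  with_seed(77, {
    for (r in 1:30) {
      sched <- ind$birthdate + 200 + cumsum(sample(60:200, 11, replace = TRUE))
      meas <- simulate_forearm_series(ind, sched, cfg$forearm_noise_sd, cfg)
      vels <- c(vels, compute_velocities(meas, ind$birthdate)$fgv)
    }
  })
  expect_gte(length(vels), 300)
  neg <- vels[vels < 0]
  expect_gt(length(neg), 0)
  expect_lt(length(neg), length(vels) / 2)
  expect_true(all(abs(neg) < 0.02)) # small in magnitude (cm/day)
})

test_that("forearm simulation validates its inputs and is seed-reproducible", {
  ind <- list(id = "x", sex = "female", birthdate = as.Date("2010-01-01"))
  expect_error(simulate_forearm_series(ind, as.Date("2009-01-01")), "birthdate")
  expect_error(simulate_forearm_series(ind, ind$birthdate + c(100, 50)), "sorted")
  a <- simulate_forearm_series(ind, ind$birthdate + c(100, 400), seed = 5)
  b <- simulate_forearm_series(ind, ind$birthdate + c(100, 400), seed = 5)
  expect_identical(a, b)
})

test_that("urine simulation: diurnal ratio of means hits the configured target", {
  cfg <- cohort_config(seed = 13)
  ind <- list(id = "x", sex = "female", birthdate = as.Date("2012-01-01"))
  n_pairs <- 2000
  dates <- ind$birthdate + rep(3000 + seq_len(n_pairs), each = 2)
  sched <- data.frame(date = dates,
                      minutes = rep(c(420L, 1080L), n_pairs))
  s <- simulate_urine_series(ind, sched, cfg, seed = 14)
  ratio <- mean(s$ctx_true[s$minutes == 1080]) / mean(s$ctx_true[s$minutes == 420])
  expect_equal(ratio, 0.55, tolerance = 0.05)
})

test_that("urine simulation: residual skewness and normality follow skew_alpha", {
  ind <- list(id = "x", sex = "female", birthdate = as.Date("2012-01-01"))
  one_day <- function(alpha, seed) {
    cfg <- cohort_config(skew_alpha = alpha)
    sched <- data.frame(date = rep(ind$birthdate + 2000, 500),
                        minutes = rep(600L, 500))
    s <- simulate_urine_series(ind, sched, cfg, seed = seed)
    log(s$ctx_true) # same day and time: only the sample residual varies
  }
  r0 <- one_day(0, 21)
  expect_gt(shapiro.test(r0)$p.value, 0.01)
  r5 <- one_day(5, 22)
  skew <- mean((r5 - mean(r5))^3) / sd(r5)^3
  expect_gt(skew, 0.5)
})

test_that("urine simulation validates inputs and handles the empty schedule", {
  cfg <- cohort_config()
  ind <- list(id = "x", sex = "male", birthdate = as.Date("2012-01-01"))
  empty <- simulate_urine_series(ind, data.frame(date = as.Date(character()),
                                                 minutes = integer()), cfg)
  expect_equal(nrow(empty), 0)
  expect_error(simulate_urine_series(
    ind, data.frame(date = ind$birthdate + 100, minutes = 1500L), cfg),
    "minutes")
})

test_that("a default cohort contains sub-threshold specific gravities and is reproducible", {
  cfg <- cohort_config(seed = 2)
  sim <- simulate_cohort(cfg)
  expect_gte(sum(sim$urine$sg < 1.003), 1)
  expect_true(all(sim$urine$sg >= 1.000))
  sim2 <- simulate_cohort(cohort_config(seed = 2))
  expect_identical(sim$urine, sim2$urine)
  expect_identical(sim$forearm, sim2$forearm)
  # sizes emulate the study datasets
  expect_equal(nrow(sim$individuals), 81)
  expect_gt(nrow(sim$urine), 120)
  expect_lt(nrow(sim$urine), 260)
  expect_gt(nrow(sim$forearm), 280)
  expect_lte(max(table(sim$forearm$id)), 10)
})

test_that("cohort CSV bundle round-trips through its own reader", {
  dir <- tempfile("cohort")
  sim <- simulate_cohort(cohort_config(seed = 6))
  write_cohort(sim, dir)
  back <- read_cohort(dir)
  expect_equal(back$individuals$id, sim$individuals$id)
  expect_equal(back$individuals$birthdate, sim$individuals$birthdate)
  expect_equal(back$urine$ctx_ng_ml, sim$urine$ctx_ng_ml, tolerance = 1e-12)
  expect_equal(back$urine$sg, sim$urine$sg, tolerance = 1e-12)
  expect_equal(back$forearm$length_cm, sim$forearm$length_cm, tolerance = 1e-12)
  expect_equal(back$truth$config$day_cv, 0.25)
  unlink(dir, recursive = TRUE)
})
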