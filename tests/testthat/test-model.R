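test_that("model specification validates settings and round-trips through YAML", {
  spec <- sn_model_spec("log_fgv", chains = 2, iter = 200, warmup = 100)
  expect_false(spec$include_time)
  expect_true(sn_model_spec("log_ctx")$include_time)
  expect_error(sn_model_spec("log_fgv", include_time = TRUE), "time")
  expect_error(sn_model_spec("log_ctx", iter = 100, warmup = 200))
  path <- tempfile(fileext = ".yaml")
  write_model_spec(spec, path)
  back <- read_model_spec(path)
  expect_equal(back$response, "log_fgv")
  expect_equal(back$iter, 200)
  unlink(path)
})

test_that("design assembly produces the documented column structure", {
  sim <- simulate_cohort(demo_cohort_config())
  prep <- prepare_model_data(sim$urine, sim$forearm, sim$individuals)
  ctx <- assemble_design(prep$urine, sn_model_spec("log_ctx"))
  vel <- assemble_design(prep$velocity, sn_model_spec("log_fgv"))
  expect_equal(sum(ctx$col_kind == "time"), 1)
  expect_equal(sum(vel$col_kind == "time"), 0)
  expect_equal(sum(ctx$col_kind == "spline"), 9)
  expect_equal(sum(ctx$col_kind == "sex_spline"), 9)
  expect_equal(nrow(ctx$X), nrow(prep$urine))
  expect_equal(nrow(vel$X), nrow(prep$velocity))
  # male-deviation columns are zero exactly on female rows
  sm <- ctx$X[, ctx$col_kind == "sex_spline"]
  expect_true(all(sm[prep$urine$sex == "female", ] == 0))
  # single-sex data flags the degenerate interaction
  fem <- prep$urine[prep$urine$sex == "female", ]
  expect_warning(assemble_design(fem, sn_model_spec("log_ctx")), "single-sex")
})

test_that("informative priors target exactly the sex-difference splines overlapping ages 5-11", {
  # uniform ages 0-20 put the nine windows at multiples of 20/9 years
  n <- 181
  dat <- data.frame(individual_id = rep(sprintf("i%02d", 1:20), length.out = n),
                    site_id = rep(c("s1", "s2"), length.out = n),
                    sex = rep(c("female", "male"), length.out = n),
                    age_years = seq(0, 20, length.out = n),
                    minutes_of_day = rep(600L, n))
  dat$age_std <- standardize_2sd(dat$age_years)$values
  dat$sex_std <- standardize_2sd(as.numeric(dat$sex == "male"))$values
  dat$time_std <- 0
  dat$log_fgv <- rnorm(n)
  des <- assemble_design(dat, sn_model_spec("log_fgv"))
  pr <- default_priors(des)
  inf <- pr$param[pr$informative]
  expect_equal(inf, paste0("sexM_spline", 3:5))
  expect_true(all(pr$sd[pr$informative] == 0.5))
  expect_true(all(pr$mean[pr$informative] == -0.5))
  expect_true(all(pr$sd[!pr$informative] == 1))
  expect_true(all(pr$mean[!pr$informative] == 0))
  # CTX model: same centers, doubled scale
  dat$log_ctx <- rnorm(n)
  des_c <- assemble_design(dat, sn_model_spec("log_ctx"))
  pr_c <- default_priors(des_c)
  expect_equal(pr_c$param[pr_c$informative], paste0("sexM_spline", 3:5))
  expect_true(all(pr_c$sd[pr_c$informative] == 1.0))
  expect_true(all(pr_c$mean[pr_c$informative] == -0.5))
})

test_that("log-posterior gradient matches central finite differences", {
  set.seed(19)
  n <- 50; p <- 5; nI <- 4; nS <- 2
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
  ind <- sample(0:(nI - 1), n, TRUE); site <- sample(0:(nS - 1), n, TRUE)
  age <- rnorm(n); y <- rnorm(n)
  th <- rnorm(p + 2 * nI + nS + 5, 0, 0.4)
  lp <- function(t) ctxgrowth:::.sn_lp_grad(t, y, X, ind, site, age, nI, nS,
                                            rep(0, p), rep(1, p), 1, 2, 4)$lp
  g <- ctxgrowth:::.sn_lp_grad(th, y, X, ind, site, age, nI, nS,
                               rep(0, p), rep(1, p), 1, 2, 4)$grad
  h <- 1e-5
  num <- vapply(seq_along(th), function(j) {
    e1 <- th; e2 <- th; e1[j] <- e1[j] + h; e2[j] <- e2[j] - h
    (lp(e1) - lp(e2)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g - num)), 1e-5)
})

test_that("Gelman-Rubin statistic matches the hand formula and its limits", {
  # toy 4x2 draw matrix, hand-computed: W = 5/3, B = 2, var+ = 1.75
  toy <- cbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(rhat(toy, split = FALSE), sqrt(1.75 / (5 / 3)), tolerance = 1e-12)
  # brute-force formula oracle on random draws
  set.seed(23)
  m <- matrix(rnorm(600), 200, 3)
  W <- mean(apply(m, 2, var))
  B <- nrow(m) * var(colMeans(m))
  oracle <- sqrt(max((199 / 200) * W + B / 200, W) / W)
  expect_equal(rhat(m, split = FALSE), oracle, tolerance = 1e-12)
  # chains that are exact copies: no between-chain variance
  copies <- cbind(m[, 1], m[, 1], m[, 1])
  expect_equal(rhat(copies, split = FALSE), 1.0, tolerance = 1e-12)
  # far-apart chains are flagged
  set.seed(24)
  far <- cbind(rnorm(1000, -5), rnorm(1000, 5))
  expect_gt(rhat(far), 1.5)
  expect_error(rhat(matrix(1:10, ncol = 1)), "two chains")
})

test_that("a converged small fit recovers the diurnal slope and the zero skewness", {
  demo <- get_demo()
  fit <- demo$fit
  expect_true(all(fit$rhat < 1.05))
  expect_gt(min(fit$ess), 100)
  # negative generator diurnal slope: the time coefficient's interval is below 0
  de <- diurnal_effect(fit)
  expect_lt(de$uci, 0)
  truth <- demo$cfg$diurnal_log_slope *
    demo$prep$standardization$time$scale
  expect_equal(de$estimate, truth, tolerance = 0.15)
  # data simulated with alpha = 0: posterior of alpha covers 0
  a <- posterior_draws(fit, "alpha")[, 1]
  qa <- quantile(a, c(0.025, 0.975))
  expect_lt(qa[1], 0)
  expect_gt(qa[2], 0)
  # deterministic given the seed
  refit <- fit_sn_spline(demo$design, chains = 2, iter = 400, warmup = 200)
  refit2 <- fit_sn_spline(demo$design, chains = 2, iter = 400, warmup = 200)
  expect_identical(refit$draws, refit2$draws)
})

test_that("a pure-noise response yields spline intervals covering zero", {
  demo <- get_demo()
  dat <- demo$prep$urine
  set.seed(99)
  dat$log_ctx <- rnorm(nrow(dat))
  des <- assemble_design(dat, sn_model_spec("log_ctx", chains = 2, iter = 800,
                                            warmup = 300, adapt_delta = 0.9,
                                            seed = 44))
  fit <- fit_sn_spline(des)
  pars <- colnames(des$X)[des$col_kind %in% c("spline", "sex_spline")]
  d <- posterior_draws(fit, pars)
  q <- apply(d, 2, quantile, c(0.025, 0.975))
  covers <- q[1, ] < 0 & q[2, ] > 0
  expect_true(all(covers))
})

test_that("posterior predictive checks are calibrated and detect a gross outlier", {
  demo <- get_demo()
  ppc <- posterior_predictive_check(demo$fit, n_rep = 200, seed = 3)
  expect_true(all(ppc$p_tail >= 0.05 & ppc$p_tail <= 0.95))
  # deterministic given the seed
  ppc2 <- posterior_predictive_check(demo$fit, n_rep = 200, seed = 3)
  expect_identical(ppc, ppc2)
  # inject a x100 outlier and refit quickly: the max statistic is flagged
  dat <- demo$prep$urine
  dat$log_ctx[1] <- max(abs(dat$log_ctx)) * 100
  des <- assemble_design(dat, sn_model_spec("log_ctx", chains = 2, iter = 600,
                                            warmup = 250, adapt_delta = 0.9,
                                            seed = 45))
  suppressWarnings(fit_o <- fit_sn_spline(des))
  ppc_o <- posterior_predictive_check(fit_o, n_rep = 200, seed = 4)
  expect_lt(ppc_o$p_tail[ppc_o$stat == "max"], 0.05)
})

test_that("fit rejects a non-finite response at initialization", {
  demo <- get_demo()
  dat <- demo$prep$urine
  dat$log_ctx[1] <- Inf
  des <- assemble_design(dat, sn_model_spec("log_ctx", chains = 1, iter = 50,
                                            warmup = 20))
  expect_error(fit_sn_spline(des), "constant|finite|initial")
})
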