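test_that("additive male derivation reproduces the published arithmetic", {
  t2 <- printed_table2()
  t3 <- printed_table3()
  fem <- t2[t2$sex == "female", ]
  mal <- t2[t2$sex == "male", ]
  for (outc in c("fgv", "ctx")) {
    main <- data.frame(spline = fem$spline, beta = fem[[paste0(outc, "_beta")]],
                       lci = fem[[paste0(outc, "_lci")]],
                       uci = fem[[paste0(outc, "_uci")]])
    diff <- data.frame(spline = t3$spline, beta = t3[[paste0(outc, "_beta")]],
                       lci = t3[[paste0(outc, "_lci")]],
                       uci = t3[[paste0(outc, "_uci")]])
    derived <- male_from_differences(main, diff)
    # every published male point estimate is exactly female + difference
    expect_equal(derived$beta, mal[[paste0(outc, "_beta")]], tolerance = 1e-9)
  }
  # the cited interval cells also add exactly (FGV spline 1)
  expect_equal(1.52 + (-2.10), -0.58)
  fgv_main <- data.frame(spline = 1, beta = 1.52, lci = -1.38, uci = 3.91)
  fgv_diff <- data.frame(spline = 1, beta = -2.10, lci = -3.89, uci = -0.23)
  d1 <- male_from_differences(fgv_main, fgv_diff)
  expect_equal(d1$beta, -0.58)
  expect_equal(d1$lci, -5.27)
  ctx_main <- data.frame(spline = 1, beta = 1.85, lci = -0.29, uci = 4.36)
  ctx_diff <- data.frame(spline = 1, beta = -3.99, lci = -6.65, uci = -1.70)
  expect_equal(male_from_differences(ctx_main, ctx_diff)$beta, -2.14)
  # an all-zero difference table returns the main table
  zero <- data.frame(spline = 1:9, beta = 0, lci = 0, uci = 0)
  main9 <- data.frame(spline = 1:9, beta = rnorm(9), lci = rnorm(9), uci = rnorm(9))
  expect_equal(male_from_differences(main9, zero), main9)
  expect_error(male_from_differences(main9, zero[c(2:9, 1), ]), "indices")
})

test_that("Spearman correlation matches the brute-force oracle over all orderings at n = 5", {
  x <- c(2.3, -1.1, 0.4, 5.0, 3.3)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  for (y in perms(c(10, 20, 30, 40, 50))) {
    got <- spearman_cor(x, y)$rho
    d <- rank(x) - rank(y)
    oracle <- 1 - 6 * sum(d^2) / (5 * (5^2 - 1))
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("Spearman: perfect correlation, invariance under monotone transforms, ties", {
  set.seed(33)
  x <- rnorm(9); y <- rnorm(9)
  expect_equal(spearman_cor(x, x)$rho, 1.0)
  base <- spearman_cor(x, y)
  expect_equal(spearman_cor(exp(x), y)$rho, base$rho)
  expect_equal(spearman_cor(x, y^3 + 5 * y)$rho, base$rho)
  expect_equal(spearman_cor(rank(x), rank(y))$rho, base$rho)
  expect_equal(base$df, 7L)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:4, 1:5), "equal length")
  # ties switch to midranks + t approximation and match the base-R oracle
  xt <- c(1, 2, 2, 3, 4, 5, 6, 7, 8)
  t_res <- spearman_cor(xt, y)
  expect_true(t_res$ties)
  expect_equal(t_res$method, "t approximation")
  expect_equal(t_res$rho, suppressWarnings(
    cor.test(xt, y, method = "spearman")$estimate[[1]]), tolerance = 1e-12)
})

test_that("exact permutation p-value agrees with subsampled enumeration and the t bound", {
  set.seed(34)
  x <- rnorm(8); y <- 0.7 * x + rnorm(8, 0, 0.6)
  res <- spearman_cor(x, y)
  expect_equal(res$method, "exact permutation")
  # Monte-Carlo subsample of the permutation distribution
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  mc <- replicate(10000, abs(cor(rx, sample(ry))) >= obs - 1e-12)
  expect_lt(abs(res$p_value - mean(mc)), 4 * sd(mc) / sqrt(10000) + 2e-3)
  # sanity bound against the t approximation
  tstat <- res$rho * sqrt((res$n - 2) / (1 - res$rho^2))
  p_t <- 2 * pt(-abs(tstat), res$n - 2)
  expect_lt(res$p_value / p_t, 3)
  expect_gt(res$p_value / p_t, 1 / 3)
})

test_that("spline tables from a fit have coherent quantile orderings", {
  demo <- get_demo()
  tabs <- extract_sex_spline_table(demo$fit)
  for (nm in c("female", "diff", "male_posterior")) {
    tb <- tabs[[nm]]
    expect_equal(nrow(tb), 9)
    expect_true(all(tb$lci <= tb$beta & tb$beta <= tb$uci))
  }
  # additive male table equals female + diff cell-by-cell
  expect_equal(tabs$male$beta, tabs$female$beta + tabs$diff$beta)
  expect_equal(tabs$male$lci, tabs$female$lci + tabs$diff$lci)
  # deterministic given the stored draws
  expect_identical(tabs$female, extract_sex_spline_table(demo$fit)$female)
  # median point estimate is available
  med <- extract_sex_spline_table(demo$fit, estimate = "median")
  expect_false(identical(med$female$beta, tabs$female$beta))
})

test_that("sexwise comparison wires the nine estimates per sex", {
  t9 <- function(b) data.frame(spline = 1:9, beta = b)
  set.seed(35)
  b <- rnorm(9)
  same <- list(female = t9(b), male = t9(rev(b)))
  cors <- compare_sexwise(same, same)
  expect_equal(cors$female$rho, 1.0)
  expect_equal(cors$male$rho, 1.0)
  expect_equal(cors$female$df, 7L)
  bad <- list(female = t9(b))
  expect_error(compare_sexwise(bad, same), "missing sex")
  short <- list(female = t9(b)[1:8, ], male = t9(b))
  expect_error(compare_sexwise(short, same), "splines 1-9")
})

test_that("diurnal effect reports the reporting-format tuple and rejects velocity fits", {
  demo <- get_demo()
  de <- diurnal_effect(demo$fit)
  expect_named(de, c("estimate", "se", "lci", "uci"))
  expect_lt(de$lci, de$uci)
  expect_gt(de$se, 0)
  vel_des <- assemble_design(demo$prep$velocity,
                             sn_model_spec("log_fgv", chains = 2, iter = 60,
                                           warmup = 30))
  suppressWarnings(vfit <- fit_sn_spline(vel_des))
  expect_error(diurnal_effect(vfit), "time")
})
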