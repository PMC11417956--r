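# Shared fixtures built in code. The demo fit is a small CTX-I model on a
# cohort generated with zero residual skewness, reused by several tests;
# it is built lazily and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

demo_cohort_config <- function(...) {
  cohort_config(skew_alpha = 0, seed = 31L, ...)
}

get_demo <- function() {
  if (!is.null(.fixture_cache$demo)) return(.fixture_cache$demo)
  cfg <- demo_cohort_config()
  sim <- simulate_cohort(cfg)
  prep <- prepare_model_data(sim$urine, sim$forearm, sim$individuals)
  spec <- sn_model_spec("log_ctx", chains = 2, iter = 800, warmup = 300,
                        adapt_delta = 0.9, seed = 32L)
  design <- assemble_design(prep$urine, spec)
  fit <- fit_sn_spline(design)
  .fixture_cache$demo <- list(cfg = cfg, sim = sim, prep = prep,
                              design = design, fit = fit)
  .fixture_cache$demo
}

# true fixed-effect surface of the CTX-I model at the observed points,
# projected onto the model design (the generator-truth coefficients)
ctx_truth_projection <- function(prep, design, cfg) {
  ur <- prep$urine
  mu <- vapply(seq_len(nrow(ur)), function(i) {
    mean_log_ctx_curve(ur$age_years[i], ur$sex[i], cfg)
  }, numeric(1))
  mu <- mu + cfg$diurnal_log_slope * (ur$minutes_of_day - 420)
  qr.coef(qr(design$X), mu)
}

# printed-table fixtures
printed_table1 <- function() {
  utils::read.csv(ctx_fixture("table1_printed.csv"), stringsAsFactors = FALSE)
}
printed_table2 <- function() {
  utils::read.csv(ctx_fixture("table2_printed.csv"), stringsAsFactors = FALSE)
}
printed_table3 <- function() {
  utils::read.csv(ctx_fixture("table3_printed.csv"), stringsAsFactors = FALSE)
}
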