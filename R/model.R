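# Hierarchical Bayesian skew-normal spline regression: model specification,
# design assembly, default priors, NUTS fitting and convergence diagnostics.

#' Specification of a skew-normal spline model
#'
#' Describes one of the two regressions: response (log growth velocity or
#' log CTX-I), the 10-knot age smooth with per-spline sex-deviation
#' coefficients, a standardized sex main effect, a standardized time-of-day
#' covariate (CTX-I model only), random intercepts and age slopes for the
#' individual and a random intercept for the housing site, and the sampler
#' settings (five chains of 10,000 iterations with 2,000 warmup and
#' adapt-delta 0.99 by default; reduce for quick runs).
#'
#' Only the location `mu` is regressed on covariates; the scale `sigma` and
#' the skewness `alpha` are scalar free parameters (identity links).
#'
#' @param response `"log_ctx"` or `"log_fgv"`.
#' @param n_knots basis dimension of the age smooth (10 knots give the nine
#'   reported age-spline coefficients).
#' @param degree spline degree (cubic).
#' @param include_time include the standardized collection-time covariate;
#'   defaults to `TRUE` for the CTX-I model and is an error-checked `FALSE`
#'   for the velocity model.
#' @param prior_scale prior standard deviation of unconstrained coefficients
#'   (on the internally standardized response scale).
#' @param informative_window age window (years) in which sex-difference
#'   spline coefficients receive the informative prior.
#' @param informative_center,informative_scale center and scale of that
#'   informative prior in the velocity model (the center encodes the
#'   expected sign of the female-earlier-spurt difference); the CTX-I model
#'   uses the same centers with the scale doubled (less informative).
#' @param re_prior_sd half-normal prior scale of the random-effect standard
#'   deviations.
#' @param sigma_prior_sd half-normal prior scale of the residual scale.
#' @param alpha_prior_sd normal prior scale of the skewness parameter.
#' @param chains,iter,warmup,adapt_delta,max_treedepth sampler settings.
#' @param seed integer seed.
#' @return list of class `sn_model_spec`.
#' @export
sn_model_spec <- function(response = c("log_ctx", "log_fgv"),
                          n_knots = 10, degree = 3,
                          include_time = NULL,
                          prior_scale = 1,
                          informative_window = c(5, 11),
                          informative_center = -0.5,
                          informative_scale = 0.5,
                          re_prior_sd = 1,
                          sigma_prior_sd = 2,
                          alpha_prior_sd = 4,
                          chains = 5, iter = 10000, warmup = 2000,
                          adapt_delta = 0.99, max_treedepth = 10,
                          seed = 1L) {
  response <- match.arg(response)
  if (is.null(include_time)) include_time <- response == "log_ctx"
  if (include_time && response == "log_fgv")
    stop("the velocity model has no collection-time covariate", call. = FALSE)
  stopifnot(iter > warmup, chains >= 1, adapt_delta > 0, adapt_delta < 1)
  structure(mget(names(formals())), class = "sn_model_spec")
}

#' Serialize / read a model specification as YAML
#' @param spec an [sn_model_spec()].
#' @param path file path.
#' @return `read_model_spec` returns the `sn_model_spec`.
#' @export
write_model_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sn_model_spec, vals)
}

#' Assemble design matrices and grouping indices
#'
#' Builds the fixed-effect matrix (intercept, nine constrained age-spline
#' columns, nine male-deviation spline columns, the 2-SD standardized sex
#' main effect, and the standardized collection time for the CTX-I model)
#' plus 0-based individual and site index vectors for the random effects.
#' The male-deviation columns are the spline columns multiplied by a 0/1
#' male indicator, so the male curve is the main (female) curve plus the
#' deviation coefficients — the arithmetic used to derive male estimates.
#'
#' @param dataset a model table from [prepare_model_data()] (`urine` for the
#'   CTX-I model, `velocity` for the velocity model); must carry `age_std`,
#'   `sex`, `sex_std`, `individual_id`, `site_id`, the response column and,
#'   for the CTX-I model, `time_std`.
#' @param spec an [sn_model_spec()].
#' @return list of class `sn_design`: `X`, `y`, `ind`, `site`, `age_std`,
#'   `basis`, `windows`, `col_kind`, `ind_levels`, `site_levels`, `spec`.
#' @export
assemble_design <- function(dataset, spec = sn_model_spec()) {
  ycol <- spec$response
  if (is.null(dataset[[ycol]]))
    stop("dataset lacks the response column `", ycol, "`", call. = FALSE)
  if (spec$include_time && is.null(dataset$time_std))
    stop("CTX-I model requires a standardized time column", call. = FALSE)
  basis <- age_spline_basis(dataset$age_std, n_knots = spec$n_knots,
                            degree = spec$degree, age = dataset$age_years)
  S <- basis$matrix
  male <- as.numeric(dataset$sex == "male")
  if (length(unique(male)) < 2)
    warning("single-sex dataset: sex-deviation columns are constant zero",
            call. = FALSE)
  SM <- S * male
  colnames(SM) <- paste0("sexM_", colnames(S))
  X <- cbind(`(Intercept)` = 1, S, SM, sex_std = dataset$sex_std)
  col_kind <- c("intercept", rep("spline", basis$n_coef),
                rep("sex_spline", basis$n_coef), "sex")
  if (spec$include_time) {
    X <- cbind(X, time_std = dataset$time_std)
    col_kind <- c(col_kind, "time")
  }
  ind_levels <- sort(unique(dataset$individual_id))
  site_levels <- sort(unique(dataset$site_id))
  ind <- match(dataset$individual_id, ind_levels) - 1L
  site <- match(dataset$site_id, site_levels) - 1L
  if (anyNA(ind) || anyNA(site))
    stop("unknown individual or site id in dataset", call. = FALSE)
  structure(list(X = X, y = dataset[[ycol]], ind = ind, site = site,
                 age_std = dataset$age_std, basis = basis,
                 windows = basis$windows, col_kind = col_kind,
                 ind_levels = ind_levels, site_levels = site_levels,
                 spec = spec),
            class = "sn_design")
}

#' Default priors for a skew-normal spline model
#'
#' All coefficients receive zero-centered weakly informative normal priors
#' (scale `prior_scale` on the internally standardized response scale),
#' except the sex-difference spline coefficients whose age windows overlap
#' the informative window (5-11 years by default): in the velocity model
#' these get the informative prior (small scale, center encoding the
#' female-earlier-spurt sign); the CTX-I model uses the same centers with
#' doubled scale. Random-effect standard deviations and the residual scale
#' get half-normal priors; the skewness gets a wide normal prior.
#'
#' @param design an [assemble_design()] result.
#' @param spec the model specification (defaults to the one in `design`).
#' @return data frame with one row per fixed-effect column: `param`,
#'   `kind`, `mean`, `sd`, `informative`, plus attributes `tau_re`,
#'   `tau_sigma`, `tau_alpha`.
#' @export
default_priors <- function(design, spec = design$spec) {
  kind <- design$col_kind
  pr <- data.frame(param = colnames(design$X), kind = kind,
                   mean = 0, sd = spec$prior_scale,
                   informative = FALSE, stringsAsFactors = FALSE)
  win <- design$windows
  lo <- spec$informative_window[1]; hi <- spec$informative_window[2]
  overlap <- win$lower < hi & win$upper > lo   # positive-length overlap
  idx_sex <- which(kind == "sex_spline")
  scale_mult <- if (spec$response == "log_ctx") 2 else 1
  pr$mean[idx_sex[overlap]] <- spec$informative_center
  pr$sd[idx_sex[overlap]] <- spec$informative_scale * scale_mult
  pr$informative[idx_sex[overlap]] <- TRUE
  attr(pr, "tau_re") <- spec$re_prior_sd
  attr(pr, "tau_sigma") <- spec$sigma_prior_sd
  attr(pr, "tau_alpha") <- spec$alpha_prior_sd
  pr
}

#' Fit the skew-normal spline model by NUTS
#'
#' Samples the posterior with the package's No-U-Turn sampler (slice
#' variant, dual-averaging step size, diagonal mass adaptation during
#' warmup). Random effects use a non-centered parametrization. The response
#' is centered and scaled internally for sampling; all reported draws are
#' transformed back to the response scale. Gelman-Rubin statistics and
#' effective sample sizes are computed for every parameter; a warning is
#' issued when the diagnostics indicate non-convergence.
#'
#' @param design an [assemble_design()] result.
#' @param priors prior table from [default_priors()]; defaults to it.
#' @param chains,iter,warmup,adapt_delta,max_treedepth,seed overrides of the
#'   settings in the design's spec.
#' @return object of class `sn_fit`: `draws` (iterations x chains x
#'   parameters, response scale), `rhat`, `ess`, `divergences`,
#'   `step_size`, `mean_accept`, `design`, `priors`, `y_center`, `y_scale`,
#'   `seed`, `runtime_s`.
#' @export
fit_sn_spline <- function(design, priors = default_priors(design),
                          chains = NULL, iter = NULL, warmup = NULL,
                          adapt_delta = NULL, max_treedepth = NULL,
                          seed = NULL) {
  spec <- design$spec
  chains <- chains %||% spec$chains
  iter <- iter %||% spec$iter
  warmup <- warmup %||% spec$warmup
  adapt_delta <- adapt_delta %||% spec$adapt_delta
  max_treedepth <- max_treedepth %||% spec$max_treedepth
  seed <- seed %||% spec$seed

  y <- design$y
  y_center <- mean(y); y_scale <- stats::sd(y)
  if (!isTRUE(y_scale > 0)) stop("constant response", call. = FALSE)
  y_int <- (y - y_center) / y_scale
  X <- design$X
  p <- ncol(X); nI <- length(design$ind_levels); nS <- length(design$site_levels)
  dim_all <- p + 2 * nI + nS + 5

  t0 <- proc.time()[["elapsed"]]
  chain_draws <- vector("list", chains)
  divergences <- integer(chains); step_size <- numeric(chains)
  accept <- numeric(chains)
  for (ch in seq_len(chains)) {
    set.seed(seed + ch)
    init <- c(stats::rnorm(p, 0, 0.1),
              stats::rnorm(2 * nI, 0, 0.1),
              stats::rnorm(nS, 0, 0.1),
              rep(log(0.3), 3) + stats::rnorm(3, 0, 0.05),
              stats::rnorm(1, 0, 0.05),   # log sigma
              stats::rnorm(1, 0, 0.05))   # alpha
    res <- .sn_nuts_chain(init, y_int, X, design$ind, design$site,
                          design$age_std, nI, nS, priors$mean, priors$sd,
                          attr(priors, "tau_re"), attr(priors, "tau_sigma"),
                          attr(priors, "tau_alpha"),
                          as.integer(iter), as.integer(warmup),
                          adapt_delta, as.integer(max_treedepth))
    chain_draws[[ch]] <- res$draws
    divergences[ch] <- res$divergences
    step_size[ch] <- res$step_size
    accept[ch] <- res$mean_accept
  }
  runtime <- proc.time()[["elapsed"]] - t0

  par_names <- c(colnames(X),
                 paste0("u[", design$ind_levels, "]"),
                 paste0("w[", design$ind_levels, "]"),
                 paste0("s[", design$site_levels, "]"),
                 "sd_ind", "sd_slope", "sd_site", "sigma", "alpha")
  n_keep <- iter - warmup
  draws <- array(NA_real_, c(n_keep, chains, dim_all),
                 dimnames = list(NULL, NULL, par_names))
  o_sd <- p + 2 * nI + nS
  for (ch in seq_len(chains)) {
    d <- chain_draws[[ch]]
    # back-transform to the response scale
    d[, 1:p] <- d[, 1:p] * y_scale
    d[, 1] <- d[, 1] + y_center
    d[, o_sd + 1:4] <- exp(d[, o_sd + 1:4]) * y_scale  # sds and sigma
    draws[, ch, ] <- d
  }
  rhat_v <- apply(draws, 3, function(m) rhat(m))
  ess_v <- apply(draws, 3, function(m) ess_basic(m))
  fit <- structure(
    list(draws = draws, par_names = par_names, rhat = rhat_v, ess = ess_v,
         divergences = divergences, step_size = step_size,
         mean_accept = accept, design = design, priors = priors,
         y_center = y_center, y_scale = y_scale, seed = seed,
         chains = chains, iter = iter, warmup = warmup,
         runtime_s = runtime),
    class = "sn_fit")
  if (all(is.finite(rhat_v)) && any(rhat_v > 1.1))
    warning(sprintf("%d parameter(s) with Gelman-Rubin diagnostic > 1.1; inspect convergence",
                    sum(rhat_v > 1.1)), call. = FALSE)
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sn_fit <- function(x, ...) {
  cat(sprintf("Skew-normal spline model fit (%s)\n", x$design$spec$response))
  cat(sprintf("  %d chains x %d iterations (%d warmup), %d parameters\n",
              x$chains, x$iter, x$warmup, length(x$par_names)))
  cat(sprintf("  max R-hat %.3f, min ESS %.0f, divergences %s, runtime %.1fs\n",
              max(x$rhat, na.rm = TRUE), min(x$ess, na.rm = TRUE),
              paste(x$divergences, collapse = "/"), x$runtime_s))
  invisible(x)
}

#' Extract posterior draws as a matrix
#'
#' @param fit an `sn_fit`.
#' @param pars optional parameter names.
#' @return matrix (chains stacked) with one column per parameter.
#' @export
posterior_draws <- function(fit, pars = fit$par_names) {
  idx <- match(pars, fit$par_names)
  if (anyNA(idx)) stop("unknown parameter: ",
                       paste(pars[is.na(idx)], collapse = ", "), call. = FALSE)
  out <- apply(fit$draws[, , idx, drop = FALSE], 3, rbind)
  out <- matrix(out, ncol = length(idx), dimnames = list(NULL, pars))
  out
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computes the potential scale reduction factor from the between- and
#' within-chain variances; with `split = TRUE` (default) each chain is first
#' split in half so within-chain trends are detected. The statistic is
#' floored at 1 (values below 1 are estimation noise).
#'
#' @param x matrix of draws, iterations x chains.
#' @param split split each chain in half first?
#' @return scalar R-hat.
#' @export
rhat <- function(x, split = TRUE) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("at least two chains are required", call. = FALSE)
  if (nrow(x) < 2) stop("at least two draws per chain are required", call. = FALSE)
  if (split && nrow(x) >= 4) {
    h <- floor(nrow(x) / 2)
    x <- cbind(x[seq_len(h), , drop = FALSE],
               x[(nrow(x) - h + 1):nrow(x), , drop = FALSE])
  }
  n <- nrow(x); m <- ncol(x)
  means <- colMeans(x)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(means)
  if (!isTRUE(W > 0)) return(ifelse(B > 0, Inf, 1))
  sigma2 <- (n - 1) / n * W + B / n
  sqrt(max(sigma2, W) / W)
}

#' Effective sample size
#'
#' Autocorrelation-based effective sample size pooled over chains, using the
#' standard within/between decomposition and Geyer's initial positive
#' sequence truncation.
#'
#' @param x matrix of draws, iterations x chains.
#' @return scalar effective sample size.
#' @export
ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4) return(NA_real_)
  W <- mean(apply(x, 2, stats::var))
  B <- if (m > 1) n * stats::var(colMeans(x)) else 0
  var_plus <- (n - 1) / n * W + B / n
  if (!isTRUE(var_plus > 0)) return(NA_real_)
  max_lag <- min(n - 2, 1000)
  acov <- sapply(seq_len(m), function(j) {
    a <- stats::acf(x[, j], lag.max = max_lag, plot = FALSE,
                    type = "covariance", demean = TRUE)$acf[, 1, 1]
    a
  })
  acov <- rowMeans(acov)
  rho <- 1 - (W - acov[-1]) / var_plus
  # Geyer initial positive sequence on paired sums
  tau <- 0; t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    tau <- tau + pair
    t <- t + 2
  }
  ess <- m * n / (1 + 2 * tau)
  min(ess, m * n)
}

#' Posterior predictive check
#'
#' Draws replicated datasets from the posterior (fixed effects plus the
#' sampled random effects and skew-normal residuals) and compares summary
#' statistics of the observed response with their replicated distributions.
#' The tail probability for statistic T is `P(T_rep >= T_obs)`; values near
#' 0 or 1 flag misfit.
#'
#' @param fit an `sn_fit`.
#' @param n_rep number of replicated datasets.
#' @param seed seed for the replication draws.
#' @return data frame of class `sn_ppc`: `stat`, `observed`, `rep_mean`,
#'   `p_tail`.
#' @export
posterior_predictive_check <- function(fit, n_rep = 200, seed = 1) {
  des <- fit$design
  y <- des$y
  stat_fun <- list(
    mean = mean, sd = stats::sd,
    skewness = function(v) mean((v - mean(v))^3) / stats::sd(v)^3,
    min = min, max = max)
  n_keep <- dim(fit$draws)[1]; chains <- dim(fit$draws)[2]
  p <- ncol(des$X); nI <- length(des$ind_levels); nS <- length(des$site_levels)
  with_seed(seed, {
    reps <- matrix(NA_real_, n_rep, length(stat_fun))
    for (r in seq_len(n_rep)) {
      it <- sample.int(n_keep, 1); ch <- sample.int(chains, 1)
      d <- fit$draws[it, ch, ]
      beta <- d[seq_len(p)]
      u <- d[p + seq_len(nI)]; w <- d[p + nI + seq_len(nI)]
      s <- d[p + 2 * nI + seq_len(nS)]
      sd_ind <- d[["sd_ind"]]; sd_slope <- d[["sd_slope"]]
      sd_site <- d[["sd_site"]]
      mu <- as.numeric(des$X %*% beta) + sd_ind * u[des$ind + 1] +
        sd_slope * w[des$ind + 1] * des$age_std + sd_site * s[des$site + 1]
      y_rep <- rskew_normal(length(y), mu, d[["sigma"]], d[["alpha"]])
      reps[r, ] <- vapply(stat_fun, function(f) f(y_rep), numeric(1))
    }
    obs <- vapply(stat_fun, function(f) f(y), numeric(1))
    out <- data.frame(stat = names(stat_fun), observed = obs,
                      rep_mean = colMeans(reps),
                      p_tail = colMeans(sweep(reps, 2, obs, `>=`)))
    rownames(out) <- NULL
    class(out) <- c("sn_ppc", "data.frame")
    out
  })
}
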