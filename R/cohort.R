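# Synthetic bonobo-like cohort generator: sex-specific growth-velocity and
# urinary CTX-I age curves, diurnal decline, day-to-day variability,
# skew-normal residuals, specific-gravity dilution.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Configuration of the synthetic cohort generator
#'
#' Returns the default generator configuration, emulating the study cohort:
#' 48 individuals (22 female / 26 male) with roughly 187 urine samples across
#' 11 housing sites, 81 individuals with roughly 364 forearm measurements, a
#' ~25% day-to-day coefficient of variation of CTX-I, a diurnal decline such
#' that the expected 18:00 concentration is 55% of the 07:00 one, specific
#' gravity occasionally below the 1.003 quality threshold, and forearm
#' measurement noise producing a minority of small negative velocities.
#'
#' @param n_individuals number of individuals in the urine dataset.
#' @param sex_ratio fraction of females.
#' @param n_sites number of housing sites (zoos).
#' @param n_individuals_forearm number of individuals in the forearm dataset
#'   (the urine individuals are a subset).
#' @param fgv_curve_params per-sex list of growth-velocity curve parameters:
#'   `baseline` and `height` (cm/day), `peak` and `width` (years),
#'   `cessation` (age at which growth reaches zero, <= 20) and `ramp`
#'   (length in years of the smooth ramp-down before cessation).
#' @param ctx_curve_params per-sex list of log CTX-I curve parameters:
#'   `level` (ng/mL scale at baseline), `height` (log-scale amplitude of the
#'   juvenile peak), `peak`, `width` (years), `decline` (log units/year of
#'   post-10-year decline).
#' @param coupling in `[0, 1]`; strength with which the female CTX-I age
#'   curve is tied to the female growth-velocity curve (1 = a monotone
#'   transform of it, 0 = fully independent).
#' @param diurnal_log_slope change in log CTX-I per minute of clock time.
#'   The default targets an 18:00/07:00 expected concentration ratio of 0.55.
#' @param day_cv day-to-day coefficient of variation (fraction) of
#'   concentrations sampled at the same time of day.
#' @param day_effect_share fraction of the day-to-day log variance carried by
#'   the shared per-(individual, day) effect; the rest is the skew-normal
#'   sample residual.
#' @param skew_alpha shape of the skew-normal residual on the log scale.
#' @param forearm_noise_sd measurement noise of a forearm length (cm).
#' @param sg_mean,sg_sd specific-gravity distribution (truncated below at 1).
#' @param sg_ref reference specific gravity at which "true" concentrations
#'   are generated; observed raw concentrations are diluted/concentrated
#'   relative to it.
#' @param ind_sd_growth,ind_sd_ctx,site_sd log-scale standard deviations of
#'   the individual growth factor, individual CTX-I intercept and site
#'   intercepts.
#' @param birth_length_cm mean forearm length at birth.
#' @param seed integer seed making the whole cohort reproducible.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals = 48,
                          sex_ratio = 22 / 48,
                          n_sites = 11,
                          n_individuals_forearm = 81,
                          fgv_curve_params = list(
                            female = list(baseline = 0.004, height = 0.008,
                                          peak = 5.5, width = 2.5,
                                          cessation = 18, ramp = 3),
                            male = list(baseline = 0.009, height = 0.003,
                                        peak = 8, width = 4.5,
                                        cessation = 20, ramp = 9)),
                          ctx_curve_params = list(
                            female = list(level = 2.0, height = 1.0,
                                          peak = 4, width = 2.5, decline = 0.10),
                            male = list(level = 2.0, height = 0.3,
                                        peak = 4.5, width = 2.5, decline = 0.03)),
                          coupling = 0.4,
                          diurnal_log_slope = log(0.55) / 660,
                          day_cv = 0.25,
                          day_effect_share = 0.75,
                          skew_alpha = -3,
                          forearm_noise_sd = 0.25,
                          sg_mean = 1.012,
                          sg_sd = 0.006,
                          sg_ref = 1.012,
                          ind_sd_growth = 0.08,
                          ind_sd_ctx = 0.15,
                          site_sd = 0.05,
                          birth_length_cm = 10,
                          seed = 1L) {
  cfg <- mget(names(formals()))
  if (sex_ratio < 0 || sex_ratio > 1)
    stop("`sex_ratio` must lie in [0, 1]", call. = FALSE)
  if (coupling < 0 || coupling > 1)
    stop("`coupling` must lie in [0, 1]", call. = FALSE)
  if (day_cv <= 0) stop("`day_cv` must be positive", call. = FALSE)
  if (sg_mean <= 1.000) stop("`sg_mean` must exceed 1.000", call. = FALSE)
  if (fgv_curve_params$female$cessation > 20 ||
      fgv_curve_params$male$cessation > 20)
    stop("growth cessation age must be <= 20 years", call. = FALSE)
  structure(cfg, class = "cohort_config")
}

check_age <- function(age) {
  if (any(age < 0 | age > 20))
    stop("age must lie in [0, 20] years", call. = FALSE)
}

#' Mean forearm growth-velocity curve
#'
#' Smooth nonnegative velocity (cm/day) across age: a Gaussian growth-spurt
#' bump on a baseline, multiplied by a smooth ramp-down that reaches exactly
#' zero at the cessation age. Under the default parameters the female curve
#' peaks during the juvenile period (ages ~5-6) while males sustain high
#' velocity from birth and only decline from about 11 years.
#'
#' @param age age in years, in `[0, 20]`.
#' @param sex `"female"` or `"male"` (abbreviations `"F"`/`"M"` accepted).
#' @param params per-sex parameter list; see [cohort_config()].
#' @return velocity in cm/day.
#' @export
mean_fgv_curve <- function(age, sex = c("female", "male"),
                           params = cohort_config()$fgv_curve_params) {
  check_age(age)
  sex <- normalize_sex(sex)
  p <- params[[sex]]
  bump <- p$baseline + p$height * exp(-((age - p$peak) / p$width)^2)
  bump * smoothstep((p$cessation - age) / p$ramp)
}

normalize_sex <- function(sex) {
  sex <- as.character(sex[1])
  out <- c(F = "female", female = "female", Female = "female",
           M = "male", male = "male", Male = "male")[sex]
  if (is.na(out)) stop("unknown sex: ", sex, call. = FALSE)
  unname(out)
}

#' Mean log urinary CTX-I curve across age
#'
#' Log concentration (log ng/mL, at the reference specific gravity and at
#' 07:00) as a function of age. The base shape is a juvenile peak (~4 years)
#' followed by a steady post-10-year decline. For females the curve is a
#' `coupling`-weighted blend of that base shape with a monotone transform of
#' the female growth-velocity curve, so `coupling = 1` makes female CTX-I a
#' rank-preserving image of growth velocity and `coupling = 0` makes it
#' independent of the growth parameters. Males are never coupled.
#'
#' @inheritParams mean_fgv_curve
#' @param config a [cohort_config()] (supplies the CTX curve parameters, the
#'   coupling strength, and the growth parameters used when coupling).
#' @return log concentration (log ng/mL).
#' @export
mean_log_ctx_curve <- function(age, sex = c("female", "male"),
                               config = cohort_config()) {
  check_age(age)
  sex <- normalize_sex(sex)
  p <- config$ctx_curve_params[[sex]]
  base <- log(p$level) + p$height * exp(-((age - p$peak) / p$width)^2) -
    p$decline * softplus(age - 10)
  kappa <- if (sex == "female") config$coupling else 0
  if (kappa == 0) return(base)
  grid <- seq(0, 20, by = 0.05)
  lf <- log(mean_fgv_curve(grid, "female", config$fgv_curve_params) + 1e-4)
  lo <- min(lf); hi <- max(lf)
  t_age <- (log(mean_fgv_curve(age, "female", config$fgv_curve_params) + 1e-4) - lo) /
    (hi - lo)
  coupled <- log(p$level) + p$height * t_age
  (1 - kappa) * base + kappa * coupled
}

#' Generate the individuals of a synthetic cohort
#'
#' Assigns ids, sexes (to match the configured sex ratio), birthdates,
#' housing sites, and latent per-individual and per-site effects used by the
#' simulators (stored in attributes `effects` and `site_effects`; they are
#' generator truth, not observable data).
#'
#' @param config a [cohort_config()].
#' @param n number of individuals; defaults to
#'   `config$n_individuals_forearm` so the cohort can serve both datasets.
#' @param reference_date latest possible observation date.
#' @return data frame with columns `id`, `sex`, `birthdate`, `site_id`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            n = config$n_individuals_forearm,
                            reference_date = as.Date("2022-03-01")) {
  if (n < 0) stop("`n` must be nonnegative", call. = FALSE)
  with_seed(config$seed, {
    if (n == 0) {
      out <- data.frame(id = character(), sex = character(),
                        birthdate = as.Date(character()),
                        site_id = character())
      attr(out, "effects") <- data.frame(id = character(),
                                         growth_log_factor = numeric(),
                                         ctx_intercept = numeric())
      attr(out, "site_effects") <- data.frame(site_id = character(),
                                              fgv_effect = numeric(),
                                              ctx_effect = numeric())
      return(out)
    }
    ids <- sprintf("ind%02d", seq_len(n))
    n_f <- round(n * config$sex_ratio)
    sex <- sample(c(rep("female", n_f), rep("male", n - n_f)))
    birthdate <- reference_date - round(stats::runif(n, 0.5, 20) * 365.25)
    site_id <- sprintf("site%02d", sample.int(config$n_sites, n, replace = TRUE))
    out <- data.frame(id = ids, sex = sex, birthdate = birthdate,
                      site_id = site_id, stringsAsFactors = FALSE)
    attr(out, "effects") <- data.frame(
      id = ids,
      growth_log_factor = stats::rnorm(n, 0, config$ind_sd_growth),
      ctx_intercept = stats::rnorm(n, 0, config$ind_sd_ctx))
    sites <- sprintf("site%02d", seq_len(config$n_sites))
    attr(out, "site_effects") <- data.frame(
      site_id = sites,
      fgv_effect = stats::rnorm(config$n_sites, 0, config$site_sd),
      ctx_effect = stats::rnorm(config$n_sites, 0, config$site_sd))
    out
  })
}

# cumulative forearm length (cm) at given ages (years) for one individual
forearm_length_at <- function(age, sex, params, growth_log_factor = 0,
                              site_effect = 0, birth_length = 10) {
  f <- function(a) mean_fgv_curve(a, sex, params) * 365.25
  ages <- sort(unique(c(0, age)))
  inc <- vapply(seq_len(length(ages) - 1), function(i) {
    stats::integrate(f, ages[i], ages[i + 1], rel.tol = 1e-10,
                     abs.tol = 1e-12, subdivisions = 400L)$value
  }, numeric(1))
  cum <- c(0, cumsum(inc))
  scale <- exp(growth_log_factor + site_effect)
  birth_length + scale * cum[match(age, ages)]
}

#' Simulate forearm length measurements for one individual
#'
#' Lengths are the cumulative integral of the individual's mean velocity
#' curve from birth (times the individual's latent growth factor), plus
#' independent Gaussian measurement noise. With `noise_sd = 0` the
#' downstream velocities equal the curve's interval averages exactly.
#'
#' @param individual one-row data frame (or list) with `sex`, `birthdate`,
#'   and optionally `growth_log_factor` and `site_fgv_effect`.
#' @param schedule vector of measurement dates (sorted, all after birth).
#' @param noise_sd measurement noise standard deviation (cm).
#' @param config a [cohort_config()].
#' @param seed optional seed.
#' @return data frame with `id`, `date`, `length_cm`.
#' @export
simulate_forearm_series <- function(individual, schedule,
                                    noise_sd = cohort_config()$forearm_noise_sd,
                                    config = cohort_config(), seed = NULL) {
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative", call. = FALSE)
  schedule <- as.Date(schedule)
  if (is.unsorted(schedule)) stop("`schedule` must be sorted", call. = FALSE)
  birth <- as.Date(individual$birthdate)
  if (any(schedule < birth))
    stop("measurement dates precede the birthdate", call. = FALSE)
  age <- as.numeric(schedule - birth) / 365.25
  check_age(age)
  glf <- if (!is.null(individual$growth_log_factor)) individual$growth_log_factor else 0
  sfe <- if (!is.null(individual$site_fgv_effect)) individual$site_fgv_effect else 0
  with_seed(seed, {
    len <- forearm_length_at(age, normalize_sex(individual$sex),
                             config$fgv_curve_params, glf, sfe,
                             config$birth_length_cm)
    len <- len + stats::rnorm(length(len), 0, noise_sd)
    data.frame(id = rep(if (!is.null(individual$id)) individual$id else "ind", length(len)),
               date = schedule, length_cm = len, stringsAsFactors = FALSE)
  })
}

# truncated-normal specific gravity, >= 1.000
draw_sg <- function(n, mean, sd) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= 1.000])
  }
  out[seq_len(n)]
}

#' Simulate urine samples for one individual
#'
#' Log concentration is the individual's mean age curve plus the diurnal
#' slope (linear in minutes of clock time), a shared per-day effect, and a
#' centered skew-normal sample residual; the day effect and the residual
#' together carry the log-scale variance equivalent to the configured
#' day-to-day CV (`log(1 + cv^2)`, split by `day_effect_share`). Specific
#' gravity is drawn from a truncated normal (>= 1.000), and the observed raw
#' concentration is the "true" concentration diluted or concentrated
#' relative to the generator's reference specific gravity.
#'
#' @param individual one-row data frame (or list) with `sex`, `birthdate`,
#'   and optionally `ctx_intercept` and `site_ctx_effect`.
#' @param schedule data frame with columns `date` and `minutes` (minutes of
#'   the day in `[0, 1440)`).
#' @param config a [cohort_config()].
#' @param seed optional seed.
#' @return data frame with `id`, `date`, `minutes`, `time_hhmm`,
#'   `ctx_ng_ml` (raw, hydration-dependent), `sg`, and the latent
#'   `ctx_true` (at reference specific gravity).
#' @export
simulate_urine_series <- function(individual, schedule,
                                  config = cohort_config(), seed = NULL) {
  if (nrow(schedule) == 0) {
    return(data.frame(id = character(), date = as.Date(character()),
                      minutes = integer(), time_hhmm = character(),
                      ctx_ng_ml = numeric(), sg = numeric(),
                      ctx_true = numeric()))
  }
  if (any(schedule$minutes < 0 | schedule$minutes >= 1440))
    stop("`minutes` must lie in [0, 1440)", call. = FALSE)
  birth <- as.Date(individual$birthdate)
  dates <- as.Date(schedule$date)
  if (any(dates < birth)) stop("sample dates precede the birthdate", call. = FALSE)
  age <- as.numeric(dates - birth) / 365.25
  check_age(age)
  sex <- normalize_sex(individual$sex)
  ii <- if (!is.null(individual$ctx_intercept)) individual$ctx_intercept else 0
  se <- if (!is.null(individual$site_ctx_effect)) individual$site_ctx_effect else 0
  v <- log(1 + config$day_cv^2)
  sd_day <- sqrt(config$day_effect_share * v)
  sd_resid <- sqrt((1 - config$day_effect_share) * v)
  with_seed(seed, {
    day_key <- as.character(dates)
    day_eff <- stats::rnorm(length(unique(day_key)), 0, sd_day)
    names(day_eff) <- unique(day_key)
    resid <- rskew_normal(length(age), mu = 0,
                          sigma = skew_normal_scale_for_sd(sd_resid, config$skew_alpha),
                          alpha = config$skew_alpha)
    logc <- mean_log_ctx_curve(age, sex, config) + ii + se +
      config$diurnal_log_slope * (schedule$minutes - 420) +
      day_eff[day_key] + resid
    ctx_true <- exp(logc)
    sg <- draw_sg(length(age), config$sg_mean, config$sg_sd)
    ctx_raw <- ctx_true * (sg - 1) / (config$sg_ref - 1)
    data.frame(
      id = rep(if (!is.null(individual$id)) individual$id else "ind", length(age)),
      date = dates, minutes = as.integer(schedule$minutes),
      time_hhmm = sprintf("%02d:%02d", schedule$minutes %/% 60, schedule$minutes %% 60),
      ctx_ng_ml = ctx_raw, sg = sg, ctx_true = ctx_true,
      stringsAsFactors = FALSE)
  })
}

#' Simulate a full synthetic cohort
#'
#' Draws individuals, observation schedules and both datasets: urine samples
#' for the first `config$n_individuals` individuals (1-18 samples each,
#' targeting ~187 in total under the defaults) collected between 07:00 and
#' 18:00, and forearm measurements for all `config$n_individuals_forearm`
#' individuals (1-10 each, targeting ~364 in total).
#'
#' @param config a [cohort_config()].
#' @return list with elements `individuals`, `urine`, `forearm`, and `truth`
#'   (the configuration plus the latent individual and site effects).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  individuals <- generate_cohort(config)
  effects <- attr(individuals, "effects")
  site_effects <- attr(individuals, "site_effects")
  n <- nrow(individuals)
  with_seed(config$seed + 1000L, {
    urine_ids <- individuals$id[seq_len(min(config$n_individuals, n))]
    urine <- list(); forearm <- list()
    for (i in seq_len(n)) {
      indiv <- as.list(individuals[i, ])
      indiv$growth_log_factor <- effects$growth_log_factor[i]
      indiv$ctx_intercept <- effects$ctx_intercept[i]
      srow <- match(indiv$site_id, site_effects$site_id)
      indiv$site_fgv_effect <- site_effects$fgv_effect[srow]
      indiv$site_ctx_effect <- site_effects$ctx_effect[srow]
      birth <- as.Date(indiv$birthdate)
      max_date <- min(as.Date("2022-03-01"), birth + round(19.9 * 365.25))
      span <- as.numeric(max_date - birth)
      # forearm: 1-10 irregular measurement dates
      k_f <- 1 + stats::rbinom(1, 9, 0.39)
      fdates <- birth + sort(sample.int(max(span - 90, k_f), k_f)) + 89
      fdates <- pmin(fdates, max_date)
      fdates <- fdates[!duplicated(fdates)]
      forearm[[i]] <- simulate_forearm_series(indiv, fdates,
                                              config$forearm_noise_sd, config)
      # urine: sample counts mimic mean ~4, median 1, range 1-18
      if (indiv$id %in% urine_ids) {
        k_u <- min(1 + stats::rnbinom(1, size = 0.8, mu = 2.9), 18)
        udates <- birth + sort(sample.int(max(span - 30, k_u), k_u,
                                          replace = TRUE)) + 29
        udates <- pmin(udates, max_date)
        sched <- data.frame(date = udates,
                            minutes = sample(420:1080, k_u, replace = TRUE))
        urine[[i]] <- simulate_urine_series(indiv, sched, config)
      }
    }
    list(individuals = individuals,
         urine = do.call(rbind, urine),
         forearm = do.call(rbind, forearm),
         truth = list(config = unclass(config),
                      individual_effects = effects,
                      site_effects = site_effects))
  })
}

#' Write a simulated cohort to CSV files plus a truth sidecar
#'
#' Writes `individuals.csv` (id, sex, birthdate, site_id), `forearm.csv`
#' (id, date, length_cm), `urine.csv` (id, date, time_hhmm, ctx_ng_ml, sg)
#' and `truth.json` (generator parameters and latent effects, for recovery
#' tests). Dates are ISO-8601, decimal point, UTF-8, header row.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_one <- function(df, cols, file) {
    utils::write.csv(df[, cols], file.path(dir, file), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  }
  ind <- sim$individuals
  ind$birthdate <- format(as.Date(ind$birthdate))
  write_one(ind, c("id", "sex", "birthdate", "site_id"), "individuals.csv")
  fa <- sim$forearm; fa$date <- format(as.Date(fa$date))
  write_one(fa, c("id", "date", "length_cm"), "forearm.csv")
  ur <- sim$urine; ur$date <- format(as.Date(ur$date))
  write_one(ur, c("id", "date", "time_hhmm", "ctx_ng_ml", "sg"), "urine.csv")
  truth <- sim$truth
  truth$config <- truth$config[!vapply(truth$config, is.function, logical(1))]
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a cohort CSV bundle written by [write_cohort()]
#'
#' @param dir directory containing the bundle.
#' @return list with `individuals`, `forearm`, `urine` data frames and
#'   `truth` (parsed JSON, or `NULL` if absent).
#' @export
read_cohort <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  individuals <- rd("individuals.csv")
  individuals$birthdate <- as.Date(individuals$birthdate)
  forearm <- rd("forearm.csv"); forearm$date <- as.Date(forearm$date)
  urine <- rd("urine.csv"); urine$date <- as.Date(urine$date)
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path,
                                                            simplifyVector = TRUE)
  else NULL
  list(individuals = individuals, forearm = forearm, urine = urine,
       truth = truth)
}
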