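# Preprocessing: specific-gravity correction and QC of urine samples,
# forearm growth-velocity derivation, positivity enforcement, and 2-SD
# standardization of model covariates.

#' Correct a urinary concentration for specific gravity
#'
#' Rescales a raw concentration to a reference hydration status:
#' `ctx_raw * (sg_ref - 1) / (sg_sample - 1)`. The correction is homogeneous
#' in the concentration and invariant to dilution (multiplying the water
#' content dilutes `ctx_raw` and shrinks `sg - 1` by the same factor).
#'
#' @param ctx_raw raw concentration (ng/mL).
#' @param sg_sample specific gravity of the sample; must exceed 1.000.
#' @param sg_ref reference specific gravity; must exceed 1.000.
#' @return corrected concentration (ng/mL).
#' @export
sg_correct <- function(ctx_raw, sg_sample, sg_ref) {
  if (any(sg_ref <= 1.000)) stop("`sg_ref` must exceed 1.000", call. = FALSE)
  if (any(sg_sample <= 1.000))
    stop("`sg_sample` must exceed 1.000 (division by a nonpositive excess density)",
         call. = FALSE)
  ctx_raw * (sg_ref - 1) / (sg_sample - 1)
}

#' Quality filter on specific gravity
#'
#' Retains samples with `sg >= sg_min` (the discard rule is a strict `<`)
#' and logs the exclusions.
#'
#' @param samples data frame of urine samples with an `sg` column.
#' @param sg_min exclusion threshold (default 1.003).
#' @return the retained rows, with an attribute `exclusions` (data frame of
#'   dropped rows plus a `reason` column) and `n_excluded`.
#' @export
qc_filter <- function(samples, sg_min = 1.003) {
  keep <- samples$sg >= sg_min
  dropped <- samples[!keep, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- sprintf("sg < %g", sg_min)
  out <- samples[keep, , drop = FALSE]
  attr(out, "exclusions") <- dropped
  attr(out, "n_excluded") <- nrow(dropped)
  out
}

#' Convert a 24-hour clock string to minutes since midnight
#'
#' @param hhmm character vector like `"07:30"`.
#' @return integer minutes since midnight.
#' @export
time_to_minutes <- function(hhmm) {
  ok <- grepl("^([01]?[0-9]|2[0-3]):[0-5][0-9]$", hhmm)
  if (any(!ok))
    stop("malformed clock time: ", paste(hhmm[!ok], collapse = ", "),
         call. = FALSE)
  h <- as.integer(sub(":.*", "", hhmm))
  m <- as.integer(sub(".*:", "", hhmm))
  h * 60L + m
}

#' Forearm growth velocities from consecutive length measurements
#'
#' For each consecutive pair of measurements the velocity is the length
#' difference divided by the number of days between them, anchored at the
#' "velocity date" midway between the two measurement dates; the age at that
#' date is `(velocity_date - birthdate) / 365.25` years.
#'
#' @param measurements data frame for one individual with columns `date`
#'   (strictly increasing) and `length_cm`; an `id` column is carried through.
#' @param birthdate the individual's birthdate.
#' @return data frame with one row per consecutive pair: `individual_id`,
#'   `velocity_date` (may fall midway between calendar days), `age_years`,
#'   `fgv` (cm/day, may be negative). Empty for fewer than two measurements.
#' @export
compute_velocities <- function(measurements, birthdate) {
  d <- as.numeric(as.Date(measurements$date))
  if (is.unsorted(d, strictly = FALSE)) stop("dates must be increasing", call. = FALSE)
  if (anyDuplicated(d)) stop("duplicate measurement dates (zero-day interval)",
                             call. = FALSE)
  n <- length(d)
  id <- if (!is.null(measurements$id)) measurements$id[1] else NA_character_
  if (n < 2) {
    return(data.frame(individual_id = character(), velocity_date = as.Date(character()),
                      age_years = numeric(), fgv = numeric()))
  }
  len <- measurements$length_cm
  dd <- diff(d)
  vd <- d[-n] + dd / 2
  birth <- as.numeric(as.Date(birthdate))
  data.frame(
    individual_id = rep(id, n - 1),
    velocity_date = as.Date(vd, origin = "1970-01-01"),
    age_years = (vd - birth) / 365.25,
    fgv = diff(len) / dd)
}

#' Force growth velocities to be positive
#'
#' Non-positive velocities (caused by measurement error) are clamped to a
#' small positive epsilon so the log transform stays finite; positive values
#' are unchanged, so ordering among positives is preserved. The default
#' epsilon is half the smallest positive velocity in the input; if no
#' positive value exists, the absolute fallback is used and a warning is
#' issued.
#'
#' @param fgv numeric vector of velocities (cm/day).
#' @param policy `"half_min_positive"` (default) or `"epsilon"` (always use
#'   the absolute `epsilon`).
#' @param epsilon absolute fallback epsilon (cm/day).
#' @return positive vector, with attributes `n_clamped` and `epsilon_used`.
#' @export
enforce_positive <- function(fgv, policy = c("half_min_positive", "epsilon"),
                             epsilon = 1e-6) {
  policy <- match.arg(policy)
  if (epsilon <= 0) stop("`epsilon` must be positive", call. = FALSE)
  pos <- fgv[fgv > 0]
  eps_use <- if (policy == "half_min_positive" && length(pos)) {
    min(pos) / 2
  } else {
    if (policy == "half_min_positive" && !length(pos))
      warning("no positive velocities; falling back to absolute epsilon")
    epsilon
  }
  out <- ifelse(fgv > 0, fgv, eps_use)
  attr(out, "n_clamped") <- sum(fgv <= 0)
  attr(out, "epsilon_used") <- eps_use
  out
}

#' Center and standardize to two standard deviations
#'
#' Subtracts the mean and divides by twice the sample standard deviation,
#' putting continuous and binary predictors on comparable scales: the output
#' has mean 0 and standard deviation 0.5.
#'
#' @param values numeric vector with at least two distinct values.
#' @param variable optional variable name stored in the parameters.
#' @return list with `values` (standardized vector) and `params` (a
#'   `standardization_params` list: `variable`, `center`, `scale`).
#' @export
standardize_2sd <- function(values, variable = NULL) {
  s <- stats::sd(values)
  if (!isTRUE(s > 0)) stop("cannot standardize a constant vector", call. = FALSE)
  params <- structure(list(variable = variable, center = mean(values),
                           scale = 2 * s), class = "standardization_params")
  list(values = (values - params$center) / params$scale, params = params)
}

#' Apply stored standardization parameters
#' @param values numeric vector.
#' @param params a `standardization_params` object.
#' @return standardized vector.
#' @export
apply_standardization <- function(values, params) {
  (values - params$center) / params$scale
}

#' Invert a standardization
#' @inheritParams apply_standardization
#' @return values on the original scale.
#' @export
invert_standardization <- function(values, params) {
  values * params$scale + params$center
}

# 2-SD standardization of the sex indicator, tolerating single-sex data
# (constant indicator -> all-zero column with unit scale, plus a warning)
standardize_sex <- function(x, name) {
  if (isTRUE(stats::sd(x) > 0)) return(standardize_2sd(x, name))
  warning("single-sex dataset: standardized sex column is constant zero",
          call. = FALSE)
  list(values = rep(0, length(x)),
       params = structure(list(variable = name, center = mean(x), scale = 1),
                          class = "standardization_params"))
}

#' Prepare model-ready urine and velocity tables
#'
#' Runs the full preprocessing chain: specific-gravity QC filter and
#' correction with log transform for urine; per-individual velocity
#' derivation, positivity enforcement and log transform for forearm data;
#' conversion of collection times to minutes; and 2-SD standardization of
#' the covariates. The age gradient is standardized on the pooled ages of
#' both datasets so the two models share one age scale; sex (0/1 indicator
#' for male) is standardized within each dataset and collection time within
#' the urine dataset.
#'
#' @param urine data frame: `id`, `date`, `time_hhmm` (or `minutes`),
#'   `ctx_ng_ml`, `sg`.
#' @param forearm data frame: `id`, `date`, `length_cm`.
#' @param individuals data frame: `id`, `sex`, `birthdate`, `site_id`.
#' @param sg_min quality threshold on specific gravity.
#' @param sg_ref reference specific gravity for the correction; default is
#'   the mean specific gravity of the retained samples.
#' @param positivity_policy,epsilon see [enforce_positive()].
#' @return list with `urine` and `velocity` model tables,
#'   `standardization` (named list of parameter sets), and `log` (counts of
#'   every filter applied).
#' @export
prepare_model_data <- function(urine, forearm, individuals, sg_min = 1.003,
                               sg_ref = NULL,
                               positivity_policy = "half_min_positive",
                               epsilon = 1e-6) {
  individuals$birthdate <- as.Date(individuals$birthdate)
  key <- match(urine$id, individuals$id)
  if (anyNA(key)) stop("urine sample with unknown individual id", call. = FALSE)

  ur <- qc_filter(urine, sg_min)
  n_excluded <- attr(ur, "n_excluded")
  if (is.null(sg_ref)) sg_ref <- mean(ur$sg)
  key <- match(ur$id, individuals$id)
  minutes <- if (!is.null(ur$minutes)) ur$minutes else time_to_minutes(ur$time_hhmm)
  ctx_sg <- sg_correct(ur$ctx_ng_ml, ur$sg, sg_ref)
  urine_tab <- data.frame(
    individual_id = ur$id,
    site_id = individuals$site_id[key],
    sex = individuals$sex[key],
    collection_date = as.Date(ur$date),
    minutes_of_day = minutes,
    age_years = as.numeric(as.Date(ur$date) - individuals$birthdate[key]) / 365.25,
    ctx_sg = ctx_sg,
    log_ctx = log(ctx_sg),
    stringsAsFactors = FALSE)
  if (any(urine_tab$age_years < 0))
    stop("urine sample collected before the individual's birthdate", call. = FALSE)

  fkey <- match(forearm$id, individuals$id)
  if (anyNA(fkey)) stop("forearm measurement with unknown individual id", call. = FALSE)
  vel_list <- lapply(split(forearm, forearm$id), function(df) {
    df <- df[order(as.Date(df$date)), , drop = FALSE]
    b <- individuals$birthdate[match(df$id[1], individuals$id)]
    compute_velocities(df, b)
  })
  vel <- do.call(rbind, vel_list[vapply(vel_list, nrow, integer(1)) > 0])
  rownames(vel) <- NULL
  fgv_pos <- enforce_positive(vel$fgv, positivity_policy, epsilon)
  n_clamped <- attr(fgv_pos, "n_clamped")
  vkey <- match(vel$individual_id, individuals$id)
  vel$site_id <- individuals$site_id[vkey]
  vel$sex <- individuals$sex[vkey]
  vel$fgv_pos <- as.numeric(fgv_pos)
  vel$log_fgv <- log(vel$fgv_pos)

  # pooled 2-SD standardization of the age gradient across both datasets
  age_std <- standardize_2sd(c(urine_tab$age_years, vel$age_years), "age_years")
  urine_tab$age_std <- apply_standardization(urine_tab$age_years, age_std$params)
  vel$age_std <- apply_standardization(vel$age_years, age_std$params)
  sex_u <- standardize_sex(as.numeric(urine_tab$sex == "male"), "sex_urine")
  urine_tab$sex_std <- sex_u$values
  sex_v <- standardize_sex(as.numeric(vel$sex == "male"), "sex_velocity")
  vel$sex_std <- sex_v$values
  time_s <- standardize_2sd(urine_tab$minutes_of_day, "minutes_of_day")
  urine_tab$time_std <- time_s$values

  list(urine = urine_tab,
       velocity = vel,
       standardization = list(age = age_std$params, sex_urine = sex_u$params,
                              sex_velocity = sex_v$params, time = time_s$params,
                              sg_ref = sg_ref),
       log = list(sg_excluded = n_excluded,
                  sg_min = sg_min,
                  velocities_clamped = n_clamped,
                  clamp_epsilon = attr(fgv_pos, "epsilon_used"),
                  n_urine = nrow(urine_tab),
                  n_velocity = nrow(vel)))
}
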