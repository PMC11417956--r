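# End-to-end pipeline orchestration and file interfaces: cohort CSV bundles
# in, per-stage tables and correlation results out, with a machine-readable
# run report.

#' Run the full validation pipeline
#'
#' Simulates (or loads) a cohort, preprocesses both datasets, computes the
#' day-to-day descriptives, fits the velocity and CTX-I skew-normal spline
#' models, extracts the per-sex spline estimate tables, and computes the
#' sex-wise rank correlations between the two models plus the diurnal
#' effect. Stage outputs and a run report (exclusion and clamping counts,
#' convergence summary, seeds) are returned and optionally written to
#' `out_dir` as CSV/JSON.
#'
#' @param cohort list with `individuals`, `urine`, `forearm` (e.g. from
#'   [simulate_cohort()] or [read_cohort()]).
#' @param vel_spec,ctx_spec model specifications; defaults use the
#'   publication-scale sampler settings, so pass reduced specs for quick
#'   runs.
#' @param sg_min specific-gravity exclusion threshold.
#' @param out_dir optional output directory.
#' @return list of class `ctx_pipeline`: `prep`, `table1`, `fits`
#'   (velocity, ctx), `tables` (velocity, ctx `spline_tables`),
#'   `correlations`, `diurnal`, `report`.
#' @export
run_ctx_pipeline <- function(cohort,
                             vel_spec = sn_model_spec("log_fgv"),
                             ctx_spec = sn_model_spec("log_ctx"),
                             sg_min = 1.003,
                             out_dir = NULL) {
  prep <- prepare_model_data(cohort$urine, cohort$forearm,
                             cohort$individuals, sg_min = sg_min)
  multi <- names(which(table(prep$urine$individual_id) >= 2))
  table1 <- if (length(multi)) {
    day_to_day_table(prep$urine[prep$urine$individual_id %in% multi, ])
  } else NULL

  vel_design <- assemble_design(prep$velocity, vel_spec)
  ctx_design <- assemble_design(prep$urine, ctx_spec)
  vel_fit <- fit_sn_spline(vel_design)
  ctx_fit <- fit_sn_spline(ctx_design)
  vel_tables <- extract_sex_spline_table(vel_fit)
  ctx_tables <- extract_sex_spline_table(ctx_fit)
  correlations <- compare_sexwise(vel_tables, ctx_tables)
  diurnal <- diurnal_effect(ctx_fit)

  report <- list(
    n_urine = prep$log$n_urine,
    n_velocity = prep$log$n_velocity,
    sg_excluded = prep$log$sg_excluded,
    velocities_clamped = prep$log$velocities_clamped,
    clamp_epsilon = prep$log$clamp_epsilon,
    seeds = list(velocity = vel_fit$seed, ctx = ctx_fit$seed),
    rhat_max = list(velocity = max(vel_fit$rhat, na.rm = TRUE),
                    ctx = max(ctx_fit$rhat, na.rm = TRUE)),
    divergences = list(velocity = sum(vel_fit$divergences),
                       ctx = sum(ctx_fit$divergences)),
    mean_day_to_day_cv = if (!is.null(table1)) cohort_mean_cv(table1) else NA_real_)

  out <- structure(
    list(prep = prep, table1 = table1,
         fits = list(velocity = vel_fit, ctx = ctx_fit),
         tables = list(velocity = vel_tables, ctx = ctx_tables),
         correlations = correlations, diurnal = diurnal, report = report),
    class = "ctx_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' Write pipeline outputs to CSV/JSON files
#'
#' Emits `table1.csv` (day-to-day summaries), `table2.csv` (per-sex spline
#' estimates for both models), `table3.csv` (sex differences),
#' `correlations.json` and `report.json`.
#'
#' @param pipeline a `ctx_pipeline`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(pipeline, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(pipeline$table1))
    utils::write.csv(pipeline$table1, file.path(dir, "table1.csv"),
                     row.names = FALSE)
  utils::write.csv(spline_tables_wide(pipeline$tables),
                   file.path(dir, "table2.csv"), row.names = FALSE)
  diff_tab <- merge_model_tables(pipeline$tables$velocity$diff,
                                 pipeline$tables$ctx$diff)
  utils::write.csv(diff_tab, file.path(dir, "table3.csv"), row.names = FALSE)
  cors <- lapply(pipeline$correlations, unclass)
  jsonlite::write_json(cors, file.path(dir, "correlations.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(pipeline$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

merge_model_tables <- function(vel, ctx) {
  data.frame(spline = vel$spline, window = vel$window,
             fgv_beta = vel$beta, fgv_lci = vel$lci, fgv_uci = vel$uci,
             ctx_beta = ctx$beta, ctx_lci = ctx$lci, ctx_uci = ctx$uci)
}

spline_tables_wide <- function(tables) {
  rows <- lapply(c("female", "male"), function(s) {
    out <- merge_model_tables(tables$velocity[[s]], tables$ctx[[s]])
    cbind(sex = s, out)
  })
  do.call(rbind, rows)
}

#' Sex-wise rank correlations from a per-sex estimate table
#'
#' Reads a CSV (or takes a data frame) in the wide per-sex estimate schema —
#' columns `sex`, `spline`, `fgv_beta`, `ctx_beta` (the packaged fixture
#' `table2_printed.csv` carries the published values in this schema) — and
#' computes the per-sex Spearman correlation of the nine growth-velocity
#' spline estimates with the nine CTX-I spline estimates.
#'
#' @param table2 path to a CSV file or a data frame.
#' @return named list (`female`, `male`) of [spearman_cor()] results.
#' @export
compare_tables <- function(table2) {
  tab <- if (is.character(table2)) {
    utils::read.csv(table2, stringsAsFactors = FALSE)
  } else table2
  need <- c("sex", "spline", "fgv_beta", "ctx_beta")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("estimate table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- lapply(c(female = "female", male = "male"), function(s) {
    rows <- tab[tab$sex == s, ]
    rows <- rows[order(rows$spline), ]
    if (nrow(rows) != 9)
      stop("expected 9 spline rows for sex ", s, ", got ", nrow(rows),
           call. = FALSE)
    spearman_cor(rows$fgv_beta, rows$ctx_beta)
  })
  out
}

#' Path to a packaged fixture table
#'
#' @param name one of `"table1_printed.csv"`, `"table2_printed.csv"`,
#'   `"table3_printed.csv"`.
#' @return file path.
#' @export
ctx_fixture <- function(name = c("table2_printed.csv", "table1_printed.csv",
                                 "table3_printed.csv")) {
  name <- match.arg(name)
  system.file("extdata", name, package = "ctxgrowth", mustWork = TRUE)
}
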