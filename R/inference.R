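# Per-sex spline estimate tables, the additive male derivation, rank
# correlation of spline estimates between models, and the diurnal effect.

#' Extract per-sex age-spline estimate tables from a fit
#'
#' The reference sex is female: the `female` table holds the posterior
#' point estimate (mean by default) and central 95% interval of each of the
#' nine main age-spline coefficients, and the `diff` table the same for the
#' nine sex-deviation coefficients (male minus female). The `male` table is
#' derived by the additive rule (see [male_from_differences()]) and, as a
#' statistically principled alternative, from the quantiles of the summed
#' draws (`male_posterior` table).
#'
#' @param fit an `sn_fit`.
#' @param estimate `"mean"` (default, matching reported estimates) or
#'   `"median"`.
#' @return list of class `spline_tables` with data frames `female`, `diff`,
#'   `male` (additive arithmetic) and `male_posterior` (posterior of the
#'   sums), each with columns `spline`, `window`, `beta`, `lci`, `uci`.
#' @export
extract_sex_spline_table <- function(fit, estimate = c("mean", "median")) {
  estimate <- match.arg(estimate)
  kind <- fit$design$col_kind
  main_pars <- colnames(fit$design$X)[kind == "spline"]
  diff_pars <- colnames(fit$design$X)[kind == "sex_spline"]
  if (!length(main_pars) || !length(diff_pars))
    stop("fit lacks age-spline coefficients", call. = FALSE)
  win <- fit$design$windows
  point <- function(m) if (estimate == "mean") colMeans(m) else
    apply(m, 2, stats::median)
  tab <- function(m) {
    q <- apply(m, 2, stats::quantile, probs = c(0.025, 0.975))
    data.frame(spline = seq_len(ncol(m)), window = win$label,
               beta = unname(point(m)), lci = unname(q[1, ]),
               uci = unname(q[2, ]))
  }
  dm <- posterior_draws(fit, main_pars)
  dd <- posterior_draws(fit, diff_pars)
  female <- tab(dm)
  diff <- tab(dd)
  male <- male_from_differences(female, diff)
  male_posterior <- tab(dm + dd)
  structure(list(female = female, diff = diff, male = male,
                 male_posterior = male_posterior),
            class = "spline_tables")
}

#' Derive the male estimate table by the additive rule
#'
#' Reproduces the published arithmetic: per spline, the male estimate is the
#' main (female) estimate plus the sex-difference estimate, and the interval
#' bounds are likewise added bound-by-bound. Adding interval bounds is not a
#' valid interval for the sum — the posterior of the summed draws (also
#' emitted by [extract_sex_spline_table()]) is the principled version — but
#' the additive rule is what the reported male tables contain, so it is
#' implemented verbatim for replication.
#'
#' @param main estimate table of the reference sex (columns `spline`,
#'   `beta`, `lci`, `uci`).
#' @param diff sex-difference table with the same spline indexing.
#' @return data frame with the same columns, for males.
#' @export
male_from_differences <- function(main, diff) {
  if (!identical(main$spline, diff$spline))
    stop("spline indices of the two tables do not match", call. = FALSE)
  out <- main
  out$beta <- main$beta + diff$beta
  out$lci <- main$lci + diff$lci
  out$uci <- main$uci + diff$uci
  out
}

#' Spearman rank correlation with exact permutation p-value
#'
#' Ranks use midranks for ties; rho is the Pearson correlation of the rank
#' vectors. For n of at most 9 without ties the two-sided p-value is
#' computed by full enumeration of all n! permutations; otherwise the t
#' approximation with n - 2 degrees of freedom is used.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return list of class `spearman_cor`: `rho`, `n`, `df`, `p_value`,
#'   `method`, `ties`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length", call. = FALSE)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("correlation undefined for a constant vector", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 9 && !ties) {
    p <- .spearman_exact_perm(rx, ry)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- min(p, 1)
    method <- "t approximation"
  }
  structure(list(rho = rho, n = n, df = n - 2L, p_value = p,
                 method = method, ties = ties),
            class = "spearman_cor")
}

#' @export
print.spearman_cor <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: r(%d) = %.2f, p = %.3g (%s%s)\n",
              x$df, x$rho, x$p_value, x$method,
              if (x$ties) ", midranks for ties" else ""))
  invisible(x)
}

#' Correlate growth-velocity and CTX-I spline estimates by sex
#'
#' For each sex, the nine per-age-window spline estimates from the velocity
#' model are rank-correlated with those from the CTX-I model — the
#' validation's headline comparison.
#'
#' @param vel_tables,ctx_tables `spline_tables` (or plain lists with
#'   `female` and `male` estimate tables covering splines 1-9).
#' @return named list (`female`, `male`) of [spearman_cor()] results.
#' @export
compare_sexwise <- function(vel_tables, ctx_tables) {
  out <- lapply(c(female = "female", male = "male"), function(s) {
    v <- vel_tables[[s]]; c_ <- ctx_tables[[s]]
    if (is.null(v) || is.null(c_)) stop("missing sex: ", s, call. = FALSE)
    if (!identical(sort(v$spline), sort(c_$spline)) || nrow(v) != 9)
      stop("tables must cover splines 1-9 for both sexes", call. = FALSE)
    spearman_cor(v$beta[order(v$spline)], c_$beta[order(c_$spline)])
  })
  out
}

#' Population-level diurnal effect of collection time
#'
#' Posterior mean, standard error (posterior sd) and central 95% interval of
#' the standardized time-of-day coefficient in a CTX-I fit.
#'
#' @param fit an `sn_fit` of the CTX-I model (with a time covariate).
#' @return list: `estimate`, `se`, `lci`, `uci`.
#' @export
diurnal_effect <- function(fit) {
  if (!"time" %in% fit$design$col_kind)
    stop("fit has no collection-time covariate (velocity model?)", call. = FALSE)
  d <- posterior_draws(fit, "time_std")[, 1]
  q <- stats::quantile(d, c(0.025, 0.975))
  list(estimate = mean(d), se = stats::sd(d),
       lci = unname(q[1]), uci = unname(q[2]))
}
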