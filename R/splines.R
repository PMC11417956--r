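#' Constrained B-spline basis for the age smooth
#'
#' Builds a cubic B-spline basis with `n_knots` basis functions (interior
#' knots at equally spaced quantiles of `x`) and absorbs a sum-to-zero
#' identifiability constraint, leaving `n_knots - 1` coefficient columns.
#' With the default ten knots this yields the nine age-spline coefficients
#' reported per age window. Each retained coefficient is labeled with an
#' approximate age window obtained by cutting the observed `age` values at
#' their equal-count quantiles, so window `k` covers roughly the k-th ninth
#' of the data's age distribution.
#'
#' @param x numeric covariate the smooth is built on (typically standardized
#'   age); must contain at least `n_knots` distinct values.
#' @param n_knots basis dimension before the constraint (default 10).
#' @param degree polynomial degree of the B-splines (default cubic).
#' @param age optional vector, same length as `x`, of ages on the original
#'   scale (years) used only to label the coefficient windows. Defaults to
#'   `x` itself.
#' @return an object of class `age_spline_basis` with elements
#'   `matrix` (constrained design columns, one per coefficient),
#'   `raw` (unconstrained basis, partition of unity),
#'   `constraint` (the transformation matrix applied),
#'   `windows` (data frame: coefficient index, age window lower/upper, label),
#'   `n_coef`, `knots`, `boundary`, `degree`.
#' @export
age_spline_basis <- function(x, n_knots = 10, degree = 3, age = x) {
  if (length(unique(x)) < n_knots)
    stop("fewer distinct `x` values than knots; cannot build the spline basis",
         call. = FALSE)
  if (length(age) != length(x)) stop("`age` must match `x` in length", call. = FALSE)
  boundary <- range(x)
  n_interior <- n_knots - degree - 1
  probs <- seq_len(n_interior) / (n_interior + 1)
  knots <- unname(stats::quantile(x, probs))
  raw <- splines::bs(x, knots = knots, degree = degree, intercept = TRUE,
                     Boundary.knots = boundary)
  raw <- raw[, , drop = FALSE]
  stopifnot(ncol(raw) == n_knots)
  # sum-to-zero over the observed points, absorbed by a QR reparametrization
  cons <- matrix(colSums(raw), ncol = 1)
  qr_c <- qr(cons)
  Q <- qr.Q(qr_c, complete = TRUE)[, -1, drop = FALSE] # n_knots x (n_knots-1)
  constrained <- raw %*% Q
  colnames(constrained) <- paste0("spline", seq_len(ncol(constrained)))

  n_coef <- n_knots - 1
  brk <- unname(stats::quantile(age, probs = seq(0, 1, length.out = n_coef + 1)))
  windows <- data.frame(
    coef = seq_len(n_coef),
    lower = brk[-length(brk)],
    upper = brk[-1]
  )
  windows$label <- sprintf("%d: %.3g-%.3g", windows$coef, windows$lower,
                           windows$upper)
  structure(
    list(matrix = constrained, raw = unclass(raw), constraint = Q,
         windows = windows, n_coef = n_coef, knots = knots,
         boundary = boundary, degree = degree),
    class = "age_spline_basis")
}

#' Evaluate a fitted spline basis at new covariate values
#'
#' @param object an [age_spline_basis()].
#' @param newx numeric vector on the same scale the basis was built on.
#'   Values outside the boundary knots are clamped to the boundary.
#' @param ... unused.
#' @return matrix with `object$n_coef` columns.
#' @export
predict.age_spline_basis <- function(object, newx, ...) {
  newx <- pmin(pmax(newx, object$boundary[1]), object$boundary[2])
  raw <- splines::bs(newx, knots = object$knots, degree = object$degree,
                     intercept = TRUE, Boundary.knots = object$boundary)
  out <- unclass(raw) %*% object$constraint
  colnames(out) <- colnames(object$matrix)
  out
}

#' @export
print.age_spline_basis <- function(x, ...) {
  cat(sprintf("B-spline age basis: %d basis functions (degree %d), %d coefficients after sum-to-zero constraint\n",
              x$n_coef + 1, x$degree, x$n_coef))
  print(x$windows, row.names = FALSE)
  invisible(x)
}
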