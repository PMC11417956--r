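#' Skew-normal density in mean parametrization
#'
#' Density of the skew-normal distribution parametrized by its mean `mu`,
#' scale `sigma` and shape (skewness) `alpha`. Internally the mean
#' parametrization is converted to the direct parameters
#' \eqn{(\xi, \omega, \alpha)} via \eqn{\delta = \alpha/\sqrt{1+\alpha^2}},
#' \eqn{\omega = \sigma} and \eqn{\xi = \mu - \omega\delta\sqrt{2/\pi}}, so
#' that the distribution's expectation equals `mu` for every `alpha`. With
#' `alpha = 0` the density reduces to the normal with mean `mu` and standard
#' deviation `sigma`.
#'
#' @param x numeric vector of quantiles.
#' @param mu mean of the distribution.
#' @param sigma scale parameter, must be positive.
#' @param alpha shape parameter; positive values skew right, negative left.
#' @param log logical; return the log density?
#' @return numeric vector of (log) density values.
#' @examples
#' dskew_normal(0, mu = 0, sigma = 1, alpha = 0) # == dnorm(0)
#' @export
dskew_normal <- function(x, mu = 0, sigma = 1, alpha = 0, log = FALSE) {
  if (any(sigma <= 0)) stop("`sigma` must be positive", call. = FALSE)
  delta <- alpha / sqrt(1 + alpha^2)
  xi <- mu - sigma * delta * sqrt(2 / pi)
  z <- (x - xi) / sigma
  out <- base::log(2) - base::log(sigma) +
    stats::dnorm(z, log = TRUE) + stats::pnorm(alpha * z, log.p = TRUE)
  if (log) out else exp(out)
}

#' Draw from the mean-parametrized skew-normal
#'
#' Uses the classical representation \eqn{\delta|z_0| + \sqrt{1-\delta^2} z_1}
#' of a standard skew-normal variate, then shifts and scales so that the
#' sample has expectation `mu`.
#'
#' @inheritParams dskew_normal
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
rskew_normal <- function(n, mu = 0, sigma = 1, alpha = 0) {
  if (any(sigma <= 0)) stop("`sigma` must be positive", call. = FALSE)
  delta <- alpha / sqrt(1 + alpha^2)
  z0 <- stats::rnorm(n)
  z1 <- stats::rnorm(n)
  u <- delta * abs(z0) + sqrt(1 - delta^2) * z1
  xi <- mu - sigma * delta * sqrt(2 / pi)
  xi + sigma * u
}

# standard deviation of the mean-parametrized skew-normal
skew_normal_sd <- function(sigma, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  sigma * sqrt(1 - 2 * delta^2 / pi)
}

# scale needed so that the centered skew-normal has standard deviation `sd`
skew_normal_scale_for_sd <- function(sd, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  sd / sqrt(1 - 2 * delta^2 / pi)
}
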