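#' Laplace (double exponential) distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the Laplace distribution with location `mu` and scale `b`.
#'
#' @param x,q numeric vector of quantiles.
#' @param p numeric vector of probabilities.
#' @param n number of draws.
#' @param mu location parameter.
#' @param b scale parameter (`b > 0`).
#' @return `dlaplace` the density, `plaplace` the CDF, `qlaplace` the
#'   quantile function, `rlaplace` random draws.
#' @name laplace
NULL

#' @rdname laplace
#' @export
dlaplace <- function(x, mu = 0, b = 1) {
  stopifnot(b > 0)
  exp(-abs(x - mu) / b) / (2 * b)
}

#' @rdname laplace
#' @export
plaplace <- function(q, mu = 0, b = 1) {
  stopifnot(b > 0)
  ifelse(q < mu, 0.5 * exp((q - mu) / b), 1 - 0.5 * exp(-(q - mu) / b))
}

#' @rdname laplace
#' @export
qlaplace <- function(p, mu = 0, b = 1) {
  stopifnot(b > 0, all(p >= 0 & p <= 1))
  ifelse(p < 0.5, mu + b * log(2 * p), mu - b * log(2 * (1 - p)))
}

#' @rdname laplace
#' @export
rlaplace <- function(n, mu = 0, b = 1) {
  qlaplace(stats::runif(n), mu, b)
}

#' Maxwell-Boltzmann distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the Maxwell-Boltzmann distribution with scale `a`: the distribution of
#' the magnitude of a 3-component isotropic Gaussian vector, with density
#' `sqrt(2/pi) x^2 exp(-x^2 / (2 a^2)) / a^3` for `x >= 0`. Implemented via
#' the chi-square(3) law of `(x/a)^2`.
#'
#' @param x,q numeric vector of quantiles.
#' @param p numeric vector of probabilities.
#' @param n number of draws.
#' @param a scale parameter (`a > 0`).
#' @return `dmaxwell` the density, `pmaxwell` the CDF, `qmaxwell` the
#'   quantile function, `rmaxwell` random draws.
#' @name maxwell
NULL

#' @rdname maxwell
#' @export
dmaxwell <- function(x, a = 1) {
  stopifnot(a > 0)
  ifelse(x < 0, 0, sqrt(2 / pi) * x^2 * exp(-x^2 / (2 * a^2)) / a^3)
}

#' @rdname maxwell
#' @export
pmaxwell <- function(q, a = 1) {
  stopifnot(a > 0)
  ifelse(q < 0, 0, stats::pchisq((q / a)^2, df = 3))
}

#' @rdname maxwell
#' @export
qmaxwell <- function(p, a = 1) {
  stopifnot(a > 0, all(p >= 0 & p <= 1))
  a * sqrt(stats::qchisq(p, df = 3))
}

#' @rdname maxwell
#' @export
rmaxwell <- function(n, a = 1) {
  a * sqrt(stats::rchisq(n, df = 3))
}
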