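# Three-parameter generalized gamma in the (mu, sigma, nu) parameterization
# used for location-scale-shape normative modelling:
#   theta = 1 / (sigma^2 nu^2),  z = (y / mu)^nu,
#   log f(y) = log|nu| + theta log theta + theta nu (log y - log mu)
#              - theta z - log Gamma(theta) - log y.
# nu = 1 recovers the gamma distribution with mean mu; nu -> 0 the lognormal
# with meanlog log(mu) and sdlog sigma. Below |nu| < .gg_nu_eps the lognormal
# limit is evaluated directly: the exact expression suffers catastrophic
# cancellation there (theta ~ nu^-2).

.gg_nu_eps <- 1e-4

.gg_check <- function(x, mu, sigma, nu) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop("values must be finite and strictly positive", call. = FALSE)
  if (any(!is.finite(mu)) || any(mu <= 0) ||
      any(!is.finite(sigma)) || any(sigma <= 0) || any(!is.finite(nu)))
    stop("distribution parameters must be finite with mu > 0, sigma > 0",
         call. = FALSE)
}

#' Generalized gamma density
#'
#' @param x Vector of positive values.
#' @param mu Location (> 0), on the scale of the data.
#' @param sigma Scale (> 0) on the log link.
#' @param nu Shape/skewness (real); `nu = 1` is the gamma distribution,
#'   `nu = 0` the lognormal limit.
#' @param log Return log density?
#' @return Density (or log density) values, recycled to common length.
#' @export
dgg <- function(x, mu, sigma, nu, log = FALSE) {
  .gg_check(x, mu, sigma, nu)
  n <- max(length(x), length(mu), length(sigma), length(nu))
  x <- rep_len(x, n); mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n); nu <- rep_len(nu, n)
  u <- base::log(x) - base::log(mu)
  out <- numeric(n)
  ln <- abs(nu) < .gg_nu_eps
  if (any(ln)) {
    out[ln] <- -base::log(x[ln] * sigma[ln]) - 0.5 * base::log(2 * pi) -
      u[ln]^2 / (2 * sigma[ln]^2)
  }
  if (any(!ln)) {
    i <- !ln
    theta <- 1 / (sigma[i]^2 * nu[i]^2)
    z <- exp(nu[i] * u[i])
    out[i] <- base::log(abs(nu[i])) + theta * base::log(theta) +
      theta * nu[i] * u[i] - theta * z - lgamma(theta) - base::log(x[i])
  }
  if (log) out else exp(out)
}

#' Generalized gamma cumulative distribution function
#'
#' @inheritParams dgg
#' @param q Vector of positive quantiles.
#' @return Probabilities in (0, 1).
#' @export
pgg <- function(q, mu, sigma, nu) {
  .gg_check(q, mu, sigma, nu)
  n <- max(length(q), length(mu), length(sigma), length(nu))
  q <- rep_len(q, n); mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n); nu <- rep_len(nu, n)
  out <- numeric(n)
  ln <- abs(nu) < .gg_nu_eps
  if (any(ln))
    out[ln] <- stats::plnorm(q[ln], base::log(mu[ln]), sigma[ln])
  if (any(!ln)) {
    i <- !ln
    theta <- 1 / (sigma[i]^2 * nu[i]^2)
    z <- exp(nu[i] * (base::log(q[i]) - base::log(mu[i])))
    p <- stats::pgamma(theta * z, shape = theta)
    out[i] <- ifelse(nu[i] > 0, p, 1 - p)
  }
  out
}

#' Generalized gamma quantile function
#'
#' @inheritParams dgg
#' @param p Vector of probabilities in (0, 1).
#' @return Quantiles (> 0).
#' @export
qgg <- function(p, mu, sigma, nu) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("probabilities must lie strictly inside (0, 1)", call. = FALSE)
  n <- max(length(p), length(mu), length(sigma), length(nu))
  p <- rep_len(p, n); mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n); nu <- rep_len(nu, n)
  out <- numeric(n)
  ln <- abs(nu) < .gg_nu_eps
  if (any(ln))
    out[ln] <- stats::qlnorm(p[ln], base::log(mu[ln]), sigma[ln])
  if (any(!ln)) {
    i <- !ln
    theta <- 1 / (sigma[i]^2 * nu[i]^2)
    pp <- ifelse(nu[i] > 0, p[i], 1 - p[i])
    g <- stats::qgamma(pp, shape = theta)
    out[i] <- mu[i] * exp(base::log(g / theta) / nu[i])
  }
  out
}

#' Sample from the generalized gamma distribution
#'
#' @inheritParams dgg
#' @param n Number of draws.
#' @return Vector of positive draws.
#' @export
rgg <- function(n, mu, sigma, nu) {
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n); nu <- rep_len(nu, n)
  out <- numeric(n)
  ln <- abs(nu) < .gg_nu_eps
  if (any(ln))
    out[ln] <- stats::rlnorm(sum(ln), base::log(mu[ln]), sigma[ln])
  if (any(!ln)) {
    i <- !ln
    theta <- 1 / (sigma[i]^2 * nu[i]^2)
    g <- stats::rgamma(sum(i), shape = theta)
    out[i] <- mu[i] * exp(base::log(g / theta) / nu[i])
  }
  out
}
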