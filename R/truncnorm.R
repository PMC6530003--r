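#' Moments of a lower-truncated normal distribution
#'
#' Closed-form mean and standard deviation of a normal distribution with
#' latent parameters `mu` and `sigma`, truncated below at `lower`.
#'
#' @param mu,sigma latent (pre-truncation) mean and standard deviation.
#' @param lower truncation point; mass below it is removed and renormalized.
#' @return list with elements `mean` and `sd` of the truncated distribution.
#' @export
tnorm_moments <- function(mu, sigma, lower) {
  stopifnot(sigma > 0)
  a <- (lower - mu) / sigma
  z <- dnorm(a) / pnorm(a, lower.tail = FALSE)
  m <- mu + sigma * z
  v <- sigma^2 * (1 + a * z - z^2)
  list(mean = m, sd = sqrt(max(v, 0)))
}

#' Sample from a lower-truncated normal
#'
#' Inverse-CDF sampling; exact, no rejection loop. Uses the current RNG
#' stream, so results are reproducible under `set.seed()`.
#'
#' @inheritParams tnorm_moments
#' @param n number of draws.
#' @return numeric vector of length `n`, all values `>= lower`.
#' @export
rtnorm <- function(n, mu, sigma, lower) {
  stopifnot(sigma > 0)
  p0 <- pnorm(lower, mu, sigma)
  qnorm(p0 + runif(n) * (1 - p0), mu, sigma)
}

#' Latent parameters whose truncated moments match target moments
#'
#' Printed cohort summaries (mean +/- SD) describe the *observed*, i.e.
#' already-truncated, variable: SUV and nodal diameters cannot go below
#' their physical floors. Sampling a normal with the printed parameters and
#' truncating would therefore inflate the realized mean above the printed
#' one. This solver inverts the truncation: it finds latent `(mu, sigma)`
#' such that the lower-truncated distribution has exactly the target mean
#' and SD, so simulated cohorts recover the printed moments.
#'
#' @param mean,sd target moments of the truncated (observed) distribution.
#' @param lower truncation point; must satisfy `lower < mean`.
#' @param tol maximum tolerated residual on either matched moment.
#' @return list with `mu`, `sigma` (latent), `lower`, and `achieved`
#'   (the truncated moments at the solution, for auditing).
#' @export
match_tnorm <- function(mean, sd, lower, tol = 1e-6) {
  stopifnot(is.finite(mean), is.finite(sd), sd > 0, mean > lower)
  obj <- function(par) {
    mo <- tnorm_moments(par[1], exp(par[2]), lower)
    (mo$mean - mean)^2 + (mo$sd - sd)^2
  }
  fit <- optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 20000))
  mu <- fit$par[1]
  sigma <- exp(fit$par[2])
  ach <- tnorm_moments(mu, sigma, lower)
  if (abs(ach$mean - mean) > tol || abs(ach$sd - sd) > tol) {
    stop("truncated-normal moment matching did not converge for mean=",
         mean, ", sd=", sd, ", lower=", lower)
  }
  list(mu = mu, sigma = sigma, lower = lower, achieved = ach)
}

#' Sample a truncated normal with given observed moments
#'
#' Convenience wrapper: moment-matches with [match_tnorm()] and draws with
#' [rtnorm()].
#'
#' @inheritParams match_tnorm
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
rtnorm_matched <- function(n, mean, sd, lower) {
  p <- match_tnorm(mean, sd, lower)
  rtnorm(n, p$mu, p$sigma, lower)
}
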