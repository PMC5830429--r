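#' Scaled Student t distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the scaled Student t distribution with scale \code{sigma} and degrees
#' of freedom \code{nu}:
#' \deqn{p(e) = \frac{\Gamma((\nu+1)/2)}{\Gamma(\nu/2)\sqrt{\pi\nu}\,\sigma}
#'   \left(1 + \frac{1}{\nu}\left(\frac{e}{\sigma}\right)^2\right)^{-(\nu+1)/2}.}
#' This is the noise model for log-response residuals: symmetric, centred at
#' zero, heavy-tailed for small \code{nu}, approaching a Gaussian with
#' standard deviation \code{sigma} as \code{nu} grows.
#'
#' @param x,q vector of quantiles.
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param sigma scale (log units), > 0.
#' @param nu degrees of freedom, > 0.
#' @param log logical; return log density.
#' @return numeric vector.
#' @export
dscaled_t <- function(x, sigma, nu, log = FALSE) {
  stopifnot(all(sigma > 0), all(nu > 0))
  if (log) {
    stats::dt(x / sigma, df = nu, log = TRUE) - log(sigma)
  } else {
    stats::dt(x / sigma, df = nu) / sigma
  }
}

#' @rdname dscaled_t
#' @export
pscaled_t <- function(q, sigma, nu) {
  stopifnot(all(sigma > 0), all(nu > 0))
  stats::pt(q / sigma, df = nu)
}

#' @rdname dscaled_t
#' @export
qscaled_t <- function(p, sigma, nu) {
  stopifnot(all(sigma > 0), all(nu > 0))
  sigma * stats::qt(p, df = nu)
}

#' @rdname dscaled_t
#' @export
rscaled_t <- function(n, sigma, nu) {
  stopifnot(sigma > 0, nu > 0)
  sigma * stats::rt(n, df = nu)
}

#' Log-likelihood of residuals under the scaled t model
#'
#' @param x residuals (log units).
#' @param sigma scale.
#' @param nu degrees of freedom.
#' @return total log-likelihood.
#' @export
scaled_t_loglik <- function(x, sigma, nu) {
  sum(dscaled_t(x, sigma, nu, log = TRUE))
}

#' Maximum-likelihood fit of the scaled t noise model
#'
#' Fits (sigma, nu) to a pooled set of residuals by maximizing the scaled-t
#' log-likelihood. Optimization runs over (log sigma, log nu) with L-BFGS-B,
#' nu constrained to \code{nu_bounds}, from three starting values of nu
#' (2, 5, 30); the best converged optimum is kept. Deterministic.
#'
#' @param x residuals (log units), length >= \code{min_n}.
#' @param nu_bounds numeric length 2, bounds for the degrees of freedom.
#' @param min_n minimum number of residuals required.
#' @return list with \code{sigma}, \code{nu}, \code{loglik}, \code{n},
#'   \code{convergence} (0 = at least one start converged).
#' @export
fit_scaled_t <- function(x, nu_bounds = c(0.5, 200), min_n = 50) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < min_n) {
    stop("fit_scaled_t: need at least ", min_n, " residuals, got ", n)
  }
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0) {
    stop("fit_scaled_t: degenerate residuals (zero spread)")
  }
  negll <- function(par) {
    -scaled_t_loglik(x, exp(par[1]), exp(par[2]))
  }
  lower <- c(log(s) - 12, log(nu_bounds[1]))
  upper <- c(log(s) + 6, log(nu_bounds[2]))
  best <- NULL
  for (nu0 in c(2, 5, 30)) {
    # moment-match the start: var of t is nu/(nu-2) * sigma^2 for nu > 2
    s0 <- if (nu0 > 2) s * sqrt((nu0 - 2) / nu0) else s / 2
    fit <- tryCatch(
      stats::optim(c(log(s0), log(nu0)), negll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("fit_scaled_t: optimizer failed at all starts")
  }
  list(sigma = exp(best$par[1]),
       nu = exp(best$par[2]),
       loglik = -best$value,
       n = n,
       convergence = best$convergence)
}
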