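#' Convert between inter-animal CV and lognormal variance
#'
#' For a lognormally distributed individual parameter with log-scale variance
#' `omega2`, the coefficient of variation is
#' `CV% = 100 * sqrt(exp(omega2) - 1)`. The two functions are exact inverses.
#'
#' @param cv_percent coefficient of variation in percent, non-negative.
#' @param omega2 variance of the log-scale random effect, non-negative.
#' @return `cv_to_omega2` returns `omega2`; `omega2_to_cv` returns the CV in
#'   percent.
#' @export
cv_to_omega2 <- function(cv_percent) {
  if (any(cv_percent < 0)) stop("'cv_percent' must be non-negative")
  log1p((cv_percent / 100)^2)
}

#' @rdname cv_to_omega2
#' @export
omega2_to_cv <- function(omega2) {
  if (any(omega2 < 0)) stop("'omega2' must be non-negative")
  100 * sqrt(expm1(omega2))
}

#' Individual parameters from fixed effects and random effects
#'
#' Under the lognormal population model each animal's parameter vector is the
#' fixed-effect (typical) vector rescaled componentwise:
#' `theta_i = theta_mu * exp(eta_i)`.
#'
#' @param theta_mu named vector of fixed effects, positive.
#' @param eta random-effect vector (log scale), same length; any real values.
#' @return Individual parameter vector, names preserved from `theta_mu`.
#' @export
individual_parameters <- function(theta_mu, eta) {
  if (any(theta_mu <= 0)) stop("'theta_mu' must be positive")
  if (length(eta) != length(theta_mu))
    stop("'eta' must match 'theta_mu' in length")
  theta_mu * exp(eta)
}

#' Log-likelihood of one subject's data under the proportional error model
#'
#' Observations follow `y = f * (1 + eps)` with `eps ~ N(0, sigma^2)`, i.e.
#' each `y` is Gaussian with mean `f` and standard deviation `sigma * f`.
#'
#' @param y observed values, positive.
#' @param f model predictions at the observation times, positive.
#' @param sigma proportional residual error, positive.
#' @return Sum of the pointwise Gaussian log-densities.
#' @export
individual_loglik <- function(y, f, sigma) {
  if (length(y) != length(f)) stop("'y' and 'f' must have equal length")
  if (sigma <= 0) stop("'sigma' must be positive")
  if (any(f <= 0))
    stop("prediction is zero/negative at an observation time; ",
         "proportional error model degenerates")
  sum(stats::dnorm(y, mean = f, sd = sigma * f, log = TRUE))
}
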