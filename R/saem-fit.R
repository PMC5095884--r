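#' Fit the growth model to a cohort by SAEM nonlinear mixed effects
#'
#' Maximum-likelihood estimation of the population parameters of the
#' logistic proliferative model from longitudinal bioluminescence data.
#' Individual parameters \eqn{(a_i, K_i)} are lognormal around the fixed
#' effects with diagonal log-scale covariance; observations follow the
#' proportional error model \eqn{y = f (1 + \varepsilon)},
#' \eqn{\varepsilon \sim N(0, \sigma^2)}. The likelihood is maximized by the
#' SAEM algorithm: a Metropolis-Hastings E-step samples each animal's
#' log-parameters from their conditional distribution, sufficient statistics
#' are accumulated by stochastic approximation (step size 1 during
#' exploration, `1/(k - K1)` during smoothing), and the M-step updates
#' \eqn{\theta_\mu}, \eqn{\theta_\omega}, \eqn{\sigma} in closed form.
#' Standard errors come from a Louis-type Monte-Carlo estimate of the
#' observed Fisher information at the optimum.
#'
#' `P0` is fixed, not estimated: it is the injected cell burden expressed in
#' signal units, `injected_cells * photons_per_cell`.
#'
#' @param data a [growth_data()] object or compatible data frame; the
#'   bioluminescence records are fit.
#' @param init optional initial values: a list with `theta_mu` (named `a`,
#'   `K`), `omega2`, `sigma`, or a `"two_stage_fit"`. Default: run
#'   [two_stage_fit()] on the data, falling back to `a = 0.3` and the
#'   geometric-mean plateau for `K` if that fails.
#' @param P0 initial proliferative signal; overrides the injected-cell
#'   default.
#' @param conv a [conversion_constants()] object.
#' @param injected_cells cells injected at day 0 (default 1.5e5).
#' @param control a [saem_control()] object.
#' @param seed integer seed; the fit is bit-reproducible given `seed` and
#'   `control`.
#' @return An object of class `"saem_fit"`; see [summary.saem_fit()].
#'   Components include `theta_mu`, `omega2`, `cv_percent`, `sigma`,
#'   `rse_percent`, `individual` (per-animal empirical-Bayes estimates),
#'   `trace`, `converged`.
#' @seealso [fit_lambda()] for the second-stage caliper proportionality
#'   constant, [two_stage_fit()] for the naive baseline.
#' @export
saem_fit <- function(data, init = NULL, P0 = NULL,
                     conv = conversion_constants(),
                     injected_cells = 1.5e5,
                     control = saem_control(), seed = 1L) {
  data <- growth_data(data)
  if (is.null(P0)) P0 <- injected_cells * conv$photons_per_cell
  raw <- .split_subjects(data, "bioluminescence")
  if (length(raw) < 3L)
    stop("mixed-effects estimation needs at least 3 subjects")
  subjects <- lapply(raw, function(s)
    list(id = s$id, streams = list(list(times = s$times, values = s$values)),
         ctx = list(P0 = P0)))
  predfn <- function(theta, subject)
    list(.prolif(subject$streams[[1]]$times, theta[1], theta[2],
                 subject$ctx$P0))

  set.seed(as.integer(seed))
  if (is.null(init)) {
    init <- tryCatch(suppressWarnings(two_stage_fit(data, P0 = P0)),
                     error = function(e) NULL)
    if (is.null(init)) {
      plateau <- exp(mean(log(vapply(raw, function(s) max(s$values),
                                     numeric(1)))))
      init <- list(theta_mu = c(a = 0.3, K = max(plateau, P0 * 10) * 1.2),
                   omega2 = c(a = 0.1, K = 0.1), sigma = 0.2)
    }
  }
  if (inherits(init, "two_stage_fit"))
    init <- list(theta_mu = init$theta_mu, omega2 = init$omega2,
                 sigma = init$sigma)
  init$theta_mu <- init$theta_mu[c("a", "K")]
  if (any(!is.finite(init$theta_mu)) || any(init$theta_mu <= 0))
    stop("initial fixed effects must be positive")
  init$omega2 <- pmax(init$omega2[c("a", "K")], 0.02)
  init$sigma <- max(init$sigma, 0.05)

  eng <- .saem_engine(subjects, predfn, init, control)
  if (!eng$converged)
    warning("SAEM trace did not stabilize; treat estimates with caution")

  fit <- structure(list(
    theta_mu = eng$theta_mu, omega2 = eng$omega2,
    cv_percent = eng$cv_percent, sigma = eng$sigma,
    phi_mean = eng$phi_mean,
    individual = data.frame(subject = rownames(eng$phi_mean),
                            a = exp(eng$phi_mean[, "a"]),
                            K = exp(eng$phi_mean[, "K"]),
                            row.names = NULL),
    trace = eng$trace, converged = eng$converged,
    rw_sd = eng$rw_sd, P0 = P0, conv = conv, control = control,
    seed = as.integer(seed), data = data, lambda = NULL),
    class = "saem_fit")
  fit$rse_percent <- compute_rse(fit)
  fit
}

## rebuild the engine-facing subject list + prediction function of a fit
.fit_surface <- function(fit, data = NULL) {
  data <- if (is.null(data)) fit$data else growth_data(data)
  raw <- .split_subjects(data, "bioluminescence")
  subjects <- lapply(raw, function(s)
    list(id = s$id, streams = list(list(times = s$times, values = s$values)),
         ctx = list(P0 = fit$P0)))
  predfn <- function(theta, subject)
    list(.prolif(subject$streams[[1]]$times, theta[1], theta[2],
                 subject$ctx$P0))
  list(subjects = subjects, predfn = predfn)
}

#' Relative standard errors from the observed Fisher information
#'
#' Monte-Carlo Louis decomposition at the fitted population parameters: the
#' observed information is \eqn{-E[H | y] - E[g g' | y] + E[g|y] E[g|y]'}
#' summed over animals, with the conditional expectations estimated from
#' Metropolis-Hastings samples of the individual log-parameters at the
#' optimum. Standard errors are the square roots of the diagonal of the
#' inverse; RSEs are `100 * se / estimate` (for the lognormal fixed effects
#' the delta method gives `RSE = 100 * se(log theta)`).
#'
#' @param fit a fitted [saem_fit()] object.
#' @param data optional replacement dataset (same design columns); defaults
#'   to the data the model was fit to. Supplying e.g. a duplicated cohort
#'   shows the information-additivity shrinkage of the RSEs.
#' @param samples Monte-Carlo sample count (default from the fit's control).
#' @param seed RNG seed for the MH chain.
#' @return Named vector of RSEs in percent: fixed effects (`a`, `K`),
#'   random-effect variances (`omega2_a`, `omega2_K`) and `sigma`. `NaN`
#'   with a warning if the information matrix is singular.
#' @export
compute_rse <- function(fit, data = NULL, samples = NULL, seed = 1L) {
  stopifnot(inherits(fit, "saem_fit"))
  surf <- .fit_surface(fit, data)
  if (is.null(samples)) samples <- fit$control$fim_samples
  mu <- log(fit$theta_mu)
  p <- length(mu)
  phi_start <- if (is.null(data)) fit$phi_mean else
    matrix(mu, length(surf$subjects), p, byrow = TRUE)
  set.seed(as.integer(seed))
  I_obs <- .louis_fim(surf$subjects, surf$predfn, mu, fit$omega2,
                      fit$sigma, fit$rw_sd, phi_start, samples = samples,
                      transitions = fit$control$transitions)
  nm <- c(names(fit$theta_mu), paste0("omega2_", names(fit$theta_mu)),
          "sigma")
  se <- tryCatch(sqrt(diag(solve(I_obs))), error = function(e) NULL)
  if (is.null(se) || any(!is.finite(se))) {
    warning("observed Fisher information is singular; RSEs set to NaN")
    return(stats::setNames(rep(NaN, 2 * p + 1), nm))
  }
  est <- c(mu, fit$omega2, fit$sigma^2)
  rse <- numeric(2 * p + 1)
  rse[seq_len(p)] <- 100 * se[seq_len(p)]             # delta method, exp scale
  rse[p + seq_len(p)] <- 100 * se[p + seq_len(p)] / fit$omega2
  rse[2 * p + 1] <- 100 * se[2 * p + 1] / (2 * fit$sigma^2)
  stats::setNames(rse, nm)
}

#' Second-stage estimation of the caliper proportionality constant
#'
#' With the individual bioluminescence kinetics \eqn{(a_i, K_i)} fixed from
#' the stage-1 fit, each animal's predicted cell-mass volume
#' \eqn{v_i(t) = (P_i + N_i)(t)} (converted to cm^3) is compared to its
#' caliper measurements through
#' \eqn{V_{ij} = \lambda_i \, v_i(t_{ij}) (1 + \varepsilon_{ij})}, with
#' \eqn{\lambda_i} lognormal around the population \eqn{\lambda} and a
#' proportional caliper error. `method = "joint"` instead refits all three
#' parameters \eqn{(a, K, \lambda)} simultaneously on both observation
#' streams (separate residual errors), initialized from the sequential fit.
#'
#' @param fit a stage-1 [saem_fit()] object.
#' @param data a [growth_data()] object containing caliper records (defaults
#'   to the data stored in `fit`).
#' @param method `"sequential"` (default, the two-stage estimation order) or
#'   `"joint"`.
#' @param control a [saem_control()] for the stage-2 run; defaults to the
#'   stage-1 control.
#' @param seed RNG seed for the stage-2 chain.
#' @return The input fit with a `lambda` component added: fixed effect,
#'   `cv_percent`, `rse_percent`, `sigma_caliper`, per-animal
#'   `individual$lam`, stage-2 `trace` and convergence flag, and the implied
#'   `stroma_percent`.
#' @export
fit_lambda <- function(fit, data = NULL, method = c("sequential", "joint"),
                       control = NULL, seed = 1L) {
  stopifnot(inherits(fit, "saem_fit"))
  method <- match.arg(method)
  data <- if (is.null(data)) fit$data else growth_data(data)
  cal <- .split_subjects(data, "caliper")
  if (length(cal) == 0L)
    stop("no caliper records in the data; cannot estimate lambda")
  if (is.null(control)) control <- fit$control
  if (method == "joint") return(.fit_joint(fit, data, control, seed))

  ids <- fit$individual$subject
  subjects <- list()
  for (s in cal) {
    j <- match(as.character(s$id), ids)
    if (is.na(j)) next   # caliper-only subject: no stage-1 kinetics
    v <- signal_to_volume_cm3(
      .total(s$times, fit$individual$a[j], fit$individual$K[j], fit$P0),
      fit$conv)
    subjects[[length(subjects) + 1L]] <-
      list(id = s$id, streams = list(list(times = s$times, values = s$values)),
           ctx = list(v = v))
  }
  if (length(subjects) < 3L)
    stop("fewer than 3 subjects have both caliper data and stage-1 estimates")
  predfn <- function(theta, subject) list(theta[1] * subject$ctx$v)

  ratios <- unlist(lapply(subjects, function(su)
    su$streams[[1]]$values / (su$ctx$v)))
  init <- list(theta_mu = c(lam = exp(mean(log(ratios)))),
               omega2 = c(lam = 0.02), sigma = fit$sigma)

  set.seed(as.integer(seed))
  eng <- .saem_engine(subjects, predfn, init, control)
  if (!eng$converged)
    warning("stage-2 SAEM trace did not stabilize")

  mu <- log(eng$theta_mu)
  set.seed(as.integer(seed) + 1L)
  I_obs <- .louis_fim(subjects, predfn, mu, eng$omega2, eng$sigma,
                      eng$rw_sd, eng$phi_mean,
                      samples = control$fim_samples,
                      transitions = control$transitions)
  se <- tryCatch(sqrt(diag(solve(I_obs))), error = function(e) NULL)
  rse_lam <- if (is.null(se) || !is.finite(se[1])) NaN else 100 * se[1]

  lam_hat <- unname(eng$theta_mu["lam"])
  fit$lambda <- list(
    lam = lam_hat,
    omega2 = unname(eng$omega2["lam"]),
    cv_percent = unname(eng$cv_percent["lam"]),
    rse_percent = rse_lam,
    sigma_caliper = eng$sigma,
    individual = data.frame(
      subject = rownames(eng$phi_mean),
      lam = exp(eng$phi_mean[, "lam"]), row.names = NULL),
    trace = eng$trace, converged = eng$converged,
    method = "sequential",
    stroma_percent = if (lam_hat >= 1) stroma_fraction(lam_hat) else NA_real_)
  fit
}

## joint three-parameter fit on both observation streams
.fit_joint <- function(fit, data, control, seed) {
  raw_b <- .split_subjects(data, "bioluminescence")
  raw_c <- .split_subjects(data, "caliper")
  cal_ids <- vapply(raw_c, function(s) as.character(s$id), character(1))
  subjects <- list()
  for (s in raw_b) {
    j <- match(as.character(s$id), cal_ids)
    if (is.na(j)) next
    subjects[[length(subjects) + 1L]] <- list(
      id = s$id,
      streams = list(list(times = s$times, values = s$values),
                     list(times = raw_c[[j]]$times, values = raw_c[[j]]$values)),
      ctx = list(P0 = fit$P0))
  }
  if (length(subjects) < 3L)
    stop("joint fit needs at least 3 subjects with both observables")
  conv <- fit$conv
  predfn <- function(theta, subject) {
    P <- .prolif(subject$streams[[1]]$times, theta[1], theta[2],
                 subject$ctx$P0)
    V <- .total(subject$streams[[2]]$times, theta[1], theta[2],
                subject$ctx$P0)
    list(P, theta[3] * V / conv$photons_per_cell / conv$cells_per_cm3)
  }
  seq_fit <- if (is.null(fit$lambda))
    fit_lambda(fit, data, method = "sequential", control = control,
               seed = seed) else fit
  init <- list(
    theta_mu = c(a = unname(fit$theta_mu["a"]),
                 K = unname(fit$theta_mu["K"]),
                 lam = seq_fit$lambda$lam),
    omega2 = c(a = unname(fit$omega2["a"]), K = unname(fit$omega2["K"]),
               lam = max(seq_fit$lambda$omega2, 0.02)),
    sigma = c(fit$sigma, seq_fit$lambda$sigma_caliper))
  set.seed(as.integer(seed))
  eng <- .saem_engine(subjects, predfn, init, control)
  if (!eng$converged) warning("joint SAEM trace did not stabilize")
  lam_hat <- unname(eng$theta_mu["lam"])
  fit$theta_mu <- eng$theta_mu[c("a", "K")]
  fit$omega2 <- eng$omega2[c("a", "K")]
  fit$cv_percent <- eng$cv_percent[c("a", "K")]
  fit$sigma <- eng$sigma[1]
  fit$phi_mean <- eng$phi_mean[, c("a", "K"), drop = FALSE]
  fit$individual <- data.frame(subject = rownames(eng$phi_mean),
                               a = exp(eng$phi_mean[, "a"]),
                               K = exp(eng$phi_mean[, "K"]),
                               row.names = NULL)
  fit$lambda <- list(
    lam = lam_hat, omega2 = unname(eng$omega2["lam"]),
    cv_percent = unname(eng$cv_percent["lam"]),
    rse_percent = NA_real_,
    sigma_caliper = eng$sigma[2],
    individual = data.frame(subject = rownames(eng$phi_mean),
                            lam = exp(eng$phi_mean[, "lam"]),
                            row.names = NULL),
    trace = eng$trace, converged = eng$converged, method = "joint",
    stroma_percent = if (lam_hat >= 1) stroma_fraction(lam_hat) else NA_real_)
  fit
}
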