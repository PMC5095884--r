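#' @export
print.saem_fit <- function(x, ...) {
  cat("SAEM nonlinear mixed-effects fit: logistic proliferative/necrotic",
      "growth model\n")
  cat(sprintf("  %d animals, %d bioluminescence observations, P0 = %.4g photons/sec\n",
              nrow(x$individual),
              sum(x$data$observable == "bioluminescence"), x$P0))
  cat(sprintf("  a = %.4g day^-1 (CV %.1f%%), K = %.4g photons/sec (CV %.1f%%), sigma = %.3f\n",
              x$theta_mu["a"], x$cv_percent["a"],
              x$theta_mu["K"], x$cv_percent["K"], x$sigma))
  if (!is.null(x$lambda))
    cat(sprintf("  lambda = %.4g (CV %.1f%%) -> stroma %.0f%% of total volume\n",
                x$lambda$lam, x$lambda$cv_percent,
                x$lambda$stroma_percent))
  if (!x$converged) cat("  WARNING: trace did not stabilize\n")
  invisible(x)
}

#' @export
coef.saem_fit <- function(object, ...) {
  out <- object$theta_mu
  if (!is.null(object$lambda)) out <- c(out, lam = object$lambda$lam)
  out
}

#' Parameter table of a SAEM fit
#'
#' Tabulates, per parameter, the population estimate, the inter-animal CV
#' (percent, from the lognormal variance) and the relative standard error
#' (percent, from the observed Fisher information) — the standard reporting
#' layout for mixed-effects growth analyses.
#'
#' @param object a [saem_fit()] object.
#' @param ... unused.
#' @return An object of class `"summary.saem_fit"` whose `table` element is
#'   a data frame with columns `parameter`, `unit`, `estimate`, `cv_percent`,
#'   `rse_percent`.
#' @export
summary.saem_fit <- function(object, ...) {
  tab <- data.frame(
    parameter = c("a", "K"),
    unit = c("day^-1", "photons/second"),
    estimate = unname(object$theta_mu[c("a", "K")]),
    cv_percent = unname(object$cv_percent[c("a", "K")]),
    rse_percent = unname(object$rse_percent[c("a", "K")]),
    stringsAsFactors = FALSE)
  if (!is.null(object$lambda))
    tab <- rbind(tab, data.frame(
      parameter = "lambda", unit = "-",
      estimate = object$lambda$lam,
      cv_percent = object$lambda$cv_percent,
      rse_percent = object$lambda$rse_percent))
  structure(list(table = tab, sigma = object$sigma,
                 stroma_percent = if (!is.null(object$lambda))
                   object$lambda$stroma_percent else NA_real_,
                 converged = object$converged,
                 n_subjects = nrow(object$individual)),
            class = "summary.saem_fit")
}

#' @export
print.summary.saem_fit <- function(x, ...) {
  cat("Population parameter estimates (", x$n_subjects, " animals)\n",
      sep = "")
  tab <- x$table
  tab$estimate <- signif(tab$estimate, 3)
  tab$cv_percent <- round(tab$cv_percent, 1)
  tab$rse_percent <- round(tab$rse_percent, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("Proportional residual error sigma = %.3f\n", x$sigma))
  if (is.finite(x$stroma_percent))
    cat(sprintf("Implied stromal fraction: %.0f%% of the total volume\n",
                x$stroma_percent))
  if (!x$converged) cat("WARNING: trace did not stabilize\n")
  invisible(x)
}

#' Predicted kinetics from a fitted model
#'
#' @param object a [saem_fit()] object.
#' @param times day grid (default: dense grid over the observed range).
#' @param level `"population"` for the typical-animal curve, `"individual"`
#'   for per-animal empirical-Bayes curves.
#' @param observable `"bioluminescence"` (proliferative signal, photons/sec)
#'   or `"caliper"` (lambda-scaled total volume, cm^3; needs a stage-2 fit
#'   for individual lambdas, otherwise the population lambda is used).
#' @param ... unused.
#' @return A data frame with columns `subject` (`"typical"` for the
#'   population level), `time`, `pred`.
#' @export
predict.saem_fit <- function(object, times = NULL,
                             level = c("population", "individual"),
                             observable = c("bioluminescence", "caliper"),
                             ...) {
  level <- match.arg(level)
  observable <- match.arg(observable)
  if (is.null(times))
    times <- seq(0, max(object$data$time), length.out = 100)
  lam_pop <- if (!is.null(object$lambda)) object$lambda$lam else 1
  one <- function(a, K, lam) {
    if (observable == "bioluminescence") .prolif(times, a, K, object$P0)
    else lam * signal_to_volume_cm3(.total(times, a, K, object$P0),
                                    object$conv)
  }
  if (level == "population") {
    data.frame(subject = "typical", time = times,
               pred = as.numeric(one(object$theta_mu[["a"]],
                                     object$theta_mu[["K"]], lam_pop)))
  } else {
    ind <- object$individual
    lam_i <- rep(lam_pop, nrow(ind))
    if (!is.null(object$lambda)) {
      j <- match(ind$subject, object$lambda$individual$subject)
      lam_i[!is.na(j)] <- object$lambda$individual$lam[j[!is.na(j)]]
    }
    do.call(rbind, lapply(seq_len(nrow(ind)), function(i)
      data.frame(subject = ind$subject[i], time = times,
                 pred = one(ind$a[i], ind$K[i], lam_i[i]))))
  }
}

#' Residuals of a SAEM fit
#'
#' @param object a [saem_fit()] object.
#' @param type `"proportional"` (default; `(y - f)/f`, the scale on which the
#'   error model is homoscedastic) or `"response"` (`y - f`).
#' @param ... unused.
#' @return Data frame with `subject`, `time`, `observed`, `fitted`,
#'   `residual` for the bioluminescence records, using each animal's
#'   empirical-Bayes parameters.
#' @export
residuals.saem_fit <- function(object,
                               type = c("proportional", "response"), ...) {
  type <- match.arg(type)
  d <- object$data[object$data$observable == "bioluminescence", ]
  j <- match(as.character(d$subject), object$individual$subject)
  f <- vapply(seq_len(nrow(d)), function(r)
    .prolif(d$time[r], object$individual$a[j[r]],
            object$individual$K[j[r]], object$P0), numeric(1))
  res <- if (type == "proportional") (d$value - f) / f else d$value - f
  data.frame(subject = d$subject, time = d$time, observed = d$value,
             fitted = f, residual = res, row.names = NULL)
}

#' @export
fitted.saem_fit <- function(object, ...) {
  residuals(object)$fitted
}

#' Simulate new cohorts from a fitted model
#'
#' Draws complete synthetic datasets from the fitted population distribution
#' (lognormal individual parameters, proportional observation noise) on the
#' observation design of the original data — the parametric-bootstrap
#' counterpart of the fit.
#'
#' @param object a [saem_fit()] object (stage-2 lambda used if present,
#'   otherwise no caliper records are simulated).
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of `nsim` [growth_data()] objects (each with a `"truth"`
#'   attribute; see [simulate_cohort()]).
#' @export
simulate.saem_fit <- function(object, nsim = 1, seed = 1L, ...) {
  days <- sort(unique(object$data$time[
    object$data$observable == "bioluminescence"]))
  has_cal <- !is.null(object$lambda)
  des <- cohort_design(
    n_subjects = nrow(object$individual),
    days = days,
    injected_cells = object$P0 / object$conv$photons_per_cell,
    a = unname(object$theta_mu["a"]), K = unname(object$theta_mu["K"]),
    lam = if (has_cal) object$lambda$lam else 1,
    cv_a = unname(object$cv_percent["a"]),
    cv_K = unname(object$cv_percent["K"]),
    cv_lam = if (has_cal) object$lambda$cv_percent else 0,
    sigma_biolum = object$sigma,
    sigma_caliper = if (has_cal) object$lambda$sigma_caliper else 0.15,
    photons_per_cell = object$conv$photons_per_cell,
    cells_per_cm3 = object$conv$cells_per_cm3,
    caliper = has_cal)
  lapply(seq_len(nsim), function(i)
    simulate_cohort(des, seed = as.integer(seed) + i - 1L))
}

#' Diagnostic plots for a SAEM fit
#'
#' Left panel: observed bioluminescence (log scale) with individual
#' empirical-Bayes fits and the typical curve. Right panel: SAEM parameter
#' trace (normalized to the final value) across iterations, with the
#' exploration/smoothing switch marked.
#'
#' @param x a [saem_fit()] object.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.saem_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  d <- x$data[x$data$observable == "bioluminescence", ]
  grid <- seq(0, max(d$time), length.out = 120)
  graphics::plot(d$time, d$value, log = "y", pch = 16, cex = 0.5,
                 col = "grey40", xlab = "days post-graft",
                 ylab = "bioluminescence (photons/sec)",
                 main = "individual fits")
  for (i in seq_len(nrow(x$individual)))
    graphics::lines(grid, .prolif(grid, x$individual$a[i],
                                  x$individual$K[i], x$P0),
                    col = grDevices::adjustcolor("steelblue", 0.4))
  graphics::lines(grid, .prolif(grid, x$theta_mu["a"], x$theta_mu["K"],
                                x$P0), lwd = 2)
  tr <- x$trace
  norm <- sweep(tr, 2, tr[nrow(tr), ], "/")
  graphics::matplot(norm, type = "l", lty = 1, xlab = "SAEM iteration",
                    ylab = "parameter / final value",
                    main = "convergence trace")
  graphics::abline(v = x$control$K1, lty = 2)
  invisible(x)
}

#' Marginal log-likelihood by importance sampling
#'
#' Estimates the observed-data log-likelihood
#' \eqn{\sum_i \log \int p(y_i | \phi_i) p(\phi_i) d\phi_i} by per-animal
#' importance sampling with a Gaussian proposal centered at the individual
#' posterior mode (Laplace-type, covariance from the numerical Hessian,
#' inflated 1.5x).
#'
#' @param object a [saem_fit()] object.
#' @param theta_mu,omega2,sigma optional population parameters at which to
#'   evaluate (defaults: the fitted values). Allows comparing the SAEM
#'   optimum with e.g. [two_stage_fit()] estimates on the same data.
#' @param M importance samples per animal.
#' @param seed RNG seed.
#' @param ... unused.
#' @return An object of class `"logLik"` (degrees of freedom: 2p + 1).
#' @export
logLik.saem_fit <- function(object, theta_mu = NULL, omega2 = NULL,
                            sigma = NULL, M = 1000, seed = 1L, ...) {
  if (is.null(theta_mu)) theta_mu <- object$theta_mu
  if (is.null(omega2)) omega2 <- object$omega2
  if (is.null(sigma)) sigma <- object$sigma
  surf <- .fit_surface(object)
  ll <- .marginal_loglik(surf$subjects, surf$predfn, log(theta_mu),
                         pmax(omega2, 1e-8), sigma, M = M, seed = seed)
  structure(ll, df = 2 * length(theta_mu) + 1, class = "logLik")
}

.marginal_loglik <- function(subjects, predfn, mu, omega2, sigma,
                             M = 1000, seed = 1L) {
  set.seed(as.integer(seed))
  p <- length(mu)
  total <- 0
  for (su in subjects) {
    logpost <- function(phi)
      .subj_data_ll(su, predfn, phi, sigma) +
      sum(stats::dnorm(phi, mu, sqrt(omega2), log = TRUE))
    negpost <- function(z) {        # finite surrogate keeps BFGS stable
      lp <- logpost(z)
      if (is.finite(lp)) -lp else 1e10
    }
    opt <- stats::optim(mu, negpost, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-10))
    H <- tryCatch(stats::optimHess(opt$par, negpost),
                  error = function(e) NULL)
    Sig <- if (!is.null(H)) tryCatch(1.5 * solve(H), error = function(e) NULL)
           else NULL
    if (is.null(Sig) || any(!is.finite(Sig)) ||
        any(diag(as.matrix(Sig)) <= 0))
      Sig <- diag(pmax(omega2, 1e-4), p)
    R <- chol(as.matrix(Sig))
    Z <- matrix(stats::rnorm(M * p), M, p)
    phis <- sweep(Z %*% R, 2, opt$par, "+")
    lw <- vapply(seq_len(M), function(m) {
      phi <- phis[m, ]
      lq <- -0.5 * p * log(2 * pi) - sum(log(diag(R))) -
        0.5 * sum((backsolve(R, phi - opt$par, transpose = TRUE))^2)
      logpost(phi) - lq
    }, numeric(1))
    lw <- lw[is.finite(lw)]
    mx <- max(lw)
    total <- total + mx + log(mean(exp(lw - mx)))
  }
  total
}
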