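## Naive two-stage baseline: per-subject nonlinear least squares on the log
## signal, pooled into population estimates. Serves as SAEM initialization
## and as an independent sanity oracle.

## logistic solution without the growth_params validation overhead; returns
## NA when K <= P0 so optimizers/MH simply reject such proposals
.prolif <- function(t, a, K, P0) {
  if (!is.finite(a) || !is.finite(K) || a <= 0 || K <= P0)
    return(rep(NA_real_, length(t)))
  la <- log1p(-P0 / K)
  lb <- log(P0 / K) + a * t
  m <- pmax(la, lb)
  exp(log(P0) + a * t - (m + log(exp(la - m) + exp(lb - m))))
}

.total <- function(t, a, K, P0) {
  if (!is.finite(a) || !is.finite(K) || a <= 0 || K <= P0)
    return(rep(NA_real_, length(t)))
  la <- log1p(-P0 / K)
  lb <- log(P0 / K) + a * t
  m <- pmax(la, lb)
  K * (m + log(exp(la - m) + exp(lb - m))) + P0
}

.fit_one_subject <- function(times, values, P0) {
  obj <- function(par) {
    f <- .prolif(times, exp(par[1]), exp(par[2]), P0)
    if (any(!is.finite(f)) || any(f <= 0)) return(1e10)
    sum((log(values) - log(f))^2)
  }
  K0 <- max(max(values) * 1.2, P0 * 10)
  low <- values < K0 / 3
  a0 <- if (sum(low) >= 2) {
    sl <- stats::coef(stats::lm(log(values[low]) ~ times[low]))[2]
    if (is.finite(sl) && sl > 1e-3) unname(sl) else 0.3
  } else 0.3
  res <- tryCatch(
    stats::optim(c(log(a0), log(K0)), obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$value) || res$value >= 1e9)
    return(NULL)
  a <- exp(res$par[1]); K <- exp(res$par[2])
  if (a < 1e-3 || a > 20) return(NULL)   # flat or pathological signal
  f <- .prolif(times, a, K, P0)
  list(a = a, K = K, resid = (values - f) / f)
}

#' Naive two-stage population estimates
#'
#' Stage A fits each subject separately by nonlinear least squares on the log
#' bioluminescence signal; stage B pools the per-subject estimates into
#' population values: geometric mean for the fixed effects, log-scale
#' variance for the random-effect variances, pooled proportional residual SD
#' for `sigma`. Subjects whose individual fit fails (e.g. flat signal) are
#' excluded with a warning. Used to initialize [saem_fit()] and as a sanity
#' baseline; unlike SAEM it ignores shrinkage and is inefficient at small n.
#'
#' @param data a [growth_data()] object (bioluminescence records are used).
#' @param P0 initial proliferative signal, photons/sec; default the injected
#'   cell burden `injected_cells * photons_per_cell`.
#' @param conv a [conversion_constants()] object (used only for the default
#'   `P0`).
#' @param injected_cells number of cells injected at day 0.
#' @return A list of class `"two_stage_fit"`: `theta_mu` (named `a`, `K`),
#'   `omega2`, `cv_percent`, `sigma`, `individual` (per-subject estimates),
#'   `excluded` (ids of dropped subjects), `P0`.
#' @export
two_stage_fit <- function(data, P0 = NULL, conv = conversion_constants(),
                          injected_cells = 1.5e5) {
  data <- growth_data(data)
  if (is.null(P0)) P0 <- injected_cells * conv$photons_per_cell
  subjects <- .split_subjects(data, "bioluminescence")
  if (any(vapply(subjects, function(s) length(s$times), numeric(1)) < 3))
    stop("two-stage fitting needs at least 3 observations per subject")
  fits <- lapply(subjects, function(s) .fit_one_subject(s$times, s$values, P0))
  ok <- !vapply(fits, is.null, logical(1))
  excluded <- vapply(subjects[!ok], function(s) as.character(s$id),
                     character(1))
  if (length(excluded))
    warning("individual fit failed for subject(s) ",
            paste(excluded, collapse = ", "), "; excluded from pooling")
  fits <- fits[ok]
  if (length(fits) < 2L)
    stop("fewer than 2 subjects with a successful individual fit")
  la <- log(vapply(fits, `[[`, numeric(1), "a"))
  lK <- log(vapply(fits, `[[`, numeric(1), "K"))
  resid <- unlist(lapply(fits, `[[`, "resid"))
  theta_mu <- c(a = exp(mean(la)), K = exp(mean(lK)))
  omega2 <- c(a = stats::var(la), K = stats::var(lK))
  out <- list(theta_mu = theta_mu, omega2 = omega2,
              cv_percent = omega2_to_cv(omega2),
              sigma = sqrt(mean(resid^2)),
              individual = data.frame(
                subject = vapply(subjects[ok], function(s)
                  as.character(s$id), character(1)),
                a = exp(la), K = exp(lK), row.names = NULL),
              excluded = excluded, P0 = P0)
  class(out) <- "two_stage_fit"
  out
}

#' @export
print.two_stage_fit <- function(x, ...) {
  cat("Two-stage (per-subject NLS + pooling) population estimates\n")
  cat(sprintf("  a = %.4g day^-1 (CV %.1f%%), K = %.4g photons/sec (CV %.1f%%)\n",
              x$theta_mu["a"], x$cv_percent["a"],
              x$theta_mu["K"], x$cv_percent["K"]))
  cat(sprintf("  sigma = %.3f, %d subjects pooled", x$sigma,
              nrow(x$individual)))
  if (length(x$excluded))
    cat(sprintf(" (%d excluded)", length(x$excluded)))
  cat("\n")
  invisible(x)
}
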