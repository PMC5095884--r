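## Internal SAEM machinery.
##
## The engine is written against an abstract model surface so the same code
## fits stage 1 (bioluminescence: theta = (a, K)) and stage 2 (caliper:
## theta = lambda), and a joint fit with both observation streams:
##   - each subject is list(id, streams, ctx); streams is a list of
##     list(times, values); ctx carries subject-specific constants.
##   - predfn(theta, subject) returns one prediction vector per stream.
## Individual parameters are lognormal: phi_i = log(theta_i) ~ N(mu, diag(omega2));
## each stream has its own proportional residual error sigma[s].

#' SAEM estimation settings
#'
#' @param K1 exploration iterations (step size 1).
#' @param K2 smoothing iterations (step size `1/(k - K1)`).
#' @param transitions random-walk Metropolis-Hastings sweeps per subject per
#'   iteration (an independence proposal from the population distribution is
#'   attempted additionally each iteration).
#' @param target_accept target acceptance rate for the adaptive random-walk
#'   proposal (adapted during the exploration phase only).
#' @param omega2_min,sigma_min numerical floors for the variance components.
#' @param fim_samples MCMC samples used for the Louis-type observed Fisher
#'   information at the optimum (see [compute_rse()]).
#' @return A list of class `"saem_control"`.
#' @export
saem_control <- function(K1 = 300, K2 = 200, transitions = 3,
                         target_accept = 0.3,
                         omega2_min = 1e-8, sigma_min = 1e-6,
                         fim_samples = 200) {
  stopifnot(K1 >= 1, K2 >= 1, transitions >= 1,
            target_accept > 0, target_accept < 1)
  structure(list(K1 = K1, K2 = K2, transitions = transitions,
                 target_accept = target_accept,
                 omega2_min = omega2_min, sigma_min = sigma_min,
                 fim_samples = fim_samples),
            class = "saem_control")
}

## data log-likelihood of subject given phi (log-parameters); returns -Inf for
## invalid predictions so MH simply rejects
.subj_data_ll <- function(subject, predfn, phi, sigma) {
  pr <- predfn(exp(phi), subject)
  ll <- 0
  for (s in seq_along(subject$streams)) {
    y <- subject$streams[[s]]$values
    f <- pr[[s]]
    if (any(!is.finite(f)) || any(f <= 0)) return(-Inf)
    ll <- ll + sum(stats::dnorm(y, f, sigma[s] * f, log = TRUE))
  }
  ll
}

.subj_resid_ss <- function(subject, predfn, phi) {
  pr <- predfn(exp(phi), subject)
  vapply(seq_along(subject$streams), function(s) {
    y <- subject$streams[[s]]$values
    sum(((y - pr[[s]]) / pr[[s]])^2)
  }, numeric(1))
}

.saem_engine <- function(subjects, predfn, init, control) {
  n <- length(subjects)
  p <- length(init$theta_mu)
  ns <- length(subjects[[1]]$streams)
  pnames <- names(init$theta_mu)
  if (is.null(pnames)) pnames <- paste0("theta", seq_len(p))

  mu <- log(init$theta_mu)
  omega2 <- pmax(init$omega2, control$omega2_min)
  sigma <- pmax(init$sigma, control$sigma_min)
  N_s <- vapply(seq_len(ns), function(s)
    sum(vapply(subjects, function(su) length(su$streams[[s]]$values),
               numeric(1))), numeric(1))

  phi <- if (!is.null(init$phi)) init$phi else
    matrix(mu, n, p, byrow = TRUE)
  cur_ll <- vapply(seq_len(n), function(i)
    .subj_data_ll(subjects[[i]], predfn, phi[i, ], sigma), numeric(1))
  ## subjects whose initial phi is invalid fall back to the population mode
  bad <- !is.finite(cur_ll)
  if (any(bad)) {
    phi[bad, ] <- matrix(mu, sum(bad), p, byrow = TRUE)
    cur_ll[bad] <- vapply(which(bad), function(i)
      .subj_data_ll(subjects[[i]], predfn, phi[i, ], sigma), numeric(1))
  }

  rw_sd <- pmax(sqrt(omega2), 0.02)
  K <- control$K1 + control$K2
  S1 <- numeric(p); S2 <- numeric(p); S3 <- numeric(ns)
  phi_mean <- phi
  trace <- matrix(NA_real_, K, 2 * p + ns,
                  dimnames = list(NULL, c(pnames,
                                          paste0("omega2_", pnames),
                                          paste0("sigma_", seq_len(ns)))))

  for (k in seq_len(K)) {
    gamma <- if (k <= control$K1) 1 else 1 / (k - control$K1)
    acc <- numeric(p)

    for (i in seq_len(n)) {
      su <- subjects[[i]]
      ## independence proposal from the population distribution
      cand <- stats::rnorm(p, mu, sqrt(omega2))
      ll_cand <- .subj_data_ll(su, predfn, cand, sigma)
      if (is.finite(ll_cand) &&
          log(stats::runif(1)) < ll_cand - cur_ll[i]) {
        phi[i, ] <- cand
        cur_ll[i] <- ll_cand
      }
      ## componentwise random-walk sweeps
      for (m in seq_len(control$transitions)) {
        for (cpt in seq_len(p)) {
          cand <- phi[i, ]
          cand[cpt] <- cand[cpt] + stats::rnorm(1, 0, rw_sd[cpt])
          ll_cand <- .subj_data_ll(su, predfn, cand, sigma)
          lr <- (ll_cand - cur_ll[i]) +
            stats::dnorm(cand[cpt], mu[cpt], sqrt(omega2[cpt]), log = TRUE) -
            stats::dnorm(phi[i, cpt], mu[cpt], sqrt(omega2[cpt]), log = TRUE)
          if (is.finite(lr) && log(stats::runif(1)) < lr) {
            phi[i, cpt] <- cand[cpt]
            cur_ll[i] <- ll_cand
            acc[cpt] <- acc[cpt] + 1
          }
        }
      }
    }

    if (k <= control$K1)   # adapt proposal toward the target acceptance rate
      rw_sd <- rw_sd * exp(0.4 * (acc / (n * control$transitions) -
                                    control$target_accept))

    stat3 <- Reduce(`+`, lapply(seq_len(n), function(i)
      .subj_resid_ss(subjects[[i]], predfn, phi[i, ])))
    S1 <- (1 - gamma) * S1 + gamma * colSums(phi)
    S2 <- (1 - gamma) * S2 + gamma * colSums(phi^2)
    S3 <- (1 - gamma) * S3 + gamma * stat3

    mu <- S1 / n
    omega2 <- pmax(S2 / n - mu^2, control$omega2_min)
    sigma <- pmax(sqrt(S3 / N_s), control$sigma_min)
    ## residual ll cache depends on sigma; refresh
    cur_ll <- vapply(seq_len(n), function(i)
      .subj_data_ll(subjects[[i]], predfn, phi[i, ], sigma), numeric(1))

    phi_mean <- if (k <= control$K1) phi else
      (1 - gamma) * phi_mean + gamma * phi
    trace[k, ] <- c(exp(mu), omega2, sigma)
  }

  converged <- all(is.finite(trace))
  if (converged) {
    tail_win <- trace[seq(max(1, K - 49), K, by = 1), seq_len(p), drop = FALSE]
    drift <- apply(tail_win, 2, function(v) diff(range(v)) / mean(v))
    converged <- all(drift < 0.2)
  }

  theta_mu <- exp(mu)
  names(theta_mu) <- pnames
  names(omega2) <- pnames
  rownames(phi_mean) <- vapply(subjects, function(s) as.character(s$id),
                               character(1))
  colnames(phi_mean) <- pnames
  list(theta_mu = theta_mu, mu = mu, omega2 = omega2, sigma = sigma,
       cv_percent = omega2_to_cv(omega2), phi_mean = phi_mean,
       trace = trace, converged = converged, rw_sd = rw_sd,
       n_subjects = n, n_obs = N_s)
}

## Louis-type observed Fisher information at fixed population parameters.
## Population parameter vector: (mu_1..mu_p, omega2_1..omega2_p,
## sigma2_1..sigma2_ns). Scores and Hessians of the complete-data
## log-likelihood are analytic; the conditional expectations are Monte-Carlo
## averages over MH samples of phi at the optimum.
.louis_fim <- function(subjects, predfn, mu, omega2, sigma, rw_sd,
                       phi_start, samples = 200, burnin = 50,
                       transitions = 3) {
  n <- length(subjects)
  p <- length(mu)
  ns <- length(sigma)
  q <- 2 * p + ns
  sigma2 <- sigma^2

  phi <- phi_start
  cur_ll <- vapply(seq_len(n), function(i)
    .subj_data_ll(subjects[[i]], predfn, phi[i, ], sigma), numeric(1))

  score_i <- function(i) {
    phii <- phi[i, ]
    dm <- (phii - mu) / omega2
    dw <- -1 / (2 * omega2) + (phii - mu)^2 / (2 * omega2^2)
    rss <- .subj_resid_ss(subjects[[i]], predfn, phii)
    ni <- vapply(subjects[[i]]$streams, function(st) length(st$values),
                 numeric(1))
    dsig <- -ni / (2 * sigma2) + rss / (2 * sigma2^2)
    c(dm, dw, dsig)
  }
  hess_i <- function(i) {
    phii <- phi[i, ]
    H <- matrix(0, q, q)
    d2m <- -1 / omega2
    d2w <- 1 / (2 * omega2^2) - (phii - mu)^2 / omega2^3
    dmw <- -(phii - mu) / omega2^2
    for (c1 in seq_len(p)) {
      H[c1, c1] <- d2m[c1]
      H[p + c1, p + c1] <- d2w[c1]
      H[c1, p + c1] <- H[p + c1, c1] <- dmw[c1]
    }
    rss <- .subj_resid_ss(subjects[[i]], predfn, phii)
    ni <- vapply(subjects[[i]]$streams, function(st) length(st$values),
                 numeric(1))
    for (s in seq_len(ns)) {
      j <- 2 * p + s
      H[j, j] <- ni[s] / (2 * sigma2[s]^2) - rss[s] / sigma2[s]^3
    }
    H
  }

  mh_sweep <- function() {
    for (i in seq_len(n)) {
      su <- subjects[[i]]
      for (m in seq_len(transitions)) {
        for (cpt in seq_len(p)) {
          cand <- phi[i, ]
          cand[cpt] <- cand[cpt] + stats::rnorm(1, 0, rw_sd[cpt])
          ll_cand <- .subj_data_ll(su, predfn, cand, sigma)
          lr <- (ll_cand - cur_ll[i]) +
            stats::dnorm(cand[cpt], mu[cpt], sqrt(omega2[cpt]), log = TRUE) -
            stats::dnorm(phi[i, cpt], mu[cpt], sqrt(omega2[cpt]), log = TRUE)
          if (is.finite(lr) && log(stats::runif(1)) < lr) {
            phi[i, cpt] <<- cand[cpt]
            cur_ll[i] <<- ll_cand
          }
        }
      }
    }
  }

  for (b in seq_len(burnin)) mh_sweep()

  D <- matrix(0, n, q)            # E[g_i | y]
  G <- matrix(0, q, q)            # sum_i E[H_i + g_i g_i' | y]
  for (m in seq_len(samples)) {
    mh_sweep()
    for (i in seq_len(n)) {
      g <- score_i(i)
      D[i, ] <- D[i, ] + g / samples
      G <- G + (hess_i(i) + tcrossprod(g)) / samples
    }
  }
  I_obs <- -G
  for (i in seq_len(n)) I_obs <- I_obs + tcrossprod(D[i, ])
  I_obs
}
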