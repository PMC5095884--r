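test_that("SAEM recovers the truth to <1% on degenerate noise-free data", {
  d <- simulate_cohort(cohort_design(n_subjects = 5, cv_a = 0, cv_K = 0,
                                     cv_lam = 0, sigma_biolum = 0,
                                     sigma_caliper = 0), seed = 1)
  ## variance components collapse to their floor here, so the information
  ## matrix is legitimately singular and RSEs are flagged NaN
  suppressWarnings(f <- saem_fit(d, control = fast_control(), seed = 1))
  expect_equal(unname(f$theta_mu["a"]), tab1$a, tolerance = 0.01)
  expect_equal(unname(f$theta_mu["K"]), tab1$K, tolerance = 0.01)
  suppressWarnings(f <- fit_lambda(f, seed = 1))
  expect_equal(f$lambda$lam, tab1$lam, tolerance = 0.01)
})

test_that("SAEM is bit-reproducible for a fixed seed and settings", {
  d <- simulate_cohort(cohort_design(n_subjects = 6), seed = 9)
  f1 <- saem_fit(d, control = fast_control(), seed = 5)
  f2 <- saem_fit(d, control = fast_control(), seed = 5)
  expect_identical(f1$theta_mu, f2$theta_mu)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$rse_percent, f2$rse_percent)
  f3 <- saem_fit(d, control = fast_control(), seed = 6)
  expect_false(identical(f1$theta_mu, f3$theta_mu))
})

test_that("fit requires enough subjects and exposes a parameter table", {
  d <- simulate_cohort(cohort_design(n_subjects = 6), seed = 9)
  small <- growth_data(as.data.frame(d)[d$subject %in% c("m01", "m02"), ])
  expect_error(saem_fit(small), "at least 3 subjects")
  f <- saem_fit(d, control = fast_control(), seed = 5)
  s <- summary(f)
  expect_named(s$table, c("parameter", "unit", "estimate", "cv_percent",
                          "rse_percent"))
  expect_true(all(s$table$estimate > 0))
  expect_output(print(f), "SAEM nonlinear mixed-effects fit")
  ## empirical-Bayes residuals are centred and on the proportional scale
  r <- residuals(f)
  expect_lt(abs(mean(r$residual)), 0.1)
  expect_equal(fitted(f), r$fitted)
})

test_that("Louis information matches the closed-form GLS oracle on a linear toy model", {
  ## constant-prediction lognormal model: log y_ij ~ phi_i + eps, so
  ## Var(mu_hat) = (omega2 + sigma^2/J)/n up to O(sigma^2) terms
  set.seed(42)
  n <- 60; J <- 5; mu <- log(10); om2 <- 0.04; sigma <- 0.05
  phi <- rnorm(n, mu, sqrt(om2))
  subjects <- lapply(seq_len(n), function(i) {
    f <- rep(exp(phi[i]), J)
    list(id = i,
         streams = list(list(times = seq_len(J),
                             values = f * (1 + rnorm(J, 0, sigma)))),
         ctx = NULL)
  })
  predfn <- function(theta, subject) list(rep(theta[1], J))
  set.seed(7)
  I_obs <- lumigrow:::.louis_fim(subjects, predfn, mu, om2, sigma,
                                 rw_sd = 0.1,
                                 phi_start = matrix(phi, n, 1),
                                 samples = 400, burnin = 100)
  se_mu <- sqrt(diag(solve(I_obs)))[1]
  expect_equal(se_mu, sqrt((om2 + sigma^2 / J) / n), tolerance = 0.05)
})

test_that("sequential lambda stage recovers unity exactly and is scale-equivariant", {
  des <- cohort_design(n_subjects = 6, lam = 1, cv_lam = 0,
                       sigma_biolum = 0, sigma_caliper = 0,
                       cv_a = 0, cv_K = 0)
  d <- simulate_cohort(des, seed = 3)
  suppressWarnings(f <- saem_fit(d, control = fast_control(), seed = 3))
  suppressWarnings(f1 <- fit_lambda(f, seed = 3))
  expect_equal(f1$lambda$lam, 1, tolerance = 0.01)
  ## tripling every caliper value triples the recovered lambda
  d3 <- as.data.frame(d)
  d3$value[d3$observable == "caliper"] <- 3 * d3$value[d3$observable == "caliper"]
  suppressWarnings(f3 <- fit_lambda(f, growth_data(d3), seed = 3))
  expect_equal(f3$lambda$lam, 3 * f1$lambda$lam, tolerance = 0.01)
  expect_error(fit_lambda(f, growth_data(
    as.data.frame(d)[d$observable == "bioluminescence", ])), "caliper")
})

test_that("joint three-parameter fit agrees with the sequential route", {
  d <- simulate_cohort(cohort_design(n_subjects = 10), seed = 6)
  f <- saem_fit(d, control = fast_control(), seed = 6)
  fs <- fit_lambda(f, method = "sequential", seed = 6)
  fj <- fit_lambda(f, method = "joint", control = fast_control(), seed = 6)
  expect_equal(fj$lambda$lam, fs$lambda$lam, tolerance = 0.1)
  expect_equal(unname(fj$theta_mu["a"]), unname(fs$theta_mu["a"]),
               tolerance = 0.1)
})

test_that("SAEM attains at least the marginal likelihood of the two-stage estimates", {
  wins <- 0L
  for (seed in 1:5) {
    d <- simulate_cohort(cohort_design(n_subjects = 10, caliper = FALSE),
                         seed = seed)
    f <- saem_fit(d, control = fast_control(), seed = seed)
    ts <- two_stage_fit(d)
    ll_saem <- as.numeric(logLik(f, M = 500, seed = 99))
    ll_ts <- as.numeric(logLik(f, theta_mu = ts$theta_mu,
                               omega2 = ts$omega2, sigma = ts$sigma,
                               M = 500, seed = 99))
    if (ll_saem >= ll_ts - 0.5) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("predict and simulate methods are coherent with the model", {
  d <- simulate_cohort(cohort_design(n_subjects = 6), seed = 12)
  f <- fit_lambda(saem_fit(d, control = fast_control(), seed = 12), seed = 12)
  pop <- predict(f, times = c(0, 43))
  expect_equal(pop$pred[1], f$P0)
  ind <- predict(f, times = c(6, 43), level = "individual")
  expect_equal(nrow(ind), 2 * 6)
  vol <- predict(f, times = 43, observable = "caliper")
  expect_equal(vol$pred,
               f$lambda$lam * signal_to_volume_cm3(
                 lumigrow:::.total(43, f$theta_mu[["a"]], f$theta_mu[["K"]],
                                   f$P0), f$conv))
  sims <- simulate(f, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "growth_data")
  expect_setequal(unique(sims[[1]]$observable),
                  c("bioluminescence", "caliper"))
})
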