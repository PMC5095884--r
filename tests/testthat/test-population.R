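test_that("CV and lognormal variance mappings are exact inverses", {
  for (cv in c(0, 5, 10, 31.1, 55.3, 150)) {
    expect_equal(omega2_to_cv(cv_to_omega2(cv)), cv, tolerance = 1e-12)
  }
  expect_equal(cv_to_omega2(0), 0)
  expect_error(cv_to_omega2(-1), "non-negative")
})

test_that("individual parameters rescale the fixed effects lognormally", {
  mu <- c(a = tab1$a, K = tab1$K)
  expect_equal(individual_parameters(mu, c(0, 0)), mu)
  doubled <- individual_parameters(mu, c(log(2), 0))
  expect_equal(unname(doubled["a"]), 2 * tab1$a)
  expect_equal(unname(doubled["K"]), tab1$K)
  ## Monte-Carlo check of the CV formula at the published inter-animal CV
  set.seed(101)
  eta <- rnorm(1e5, 0, sqrt(cv_to_omega2(tab1$cv_a)))
  draws <- tab1$a * exp(eta)
  emp_cv <- 100 * sd(draws) / mean(draws)
  expect_equal(emp_cv, tab1$cv_a, tolerance = 0.01)
})

test_that("proportional-error log-likelihood has its closed form and shape", {
  f <- 1000
  sigma <- 0.15
  expect_equal(individual_loglik(f, f, sigma),
               -0.5 * log(2 * pi) - log(sigma * f))
  ## far-from-prediction data prefer a larger sigma, near data a smaller one
  y_far <- f * 1.8
  expect_gt(individual_loglik(y_far, f, 0.3), individual_loglik(y_far, f, 0.15))
  expect_gt(individual_loglik(f * 1.01, f, 0.05),
            individual_loglik(f * 1.01, f, 0.3))
  expect_error(individual_loglik(1, 0, 0.1), "degenerate")
  expect_error(individual_loglik(1, 1, 0), "positive")
})

test_that("importance-sampled marginal likelihood matches brute-force quadrature", {
  ## one animal, one lognormal parameter, constant prediction
  y <- c(9.5, 10.4, 10.1)
  mu <- log(10); om2 <- 0.09; sigma <- 0.1
  su <- list(list(id = 1,
                  streams = list(list(times = 1:3, values = y)),
                  ctx = NULL))
  pf <- function(theta, subject) list(rep(theta[1], 3))
  quad <- stats::integrate(Vectorize(function(ph) {
    f <- exp(ph)
    prod(stats::dnorm(y, f, sigma * f)) *
      stats::dnorm(ph, mu, sqrt(om2))
  }), mu - 4, mu + 4, rel.tol = 1e-12)$value
  ll_is <- lumigrow:::.marginal_loglik(su, pf, mu, om2, sigma,
                                       M = 5000, seed = 3)
  expect_equal(exp(ll_is) / quad, 1, tolerance = 0.02)
})

test_that("two-stage fit is exact on noiseless, variability-free data", {
  d <- simulate_cohort(cohort_design(n_subjects = 5, cv_a = 0, cv_K = 0,
                                     cv_lam = 0, sigma_biolum = 0,
                                     sigma_caliper = 0), seed = 1)
  ts <- two_stage_fit(d)
  expect_equal(unname(ts$theta_mu["a"]), tab1$a, tolerance = 1e-4)
  expect_equal(unname(ts$theta_mu["K"]), tab1$K, tolerance = 1e-4)
  expect_lt(ts$sigma, 1e-4)
})

test_that("a flat-signal subject is excluded and the run continues", {
  d <- simulate_cohort(cohort_design(n_subjects = 5, sigma_biolum = 0.05),
                       seed = 4)
  ## a signal stuck below the injected burden cannot be fit by the
  ## (monotone increasing) logistic solution except with a -> 0
  flat <- data.frame(subject = "flat", time = c(6, 12, 20, 30, 43),
                     observable = "bioluminescence",
                     value = rep(1.0e7, 5))
  d2 <- growth_data(rbind(as.data.frame(d), flat))
  expect_warning(ts <- two_stage_fit(d2), "flat")
  expect_false("flat" %in% ts$individual$subject)
  expect_equal(nrow(ts$individual), 5)
})

test_that("two-stage and SAEM agree on rich, low-noise data", {
  des <- cohort_design(n_subjects = 12,
                       days = seq(4, 43, by = 3),
                       sigma_biolum = 0.05, caliper = FALSE)
  d <- simulate_cohort(des, seed = 2)
  ts <- two_stage_fit(d)
  sf <- saem_fit(d, control = fast_control(), seed = 2)
  expect_equal(unname(sf$theta_mu["a"]), unname(ts$theta_mu["a"]),
               tolerance = 0.1)
  expect_equal(unname(sf$theta_mu["K"]), unname(ts$theta_mu["K"]),
               tolerance = 0.1)
})
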