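test_that("parameter construction enforces positivity and P0 < K", {
  expect_s3_class(growth_params(0.4, 1e9, 1e7), "growth_params")
  expect_error(growth_params(-0.1, 1e9, 1e7), "positive")
  expect_error(growth_params(0.4, 1e9, 0), "positive")
  expect_error(growth_params(0.4, 1e7, 1e7), "below the carrying capacity")
  expect_error(growth_params(0.4, 1e9, 1e7, lam = 0), "positive")
  expect_equal(cell_cycle_length(log(2)), 1)
})

test_that("initial conditions and saturation limits hold", {
  p <- typical_params()
  expect_equal(prolif_signal(0, p), p$P0)
  expect_equal(necrotic_signal(0, p), 0)
  expect_equal(total_signal(0, p), p$P0)
  ## a*t >= 40: proliferative compartment at carrying capacity
  expect_equal(prolif_signal(150, p), tab1$K, tolerance = 1e-12)
  expect_error(prolif_signal(-1, p), "non-negative")
  expect_error(necrotic_signal(-1, p), "non-negative")
})

test_that("closed forms agree with adaptive ODE integration over a parameter sweep", {
  for (a in c(0.05, 0.2, 0.399, 1)) {
    for (ratio in c(10, 1e3, 1e5)) {
      P0 <- 1.326e7
      p <- growth_params(a, ratio * P0, P0)
      times <- seq(1, 60, by = 2.5)
      ode <- simulate_ode(p, times, rtol = 1e-11, atol = 1e-6)
      expect_equal(prolif_signal(times, p), ode$P, tolerance = 1e-6)
      expect_equal(necrotic_signal(times, p), ode$N, tolerance = 1e-6)
      expect_equal(total_signal(times, p), ode$V, tolerance = 1e-6)
    }
  }
})

test_that("necrotic compartment equals the cumulative quadrature of a*P^2/K", {
  p <- typical_params()
  for (t_end in c(10, 25, 43)) {
    q <- stats::integrate(function(s) p$a * prolif_signal(s, p)^2 / p$K,
                          0, t_end, rel.tol = 1e-10)$value
    expect_equal(necrotic_signal(t_end, p), q, tolerance = 1e-6)
  }
})

test_that("mass conservation: P + N - P0 = a * integral of P", {
  for (p in list(typical_params(), growth_params(0.1, 1e8, 1e5))) {
    for (t_end in c(5, 20, 50)) {
      lhs <- prolif_signal(t_end, p) + necrotic_signal(t_end, p) - p$P0
      rhs <- p$a * stats::integrate(function(s) prolif_signal(s, p),
                                    0, t_end, rel.tol = 1e-10)$value
      expect_equal(lhs, rhs, tolerance = 1e-6)
    }
  }
})

test_that("monotonicity: P increasing and bounded by K, N and V non-decreasing", {
  grid <- seq(0, 60, by = 0.25)
  for (a in c(0.1, 0.399, 0.8)) {
    p <- growth_params(a, 4.35e9, 1.326e7)
    P <- prolif_signal(grid, p)
    ## strictly increasing until the plateau is reached; the plateau itself
    ## is flat only up to double-precision roundoff (~1e-15 relative)
    expect_true(all(diff(P) >= -1e-12 * p$K))
    expect_true(all(diff(P[P < 0.99 * p$K]) > 0))
    expect_true(all(P <= p$K * (1 + 1e-12)))
    expect_true(all(diff(necrotic_signal(grid, p)) >= 0))
    expect_true(all(diff(total_signal(grid, p)) >= -1e-12 * p$K))
  }
})

test_that("total burden becomes linear with slope a*K after saturation", {
  p <- typical_params()
  slope <- (total_signal(43, p) - total_signal(40, p)) / 3
  expect_equal(slope, p$a * p$K, tolerance = 0.02)
})

test_that("growth acceleration peaks exactly once: the exponential-to-linear transition", {
  ## V'' = a^2 P (1 - P/K) rises to a single maximum (P = K/2) then decays,
  ## so its finite-difference derivative changes sign exactly once; log V
  ## itself is strictly concave throughout.
  p <- typical_params()
  grid <- seq(0.5, 43, by = 0.05)
  V <- total_signal(grid, p)
  accel <- diff(V, differences = 2)
  expect_equal(n_sign_changes(diff(accel)), 1)
  lv_curv <- diff(log(V), differences = 2)
  expect_true(all(lv_curv < 0))
})

test_that("overflow-safe evaluation far beyond exp() range", {
  p <- typical_params()
  for (t in c(700 / p$a, 2000, 5000)) {
    expect_true(is.finite(prolif_signal(t, p)))
    expect_true(is.finite(total_signal(t, p)))
  }
  expect_equal(prolif_signal(5000, p), p$K)
})

test_that("numerical ODE route validates input and handles degenerate growth", {
  p <- typical_params()
  expect_error(simulate_ode(p, c(5, 3)), "ascending")
  tr <- simulate_ode(p, 0)
  expect_equal(tr$P, p$P0)
  expect_equal(tr$N, 0)
  ## vanishing proliferation: flat P, empty necrotic compartment
  slow <- growth_params(1e-10, 4.35e9, 1.326e7)
  tr <- simulate_ode(slow, c(0, 20, 43))
  expect_equal(tr$P, rep(slow$P0, 3), tolerance = 1e-7)
  expect_lt(max(tr$N) / slow$P0, 1e-10)
  ## trajectory container invariants
  tr2 <- growth_trajectory(p, c(0, 10, 43))
  expect_equal(tr2$V, tr2$P + tr2$N)
  expect_true(all(tr2$N >= 0) && tr2$N[1] == 0)
})

test_that("unit conversions are exact inverses and match the definitional anchors", {
  conv <- conversion_constants()
  expect_equal(signal_to_volume_cm3(0, conv), 0)
  expect_equal(signal_to_volume_cm3(88.4e9, conv), 1)
  ## injected burden: 1.5e5 cells at 88.4 photons/sec/cell -> 1.5e-4 cm^3
  expect_equal(signal_to_volume_cm3(1.5e5 * 88.4, conv), 1.5e-4)
  for (x in c(1, 1e7, 3.7e10)) {
    expect_equal(volume_cm3_to_signal(signal_to_volume_cm3(x, conv), conv),
                 x, tolerance = 1e-12)
  }
  expect_error(signal_to_volume_cm3(-1, conv), "non-negative")
})

test_that("lambda-scaled caliper prediction is linear in lambda and hits the printed plateau", {
  conv <- conversion_constants()
  p1 <- typical_params(lam = 1)
  expect_equal(predicted_caliper_volume(0, p1, conv),
               signal_to_volume_cm3(p1$P0, conv))
  p2 <- typical_params(lam = 2.25)
  p4 <- typical_params(lam = 4.5)
  t <- c(0, 10, 30, 43)
  expect_equal(predicted_caliper_volume(t, p4, conv),
               2 * predicted_caliper_volume(t, p2, conv))
  ## day-43 plateau of the typical animal: about 1.3 cm^3
  expect_equal(predicted_caliper_volume(43, p2, conv), 1.3, tolerance = 0.1)
})

test_that("stroma fraction formula and its domain", {
  expect_equal(stroma_fraction(1), 0)
  expect_equal(stroma_fraction(2), 50)
  expect_equal(stroma_fraction(2.25), 100 * (1 - 1 / 2.25))
  expect_identical(round(stroma_fraction(2.25)), 56)
  expect_error(stroma_fraction(0.9), "not meaningful")
})

test_that("Carlsson caliper volume, including axis-swap tolerance", {
  expect_equal(carlsson_volume(1, 1), 0.5)
  expect_equal(carlsson_volume(2, 1), 1)
  expect_equal(carlsson_volume(1.72, 1.23), 1.301, tolerance = 1e-3)
  expect_warning(v <- carlsson_volume(1, 2), "swapped")
  expect_equal(v, 1)
  expect_error(carlsson_volume(0, 1), "positive")
})
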