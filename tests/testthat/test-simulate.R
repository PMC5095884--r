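test_that("zero variability and zero noise give identical typical trajectories", {
  des <- cohort_design(n_subjects = 4, cv_a = 0, cv_K = 0, cv_lam = 0,
                       sigma_biolum = 0, sigma_caliper = 0)
  d <- simulate_cohort(des, seed = 1)
  p <- typical_params()
  for (id in unique(d$subject)) {
    b <- d[d$subject == id & d$observable == "bioluminescence", ]
    expect_equal(b$value, prolif_signal(b$time, p), tolerance = 1e-10)
    v <- d[d$subject == id & d$observable == "caliper", ]
    expect_equal(v$value,
                 predicted_caliper_volume(v$time, p), tolerance = 1e-10)
  }
  expect_identical(attr(d, "resampled"), 0L)
})

test_that("sampled parameters reproduce the design CVs in large cohorts", {
  d <- simulate_cohort(cohort_design(n_subjects = 500, caliper = FALSE),
                       seed = 8)
  tr <- attr(d, "truth")
  expect_equal(100 * sd(tr$a) / mean(tr$a), tab1$cv_a, tolerance = 0.05)
  expect_equal(100 * sd(tr$K) / mean(tr$K), tab1$cv_K, tolerance = 0.15)
  expect_equal(mean(tr$a), tab1$a, tolerance = 0.05)
})

test_that("generation is deterministic per seed and respects the design", {
  des <- cohort_design(n_subjects = 5)
  d1 <- simulate_cohort(des, seed = 42)
  d2 <- simulate_cohort(des, seed = 42)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_identical(attr(d1, "truth"), attr(d2, "truth"))
  d3 <- simulate_cohort(des, seed = 43)
  expect_false(identical(d1$value, d3$value))
  expect_setequal(unique(d1$time), des$days)
  expect_equal(length(unique(d1$subject)), 5)
  no_cal <- simulate_cohort(cohort_design(n_subjects = 4, caliper = FALSE),
                            seed = 1)
  expect_false("caliper" %in% no_cal$observable)
})

test_that("all observations stay positive, with resampling logged at high noise", {
  d <- simulate_cohort(cohort_design(n_subjects = 30, sigma_biolum = 0.45,
                                     sigma_caliper = 0.45), seed = 2)
  expect_true(all(d$value > 0))
  expect_gt(attr(d, "resampled"), 0)
})

test_that("design validation catches impossible cohorts", {
  expect_error(cohort_design(n_subjects = 2), "at least 3")
  expect_error(cohort_design(days = c(10, 5)), "ascending")
  expect_error(cohort_design(sigma_biolum = 1.2), "noise")
})

test_that("calibration plate generator hits its line exactly at zero noise", {
  plate <- simulate_calibration_plate(slope = 88.4, noise = 0, seed = 1)
  expect_equal(plate$signal, 88.4 * plate$cells)
  expect_identical(attr(plate, "truth"), 88.4)
})

test_that("humane-endpoint censoring removes records after threshold crossing", {
  d <- simulate_cohort(cohort_design(), seed = 1)
  ## infinite threshold: untouched
  expect_equal(nrow(inject_dropout(d, threshold = 1e9)), nrow(d))
  ## near-zero threshold: only each animal's first imaging day survives
  d0 <- inject_dropout(d, threshold = 1e-12)
  expect_true(all(d0$time == min(d$time)))
  ## realistic 2.5 cm^3 endpoint: subject counts non-increasing over time
  d25 <- inject_dropout(d, threshold = 2.5)
  counts <- vapply(sort(unique(d$time)), function(t)
    length(unique(d25$subject[d25$time == t])), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(inject_dropout(d, threshold = -1), "positive")
})

test_that("cohort CSV and truth sidecar round-trip", {
  d <- simulate_cohort(cohort_design(n_subjects = 4), seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  paths <- write_cohort(d, path)
  again <- read_growth_csv(paths[["csv"]])
  expect_equal(as.data.frame(again), as.data.frame(d), tolerance = 1e-12,
               ignore_attr = TRUE)
  side <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(side$truth$a, attr(d, "truth")$a, tolerance = 1e-12)
  expect_equal(side$seed, 5)
})
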