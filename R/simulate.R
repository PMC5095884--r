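#' Design of a virtual mouse cohort experiment
#'
#' Encodes the study conditions the generator emulates: 20 animals imaged
#' twice weekly from day 6 to day 43 post-graft after orthotopic injection of
#' 1.5e5 luciferase-expressing cells, with lognormal inter-animal variability
#' around the typical growth parameters, a lognormal caliper proportionality
#' constant, and independent proportional measurement noise on the
#' bioluminescence and caliper channels.
#'
#' @param n_subjects number of animals (default 20).
#' @param days observation days post-graft (default 12 twice-weekly visits,
#'   days 6 to 43).
#' @param injected_cells cells injected at day 0 (default 1.5e5).
#' @param a,K typical proliferation rate (day^-1) and carrying capacity
#'   (photons/sec); defaults 0.399 and 4.35e9.
#' @param lam typical caliper proportionality constant (default 2.25).
#' @param cv_a,cv_K,cv_lam inter-animal CVs in percent (defaults 31.1, 55.3,
#'   10).
#' @param sigma_biolum,sigma_caliper proportional residual noise, in (0, 1)
#'   (defaults 0.15 each; independent channels).
#' @param photons_per_cell,cells_per_cm3 conversion constants (88.4, 1e9).
#' @param caliper simulate the caliper channel as well? (default TRUE).
#' @return A list of class `"cohort_design"`.
#' @export
cohort_design <- function(n_subjects = 20,
                          days = c(6, 9, 12, 15, 18, 22, 25, 29, 32, 36,
                                   39, 43),
                          injected_cells = 1.5e5,
                          a = 0.399, K = 4.35e9, lam = 2.25,
                          cv_a = 31.1, cv_K = 55.3, cv_lam = 10,
                          sigma_biolum = 0.15, sigma_caliper = 0.15,
                          photons_per_cell = 88.4, cells_per_cm3 = 1e9,
                          caliper = TRUE) {
  if (n_subjects < 3) stop("'n_subjects' must be at least 3")
  if (is.unsorted(days, strictly = TRUE) || any(days < 0) || any(days > 60))
    stop("'days' must be strictly ascending within [0, 60]")
  for (s in c(sigma_biolum, sigma_caliper))
    if (s < 0 || s >= 1) stop("noise levels must lie in [0, 1)")
  if (any(c(a, K, lam, injected_cells) <= 0))
    stop("typical parameters must be positive")
  structure(list(n_subjects = n_subjects, days = days,
                 injected_cells = injected_cells,
                 a = a, K = K, lam = lam,
                 cv_a = cv_a, cv_K = cv_K, cv_lam = cv_lam,
                 sigma_biolum = sigma_biolum, sigma_caliper = sigma_caliper,
                 photons_per_cell = photons_per_cell,
                 cells_per_cm3 = cells_per_cm3, caliper = caliper),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("Virtual cohort: %d animals, %d visits (days %g-%g), %.3g cells injected\n",
              x$n_subjects, length(x$days), min(x$days), max(x$days),
              x$injected_cells))
  cat(sprintf("  truth: a = %.3g (CV %.1f%%), K = %.3g (CV %.1f%%), lambda = %.3g (CV %.1f%%)\n",
              x$a, x$cv_a, x$K, x$cv_K, x$lam, x$cv_lam))
  cat(sprintf("  noise: %.0f%% bioluminescence, %.0f%% caliper\n",
              100 * x$sigma_biolum, 100 * x$sigma_caliper))
  invisible(x)
}

## multiplicative proportional noise, resampled until positive; the resample
## count is recorded because truncation introduces (negligible) bias
.prop_noise <- function(f, sigma, counter_env) {
  if (sigma == 0) return(f)
  y <- f * (1 + stats::rnorm(length(f), 0, sigma))
  bad <- which(y <= 0)
  while (length(bad)) {
    counter_env$resampled <- counter_env$resampled + length(bad)
    y[bad] <- f[bad] * (1 + stats::rnorm(length(bad), 0, sigma))
    bad <- bad[y[bad] <= 0]
  }
  y
}

#' Generate a synthetic cohort dataset
#'
#' Samples each animal's parameters lognormally around the design truth with
#' the stated CVs, evaluates the closed-form growth trajectories, and emits
#' noisy observations: bioluminescence as \eqn{P_i(t)(1+\varepsilon)} and
#' caliper volume as \eqn{\lambda_i (P_i + N_i)(t)} converted to cm^3, with
#' independent proportional Gaussian noise per channel. Draws that would be
#' non-positive are resampled (count recorded in the `"resampled"`
#' attribute). Deterministic for a given seed.
#'
#' @param design a [cohort_design()] object.
#' @param seed integer RNG seed.
#' @return A [growth_data()] object with attributes `"truth"` (data frame of
#'   per-animal true `a`, `K`, `lam`), `"design"`, `"seed"`, `"resampled"`.
#' @examples
#' d <- simulate_cohort(cohort_design(n_subjects = 4), seed = 1)
#' head(d)
#' attr(d, "truth")
#' @export
simulate_cohort <- function(design = cohort_design(), seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(as.integer(seed))
  conv <- conversion_constants(design$photons_per_cell,
                               design$cells_per_cm3)
  P0 <- design$injected_cells * design$photons_per_cell
  n <- design$n_subjects
  a_i <- design$a * exp(stats::rnorm(n, 0, sqrt(cv_to_omega2(design$cv_a))))
  K_i <- design$K * exp(stats::rnorm(n, 0, sqrt(cv_to_omega2(design$cv_K))))
  lam_i <- design$lam *
    exp(stats::rnorm(n, 0, sqrt(cv_to_omega2(design$cv_lam))))
  K_i <- pmax(K_i, P0 * 1.01)   # keep the injected burden below capacity
  env <- new.env(); env$resampled <- 0L
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    P <- .prolif(design$days, a_i[i], K_i[i], P0)
    yb <- .prop_noise(P, design$sigma_biolum, env)
    r <- data.frame(subject = sprintf("m%02d", i), time = design$days,
                    observable = "bioluminescence", value = yb)
    if (design$caliper) {
      V <- lam_i[i] * signal_to_volume_cm3(
        .total(design$days, a_i[i], K_i[i], P0), conv)
      yc <- .prop_noise(V, design$sigma_caliper, env)
      r <- rbind(r, data.frame(subject = sprintf("m%02d", i),
                               time = design$days,
                               observable = "caliper", value = yc))
    }
    recs[[i]] <- r
  }
  out <- growth_data(do.call(rbind, recs))
  attr(out, "truth") <- data.frame(subject = sprintf("m%02d", seq_len(n)),
                                   a = a_i, K = K_i, lam = lam_i)
  attr(out, "design") <- design
  attr(out, "seed") <- as.integer(seed)
  attr(out, "resampled") <- env$resampled
  out
}

#' Generate a synthetic cells-to-light calibration plate
#'
#' Well signals are `slope * cells * (1 + eps)`, `eps ~ N(0, noise^2)`,
#' mirroring the in vitro dilution-series design used to calibrate the
#' imager.
#'
#' @param slope true photons/sec per cell (default 88.4).
#' @param densities cells per well (default five log-spaced densities, 1e2 to
#'   1e6).
#' @param replicates wells per density (default 16, two 96-well plate rows
#'   per density; the through-origin slope is dominated by the top density,
#'   so its relative SE is about `noise/sqrt(replicates)` — 16 replicates
#'   put a 3% error at 2.4 SE).
#' @param noise proportional noise SD.
#' @param seed RNG seed.
#' @return A [calibration_plate()] object with a `"truth"` attribute (the
#'   slope).
#' @export
simulate_calibration_plate <- function(slope = 88.4,
                                       densities = 10^(2:6),
                                       replicates = 16, noise = 0.05,
                                       seed = 1L) {
  if (slope <= 0) stop("'slope' must be positive")
  if (any(densities <= 0)) stop("'densities' must be positive")
  set.seed(as.integer(seed))
  cells <- rep(densities, each = replicates)
  env <- new.env(); env$resampled <- 0L
  signal <- .prop_noise(slope * cells, noise, env)
  plate <- calibration_plate(cells, signal,
                             replicate = rep(seq_len(replicates),
                                             times = length(densities)))
  attr(plate, "truth") <- slope
  plate
}

#' Censor a cohort at a humane-endpoint volume threshold
#'
#' Emulates welfare-mandated sacrifice: for each animal, all records after
#' its first caliper observation above `threshold` (cm^3) are removed.
#'
#' @param data a [growth_data()] object.
#' @param threshold caliper volume triggering sacrifice, cm^3, positive
#'   (2.5 cm^3 approximates the usual 2.5 g limit at unit density).
#' @return The censored [growth_data()], with a `"censoring"` attribute
#'   giving each animal's last retained day (NA if never censored).
#' @export
inject_dropout <- function(data, threshold = 2.5) {
  if (threshold <= 0) stop("'threshold' must be positive")
  data <- growth_data(data)
  keep <- rep(TRUE, nrow(data))
  cens <- list()
  for (id in unique(data$subject)) {
    rows <- data$subject == id
    cal <- which(rows & data$observable == "caliper" &
                   data$value > threshold)
    if (length(cal)) {
      t_cut <- min(data$time[cal])
      keep[rows & data$time > t_cut] <- FALSE
      cens[[as.character(id)]] <- t_cut
    } else cens[[as.character(id)]] <- NA_real_
  }
  out <- data[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("growth_data", "data.frame")
  attr(out, "censoring") <- unlist(cens)
  out
}

#' Write a cohort with its ground-truth sidecar
#'
#' Writes the dataset CSV plus a JSON sidecar carrying the per-animal true
#' parameters, the seed and the design, for recovery studies.
#'
#' @param data a [simulate_cohort()] result.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.truth.json`.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(data, path) {
  write_growth_csv(data, path)
  side <- paste0(path, ".truth.json")
  des <- attr(data, "design")
  jsonlite::write_json(
    list(truth = attr(data, "truth"),
         seed = attr(data, "seed"),
         resampled = attr(data, "resampled"),
         design = unclass(des)),
    side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv = path, truth = side))
}
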