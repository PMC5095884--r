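#' Run the full growth-kinetics analysis
#'
#' End-to-end orchestration: optional cells-to-light calibration, stage-1
#' SAEM fit of the proliferative model to bioluminescence, stage-2 estimation
#' of the caliper proportionality constant lambda, the implied stromal
#' fraction, typical-animal trajectories and pointwise 10/50/90 percentile
#' bands of the individual fits. Fully deterministic for a given config.
#'
#' @param config a named list, or a path to a YAML/JSON file with the same
#'   structure. Recognized fields (all optional): `data` (CSV path; if
#'   absent a synthetic cohort is generated), `design` (arguments to
#'   [cohort_design()]), `seed` (default 1), `injected_cells`,
#'   `calibration` (plate CSV path, or a number used directly as the
#'   photons/cell slope; default 88.4), `control` (arguments to
#'   [saem_control()]), `lambda_method` (`"sequential"` or `"joint"`),
#'   `grid` (day grid for the tabulated trajectories; default 0-43 by 0.5).
#' @return An object of class `"analysis_report"`: `table1` (estimate / CV /
#'   RSE per parameter), `lambda`, `stroma_percent`, `typical` (the
#'   [simulate_typical()] table), `bands` (percentile bands of individual
#'   fitted curves, bioluminescence and volume — the latter with both
#'   per-animal and typical lambda scaling), `fit` (the underlying
#'   [saem_fit()]), `provenance`, and `errors` (named stage-labeled messages
#'   for stages that failed; completed stages are still reported).
#' @export
run_analysis <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  errors <- list()

  ## calibration stage
  conv <- tryCatch({
    cal <- config$calibration %||% 88.4
    slope <- if (is.character(cal))
      fit_cells_to_light(read_calibration_csv(cal))$slope
    else as.numeric(cal)
    conversion_constants(photons_per_cell = slope)
  }, error = function(e) {
    errors[["calibration"]] <<- conditionMessage(e)
    conversion_constants()
  })

  ## data stage
  data <- tryCatch({
    if (!is.null(config$data)) read_growth_csv(config$data)
    else simulate_cohort(do.call(cohort_design, config$design %||% list()),
                         seed = seed)
  }, error = function(e) {
    errors[["data"]] <<- conditionMessage(e)
    NULL
  })
  if (is.null(data))
    stop("stage [data]: ", errors[["data"]])

  control <- do.call(saem_control, config$control %||% list())
  injected <- config$injected_cells %||% 1.5e5

  ## stage-1 mixed-effects fit
  fit <- tryCatch(
    saem_fit(data, conv = conv, injected_cells = injected,
             control = control, seed = seed),
    error = function(e) {
      errors[["stage1"]] <<- conditionMessage(e)
      NULL
    })
  if (is.null(fit))
    stop("stage [stage1]: ", errors[["stage1"]])

  ## stage-2 lambda fit (skipped when no caliper records)
  has_caliper <- any(data$observable == "caliper")
  if (has_caliper) {
    fit <- tryCatch(
      fit_lambda(fit, method = config$lambda_method %||% "sequential",
                 seed = seed),
      error = function(e) {
        errors[["stage2"]] <<- conditionMessage(e)
        fit
      })
  }

  grid <- config$grid %||% seq(0, 43, by = 0.5)
  lam <- if (!is.null(fit$lambda)) fit$lambda$lam else NA_real_
  typ_params <- growth_params(a = unname(fit$theta_mu["a"]),
                              K = unname(fit$theta_mu["K"]),
                              P0 = fit$P0,
                              lam = if (is.finite(lam)) lam else 1)
  typical <- simulate_typical(typ_params, grid, conv)
  bands <- .percentile_bands(fit, grid)

  smry <- summary(fit)
  report <- structure(list(
    table1 = smry$table,
    sigma = fit$sigma,
    lambda = lam,
    stroma_percent = if (!is.null(fit$lambda))
      fit$lambda$stroma_percent else NA_real_,
    typical = typical,
    bands = bands,
    fit = fit,
    converged = fit$converged,
    errors = errors,
    provenance = list(seed = seed,
                      config_hash = .config_hash(config),
                      n_subjects = nrow(fit$individual),
                      n_records = nrow(data),
                      package_version =
                        as.character(utils::packageVersion("lumigrow")))),
    class = "analysis_report")
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config[order(names(config))]), tf)
  unname(tools::md5sum(tf))
}

## pointwise 10/50/90 percentiles of the individual fitted curves
.percentile_bands <- function(fit, grid) {
  ind <- fit$individual
  Pm <- vapply(seq_len(nrow(ind)), function(i)
    .prolif(grid, ind$a[i], ind$K[i], fit$P0), numeric(length(grid)))
  qs <- function(M) t(apply(M, 1, stats::quantile,
                            probs = c(0.1, 0.5, 0.9), names = FALSE))
  b <- qs(Pm)
  out <- list(bioluminescence = data.frame(time = grid, p10 = b[, 1],
                                           p50 = b[, 2], p90 = b[, 3]))
  if (!is.null(fit$lambda)) {
    Vm <- vapply(seq_len(nrow(ind)), function(i)
      signal_to_volume_cm3(.total(grid, ind$a[i], ind$K[i], fit$P0),
                           fit$conv), numeric(length(grid)))
    j <- match(ind$subject, fit$lambda$individual$subject)
    lam_i <- ifelse(is.na(j), fit$lambda$lam,
                    fit$lambda$individual$lam[j])
    bi <- qs(sweep(Vm, 2, lam_i, "*"))
    bt <- qs(Vm * fit$lambda$lam)
    out$volume_individual_lambda <-
      data.frame(time = grid, p10 = bi[, 1], p50 = bi[, 2], p90 = bi[, 3])
    out$volume_typical_lambda <-
      data.frame(time = grid, p10 = bt[, 1], p50 = bt[, 2], p90 = bt[, 3])
  }
  out
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Tumor growth kinetics analysis report\n")
  print(summary(x$fit))
  if (length(x$errors))
    for (nm in names(x$errors))
      cat(sprintf("stage [%s] failed: %s\n", nm, x$errors[[nm]]))
  invisible(x)
}

#' Serialize an analysis report
#'
#' Writes the report as JSON (`<stem>.json`), the parameter table as TSV
#' (`<stem>_table1.tsv`) and the typical trajectories as CSV
#' (`<stem>_typical.csv`). The JSON carries no timestamp, so identical
#' configs give byte-identical files.
#'
#' @param report an [run_analysis()] report.
#' @param stem output path stem.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, stem) {
  stopifnot(inherits(report, "analysis_report"))
  pj <- paste0(stem, ".json")
  pt <- paste0(stem, "_table1.tsv")
  pc <- paste0(stem, "_typical.csv")
  keep <- report[c("table1", "sigma", "lambda", "stroma_percent",
                   "typical", "bands", "converged", "provenance")]
  jsonlite::write_json(keep, pj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  utils::write.table(report$table1, pt, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.csv(report$typical, pc, row.names = FALSE)
  invisible(c(json = pj, table1 = pt, typical = pc))
}

#' Tabulate the typical model dynamics
#'
#' Evaluates the proliferative, necrotic and total compartments of the
#' typical animal on a day grid, in signal units (photons/sec) and converted
#' to cm^3; the caliper-scale column applies the lambda of `params`.
#'
#' @param params a [growth_params()] object.
#' @param grid ascending day grid.
#' @param conv a [conversion_constants()] object.
#' @return A data frame with columns `time`, `P_signal`, `N_signal`,
#'   `V_signal`, `P_cm3`, `N_cm3`, `V_cm3`, `V_caliper_cm3`.
#' @export
simulate_typical <- function(params, grid = seq(0, 43, by = 0.5),
                             conv = conversion_constants()) {
  tr <- growth_trajectory(params, grid)
  data.frame(time = tr$time,
             P_signal = tr$P, N_signal = tr$N, V_signal = tr$V,
             P_cm3 = signal_to_volume_cm3(tr$P, conv),
             N_cm3 = signal_to_volume_cm3(tr$N, conv),
             V_cm3 = signal_to_volume_cm3(tr$V, conv),
             V_caliper_cm3 = params$lam * signal_to_volume_cm3(tr$V, conv))
}

#' Parameter-recovery experiment
#'
#' Runs `R` independent simulate-then-fit cycles from a known design and
#' summarizes how well the population parameters are recovered: per-replicate
#' estimates, relative errors against the generating truth, and pass/fail
#' against configurable relative-error bands on the median.
#'
#' @param R number of replicates.
#' @param design a [cohort_design()] (its typical values are the truth).
#' @param seed_base replicate `r` uses seed `seed_base + r - 1`.
#' @param control a [saem_control()].
#' @param bands named relative-error bands for the median recovered fixed
#'   effects (defaults `a` 0.15, `K` 0.25, `lam` 0.10).
#' @return An object of class `"recovery_experiment"`: `estimates` (one row
#'   per replicate), `median_rel_error`, `pass` (named logicals),
#'   `convergence_rate`. Replicate failures are recorded, not fatal, but an
#'   error is raised if fewer than 80\% of replicates converge.
#' @export
recovery_experiment <- function(R = 5, design = cohort_design(),
                                seed_base = 1L,
                                control = saem_control(),
                                bands = c(a = 0.15, K = 0.25, lam = 0.10)) {
  rows <- vector("list", R)
  for (r in seq_len(R)) {
    seed <- as.integer(seed_base) + r - 1L
    est <- tryCatch({
      d <- simulate_cohort(design, seed = seed)
      f <- saem_fit(d, control = control, seed = seed,
                    injected_cells = design$injected_cells,
                    conv = conversion_constants(design$photons_per_cell,
                                                design$cells_per_cm3))
      lam <- NA_real_
      if (design$caliper) {
        f <- fit_lambda(f, seed = seed)
        lam <- f$lambda$lam
      }
      data.frame(replicate = r, seed = seed,
                 a = unname(f$theta_mu["a"]), K = unname(f$theta_mu["K"]),
                 lam = lam,
                 cv_a = unname(f$cv_percent["a"]),
                 cv_K = unname(f$cv_percent["K"]),
                 converged = f$converged, failed = FALSE)
    }, error = function(e)
      data.frame(replicate = r, seed = seed, a = NA, K = NA, lam = NA,
                 cv_a = NA, cv_K = NA, converged = FALSE, failed = TRUE))
    rows[[r]] <- est
  }
  est <- do.call(rbind, rows)
  conv_rate <- mean(est$converged & !est$failed)
  if (conv_rate < 0.8)
    stop(sprintf("only %.0f%% of replicates converged", 100 * conv_rate))
  truth <- c(a = design$a, K = design$K, lam = design$lam)
  med_err <- vapply(names(truth), function(p)
    stats::median(abs(est[[p]] - truth[[p]]) / truth[[p]], na.rm = TRUE),
    numeric(1))
  if (!design$caliper) med_err["lam"] <- NA_real_
  pass <- med_err[names(bands)] <= bands
  structure(list(estimates = est, truth = truth,
                 median_rel_error = med_err, bands = bands, pass = pass,
                 convergence_rate = conv_rate),
            class = "recovery_experiment")
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat(sprintf("Recovery experiment: %d replicates, %.0f%% converged\n",
              nrow(x$estimates), 100 * x$convergence_rate))
  for (p in names(x$median_rel_error))
    cat(sprintf("  %-4s truth %.4g, median rel. error %.1f%%%s\n",
                p, x$truth[[p]], 100 * x$median_rel_error[[p]],
                if (p %in% names(x$pass))
                  if (isTRUE(x$pass[[p]])) "  [within band]"
                  else "  [OUTSIDE band]"
                else ""))
  invisible(x)
}
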