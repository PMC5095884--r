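#' Cells-to-light calibration plate
#'
#' Container for an in vitro calibration experiment: wells seeded at known
#' cell densities whose photon flux is read on the imager. The design spans
#' several decades (typically 1e2 to 1e6 cells/well) so the per-cell light
#' output can be estimated by regression through the origin.
#'
#' @param cells cells seeded per well, positive.
#' @param signal measured photon flux per well, photons/sec, non-negative.
#' @param replicate optional replicate identifier per well.
#' @return An object of class `"calibration_plate"` (a data frame with
#'   columns `cells`, `signal`, `replicate`).
#' @export
calibration_plate <- function(cells, signal, replicate = NULL) {
  if (length(cells) != length(signal))
    stop("'cells' and 'signal' must have equal length")
  if (any(cells <= 0)) stop("'cells' must be positive")
  if (any(signal < 0)) stop("'signal' must be non-negative")
  if (length(unique(cells)) < 3L)
    stop("calibration needs at least 3 distinct seeding densities")
  if (is.null(replicate)) replicate <- rep(1L, length(cells))
  structure(data.frame(cells = cells, signal = signal,
                       replicate = replicate),
            class = c("calibration_plate", "data.frame"))
}

#' Read a calibration plate from CSV
#'
#' Expects columns `cells`, `signal` and optionally `replicate`.
#'
#' @param path path to a CSV file.
#' @return A [calibration_plate()] object.
#' @export
read_calibration_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cells", "signal") %in% names(d)))
    stop("CSV must contain columns 'cells' and 'signal'")
  calibration_plate(d$cells, d$signal,
                    if ("replicate" %in% names(d)) d$replicate else NULL)
}

#' Fit the cells-to-light ratio by regression through the origin
#'
#' Fits `signal = b * cells` by least squares without an intercept
#' (`b = sum(x*y) / sum(x^2)`): zero cells must mean zero signal. The reported
#' `r_squared` is the uncentered coefficient of determination
#' `1 - SS_res / sum(y^2)`, the convention consistent with forcing the
#' intercept; it is not comparable with the centered r-squared of a model
#' with intercept.
#'
#' @param plate a [calibration_plate()] object.
#' @return An object of class `"light_calibration"` with fields `slope`
#'   (photons/sec per cell), `r_squared`, `n_wells`.
#' @examples
#' plate <- calibration_plate(cells = 10^(2:6), signal = 88.4 * 10^(2:6))
#' fit_cells_to_light(plate)
#' @export
fit_cells_to_light <- function(plate) {
  stopifnot(inherits(plate, "calibration_plate"))
  if (all(plate$signal == 0))
    stop("all signals are zero; cannot calibrate")
  x <- plate$cells
  y <- plate$signal
  slope <- sum(x * y) / sum(x^2)
  ss_res <- sum((y - slope * x)^2)
  r2 <- 1 - ss_res / sum(y^2)
  structure(list(slope = slope, r_squared = r2, n_wells = length(x)),
            class = "light_calibration")
}

#' @export
print.light_calibration <- function(x, ...) {
  cat("Cells-to-light calibration (through-origin least squares)\n")
  cat(sprintf("  slope = %.4g photons/sec per cell (uncentered r^2 = %.4f, %d wells)\n",
              x$slope, x$r_squared, x$n_wells))
  invisible(x)
}

#' @export
coef.light_calibration <- function(object, ...) {
  c(slope = object$slope)
}

#' @export
predict.light_calibration <- function(object, cells, ...) {
  if (any(cells < 0)) stop("'cells' must be non-negative")
  object$slope * cells
}

#' Build conversion constants from a calibration fit
#'
#' Packages the fitted per-cell light output with a cell packing density
#' (default 1e9 cells per cm^3) into the [conversion_constants()] consumed by
#' the growth model.
#'
#' @param fit a `"light_calibration"` object (or a bare positive slope).
#' @param cells_per_cm3 cells per cm^3.
#' @return A [conversion_constants()] object.
#' @export
make_conversion <- function(fit, cells_per_cm3 = 1e9) {
  slope <- if (inherits(fit, "light_calibration")) fit$slope else fit
  if (!is.numeric(slope) || length(slope) != 1L || slope <= 0)
    stop("calibration slope must be a single positive number")
  conversion_constants(photons_per_cell = slope,
                       cells_per_cm3 = cells_per_cm3)
}
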