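#' Structural parameters of the proliferative/necrotic growth model
#'
#' Bundles the parameters of the two-compartment tumor growth model: the
#' proliferative compartment \eqn{P(t)} (bioluminescent, living cells) grows
#' logistically with proliferation rate \eqn{a} towards a micro-environment
#' carrying capacity \eqn{K}, and cells displaced by competition accumulate in
#' a necrotic compartment \eqn{N(t)} at rate \eqn{a P^2 / K}. Both compartments
#' contribute to the caliper-measured volume up to a proportionality constant
#' \eqn{\lambda}; only \eqn{P} emits light.
#'
#' @param a proliferation rate, day^-1, strictly positive.
#' @param K carrying capacity of the proliferative signal, photons/sec,
#'   strictly positive.
#' @param P0 initial proliferative signal (injected cell burden expressed in
#'   photons/sec), strictly positive and below `K`.
#' @param lam caliper-volume proportionality constant (dimensionless,
#'   strictly positive). Values above 1 are read as non-tumor-cell (stromal)
#'   volume; see [stroma_fraction()].
#'
#' @return An object of class `"growth_params"`: a named list with fields
#'   `a`, `K`, `P0`, `lam`.
#' @seealso [prolif_signal()], [necrotic_signal()], [total_signal()],
#'   [simulate_ode()], [cell_cycle_length()]
#' @examples
#' growth_params(a = 0.399, K = 4.35e9, P0 = 1.5e5 * 88.4, lam = 2.25)
#' @export
growth_params <- function(a, K, P0, lam = 1) {
  for (nm in c("a", "K", "P0", "lam")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm))
  }
  if (P0 >= K)
    stop("'P0' must be strictly below the carrying capacity 'K'")
  structure(list(a = a, K = K, P0 = P0, lam = lam),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Tumor growth model parameters (logistic + necrotic compartment)\n")
  cat(sprintf("  a   = %.4g day^-1   (cell cycle length ~ %.3g days)\n",
              x$a, cell_cycle_length(x$a)))
  cat(sprintf("  K   = %.4g photons/sec\n", x$K))
  cat(sprintf("  P0  = %.4g photons/sec\n", x$P0))
  cat(sprintf("  lam = %.4g\n", x$lam))
  invisible(x)
}

#' Cell cycle length implied by the proliferation rate
#'
#' Interprets the logistic proliferation rate as exponential doubling at low
#' density, giving a nominal cell cycle length `log(2)/a`. This is a derived
#' convenience reading, not a fitted quantity.
#'
#' @param a proliferation rate, day^-1, positive.
#' @return Cell cycle length in days.
#' @export
cell_cycle_length <- function(a) {
  if (any(a <= 0)) stop("'a' must be positive")
  log(2) / a
}

## log(1 + (P0/K) * (exp(a t) - 1)) computed without forming exp(a t).
## Writing S(t) = (1 - P0/K) + (P0/K) e^{a t}, log S is a two-term
## log-sum-exp, stable for arbitrarily large a*t.
.log_logistic_denom <- function(t, a, K, P0) {
  la <- log1p(-P0 / K)        # log(1 - P0/K), P0 < K guaranteed
  lb <- log(P0 / K) + a * t
  m <- pmax(la, lb)
  m + log(exp(la - m) + exp(lb - m))
}

.check_time <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("time 't' must be finite and non-negative (days post-graft)")
}

#' Proliferative (bioluminescent) signal of the logistic growth model
#'
#' Closed-form solution of \eqn{dP/dt = a P (1 - P/K)}, \eqn{P(0) = P_0}:
#' \deqn{P(t) = \frac{K P_0 e^{a t}}{K + P_0 (e^{a t} - 1)}.}
#' Evaluated in the log domain so that arbitrarily large `a * t` (well beyond
#' 700) never overflows.
#'
#' @param t time in days post-graft, non-negative; vectorized.
#' @param params a [growth_params()] object.
#' @return Proliferative signal in photons/sec, same length as `t`.
#' @export
prolif_signal <- function(t, params) {
  stopifnot(inherits(params, "growth_params"))
  .check_time(t)
  ## P(t) = P0 e^{a t} / S(t) = exp(log P0 + a t - log S)
  exp(log(params$P0) + params$a * t -
        .log_logistic_denom(t, params$a, params$K, params$P0))
}

#' Necrotic signal-equivalent of the growth model
#'
#' Closed-form solution of \eqn{dN/dt = a P(t)^2 / K}, \eqn{N(0) = 0}:
#' \deqn{N(t) = K \log\left(1 + \frac{P_0}{K}(e^{a t} - 1)\right) - P(t) + P_0.}
#' `N` is expressed in the same signal-equivalent units as `P` (photons/sec a
#' living cell of that mass would emit); necrotic tissue itself emits no light.
#'
#' @inheritParams prolif_signal
#' @return Necrotic signal-equivalent in photons/sec, non-decreasing in `t`.
#' @export
necrotic_signal <- function(t, params) {
  stopifnot(inherits(params, "growth_params"))
  .check_time(t)
  n <- params$K * .log_logistic_denom(t, params$a, params$K, params$P0) -
    prolif_signal(t, params) + params$P0
  pmax(n, 0)  # guards the t = 0 endpoint against roundoff below zero
}

#' Total tumor burden (proliferative + necrotic) in signal units
#'
#' \eqn{V(t) = P(t) + N(t) = K \log S(t) + P_0}. The curve is exponential at
#' early times and asymptotically linear with slope \eqn{a K}, the transition
#' occurring as the proliferative compartment saturates.
#'
#' @inheritParams prolif_signal
#' @return Total signal-equivalent burden in photons/sec.
#' @export
total_signal <- function(t, params) {
  stopifnot(inherits(params, "growth_params"))
  .check_time(t)
  params$K * .log_logistic_denom(t, params$a, params$K, params$P0) + params$P0
}

#' Numerically integrate the growth ODE system
#'
#' Adaptive-step integration (lsoda via \pkg{deSolve}) of
#' \eqn{dP/dt = a P (1 - P/K)}, \eqn{dN/dt = a P^2/K} from \eqn{(P_0, 0)}.
#' Serves as the numerical oracle for the closed forms in [prolif_signal()]
#' and [necrotic_signal()]; both routes agree to relative tolerance 1e-6.
#'
#' @param params a [growth_params()] object.
#' @param times ascending vector of days, `times[1] >= 0`.
#' @param rtol,atol relative/absolute integration tolerances.
#' @return A `data.frame` of class `"growth_trajectory"` with columns `time`,
#'   `P`, `N`, `V` (photons/sec; `V = P + N`).
#' @export
simulate_ode <- function(params, times, rtol = 1e-10, atol = 1e-4) {
  stopifnot(inherits(params, "growth_params"))
  if (length(times) < 1L || any(!is.finite(times)) || times[1] < 0 ||
      is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly ascending and start at or after day 0")
  if (length(times) == 1L && times == 0) {   # no integration needed
    out <- data.frame(time = 0, P = params$P0, N = 0, V = params$P0)
    class(out) <- c("growth_trajectory", "data.frame")
    return(out)
  }
  grid <- times
  added0 <- FALSE
  if (grid[1] > 0) {        # lsoda integrates from the first grid point
    grid <- c(0, grid)
    added0 <- TRUE
  }
  rhs <- function(t, y, p) {
    dP <- p$a * y[1] * (1 - y[1] / p$K)
    dN <- p$a * y[1]^2 / p$K
    list(c(dP, dN))
  }
  sol <- deSolve::lsoda(c(P = params$P0, N = 0), grid, rhs, params,
                        rtol = rtol, atol = atol)
  sol <- as.data.frame(sol)
  if (added0) sol <- sol[-1L, , drop = FALSE]
  out <- data.frame(time = times, P = sol$P, N = pmax(sol$N, 0))
  out$V <- out$P + out$N
  class(out) <- c("growth_trajectory", "data.frame")
  out
}

#' Evaluate the closed-form trajectory on a time grid
#'
#' Convenience wrapper tabulating [prolif_signal()], [necrotic_signal()] and
#' [total_signal()] into the same `"growth_trajectory"` layout as
#' [simulate_ode()].
#'
#' @inheritParams simulate_ode
#' @return A `"growth_trajectory"` data frame (columns `time`, `P`, `N`, `V`).
#' @export
growth_trajectory <- function(params, times) {
  stopifnot(inherits(params, "growth_params"))
  if (any(diff(times) <= 0)) stop("'times' must be strictly ascending")
  out <- data.frame(time = times,
                    P = prolif_signal(times, params),
                    N = necrotic_signal(times, params))
  out$V <- out$P + out$N
  class(out) <- c("growth_trajectory", "data.frame")
  out
}

#' Conversion constants between photon flux, cell number and volume
#'
#' @param photons_per_cell photons/sec emitted per living cell (default 88.4,
#'   the in vitro calibration slope; see [fit_cells_to_light()]).
#' @param cells_per_cm3 cell packing density, cells per cm^3 (default 1e9).
#' @return An object of class `"conversion_constants"`.
#' @export
conversion_constants <- function(photons_per_cell = 88.4,
                                 cells_per_cm3 = 1e9) {
  if (photons_per_cell <= 0 || cells_per_cm3 <= 0)
    stop("conversion constants must be positive")
  structure(list(photons_per_cell = photons_per_cell,
                 cells_per_cm3 = cells_per_cm3),
            class = "conversion_constants")
}

#' @export
print.conversion_constants <- function(x, ...) {
  cat(sprintf("Conversion: %.4g photons/sec per cell, %.4g cells per cm^3\n",
              x$photons_per_cell, x$cells_per_cm3))
  invisible(x)
}

#' Convert a bioluminescence signal to a cell-mass volume
#'
#' Divides the photon flux by the per-cell light output and the cell packing
#' density: `signal / photons_per_cell / cells_per_cm3`.
#'
#' @param signal photon flux, photons/sec, non-negative; vectorized.
#' @param conv a [conversion_constants()] object.
#' @return Volume in cm^3.
#' @export
signal_to_volume_cm3 <- function(signal, conv = conversion_constants()) {
  stopifnot(inherits(conv, "conversion_constants"))
  if (any(signal < 0)) stop("'signal' must be non-negative")
  signal / conv$photons_per_cell / conv$cells_per_cm3
}

#' Convert a cell-mass volume to the bioluminescence signal it would emit
#'
#' Exact inverse of [signal_to_volume_cm3()].
#'
#' @param volume volume in cm^3, non-negative; vectorized.
#' @inheritParams signal_to_volume_cm3
#' @return Photon flux in photons/sec.
#' @export
volume_cm3_to_signal <- function(volume, conv = conversion_constants()) {
  stopifnot(inherits(conv, "conversion_constants"))
  if (any(volume < 0)) stop("'volume' must be non-negative")
  volume * conv$photons_per_cell * conv$cells_per_cm3
}

#' Model-predicted caliper volume
#'
#' The caliper measures the whole palpable mass — tumor cells (living plus
#' necrotic) and stroma — so the model prediction is the converted total
#' burden scaled by the proportionality constant \eqn{\lambda}:
#' `lam * signal_to_volume_cm3(total_signal(t))`.
#'
#' @inheritParams prolif_signal
#' @param conv a [conversion_constants()] object.
#' @return Predicted caliper volume in cm^3.
#' @export
predicted_caliper_volume <- function(t, params,
                                     conv = conversion_constants()) {
  params$lam * signal_to_volume_cm3(total_signal(t, params), conv)
}

#' Stromal fraction implied by the caliper proportionality constant
#'
#' If the caliper volume is `lam` times the cell-mass volume, the fraction of
#' the total volume not attributable to tumor cells is
#' \eqn{100 (1 - 1/\lambda)} percent.
#'
#' @param lam proportionality constant, `>= 1`.
#' @return Stromal fraction in percent.
#' @examples
#' stroma_fraction(2.25)  # 55.6% of the palpable volume is stroma
#' @export
stroma_fraction <- function(lam) {
  if (any(lam < 1))
    stop("'lam' below 1 would make the palpable volume smaller than the ",
         "cell mass it contains; not meaningful under this model")
  100 * (1 - 1 / lam)
}

#' Caliper tumor volume by the Carlsson formula
#'
#' `V = length * width^2 / 2` with both dimensions in cm. If `width` exceeds
#' `length` the two are swapped with a warning, since caliper operators record
#' the two axes inconsistently.
#'
#' @param length largest diameter, cm, positive.
#' @param width perpendicular diameter, cm, positive.
#' @return Volume in cm^3.
#' @export
carlsson_volume <- function(length, width) {
  if (any(length <= 0) || any(width <= 0))
    stop("caliper dimensions must be positive")
  swap <- width > length
  if (any(swap)) {
    warning("width > length for ", sum(swap),
            " measurement(s); axes swapped")
    tmp <- length[swap]
    length[swap] <- width[swap]
    width[swap] <- tmp
  }
  length * width^2 / 2
}
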