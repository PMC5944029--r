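# Unit conversions used throughout. Internal solver arithmetic is SI;
# user-facing quantities follow clinical convention (mm, mL/s, L/min, mmHg).

MMHG_PA <- 133.322387415

#' Unit conversion helpers
#'
#' Flow between L/min, mL/s and m^3/s; lengths between mm and m; pressure
#' between mmHg and Pa (1 mmHg = 133.322 Pa).
#'
#' @param x numeric vector in the source unit.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
lmin_to_mls <- function(x) x * 1000 / 60
#' @rdname units
#' @export
mls_to_lmin <- function(x) x * 60 / 1000
#' @rdname units
#' @export
mls_to_m3s <- function(x) x * 1e-6
#' @rdname units
#' @export
m3s_to_mls <- function(x) x * 1e6
#' @rdname units
#' @export
mm_to_m <- function(x) x * 1e-3
#' @rdname units
#' @export
mmhg_to_pa <- function(x) x * MMHG_PA
#' @rdname units
#' @export
pa_to_mmhg <- function(x) x / MMHG_PA

#' Trapezoidal cycle integral of a periodic series
#'
#' Integrates a periodic signal sampled on a uniform grid covering one period
#' with the endpoint excluded (`t_i = (i-1) T / n`). The trapezoid closing the
#' cycle wraps back to the first sample.
#'
#' @param values numeric vector, one sample per grid point.
#' @param period period length in the time unit of interest.
#' @return the integral over one full period.
#' @keywords internal
cycle_integral <- function(values, period) {
  n <- length(values)
  dt <- period / n
  # uniform wrapped trapezoid == dt * sum for a periodic grid
  sum((values + values[c(2:n, 1)]) / 2) * dt
}

cycle_mean <- function(values, period) cycle_integral(values, period) / period

stopf <- function(...) stop(sprintf(...), call. = FALSE)
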