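#' Blood assist index (BAI)
#'
#' Fraction of total perfusion supplied by the ECMO circuit over one cardiac
#' cycle. Two readings are implemented:
#'
#' * `instantaneous_ratio`: the cycle average of the pointwise ratio
#'   `F_E / (F_E + F_C)` (trapezoidal integration over one period). Samples
#'   where both flows are zero contribute 0, so a pure cardiac run scores
#'   exactly 0.
#' * `mean_flow_ratio`: the ratio of cycle-mean flows,
#'   `mean(F_E) / (mean(F_E) + mean(F_C))`.
#'
#' With a cardiac waveform that is zero in diastole the instantaneous reading
#' is bounded below by the diastolic fraction of the cycle whenever any ECMO
#' flow is present; the mean-flow reading covers the whole of \[0,1\] and is
#' the package default.
#'
#' @param ecmo,cardiac [flow_waveform()]s on the same sampling grid.
#' @param mode `"mean_flow_ratio"` (default) or `"instantaneous_ratio"`.
#' @return the index as a fraction in \[0,1\].
#' @export
bai <- function(ecmo, cardiac,
                mode = c("mean_flow_ratio", "instantaneous_ratio")) {
  mode <- match.arg(mode)
  if (!inherits(ecmo, "flow_waveform") || !inherits(cardiac, "flow_waveform"))
    stopf("`ecmo` and `cardiac` must be flow_waveform objects")
  if (length(ecmo$values) != length(cardiac$values) ||
      abs(ecmo$period - cardiac$period) > 1e-12)
    stopf("ECMO and cardiac waveforms must share sampling grid and period")
  if (mode == "mean_flow_ratio") {
    me <- waveform_mean(ecmo); mc <- waveform_mean(cardiac)
    if (me + mc == 0) return(0)
    return(me / (me + mc))
  }
  tot <- ecmo$values + cardiac$values
  ratio <- ifelse(tot == 0, 0, ecmo$values / tot)
  val <- cycle_mean(ratio, ecmo$period)
  min(max(val, 0), 1)
}

#' Upper/lower flow-split ratios
#'
#' `r_up` is the fraction of total perfusion delivered to the brain and upper
#' limbs (innominate + left common carotid + left subclavian); `r_down` the
#' fraction delivered to the lower limbs (left + right femoral).
#'
#' @param outlet_mean_flows named numeric vector or list of cycle-mean outlet
#'   flows containing keys `IA`, `LCCA`, `LSA`, `LFA`, `RFA` (any flow unit,
#'   consistent with `aorta_total`).
#' @param aorta_total total perfusion in the same unit (> 0).
#' @return list with fractions `r_up` and `r_down`.
#' @export
flow_ratios <- function(outlet_mean_flows, aorta_total) {
  if (!is.numeric(aorta_total) || aorta_total <= 0)
    stopf("`aorta_total` must be positive")
  q <- unlist(outlet_mean_flows)
  need <- c("IA", "LCCA", "LSA", "LFA", "RFA")
  missing <- setdiff(need, names(q))
  if (length(missing))
    stopf("outlet_mean_flows is missing outlet(s): %s",
          paste(missing, collapse = ", "))
  list(r_up = unname(q["IA"] + q["LCCA"] + q["LSA"]) / aorta_total,
       r_down = unname(q["LFA"] + q["RFA"]) / aorta_total)
}

#' Harmonic index (HI) of pulsatility
#'
#' The fraction of a waveform's one-sided discrete Fourier amplitude spectrum
#' carried by the nonzero-frequency harmonics:
#' `HI = sum_{n>=1} T[n w0] / sum_{n>=0} T[n w0]`, with the sums truncated at
#' the Nyquist harmonic of the sampling grid. HI is 0 for a steady nonzero
#' signal and 1 for a zero-mean oscillation. An identically zero signal maps
#' to 0 by convention (degenerate input, keeps BAI-extreme sweeps finite).
#'
#' One-sided amplitudes are `|X_0|/N` for the mean, `2|X_n|/N` for
#' `0 < n < N/2`, and `|X_{N/2}|/N` at Nyquist for even N.
#'
#' @param w a [flow_waveform()] or a numeric vector (>= 64 samples).
#' @return HI in \[0,1\].
#' @export
harmonic_index <- function(w) {
  v <- if (inherits(w, "flow_waveform")) w$values else as.numeric(w)
  n <- length(v)
  if (n < 64L) stopf("harmonic_index needs at least 64 samples")
  if (all(v == 0)) return(0)
  X <- stats::fft(v)
  half <- floor(n / 2)
  amp <- Mod(X[seq_len(half + 1L)]) / n
  scale <- rep(2, half + 1L)
  scale[1L] <- 1
  if (n %% 2L == 0L) scale[half + 1L] <- 1
  amp <- amp * scale
  total <- sum(amp)
  if (total == 0) return(0)
  sum(amp[-1L]) / total
}

#' Oscillatory shear index (OSI)
#'
#' `OSI = 0.5 * (1 - |int tau dt| / int |tau| dt)` over one cycle, trapezoidal
#' integration on the periodic grid. 0 marks purely unidirectional wall shear,
#' 0.5 purely oscillatory shear with zero net. An identically zero series maps
#' to 0 by convention.
#'
#' @param wss signed wall-shear-stress series in Pa: numeric vector sampled on
#'   a uniform one-period grid.
#' @param period cycle length in seconds (only the ratio matters; default 0.8).
#' @return OSI in \[0, 0.5\].
#' @export
osi <- function(wss, period = 0.8) {
  wss <- as.numeric(wss)
  if (!all(is.finite(wss))) stopf("WSS series must be finite")
  denom <- cycle_integral(abs(wss), period)
  if (denom == 0) return(0)
  val <- 0.5 * (1 - abs(cycle_integral(wss, period)) / denom)
  min(max(val, 0), 0.5)
}

#' Time-and-station averaged wall shear stress over a region
#'
#' Averages `|tau_w|` over one cycle and over the stations of a region of a
#' solved network (the 1D analogue of a surface-averaged WSS; the model has
#' no inner/outer wall distinction, so the station value is the section
#' average).
#'
#' @param solution a [reconstruct_cycle()] result.
#' @param region integer station indices (rows of `solution$stations`) or a
#'   region name from [default_regions()].
#' @return mean WSS magnitude in Pa.
#' @export
regional_mean_wss <- function(solution, region) {
  if (is.character(region) && length(region) == 1L)
    region <- default_regions(solution)[[region]]
  region <- as.integer(region)
  if (length(region) == 0L) stopf("`region` must name at least one station")
  if (any(region < 1L | region > ncol(solution$station_wss)))
    stopf("region station index out of range")
  mean(colMeans(abs(solution$station_wss[, region, drop = FALSE])))
}

#' Sample Pearson correlation
#'
#' Plain sample Pearson r with explicit domain checks; errors (rather than
#' returning NA) when either sequence has zero variance, since a correlation
#' is then undefined.
#'
#' @param x,y numeric sequences of equal length >= 3.
#' @return r in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L)
    stopf("`x` and `y` must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("pearson_r is undefined for a zero-variance sequence")
  stats::cor(x, y)
}
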