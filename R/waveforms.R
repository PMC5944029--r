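#' Periodic volumetric flow waveform
#'
#' Container for one cardiac cycle of volumetric flow, sampled on a uniform
#' grid `t_i = (i-1) * period / n` (endpoint excluded, so the grid tiles the
#' period exactly).
#'
#' @param values numeric vector of flow samples in mL/s; at least 64 samples.
#' @param period cycle length in seconds (default 0.8 s).
#' @param times optional explicit sample times; must match the uniform grid.
#' @return an object of class `flow_waveform` with fields `times` (s),
#'   `values` (mL/s) and `period` (s).
#' @export
flow_waveform <- function(values, period = 0.8, times = NULL) {
  if (!is.numeric(period) || length(period) != 1L || period <= 0)
    stopf("`period` must be a single positive number, got %s", format(period))
  values <- as.numeric(values)
  n <- length(values)
  if (n < 64L)
    stopf("a flow waveform needs at least 64 samples, got %d", n)
  if (!all(is.finite(values)))
    stopf("flow waveform values must all be finite")
  grid <- seq(0, period, length.out = n + 1L)[seq_len(n)]
  if (!is.null(times)) {
    times <- as.numeric(times)
    if (length(times) != n || any(diff(times) <= 0))
      stopf("`times` must be strictly increasing and match `values` in length")
    if (max(abs(times - grid)) > 1e-9 * period)
      stopf("`times` must be the uniform one-period grid (endpoint excluded)")
  }
  structure(list(times = grid, values = values, period = period),
            class = "flow_waveform")
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf(
    "<flow_waveform> %d samples over %.3g s; mean %.3f L/min, peak %.3f L/min\n",
    length(x$values), x$period, mls_to_lmin(waveform_mean(x)),
    mls_to_lmin(max(x$values))))
  invisible(x)
}

#' Cycle-averaged flow of a waveform
#'
#' @param w a [flow_waveform()].
#' @param units `"mL_s"` (default) or `"L_min"`.
#' @return the trapezoidal time average over one period.
#' @export
waveform_mean <- function(w, units = c("mL_s", "L_min")) {
  units <- match.arg(units)
  m <- cycle_mean(w$values, w$period)
  if (units == "L_min") mls_to_lmin(m) else m
}

check_waveform_args <- function(period, n_samples) {
  if (!is.numeric(period) || length(period) != 1L || period <= 0)
    stopf("`period` must be a single positive number")
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 64)
    stopf("`n_samples` must be at least 64, got %s", format(n_samples))
}

#' Parametric cardiac ejection waveform
#'
#' Half-sine systolic ejection over the systolic window, zero diastolic flow.
#' A parametric stand-in for a lumped-parameter heart model inlet: the peak is
#' solved analytically so the continuous-time average equals `mean_flow`
#' (peak = mean * pi / (2 * systolic_fraction)).
#'
#' @param mean_flow target cycle-mean flow in L/min (>= 0).
#' @param period cycle length in seconds.
#' @param systolic_fraction fraction of the cycle spent in ejection, in (0,1).
#' @param n_samples samples per cycle (>= 64).
#' @return a [flow_waveform()] in mL/s.
#' @export
cardiac_waveform <- function(mean_flow, period = 0.8, systolic_fraction = 0.35,
                             n_samples = 800L) {
  check_waveform_args(period, n_samples)
  if (!is.numeric(mean_flow) || length(mean_flow) != 1L || mean_flow < 0)
    stopf("`mean_flow` must be a single non-negative number (L/min)")
  if (systolic_fraction <= 0 || systolic_fraction >= 1)
    stopf("`systolic_fraction` must lie strictly between 0 and 1")
  t <- seq(0, period, length.out = n_samples + 1L)[seq_len(n_samples)]
  t_sys <- systolic_fraction * period
  peak <- lmin_to_mls(mean_flow) * pi / (2 * systolic_fraction)
  v <- ifelse(t < t_sys, peak * sin(pi * t / t_sys), 0)
  flow_waveform(v, period)
}

#' Constant (non-pulsatile) ECMO cannula waveform
#'
#' @inheritParams cardiac_waveform
#' @return a [flow_waveform()] constant at `mean_flow`.
#' @export
ecmo_waveform <- function(mean_flow, period = 0.8, n_samples = 800L) {
  check_waveform_args(period, n_samples)
  if (!is.numeric(mean_flow) || length(mean_flow) != 1L || mean_flow < 0)
    stopf("`mean_flow` must be a single non-negative number (L/min)")
  flow_waveform(rep(lmin_to_mls(mean_flow), n_samples), period)
}

#' Perfusion specification for the boundary-condition composer
#'
#' @param target_bai blood assist index target as a fraction in \[0,1\].
#' @param total_mean_flow total perfusion (cardiac + ECMO means) in L/min.
#' @param period cycle length, s.
#' @param systolic_fraction systolic fraction of the cardiac waveform.
#' @param bai_mode `"mean_flow_ratio"` (default) or `"instantaneous_ratio"`;
#'   see [bai()] for the two readings of the index.
#' @param n_samples samples per cycle.
#' @return an object of class `perfusion_spec`.
#' @export
perfusion_spec <- function(target_bai, total_mean_flow = 5, period = 0.8,
                           systolic_fraction = 0.35,
                           bai_mode = c("mean_flow_ratio", "instantaneous_ratio"),
                           n_samples = 800L) {
  bai_mode <- match.arg(bai_mode)
  if (!is.numeric(target_bai) || length(target_bai) != 1L ||
      target_bai < 0 || target_bai > 1)
    stopf("`target_bai` must be a fraction in [0,1], got %s", format(target_bai))
  if (!is.numeric(total_mean_flow) || total_mean_flow <= 0)
    stopf("`total_mean_flow` must be positive (L/min)")
  structure(list(target_bai = target_bai, total_mean_flow = total_mean_flow,
                 period = period, systolic_fraction = systolic_fraction,
                 bai_mode = bai_mode, n_samples = as.integer(n_samples)),
            class = "perfusion_spec")
}

#' Compose cardiac and ECMO source waveforms for a target BAI
#'
#' Splits a fixed total perfusion between a pulsatile cardiac source and a
#' constant ECMO source so that the blood assist index of the pair, evaluated
#' in `spec$bai_mode`, equals `spec$target_bai`. The ECMO level is found by
#' bracketed scalar root-finding on \[0, total\]; the cardiac mean is the
#' complement.
#'
#' In `instantaneous_ratio` mode a zero-diastolic-flow cardiac shape forces
#' the index to at least the diastolic fraction of the cycle for any nonzero
#' ECMO flow, so targets strictly between 0 and that floor are infeasible and
#' raise an error naming the achievable range.
#'
#' @param spec a [perfusion_spec()].
#' @return list with elements `cardiac` and `ecmo`, both [flow_waveform()]s.
#' @export
compose_perfusion <- function(spec) {
  if (!inherits(spec, "perfusion_spec"))
    stopf("`spec` must be a perfusion_spec object")
  total <- spec$total_mean_flow
  mk <- function(ecmo_level) {
    list(
      cardiac = cardiac_waveform(total - ecmo_level, spec$period,
                                 spec$systolic_fraction, spec$n_samples),
      ecmo = ecmo_waveform(ecmo_level, spec$period, spec$n_samples))
  }
  bai_of <- function(ecmo_level) {
    p <- mk(ecmo_level)
    bai(p$ecmo, p$cardiac, mode = spec$bai_mode)
  }
  if (spec$target_bai == 0) return(mk(0))
  if (spec$target_bai == 1) return(mk(total))
  if (spec$bai_mode == "instantaneous_ratio") {
    floor_bai <- bai_of(1e-9 * total)
    if (spec$target_bai < floor_bai)
      stopf(paste0(
        "target_bai %.4g is infeasible in instantaneous_ratio mode with a ",
        "zero-diastolic cardiac shape: achievable values are 0 or ",
        "[%.4g, 1]"), spec$target_bai, floor_bai)
  }
  root <- stats::uniroot(function(e) bai_of(e) - spec$target_bai,
                         interval = c(0, total), tol = 1e-12)
  mk(root$root)
}

#' Read a one-period flow waveform from CSV
#'
#' Expects a header row `time_s,flow_mL_s` and exactly one period of samples
#' on a uniform grid with the endpoint excluded.
#'
#' @param path CSV file path.
#' @param period optional period; inferred as `n * dt` from the grid if NULL.
#' @return a [flow_waveform()].
#' @export
read_waveform_csv <- function(path, period = NULL) {
  d <- utils::read.csv(path)
  need <- c("time_s", "flow_mL_s")
  if (!all(need %in% names(d)))
    stopf("waveform CSV must have columns %s", paste(need, collapse = ", "))
  if (is.null(period)) {
    dt <- diff(d$time_s)
    if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * mean(dt))
      stopf("waveform CSV times must be a uniform increasing grid")
    period <- mean(dt) * nrow(d)
  }
  flow_waveform(d$flow_mL_s, period, times = d$time_s)
}

#' Write a flow waveform to CSV (`time_s,flow_mL_s`)
#'
#' @param w a [flow_waveform()].
#' @param path output file path.
#' @export
write_waveform_csv <- function(w, path) {
  utils::write.csv(data.frame(time_s = w$times, flow_mL_s = w$values),
                   path, row.names = FALSE)
  invisible(path)
}
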