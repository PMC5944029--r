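# Frequency-domain transmission-line solver. Each segment is a linear
# two-port in each harmonic; junctions impose single-valued pressure and
# complex flow conservation; outlets hold zero oscillatory pressure (a
# constant outlet pressure has no harmonics).

#' Ratio J1(z)/J0(z) for complex argument
#'
#' Evaluated by the modified Lentz continued fraction built from the Bessel
#' three-term recurrence. Converges for any complex z (J_n is the minimal
#' solution of the recurrence in n), and in particular along
#' `arg z = 3*pi/4` where the Womersley argument `i^{3/2} alpha` lives —
#' a regime where the naive power series cancels catastrophically.
#'
#' @param z complex scalar.
#' @param tol relative convergence tolerance.
#' @return complex scalar J1(z)/J0(z).
#' @keywords internal
besselj_ratio <- function(z, tol = 1e-15) {
  if (Mod(z) < 1e-14) return(z / 2)
  tiny <- 1e-300
  f <- complex(real = tiny); C <- f; D <- 0 + 0i
  for (m in seq_len(20000L)) {
    b <- 2 * m / z
    a <- if (m == 1L) 1 + 0i else -1 + 0i
    D <- b + a * D; if (Mod(D) < tiny) D <- complex(real = tiny)
    C <- b + a / C; if (Mod(C) < tiny) C <- complex(real = tiny)
    D <- 1 / D
    delta <- C * D
    f <- f * delta
    if (Mod(delta - 1) < tol) return(f)
  }
  stopf("besselj_ratio: continued fraction failed to converge at |z| = %g",
        Mod(z))
}

#' Womersley two-port parameters of a segment at one frequency
#'
#' Computes the per-harmonic transmission-line constants of a compliant tube:
#' the Womersley number `alpha = R sqrt(omega rho / mu)`, the wall-friction
#' factor `F10 = 2 J1(L)/(L J0(L))` with `L = i^{3/2} alpha`, the
#' longitudinal impedance per length `Z_l = i omega rho / (A (1 - F10))`
#' (which reduces to the Poiseuille value `128 mu / (pi D^4)` as alpha -> 0),
#' the compliance per length `C' = A / (rho c^2)` from the segment wave
#' speed, and from these the propagation constant `gamma = sqrt(Z_l i omega
#' C')` and characteristic impedance `Zc = Z_l / gamma`.
#'
#' @param segment a [vessel_segment()].
#' @param fluid a [fluid_props()].
#' @param angular_frequency omega in rad/s (> 0).
#' @return list with `alpha`, `F10`, `Zl` (Pa s/m^4), `gamma` (1/m),
#'   `Zc` (Pa s/m^3).
#' @export
womersley_twoport <- function(segment, fluid, angular_frequency) {
  if (!is.numeric(angular_frequency) || angular_frequency <= 0)
    stopf("angular_frequency must be positive")
  R <- mm_to_m(segment$diameter_mm) / 2
  A <- pi * R^2
  alpha <- R * sqrt(angular_frequency * fluid$density / fluid$viscosity)
  lam <- complex(modulus = alpha, argument = 3 * pi / 4)  # i^{3/2} alpha
  F10 <- (2 / lam) * besselj_ratio(lam)
  Zl <- 1i * angular_frequency * fluid$density / (A * (1 - F10))
  Cp <- A / (fluid$density * segment$wave_speed_m_s^2)
  gamma <- sqrt(Zl * 1i * angular_frequency * Cp)
  if (Re(gamma) < 0) gamma <- -gamma
  Zc <- Zl / gamma
  out <- list(alpha = alpha, F10 = F10, Zl = Zl, gamma = gamma, Zc = Zc)
  if (!all(vapply(out, function(x) all(is.finite(c(Re(x), Im(x)))), TRUE)))
    stopf("womersley_twoport overflow at alpha = %.3g; cap the harmonic count",
          alpha)
  out
}

# Two-port admittance entries for one segment at one harmonic:
# I_prox = y11 P_prox + y12 P_dist, I_dist = y21 P_prox + y22 P_dist,
# currents positive OUT of each node into the segment.
segment_admittance <- function(tp, length_m) {
  gl <- tp$gamma * length_m
  sh <- sinh(gl); ch <- cosh(gl)
  y <- ch / (tp$Zc * sh)
  m <- -1 / (tp$Zc * sh)
  c(y, m, m, y)
}

# Complex Fourier coefficient of harmonic k for each source waveform,
# normalised so q(t) = c0 + sum_k Re(c_k exp(i k w0 t)).
source_harmonic <- function(network, k) {
  vapply(network$sources, function(w) {
    X <- stats::fft(w$values)
    n <- length(w$values)
    mls_to_m3s(2 * X[k + 1L] / n)
  }, complex(1))
}

#' Single-harmonic network solve
#'
#' Assembles the per-segment two-port admittances at harmonic
#' `k` of the source fundamental and solves the complex nodal system with
#' zero oscillatory pressure at the outlets (or an optional terminal
#' impedance) and the sources' k-th Fourier coefficients as injections.
#'
#' @param network a [network_topology()] with sources attached.
#' @param fluid a [fluid_props()].
#' @param harmonic_index integer harmonic number k >= 1.
#' @param terminations optional named list mapping an outlet node to a
#'   complex terminal impedance Z_t (Pa s/m^3) so that `P = Z_t Q` there;
#'   outlets not named keep the zero-pressure condition.
#' @return list with complex `node_pressures_Pa`, and per-segment complex
#'   `flow_prox_m3_s`, `flow_dist_m3_s` (positive proximal-to-distal).
#' @export
solve_harmonic <- function(network, fluid, harmonic_index,
                           terminations = NULL) {
  k <- as.integer(harmonic_index)
  if (k < 1L) stopf("harmonic_index must be >= 1")
  if (!length(network$sources)) stopf("network has no sources")
  period <- network$sources[[1L]]$period
  nyq <- floor(length(network$sources[[1L]]$values) / 2)
  if (k > nyq)
    stopf("harmonic %d exceeds the Nyquist harmonic %d of the sampling grid",
          k, nyq)
  omega <- 2 * pi * k / period
  tps <- lapply(network$segments, womersley_twoport, fluid = fluid,
                angular_frequency = omega)
  seg_y <- Map(function(tp, s) segment_admittance(tp, mm_to_m(s$length_mm)),
               tps, network$segments)
  inj <- source_harmonic(network, k)
  dir <- stats::setNames(rep(0 + 0i, length(network$outlets)),
                         names(network$outlets))
  nodes <- network$nodes
  idx <- stats::setNames(seq_along(nodes), nodes)
  n <- length(nodes)
  A <- matrix(0 + 0i, n, n); b <- rep(0 + 0i, n)
  for (j in seq_along(network$segments)) {
    s <- network$segments[[j]]; y <- seg_y[[j]]
    ip <- idx[[s$from]]; id <- idx[[s$to]]
    A[ip, ip] <- A[ip, ip] + y[1]; A[ip, id] <- A[ip, id] + y[2]
    A[id, ip] <- A[id, ip] + y[3]; A[id, id] <- A[id, id] + y[4]
  }
  for (nm in names(inj)) b[idx[[nm]]] <- b[idx[[nm]]] + inj[[nm]]
  for (nm in names(dir)) {
    i <- idx[[nm]]
    zt <- terminations[[nm]]
    if (is.null(zt)) {
      A[i, ] <- 0 + 0i; A[i, i] <- 1 + 0i; b[i] <- 0 + 0i
    } else {
      # P - Z_t * Q_in = 0 where Q_in = -(y21 P_prox + y22 P_dist)
      s <- Find(function(s) s$to == nm, network$segments)
      if (is.null(s)) stopf("terminated outlet %s has no incoming segment", nm)
      y <- seg_y[[s$name]]
      A[i, ] <- 0 + 0i
      A[i, idx[[s$from]]] <- zt * y[3]
      A[i, i] <- 1 + zt * y[4]
      b[i] <- 0 + 0i
    }
  }
  p <- tryCatch(solve(A, b), error = function(e)
    stopf("singular harmonic assembly at k = %d: %s", k, conditionMessage(e)))
  p <- stats::setNames(as.vector(p), nodes)
  qp <- vapply(seq_along(network$segments), function(j) {
    s <- network$segments[[j]]; y <- seg_y[[j]]
    y[1] * p[[s$from]] + y[2] * p[[s$to]]
  }, complex(1))
  qd <- vapply(seq_along(network$segments), function(j) {
    s <- network$segments[[j]]; y <- seg_y[[j]]
    -(y[3] * p[[s$from]] + y[4] * p[[s$to]])
  }, complex(1))
  names(qp) <- names(qd) <- names(network$segments)
  list(node_pressures_Pa = p, flow_prox_m3_s = qp, flow_dist_m3_s = qd,
       twoports = tps, omega = omega)
}

# Station grid along one segment: local positions from the proximal end,
# uniform spacing, both ends always included.
segment_stations <- function(length_mm, spacing_mm) {
  x <- seq(0, length_mm, by = spacing_mm)
  if (abs(x[length(x)] - length_mm) > 1e-9) x <- c(x, length_mm)
  x
}

#' Reconstruct one cardiac cycle from the harmonic solutions
#'
#' Runs the steady solve and harmonics `1..n_harmonics`, evaluates pressure
#' and flow at uniformly spaced stations along every segment (two-port
#' propagation from the distal state within each segment), synthesises time
#' series by inverse Fourier summation, and computes signed wall shear
#' stress per station: steady part `4 mu Q / (pi R^3)` plus the per-harmonic
#' Womersley wall-gradient term
#' `tau_k = i omega rho R F10 Q_k / (2 A (1 - F10))`.
#'
#' @param network a [network_topology()] with sources attached.
#' @param fluid a [fluid_props()].
#' @param n_harmonics harmonics retained (default 20; must stay below the
#'   Nyquist harmonic of the source grid).
#' @param station_spacing_mm spacing of WSS/flow stations along each segment.
#' @return an object of class `cycle_solution`: `times`, matrices (time x
#'   station/node/segment) `node_pressures_mmHg`, `segment_flow_prox_mL_s`,
#'   `segment_flow_dist_mL_s`, `outlet_flows_mL_s`, `station_flow_mL_s`,
#'   `station_wss_Pa`, `station_pressure_mmHg`, the `stations` table (with
#'   trunk arc-length in mm from the aortic root where defined), and a
#'   `conservation` record of the worst junction residual.
#' @export
reconstruct_cycle <- function(network, fluid = fluid_props(),
                              n_harmonics = 20L, station_spacing_mm = 5) {
  if (!length(network$sources)) stopf("network has no sources")
  w0 <- network$sources[[1L]]
  nt <- length(w0$values)
  period <- w0$period
  K <- as.integer(n_harmonics)
  if (K >= floor(nt / 2))
    stopf("n_harmonics = %d exceeds the Nyquist harmonic of %d samples",
          K, nt)
  times <- w0$times
  mean_sol <- solve_mean(network, fluid)
  harm <- lapply(seq_len(K), function(k) solve_harmonic(network, fluid, k))

  segs <- network$segments
  nseg <- length(segs)
  # station bookkeeping ------------------------------------------------
  st_seg <- character(0); st_x <- numeric(0)
  for (s in segs) {
    x <- segment_stations(s$length_mm, station_spacing_mm)
    st_seg <- c(st_seg, rep(s$name, length(x)))
    st_x <- c(st_x, x)
  }
  arc <- rep(NA_real_, length(st_x))
  if (!is.null(network$trunk)) {
    offset <- 0
    for (nm in network$trunk) {
      sel <- st_seg == nm
      arc[sel] <- offset + st_x[sel]
      offset <- offset + segs[[nm]]$length_mm
    }
  }
  stations <- data.frame(segment = st_seg, x_mm = st_x, arc_mm = arc,
                         diameter_mm = vapply(st_seg, function(nm)
                           segs[[nm]]$diameter_mm, 0),
                         stringsAsFactors = FALSE)
  S <- nrow(stations)

  # steady fields ------------------------------------------------------
  p0 <- mmhg_to_pa(mean_sol$node_pressures_mmHg)
  q0 <- mls_to_m3s(mean_sol$segment_flows_mL_s)
  st_q0 <- q0[st_seg]
  st_p0 <- vapply(seq_len(S), function(i) {
    s <- segs[[st_seg[i]]]
    f <- st_x[i] / s$length_mm
    (1 - f) * p0[[s$from]] + f * p0[[s$to]]
  }, 0)
  st_R <- mm_to_m(stations$diameter_mm) / 2
  st_tau0 <- 4 * fluid$viscosity * st_q0 / (pi * st_R^3)

  # harmonic complex amplitudes per station ----------------------------
  stQ <- matrix(0 + 0i, S, K)   # flow amplitude, m^3/s
  stP <- matrix(0 + 0i, S, K)   # pressure amplitude, Pa
  stT <- matrix(0 + 0i, S, K)   # WSS amplitude, Pa
  ndP <- matrix(0 + 0i, length(network$nodes), K,
                dimnames = list(network$nodes, NULL))
  sgQp <- matrix(0 + 0i, nseg, K, dimnames = list(names(segs), NULL))
  sgQd <- matrix(0 + 0i, nseg, K, dimnames = list(names(segs), NULL))
  for (k in seq_len(K)) {
    h <- harm[[k]]
    ndP[, k] <- h$node_pressures_Pa[network$nodes]
    sgQp[, k] <- h$flow_prox_m3_s[names(segs)]
    sgQd[, k] <- h$flow_dist_m3_s[names(segs)]
    for (j in seq_len(nseg)) {
      s <- segs[[j]]; tp <- h$twoports[[j]]
      sel <- which(st_seg == s$name)
      sdist <- mm_to_m(s$length_mm - st_x[sel])        # distance to distal end
      pd <- h$node_pressures_Pa[[s$to]]
      qdist <- h$flow_dist_m3_s[[s$name]]
      ch <- cosh(tp$gamma * sdist); sh <- sinh(tp$gamma * sdist)
      stP[sel, k] <- ch * pd + tp$Zc * sh * qdist
      stQ[sel, k] <- sh / tp$Zc * pd + ch * qdist
      A <- pi * (mm_to_m(s$diameter_mm) / 2)^2
      wall <- 1i * h$omega * fluid$density * (mm_to_m(s$diameter_mm) / 2) *
        tp$F10 / (2 * A * (1 - tp$F10))
      stT[sel, k] <- wall * stQ[sel, k]
    }
  }

  # inverse synthesis ---------------------------------------------------
  E <- exp(1i * outer(times, 2 * pi * seq_len(K) / period))   # nt x K
  synth <- function(amp, base) {
    # amp: entities x K complex, base: entities-long steady part
    ts <- Re(E %*% t(amp))
    sweep(ts, 2, base, `+`)
  }
  station_flow <- synth(stQ, st_q0)
  station_p <- synth(stP, st_p0)
  station_wss <- synth(stT, st_tau0)
  node_p <- synth(ndP, p0[network$nodes])
  seg_qp <- synth(sgQp, q0[names(segs)])
  seg_qd <- synth(sgQd, q0[names(segs)])
  colnames(node_p) <- network$nodes
  colnames(seg_qp) <- colnames(seg_qd) <- names(segs)

  outlet_seg <- vapply(names(network$outlets), function(nm)
    Find(function(s) s$to == nm, segs)$name, "")
  outlet_flows <- seg_qd[, outlet_seg, drop = FALSE]
  colnames(outlet_flows) <- names(network$outlets)

  # junction closure ----------------------------------------------------
  total_mean <- sum(vapply(network$sources, function(w)
    abs(waveform_mean(w)), 0))
  # Junction closure is checked against the band-limited projection of each
  # source (harmonics 0..K): that is the inflow the truncated model actually
  # imposes, and the nodal solve conserves it exactly per harmonic. The
  # spectral tail of the raw source above K is recorded separately as the
  # band-limiting error; the 20-vs-40-harmonic convergence check bounds its
  # effect on the solution.
  bandlimit <- function(values) {
    X <- stats::fft(values)
    keep <- c(seq_len(K + 1L), if (K >= 1L) nt - seq_len(K) + 1L)
    X[-keep] <- 0 + 0i
    Re(stats::fft(X, inverse = TRUE)) / nt
  }
  internal <- setdiff(network$nodes, names(network$outlets))
  resid <- 0
  trunc_err <- 0
  for (nm in internal) {
    into <- vapply(segs, function(s) s$to == nm, TRUE)
    outof <- vapply(segs, function(s) s$from == nm, TRUE)
    src <- if (nm %in% names(network$sources)) {
      raw <- network$sources[[nm]]$values
      bl <- bandlimit(raw)
      trunc_err <- max(trunc_err, max(abs(raw - bl)))
      mls_to_m3s(bl)
    } else 0
    r <- src + rowSums(seg_qd[, into, drop = FALSE]) -
      rowSums(seg_qp[, outof, drop = FALSE])
    resid <- max(resid, max(abs(r)))
  }
  cons <- list(max_junction_residual_m3_s = resid,
               total_mean_source_m3_s = mls_to_m3s(total_mean),
               residual_fraction = if (total_mean > 0)
                 resid / mls_to_m3s(total_mean) else 0,
               source_bandlimit_error_fraction = if (total_mean > 0)
                 trunc_err / total_mean else 0)

  structure(list(
    times = times, period = period, n_harmonics = K,
    stations = stations,
    station_flow_mL_s = m3s_to_mls(station_flow),
    station_wss_Pa = station_wss,
    station_pressure_mmHg = pa_to_mmhg(station_p),
    node_pressures_mmHg = pa_to_mmhg(node_p),
    segment_flow_prox_mL_s = m3s_to_mls(seg_qp),
    segment_flow_dist_mL_s = m3s_to_mls(seg_qd),
    outlet_flows_mL_s = m3s_to_mls(outlet_flows),
    conservation = cons,
    network = network, fluid = fluid), class = "cycle_solution")
}

#' @export
print.cycle_solution <- function(x, ...) {
  cat(sprintf(
    "<cycle_solution> %d samples, %d harmonics, %d stations; worst junction residual %.3g%% of mean perfusion\n",
    length(x$times), x$n_harmonics, nrow(x$stations),
    100 * x$conservation$residual_fraction))
  invisible(x)
}

#' Default analysis regions of a solved network
#'
#' Maps the two reporting regions onto stations of the default geometry:
#' `aortic_arch` — trunk stations within 40 mm of the arch branch node
#' (distal ascending aorta and proximal descending aorta); `femoral_artery`
#' — stations within one femoral diameter of the iliac bifurcation on the
#' descending aorta and both femoral limbs.
#'
#' @param solution a [reconstruct_cycle()] result on [default_network()].
#' @return named list of integer station-index vectors.
#' @export
default_regions <- function(solution) {
  st <- solution$stations
  segs <- solution$network$segments
  need <- c("asc_aorta", "desc_aorta", "left_femoral", "rf_proximal")
  if (!all(need %in% names(segs)))
    stopf("default_regions needs the default network segment names")
  L_asc <- segs$asc_aorta$length_mm
  L_desc <- segs$desc_aorta$length_mm
  arch <- which((st$segment == "asc_aorta" & st$x_mm >= L_asc - 40) |
                  (st$segment == "desc_aorta" & st$x_mm <= 40))
  d_fem <- segs$left_femoral$diameter_mm
  femoral <- which((st$segment == "desc_aorta" & st$x_mm >= L_desc - d_fem) |
                     (st$segment == "left_femoral" & st$x_mm <= d_fem) |
                     (st$segment == "rf_proximal" & st$x_mm <= d_fem))
  list(aortic_arch = arch, femoral_artery = femoral)
}
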