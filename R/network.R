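#' Blood fluid properties
#'
#' @param density blood density in kg/m^3 (default 1050).
#' @param viscosity dynamic viscosity in kg/(m s) (default 0.0035).
#' @return an object of class `fluid_props`.
#' @export
fluid_props <- function(density = 1050, viscosity = 0.0035) {
  if (!is.numeric(density) || density <= 0 || !is.numeric(viscosity) ||
      viscosity <= 0)
    stopf("density and viscosity must be positive")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_props")
}

#' One arterial segment
#'
#' @param name segment identifier.
#' @param diameter_mm lumen diameter, mm.
#' @param length_mm segment length, mm.
#' @param wave_speed_m_s pulse wave speed, m/s — the wall-stiffness surrogate
#'   entering the transmission-line compliance (default 6).
#' @param from,to proximal (root-side) and distal node identifiers.
#' @return an object of class `vessel_segment`.
#' @export
vessel_segment <- function(name, diameter_mm, length_mm, wave_speed_m_s = 6,
                           from, to) {
  if (!is.numeric(diameter_mm) || diameter_mm <= 0)
    stopf("segment %s: diameter must be positive", name)
  if (!is.numeric(length_mm) || length_mm <= 0)
    stopf("segment %s: length must be positive", name)
  if (!is.numeric(wave_speed_m_s) || wave_speed_m_s <= 0)
    stopf("segment %s: wave speed must be positive", name)
  structure(list(name = as.character(name), diameter_mm = diameter_mm,
                 length_mm = length_mm, wave_speed_m_s = wave_speed_m_s,
                 from = as.character(from), to = as.character(to)),
            class = "vessel_segment")
}

#' Arterial tree with flow sources and pressure outlets
#'
#' @param segments list of [vessel_segment()]s forming a tree.
#' @param sources named list mapping node id to a [flow_waveform()] injected
#'   at that node (positive into the network).
#' @param outlets named numeric vector mapping node id to a fixed outlet
#'   pressure in mmHg.
#' @param trunk optional character vector of segment names tracing the aortic
#'   trunk from the root (used for the arc-length station coordinate).
#' @return an object of class `network_topology`.
#' @export
network_topology <- function(segments, sources, outlets, trunk = NULL) {
  if (!length(segments)) stopf("a network needs at least one segment")
  names(segments) <- vapply(segments, `[[`, "", "name")
  if (anyDuplicated(names(segments)))
    stopf("segment names must be unique")
  nodes <- unique(unlist(lapply(segments, function(s) c(s$from, s$to))))
  if (length(nodes) != length(segments) + 1L)
    stopf("segments must form a tree (%d nodes for %d segments)",
          length(nodes), length(segments))
  # connectivity over the undirected edge set
  adj <- lapply(stats::setNames(nodes, nodes), function(n) character(0))
  for (s in segments) {
    adj[[s$from]] <- c(adj[[s$from]], s$to)
    adj[[s$to]] <- c(adj[[s$to]], s$from)
  }
  seen <- nodes[1L]; frontier <- nodes[1L]
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier])), seen)
    seen <- c(seen, nxt); frontier <- nxt
  }
  if (length(seen) != length(nodes)) stopf("network graph is not connected")
  if (!length(outlets)) stopf("a network needs at least one pressure outlet")
  if (is.null(names(outlets)) || !all(names(outlets) %in% nodes))
    stopf("outlets must be named by network nodes")
  if (length(sources)) {
    if (is.null(names(sources)) || !all(names(sources) %in% nodes))
      stopf("sources must be named by network nodes")
    for (w in sources)
      if (!inherits(w, "flow_waveform"))
        stopf("every source must be a flow_waveform")
    ns <- vapply(sources, function(w) length(w$values), 0L)
    ps <- vapply(sources, function(w) w$period, 0)
    if (length(unique(ns)) > 1L || diff(range(ps)) > 1e-12)
      stopf("all source waveforms must share one sampling grid and period")
  }
  degree <- vapply(adj, length, 0L)
  leaves <- nodes[degree == 1L]
  bad <- setdiff(leaves, c(names(outlets), names(sources)))
  if (length(bad))
    stopf("leaf node(s) with neither source nor outlet: %s",
          paste(bad, collapse = ", "))
  if (!is.null(trunk) && !all(trunk %in% names(segments)))
    stopf("trunk names not all present among segments")
  structure(list(segments = segments, sources = sources, outlets = outlets,
                 nodes = nodes, trunk = trunk),
            class = "network_topology")
}

#' @export
print.network_topology <- function(x, ...) {
  cat(sprintf("<network_topology> %d segments, %d nodes, %d source(s), %d outlet(s)\n",
              length(x$segments), length(x$nodes), length(x$sources),
              length(x$outlets)))
  invisible(x)
}

DEFAULT_LENGTHS_MM <- c(
  asc_aorta = 80, IA = 50, LCCA = 50, LSA = 50, desc_aorta = 400,
  left_femoral = 250, rf_proximal = 200, rf_distal = 50)

DEFAULT_DIAMETERS_MM <- c(
  asc_aorta = 28, IA = 7, LCCA = 7, LSA = 7, desc_aorta = 11.3,
  left_femoral = 10.3, rf_proximal = 10.3, rf_distal = 10.3)

#' Default aorta-branch-femoral network
#'
#' Builds the reduced 1D tree of a peripheral (femoral) VA-ECMO cannulation:
#' ascending aorta to the arch node (innominate, left common carotid and left
#' subclavian branches), descending aorta (diaphragm-calibre) to the iliac
#' bifurcation, left femoral outlet, and a right femoral limb split at the
#' ECMO cannula access node with a retained distal outlet.
#'
#' Diameters default to the reference geometry (aorta inlet 28 mm, arch
#' branches 7 mm, left femoral 10.3 mm, descending aorta at the diaphragm
#' 11.3 mm; the right femoral reuses the left femoral calibre). Lengths and
#' wave speeds are representative adult values and fully configurable.
#'
#' @param config optional list of overrides; recognised keys:
#'   `lengths_mm`, `diameters_mm` (named, per segment),
#'   `wave_speed_m_s` (scalar or named per segment),
#'   `outlet_pressure_mmHg` (scalar), `ecmo_source` (logical; FALSE removes
#'   the ECMO source node mapping for a cardiac-only network).
#' @param cardiac,ecmo optional [flow_waveform()]s attached as the aortic-root
#'   and cannula-node sources; zero waveforms are attached when omitted (so
#'   the topology is always solvable).
#' @return a [network_topology()].
#' @export
default_network <- function(config = list(), cardiac = NULL, ecmo = NULL) {
  known <- c("lengths_mm", "diameters_mm", "wave_speed_m_s",
             "outlet_pressure_mmHg", "ecmo_source", "n_samples", "period_s")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stopf("unknown config key(s): %s (known: %s)",
          paste(bad, collapse = ", "), paste(known, collapse = ", "))
  lengths <- DEFAULT_LENGTHS_MM
  diams <- DEFAULT_DIAMETERS_MM
  merge_named <- function(base, over, what) {
    if (is.null(over)) return(base)
    over <- unlist(over)
    bad <- setdiff(names(over), names(base))
    if (length(bad))
      stopf("config %s: unknown segment name(s): %s", what,
            paste(bad, collapse = ", "))
    base[names(over)] <- over
    base
  }
  lengths <- merge_named(lengths, config$lengths_mm, "lengths_mm")
  diams <- merge_named(diams, config$diameters_mm, "diameters_mm")
  ws <- config$wave_speed_m_s %||% 6
  wspeed <- if (length(ws) == 1L && is.null(names(ws)))
    stats::setNames(rep(as.numeric(ws), length(lengths)), names(lengths))
  else merge_named(stats::setNames(rep(6, length(lengths)), names(lengths)),
                   ws, "wave_speed_m_s")
  p_out <- config$outlet_pressure_mmHg %||% 70
  edges <- list(
    asc_aorta    = c("root", "arch"),
    IA           = c("arch", "IA_out"),
    LCCA         = c("arch", "LCCA_out"),
    LSA          = c("arch", "LSA_out"),
    desc_aorta   = c("arch", "iliac"),
    left_femoral = c("iliac", "LFA_out"),
    rf_proximal  = c("iliac", "ecmo_node"),
    rf_distal    = c("ecmo_node", "RFA_out"))
  segs <- lapply(names(edges), function(nm)
    vessel_segment(nm, diams[[nm]], lengths[[nm]], wspeed[[nm]],
                   edges[[nm]][1], edges[[nm]][2]))
  period <- config$period_s %||%
    (if (!is.null(cardiac)) cardiac$period else if (!is.null(ecmo)) ecmo$period else 0.8)
  nsamp <- config$n_samples %||%
    (if (!is.null(cardiac)) length(cardiac$values)
     else if (!is.null(ecmo)) length(ecmo$values) else 800L)
  zero <- flow_waveform(rep(0, nsamp), period)
  with_ecmo <- config$ecmo_source %||% TRUE
  sources <- list(root = cardiac %||% zero)
  if (isTRUE(with_ecmo)) sources$ecmo_node <- ecmo %||% zero
  else if (!is.null(ecmo)) stopf("ecmo waveform given but ecmo_source = FALSE")
  outlets <- stats::setNames(
    rep(as.numeric(p_out), 5),
    c("IA_out", "LCCA_out", "LSA_out", "LFA_out", "RFA_out"))
  # The interface arc-length coordinate follows the cardiac-to-cannula path:
  # ascending aorta -> descending aorta -> right femoral access limb.
  network_topology(segs, sources, outlets,
                   trunk = c("asc_aorta", "desc_aorta", "rf_proximal"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Poiseuille resistance of a segment
#'
#' Fully developed steady laminar resistance `128 mu L / (pi D^4)`.
#'
#' @param segment a [vessel_segment()].
#' @param fluid a [fluid_props()].
#' @return resistance in Pa s / m^3.
#' @export
poiseuille_resistance <- function(segment, fluid = fluid_props()) {
  D <- mm_to_m(segment$diameter_mm)
  L <- mm_to_m(segment$length_mm)
  128 * fluid$viscosity * L / (pi * D^4)
}

# Generic nodal solve shared by the mean and harmonic problems.
# seg_y: list per segment of c(y11, y12, y21, y22) with
#   I_prox = y11 P_prox + y12 P_dist (flow out of the proximal node)
#   I_dist = y21 P_prox + y22 P_dist (flow out of the distal node)
# dirichlet: named vector of fixed node pressures; injections: named vector
# of source inflows. Returns node potentials.
nodal_solve <- function(network, seg_y, dirichlet, injections,
                        complex_valued = FALSE) {
  nodes <- network$nodes
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  A <- matrix(if (complex_valued) 0+0i else 0, n, n)
  b <- rep(if (complex_valued) 0+0i else 0, n)
  for (k in seq_along(network$segments)) {
    s <- network$segments[[k]]
    y <- seg_y[[k]]
    ip <- idx[[s$from]]; id <- idx[[s$to]]
    A[ip, ip] <- A[ip, ip] + y[1]; A[ip, id] <- A[ip, id] + y[2]
    A[id, ip] <- A[id, ip] + y[3]; A[id, id] <- A[id, id] + y[4]
  }
  for (nm in names(injections)) b[idx[[nm]]] <- b[idx[[nm]]] + injections[[nm]]
  for (nm in names(dirichlet)) {
    i <- idx[[nm]]
    A[i, ] <- 0; A[i, i] <- 1; b[i] <- dirichlet[[nm]]
  }
  p <- tryCatch(solve(A, b), error = function(e)
    stopf("singular nodal system (check that the network has an outlet): %s",
          conditionMessage(e)))
  stats::setNames(as.vector(p), nodes)
}

#' Steady (cycle-mean) pressure/flow solve
#'
#' Zeroth-harmonic solve: Poiseuille conductances, cycle-mean source inflows,
#' fixed outlet pressures; Kirchhoff flow conservation at every node.
#'
#' @param network a [network_topology()].
#' @param fluid a [fluid_props()].
#' @return list with `node_pressures_mmHg` (named), `segment_flows_mL_s`
#'   (named, signed positive proximal-to-distal) and `outlet_flows_mL_s`.
#' @export
solve_mean <- function(network, fluid = fluid_props()) {
  inj <- vapply(network$sources, function(w)
    mls_to_m3s(waveform_mean(w)), 0)
  if (!all(is.finite(inj))) stopf("source means must be finite")
  seg_y <- lapply(network$segments, function(s) {
    g <- 1 / poiseuille_resistance(s, fluid)
    c(g, -g, -g, g)
  })
  dir <- mmhg_to_pa(network$outlets)
  p <- nodal_solve(network, seg_y, dir, inj)
  q <- vapply(network$segments, function(s) {
    g <- 1 / poiseuille_resistance(s, fluid)
    g * (p[[s$from]] - p[[s$to]])
  }, 0)
  outlet_q <- vapply(names(network$outlets), function(nm) {
    s <- Find(function(s) s$to == nm, network$segments)
    if (is.null(s)) stopf("outlet node %s has no incoming segment", nm)
    q[[s$name]]
  }, 0)
  list(node_pressures_mmHg = pa_to_mmhg(p),
       segment_flows_mL_s = m3s_to_mls(q),
       outlet_flows_mL_s = m3s_to_mls(outlet_q))
}
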