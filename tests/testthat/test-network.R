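single_tube <- function(source_values, n = fast_n, period = 0.8,
                        diameter = 10, length = 200, c0 = 6) {
  w <- flow_waveform(source_values, period)
  network_topology(
    list(vessel_segment("tube", diameter, length, c0, "in", "out")),
    sources = list(`in` = w), outlets = c(out = 70))
}

test_that("constructors enforce geometry and tree invariants", {
  expect_error(vessel_segment("x", -1, 10, 6, "a", "b"), "diameter")
  expect_error(vessel_segment("x", 10, 0, 6, "a", "b"), "length")
  expect_error(vessel_segment("x", 10, 10, -6, "a", "b"), "wave speed")
  w <- flow_waveform(rep(1, 64))
  segs <- list(vessel_segment("a", 10, 100, 6, "n1", "n2"),
               vessel_segment("b", 10, 100, 6, "n2", "n3"))
  expect_error(network_topology(segs, list(n1 = w), c(nX = 70)), "named by")
  # a cycle is not a tree
  segs_cyc <- c(segs, list(vessel_segment("c", 10, 100, 6, "n3", "n1")))
  expect_error(network_topology(segs_cyc, list(n1 = w), c(n3 = 70)), "tree")
  # dangling leaf without source or outlet
  expect_error(network_topology(segs, list(n1 = w), c(n2 = 70)),
               "neither source nor outlet")
})

test_that("default_network has the documented shape and reference diameters", {
  net <- default_network()
  expect_length(net$segments, 8)
  expect_length(net$sources, 2)
  expect_length(net$outlets, 5)
  d <- vapply(net$segments, `[[`, 0, "diameter_mm")
  expect_equal(unname(d["asc_aorta"]), 28)
  expect_equal(unname(d[c("IA", "LCCA", "LSA")]), c(7, 7, 7))
  expect_equal(unname(d["left_femoral"]), 10.3)
  expect_equal(unname(d["desc_aorta"]), 11.3)
  expect_true(all(net$outlets == 70))
  # cardiac-only variant
  net0 <- default_network(list(ecmo_source = FALSE))
  expect_length(net0$sources, 1)
  expect_error(default_network(list(bogus_key = 1)), "bogus_key")
  expect_error(default_network(list(lengths_mm = list(nope = 10))), "nope")
})

test_that("poiseuille_resistance: scaling laws and direct formula", {
  fl <- fluid_props()
  s <- vessel_segment("s", 10.3, 100, 6, "a", "b")
  expect_equal(poiseuille_resistance(s, fl), 1267007.666, tolerance = 1e-9)
  s2 <- vessel_segment("s", 2 * 10.3, 100, 6, "a", "b")
  expect_equal(poiseuille_resistance(s2, fl),
               poiseuille_resistance(s, fl) / 16, tolerance = 1e-12)
  s3 <- vessel_segment("s", 10.3, 200, 6, "a", "b")
  expect_equal(poiseuille_resistance(s3, fl),
               2 * poiseuille_resistance(s, fl), tolerance = 1e-12)
})

test_that("solve_mean: zero inflow, series circuit, Y-split vs dense oracle", {
  fl <- fluid_props()
  net <- single_tube(rep(0, fast_n))
  m <- solve_mean(net, fl)
  expect_equal(unname(m$node_pressures_mmHg), c(70, 70), tolerance = 1e-12)
  expect_equal(unname(m$segment_flows_mL_s), 0)

  q_lmin <- 2
  net2 <- single_tube(rep(lmin_to_mls(q_lmin), fast_n))
  m2 <- solve_mean(net2, fl)
  R <- poiseuille_resistance(net2$segments$tube, fl)
  expect_equal(unname(m2$outlet_flows_mL_s["out"]), lmin_to_mls(q_lmin),
               tolerance = 1e-9)
  expect_equal(unname(m2$node_pressures_mmHg["in"]),
               70 + pa_to_mmhg(R * mls_to_m3s(lmin_to_mls(q_lmin))),
               tolerance = 1e-9)

  # Y-network with unequal branches and unequal outlet pressures
  w <- flow_waveform(rep(lmin_to_mls(3), fast_n))
  segs <- list(vessel_segment("stem", 12, 150, 6, "src", "mid"),
               vessel_segment("b1", 8, 120, 6, "mid", "o1"),
               vessel_segment("b2", 6, 90, 6, "mid", "o2"))
  net3 <- network_topology(segs, list(src = w), c(o1 = 70, o2 = 65))
  m3 <- solve_mean(net3, fl)
  R1 <- poiseuille_resistance(segs[[1]], fl)
  R2 <- poiseuille_resistance(segs[[2]], fl)
  R3 <- poiseuille_resistance(segs[[3]], fl)
  expected <- oracle_y_split(mls_to_m3s(lmin_to_mls(3)), R1, R2, R3,
                             mmhg_to_pa(70), mmhg_to_pa(65))
  expect_equal(unname(m3$segment_flows_mL_s[c("b1", "b2")]),
               m3s_to_mls(expected), tolerance = 1e-9)
  # equal split when branches and pressures are equal
  segs_eq <- list(segs[[1]],
                  vessel_segment("b1", 8, 120, 6, "mid", "o1"),
                  vessel_segment("b2", 8, 120, 6, "mid", "o2"))
  m4 <- solve_mean(network_topology(segs_eq, list(src = w),
                                    c(o1 = 70, o2 = 70)), fl)
  expect_equal(unname(m4$segment_flows_mL_s["b1"]),
               unname(m4$segment_flows_mL_s["b2"]), tolerance = 1e-9)
})

test_that("womersley_twoport: Poiseuille and inviscid limits, series oracle at alpha = 5", {
  fl <- fluid_props()
  # pick omega to set alpha exactly
  alpha_to_omega <- function(alpha, R) alpha^2 * fl$viscosity /
    (fl$density * R^2)
  s <- vessel_segment("s", 10, 100, 6, "a", "b")
  R <- mm_to_m(10) / 2
  # alpha <= 0.1: longitudinal impedance within 1% of Poiseuille per length
  tp <- womersley_twoport(s, fl, alpha_to_omega(0.1, R))
  expect_equal(tp$alpha, 0.1, tolerance = 1e-12)
  poiseuille_per_len <- 128 * fl$viscosity / (pi * mm_to_m(10)^4)
  expect_equal(Mod(tp$Zl), poiseuille_per_len, tolerance = 0.01)
  # alpha >= 50: |Zc| within 2% of the inviscid rho c / A
  tp2 <- womersley_twoport(s, fl, alpha_to_omega(50, R))
  A <- pi * R^2
  expect_equal(Mod(tp2$Zc), fl$density * 6 / A, tolerance = 0.02)
  # alpha = 5: friction factor against the independent power-series oracle
  tp3 <- womersley_twoport(s, fl, alpha_to_omega(5, R))
  lam <- complex(modulus = 5, argument = 3 * pi / 4)
  F_oracle <- 2 * oracle_J1(lam) / (lam * oracle_J0(lam))
  expect_equal(tp3$F10, F_oracle, tolerance = 1e-10)
  expect_error(womersley_twoport(s, fl, -1), "positive")
})

test_that("solve_harmonic: linearity, zero source, closed-form tube and series", {
  fl <- fluid_props()
  n <- fast_n; period <- 0.8
  t <- seq(0, period, length.out = n + 1L)[seq_len(n)]
  amp_mls <- 10
  net <- single_tube(amp_mls * cos(2 * pi * t / period))
  h1 <- solve_harmonic(net, fl, 1)
  # zero source harmonic (k = 2 of a pure fundamental) -> zero field
  h2 <- solve_harmonic(net, fl, 2)
  expect_lt(max(Mod(h2$node_pressures_Pa)), 1e-12 * max(Mod(h1$node_pressures_Pa)))
  # homogeneity: scaling the source scales the field
  net3 <- single_tube(3 * amp_mls * cos(2 * pi * t / period))
  h3 <- solve_harmonic(net3, fl, 1)
  expect_equal(h3$node_pressures_Pa, 3 * h1$node_pressures_Pa,
               tolerance = 1e-10)

  # closed form: P_in = Zc tanh(gL) Q, Q_out = Q / cosh(gL)
  tp <- womersley_twoport(net$segments$tube, fl, 2 * pi / period)
  gL <- tp$gamma * mm_to_m(200)
  q <- mls_to_m3s(amp_mls)
  expect_equal(h1$node_pressures_Pa[["in"]], tp$Zc * tanh(gL) * q,
               tolerance = 1e-8)
  expect_equal(h1$flow_dist_m3_s[["tube"]], q / cosh(gL), tolerance = 1e-8)

  # two-segment series vs cascaded closed form
  w <- flow_waveform(amp_mls * cos(2 * pi * t / period), period)
  segs <- list(vessel_segment("s1", 12, 150, 5, "in", "mid"),
               vessel_segment("s2", 8, 250, 7, "mid", "out"))
  net_s <- network_topology(segs, list(`in` = w), c(out = 70))
  hs <- solve_harmonic(net_s, fl, 1)
  tp1 <- womersley_twoport(segs[[1]], fl, 2 * pi / period)
  tp2 <- womersley_twoport(segs[[2]], fl, 2 * pi / period)
  Zin2 <- tp2$Zc * tanh(tp2$gamma * mm_to_m(250))
  Zin <- oracle_input_impedance(tp1$Zc, tp1$gamma * mm_to_m(150), Zin2)
  expect_equal(hs$node_pressures_Pa[["in"]], Zin * q, tolerance = 1e-8)
  expect_equal(hs$node_pressures_Pa[["mid"]] /
                 (hs$flow_prox_m3_s[["s2"]]), Zin2, tolerance = 1e-8)

  # matched termination: input impedance equals Zc exactly
  hm <- solve_harmonic(net, fl, 1, terminations = list(out = tp$Zc))
  expect_equal(hm$node_pressures_Pa[["in"]] / mls_to_m3s(amp_mls), tp$Zc,
               tolerance = 1e-10)
  expect_error(solve_harmonic(net, fl, 0), ">= 1")
  expect_error(solve_harmonic(net, fl, n), "Nyquist")
})

test_that("reconstruct_cycle: steady Poiseuille WSS, closure, regional WSS arithmetic", {
  fl <- fluid_props()
  q_lmin <- 2
  net <- single_tube(rep(lmin_to_mls(q_lmin), fast_n))
  sol <- reconstruct_cycle(net, fl, n_harmonics = 8)
  R <- mm_to_m(10) / 2
  tau <- 4 * fl$viscosity * mls_to_m3s(lmin_to_mls(q_lmin)) / (pi * R^3)
  expect_equal(max(abs(sol$station_wss_Pa - tau)), 0, tolerance = 1e-9 * tau)
  expect_lt(sol$conservation$residual_fraction, 1e-10)
  expect_equal(regional_mean_wss(sol, seq_len(nrow(sol$stations))), tau,
               tolerance = 1e-9)

  # two segments of different calibre: region of one station in each averages
  # the two Poiseuille values
  w <- flow_waveform(rep(lmin_to_mls(q_lmin), fast_n))
  segs <- list(vessel_segment("wide", 12, 100, 6, "in", "mid"),
               vessel_segment("narrow", 8, 100, 6, "mid", "out"))
  net2 <- network_topology(segs, list(`in` = w), c(out = 70))
  sol2 <- reconstruct_cycle(net2, fl, n_harmonics = 4)
  tau_of <- function(d) 4 * fl$viscosity * mls_to_m3s(lmin_to_mls(q_lmin)) /
    (pi * (mm_to_m(d) / 2)^3)
  i_wide <- which(sol2$stations$segment == "wide")[1]
  i_narrow <- which(sol2$stations$segment == "narrow")[1]
  expect_equal(regional_mean_wss(sol2, c(i_wide, i_narrow)),
               (tau_of(12) + tau_of(8)) / 2, tolerance = 1e-9)
  expect_error(regional_mean_wss(sol2, integer(0)), "at least one")
  expect_error(reconstruct_cycle(net2, fl, n_harmonics = fast_n), "Nyquist")
})

test_that("solution is additive over the two sources", {
  src <- make_sources(0.6)
  net_b <- default_network(cardiac = src$cardiac, ecmo = src$ecmo)
  net_c <- default_network(cardiac = src$cardiac)
  net_e <- default_network(ecmo = src$ecmo)
  sb <- reconstruct_cycle(net_b, n_harmonics = fast_K)
  sc <- reconstruct_cycle(net_c, n_harmonics = fast_K)
  se <- reconstruct_cycle(net_e, n_harmonics = fast_K)
  expect_equal(sc$segment_flow_prox_mL_s + se$segment_flow_prox_mL_s,
               sb$segment_flow_prox_mL_s, tolerance = 1e-9)
  # pressures superpose about the common 70 mmHg outlet baseline
  expect_equal(sc$node_pressures_mmHg + se$node_pressures_mmHg - 70,
               sb$node_pressures_mmHg, tolerance = 1e-9)
})

test_that("model properties: antegrade femoral at BAI 0, retrograde descending aorta at BAI 0.8", {
  src0 <- make_sources(0)
  s0 <- reconstruct_cycle(default_network(cardiac = src0$cardiac,
                                          ecmo = src0$ecmo),
                          n_harmonics = fast_K)
  ipk <- which.max(src0$cardiac$values)
  expect_gt(s0$segment_flow_prox_mL_s[ipk, "rf_proximal"], 0)
  expect_gt(s0$segment_flow_prox_mL_s[ipk, "rf_distal"], 0)

  src8 <- make_sources(0.8)
  s8 <- reconstruct_cycle(default_network(cardiac = src8$cardiac,
                                          ecmo = src8$ecmo),
                          n_harmonics = fast_K)
  expect_lt(mean(s8$segment_flow_prox_mL_s[, "desc_aorta"]), 0)
})
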