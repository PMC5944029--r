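# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: power series for the complex Bessel functions,
# closed-form transmission-line formulas, and hand-written nodal algebra.

# Power series J0, J1 for complex z; accurate to ~1e-12 for |z| <= 8.
oracle_J0 <- function(z) {
  term <- 1 + 0i; s <- term
  for (k in 1:60) {
    term <- term * (-(z^2) / 4) / k^2
    s <- s + term
  }
  s
}
oracle_J1 <- function(z) {
  term <- z / 2; s <- term
  for (k in 1:60) {
    term <- term * (-(z^2) / 4) / (k * (k + 1))
    s <- s + term
  }
  s
}

# Closed-form input impedance of a line of characteristic impedance Zc and
# propagation gamma*L, terminated by load ZL.
oracle_input_impedance <- function(Zc, gL, ZL) {
  Zc * (ZL + Zc * tanh(gL)) / (Zc + ZL * tanh(gL))
}

# Dense hand-assembled steady nodal solve of a Y-network: one source node
# feeding resistance R1 to a mid node, which splits over R2, R3 into outlets
# held at pressures p2, p3. Returns the two branch flows.
oracle_y_split <- function(Q, R1, R2, R3, p2, p3) {
  p_mid <- (p2 / R2 + p3 / R3 + Q) / (1 / R2 + 1 / R3)
  c((p_mid - p2) / R2, (p_mid - p3) / R3)
}

# Reduced solver settings that keep property loops fast but stay above the
# 64-sample floor and well-resolved in harmonics.
fast_n <- 256L
fast_K <- 12L

make_sources <- function(level, n = fast_n) {
  compose_perfusion(perfusion_spec(level, n_samples = n))
}
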