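test_that("bai limit cases match the definitional anchors", {
  n <- fast_n
  zero <- flow_waveform(rep(0, n))
  four <- flow_waveform(rep(lmin_to_mls(4), n))
  # cardiac identically zero, ECMO positive -> 1 in both modes
  expect_equal(bai(four, zero, "instantaneous_ratio"), 1)
  expect_equal(bai(four, zero, "mean_flow_ratio"), 1)
  # ECMO identically zero -> 0
  card <- cardiac_waveform(5, n_samples = n)
  expect_equal(bai(zero, card, "instantaneous_ratio"), 0)
  expect_equal(bai(zero, card, "mean_flow_ratio"), 0)
  # both zero: degenerate, defined as 0
  expect_equal(bai(zero, zero, "mean_flow_ratio"), 0)
})

test_that("bai instantaneous: half-duty square cardiac against constant ECMO is 0.75", {
  n <- fast_n
  t <- seq(0, 0.8, length.out = n + 1L)[seq_len(n)]
  ecmo <- flow_waveform(rep(2, n))
  cardiac <- flow_waveform(ifelse(t < 0.4, 2, 0))
  # ratio is 0.5 for half the cycle and 1 for the other half
  expect_equal(bai(ecmo, cardiac, "instantaneous_ratio"), 0.75,
               tolerance = 1e-12)
})

test_that("bai requires matched grids and is monotone in the ECMO level", {
  card <- cardiac_waveform(3, n_samples = fast_n)
  expect_error(bai(ecmo_waveform(2, n_samples = 128L), card), "grid")
  levels <- seq(0, 5, by = 0.5)
  vals <- vapply(levels, function(e)
    bai(ecmo_waveform(e, n_samples = fast_n), card, "mean_flow_ratio"), 0)
  expect_true(all(diff(vals) > 0))
})

test_that("flow_ratios arithmetic and key checking", {
  r <- flow_ratios(c(IA = 1, LCCA = 0.5, LSA = 0.5, LFA = 0.75, RFA = 0.75), 5)
  expect_equal(r$r_up, 0.4)
  expect_equal(r$r_down, 0.3)
  r2 <- flow_ratios(c(IA = 2, LCCA = 2, LSA = 1, LFA = 0, RFA = 0), 5)
  expect_equal(r2$r_up, 1)
  expect_equal(r2$r_down, 0)
  expect_equal(flow_ratios(c(IA = 0, LCCA = 0, LSA = 0, LFA = 0, RFA = 0),
                           5)$r_up, 0)
  expect_error(flow_ratios(c(IA = 1, LCCA = 1, LSA = 1, LFA = 1), 5), "RFA")
  expect_error(flow_ratios(c(IA = 1, LCCA = 1, LSA = 1, LFA = 1, RFA = 1), 0),
               "positive")
})

test_that("harmonic_index hits its definitional anchors", {
  n <- 512L
  t <- seq(0, 0.8, length.out = n + 1L)[seq_len(n)]
  expect_equal(harmonic_index(rep(7, n)), 0)              # steady nonzero
  expect_equal(harmonic_index(sin(2 * pi * t / 0.8)), 1)  # zero-mean
  # 1 + cos(w0 t): one-sided amplitudes 1 and 1 -> HI = 0.5
  expect_equal(harmonic_index(1 + cos(2 * pi * t / 0.8)), 0.5,
               tolerance = 1e-12)
  expect_equal(harmonic_index(rep(0, n)), 0)              # degenerate
  expect_error(harmonic_index(rep(1, 10)), "64")
})

test_that("harmonic_index properties: scale invariance, offset suppression", {
  n <- fast_n
  t <- seq(0, 0.8, length.out = n + 1L)[seq_len(n)]
  w <- 2 + sin(2 * pi * t / 0.8) + 0.5 * cos(4 * pi * t / 0.8)
  h <- harmonic_index(w)
  for (c in c(0.1, 3, 100))
    expect_equal(harmonic_index(c * w), h, tolerance = 1e-12)
  offsets <- c(0, 1, 10, 100, 1000)
  hs <- vapply(offsets, function(k) harmonic_index(w + k), 0)
  expect_true(all(diff(hs) < 0))
  expect_lt(hs[length(hs)], 0.01)
})

test_that("osi hits its definitional anchors", {
  n <- 96L
  t <- seq(0, 0.8, length.out = n + 1L)[seq_len(n)]
  expect_equal(osi(2 + sin(2 * pi * t / 0.8)), 0)        # never changes sign
  expect_equal(osi(sin(2 * pi * t / 0.8)), 0.5, tolerance = 1e-12)
  # +3 for two thirds of the cycle, -3 for one third -> 1/3
  tau <- ifelse(t < 0.8 * 2 / 3, 3, -3)
  expect_equal(osi(tau), 1 / 3, tolerance = 1e-12)
  expect_equal(osi(rep(0, n)), 0)                        # degenerate
})

test_that("osi properties: sign flip, scaling, offset suppression", {
  n <- fast_n
  t <- seq(0, 0.8, length.out = n + 1L)[seq_len(n)]
  tau <- sin(2 * pi * t / 0.8) + 0.3 * sin(6 * pi * t / 0.8)
  v <- osi(tau)
  expect_equal(osi(-tau), v, tolerance = 1e-12)
  expect_equal(osi(5 * tau), v, tolerance = 1e-12)
  offsets <- c(0.5, 1, 2, 5, 20)
  vs <- vapply(offsets, function(k) osi(tau + k), 0)
  expect_true(all(diff(vs) <= 0))
  expect_equal(vs[length(vs)], 0)
})

test_that("pearson_r matches hand-computed values and rejects degenerate input", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, c(2, 1, 4, 3)), 0.6)
  expect_error(pearson_r(x, rep(1, 4)), "zero-variance")
  expect_error(pearson_r(1:2, 1:2), "length")
})
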