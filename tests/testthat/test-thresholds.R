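p_tab <- model_parameters()

test_that("kill pressure has the derived small- and large-dose slopes", {
  # small N: MHC-I production ~ gMI, so G1(N)/N -> aT gMI/(gMI+eT)/muC
  expect_equal(kill_pressure_T(1e-9, p_tab) / 1e-9,
               .12 * 1.44 / 51.44 / .007, tolerance = 1e-6)
  # saturated IFN-gamma: X -> gMI + aMIgamma = 4.32
  expect_equal(kill_pressure_T(1e30, p_tab) / 1e30,
               .12 * 4.32 / 54.32 / .007, tolerance = 1e-6)
  expect_equal(kill_pressure_T(0, p_tab), 0)
  expect_error(kill_pressure_T(-1, p_tab))
})

test_that("kill pressures are strictly increasing in dose", {
  Ns <- 10^seq(-6, 18, length.out = 1e4)
  for (mode in c("paper", "consistent")) {
    expect_true(all(diff(kill_pressure_T(Ns, p_tab, mode)) > 0))
    expect_true(all(diff(kill_pressure_S(Ns, p_tab, mode)) > 0))
  }
})

test_that("monotone inversion round-trips and flags bad targets", {
  g <- function(N) kill_pressure_T(N, p_tab)
  expect_equal(invert_monotone(g, g(7.3)), 7.3, tolerance = 1e-10)
  expect_equal(invert_monotone(g, 0), 0)
  expect_error(invert_monotone(g, -1), "inversion error")
  expect_error(invert_monotone(function(N) N, Inf), "inversion error")
})

test_that("bisection inversion agrees with a 1e7-point grid search", {
  g <- function(N) kill_pressure_T(N, p_tab)
  target <- g(7.3)
  xs <- seq(0, 20, length.out = 1e7)
  oracle <- xs[which.min(abs(g(xs) - target))]
  expect_lt(abs(invert_monotone(g, target) - oracle) / oracle, 1e-6)
})

test_that("published worked example reproduces to printed precision", {
  th <- compute_thresholds(p_tab, mode = "paper")
  rel <- function(a, b) abs(a - b) / abs(b)
  expect_printed(th$target_T, .00117, digits = 3)
  expect_lt(rel(th$target_S, .09976), 1e-3)
  expect_printed(th$Nmin_T, .00245, digits = 3)
  expect_lt(rel(th$Nmin_S, 2.07889), 1e-3)
  expect_lt(rel(th$aleph_T, 3.60322e17), 1e-3)
  expect_lt(rel(th$aleph_S, 1.4866e15), 1e-3)
  expect_lt(rel(th$Nthr_T, 3.10199e14), 1e-3)
  expect_lt(rel(th$Nthr_S, 1.08783e15), 1e-3)
  expect_lt(rel(th$Ncure, 1.08783e15), 1e-3)
})

test_that("threshold report invariants hold in both modes", {
  for (mode in c("paper", "consistent")) {
    th <- compute_thresholds(p_tab, mode = mode)
    expect_equal(th$Ncure, max(th$Nthr_T, th$Nthr_S))
    expect_gte(th$Nthr_T, th$Nmin_T)
    expect_gte(th$Nthr_S, th$Nmin_S)
    expect_gte(th$aleph_T, 1)
    expect_gte(th$aleph_S, 1)
    expect_gte(th$recurrence_Nthr, th$recurrence_Nmin)
    # feeding the threshold back exceeds the amplified target
    g1 <- function(N) kill_pressure_T(N, p_tab, mode)
    expect_gt(g1(th$Nthr_T * (1 + 1e-6)), th$target_T * th$aleph_T)
  }
})

test_that("recurrence balance is negative everywhere above its threshold", {
  rec <- recurrence_thresholds(p_tab, mode = "paper")
  expect_gte(rec$Nthr, rec$Nmin)
  S <- seq(0, p_tab$K2, length.out = 1e4)
  expect_true(all(gbmcsc:::recurrence_L(S, rec$Nthr * (1 + 1e-6), p_tab,
                                        "paper") < 0))
  # without treatment the origin repels the stem-cell compartment
  expect_equal(gbmcsc:::recurrence_L(0, 0, p_tab, "paper"), p_tab$r2)
  # the carrying-capacity end is always a sink under any treatment
  for (N in 10^seq(-3, 15, length.out = 10))
    expect_lt(gbmcsc:::recurrence_L(p_tab$K2, N, p_tab, "paper"), 0)
})
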