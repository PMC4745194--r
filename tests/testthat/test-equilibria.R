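test_that("cure equilibrium matches the closed-form chain", {
  p0 <- model_parameters(N = 0)
  eq0 <- cure_equilibrium(p0)
  expect_equal(unname(unclass(eq0$state)),
               c(0, 0, 0, 9135, 0, 100, 0))
  expect_equal(eq0$label, "unstable")      # untreated tumor can invade

  p1 <- model_parameters(N = 1)
  eq1 <- cure_equilibrium(p1)
  expect_equal(eq1$state[["C"]], 1 / .007)  # 142.857...
  expect_lte(eq1$residual, 1e-8 * max(1, max(abs(eq1$state))))

  expect_error(cure_equilibrium(model_parameters(mugamma = 0)))
})

test_that("recruitment-free CTL balance returns the infusion steady state", {
  p <- model_parameters(N = 1)
  f <- kronik_forms(p)   # fC = 0: constant-inflow balance, C = N/muC
  expect_equal(solve_recruitment_C(0, 0, f), 1 / p$muC, tolerance = 1e-10)
  expect_equal(solve_recruitment_C(1e6, 1e5, f), 1 / p$muC,
               tolerance = 1e-10)
})

test_that("recruitment root matches a dense-grid sign-change oracle", {
  set.seed(5)
  for (i in 1:5) {
    f <- random_a2_forms()
    T0 <- runif(1, 0, 50); S0 <- runif(1, 0, 20)
    root <- solve_recruitment_C(T0, S0, f)
    mu <- f$mu
    xp <- f$fx(T0 + S0) / mu[["x"]]
    H <- function(C) {
      vp <- f$fv(xp) * f$gv(f$fy(C) / mu[["y"]]) / mu[["v"]]
      f$fC((T0 + S0) * vp) * f$gC(xp) - mu[["C"]] * C + f$N
    }
    cg <- seq(0, 4 * root, length.out = 1e6)
    hv <- H(cg)
    j <- which(diff(sign(hv)) != 0)[1]
    oracle <- (cg[j] + cg[j + 1]) / 2
    expect_lt(abs(root - oracle) / oracle, 1e-5)
    expect_lt(abs(H(root)), 1e-9 * max(1, mu[["C"]] * root))
  }
})

test_that("untreated recurrence submodel rests at carrying capacity", {
  p <- model_parameters()
  res <- recurrence_equilibria(p, N = 0)
  expect_equal(nrow(res), 1)
  expect_equal(res$S, p$K2)
  expect_equal(res$stability, "stable")
})

test_that("recurrence roots vanish above the submodel threshold", {
  p <- model_parameters()
  for (mode in c("paper", "consistent")) {
    rec <- recurrence_thresholds(p, mode = mode)
    res <- recurrence_equilibria(p, N = rec$Nthr * 1.001, mode = mode)
    expect_equal(nrow(res), 0)
  }
})

test_that("recurrence root finder agrees with a 1e6-point sign scan", {
  p <- model_parameters()
  for (N in c(0, 1e6, 1e8, 2e8)) {
    res <- recurrence_equilibria(p, N, mode = "consistent")
    oracle <- sign_scan_roots(
      function(S) gbmcsc:::recurrence_L(S, N, p, mode = "consistent"),
      0, p$K2)
    expect_equal(nrow(res), length(oracle))
    if (length(oracle))
      expect_lt(max(abs(sort(res$S) - sort(oracle)) / p$K2), 1e-5)
  }
})

test_that("odd root count below the local-stability dose", {
  p <- model_parameters()
  rec <- recurrence_thresholds(p, mode = "consistent")
  for (N in c(rec$Nmin * .1, rec$Nmin * .9)) {
    expect_gt(gbmcsc:::recurrence_L(0, N, p, "consistent"), 0)
    res <- recurrence_equilibria(p, N, mode = "consistent")
    expect_equal(nrow(res) %% 2, 1)
  }
})

test_that("untreated coexistence rests at both carrying capacities", {
  p <- model_parameters()
  res <- coexistence_equilibria(p, N = 0)
  expect_gte(nrow(res), 1)
  i <- which.min(abs(res$T - p$K1))
  expect_equal(res$T[i], p$K1, tolerance = 1e-8)
  expect_equal(res$S[i], p$K2, tolerance = 1e-8)
  expect_equal(res$stability[i], "stable")
  # root contract: per-capita balances vanish at every returned point
  for (k in seq_len(nrow(res))) {
    expect_lte(abs(gbmcsc:::coexistence_M1(res$T[k], res$S[k], 0, p)), 1e-8)
    expect_lte(abs(gbmcsc:::coexistence_M2(res$T[k], res$S[k], 0, p)), 1e-8)
  }
})

test_that("no coexistence equilibrium above the cure dose", {
  p <- model_parameters()
  th <- compute_thresholds(p, mode = "paper")
  res <- coexistence_equilibria(p, N = th$Ncure * 1.01, mode = "paper",
                                n_grid = 256)
  expect_equal(nrow(res), 0)
})
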