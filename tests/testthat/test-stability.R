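p_tab <- model_parameters()

test_that("analytic Jacobian carries the linear couplings", {
  set.seed(2)
  s <- random_state(p_tab)
  J <- jacobian_at(s, p_tab, method = "analytic")
  expect_equal(J["Fgamma", "C"], p_tab$agammaC)   # linear IFN-gamma source
  expect_equal(J["MI", "T"], 0)                   # MHC-I blind to tumor load
  expect_equal(J["C", "C"], -p_tab$muC)
  expect_equal(J["Fbeta", "T"], p_tab$abetaT)
})

test_that("finite differences reproduce the analytic Jacobian", {
  set.seed(3)
  for (i in 1:50) {
    s <- random_state(p_tab)
    J1 <- jacobian_at(s, p_tab)
    J2 <- jacobian_at(s, p_tab, method = "analytic")
    rowscale <- apply(abs(J2), 1, max)
    # a central difference cannot beat the roundoff floor eps |f| / h
    h <- pmax(1e-8, 1e-6 * abs(as.numeric(s)))
    noise <- outer(abs(gbm_rhs(s, p_tab)), h,
                   function(f, hh) .Machine$double.eps * f / hh)
    tol <- 1e-6 * pmax(abs(J2), rowscale) + 10 * noise
    expect_true(all(abs(J1 - J2) <= tol))
  }
})

test_that("cure spectrum carries the death rates and invasion rates", {
  for (N in c(0, 1, 1.08783e15)) {
    ev <- Re(cure_eigenvalues(p_tab, N))
    expect_true(any(abs(ev + 7) < 1e-10))      # -mubeta
    expect_true(any(abs(ev + .102) < 1e-10))   # -mugamma
  }
  ev0 <- Re(cure_eigenvalues(p_tab, 0))
  expect_true(any(abs(ev0 - .001) < 1e-12))    # r1: kill vanishes at C*=0
  expect_true(any(abs(ev0 - .1) < 1e-12))      # r2
  expect_true(all(Re(cure_eigenvalues(p_tab, 1.08783e15)) < 0))
  # closed form agrees with the numerical spectrum
  for (N in c(0, 1, 1e10)) {
    a <- sort(Re(cure_eigenvalues(p_tab, N, method = "closed")))
    b <- sort(Re(cure_eigenvalues(p_tab, N, method = "numeric")))
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("closed-form cure spectra match finite differences on random abstract systems", {
  set.seed(42)
  err <- 0
  for (i in 1:50) {
    f <- random_a2_forms()
    a <- sort(Re(cure_eigenvalues_closed(f)))
    J <- jacobian_at(abstract_cure_state(f), f)
    b <- sort(Re(eigen(J, only.values = TRUE)$values))
    err <- max(err, max(abs(a - b) / pmax(abs(a), 1e-12)))
  }
  expect_lt(err, 1e-8)
})

test_that("cure stability flips with treatment", {
  expect_false(is_cure_stable(p_tab, N = 0)$stable)
  st <- is_cure_stable(p_tab, N = 1.08783e15)
  expect_true(st$stable)
  expect_gt(st$margin, 0)
  # abstract bundle meeting both invasion inequalities strictly
  set.seed(8)
  f <- random_a2_forms()
  big <- invert_monotone(function(N) {
    mu <- f$mu
    us <- f$fu(f$fy(N / mu[["C"]]) / mu[["y"]]) / mu[["u"]]
    min(f$fT(f$fx(0) / mu[["x"]]) * f$gT(us) * f$hT(0),
        f$fS(f$fx(0) / mu[["x"]]) * f$gS(us) * f$hS(0)) * N / mu[["C"]]
  }, max(f$R1(0), f$R2(0)) * 2)
  expect_true(is_cure_stable(f, N = big)$stable)
})

test_that("decay-rate certificates behave as derived", {
  expect_equal(tgfb_qss(p_tab$K1, p_tab$K2, p_tab), 9225.357142857143)
  a0 <- cure_decay_rates(p_tab, N = 0)
  expect_lt(a0[["a1"]], 0)
  expect_lt(a0[["a2"]], 0)
  aN <- cure_decay_rates(p_tab, N = 1.08783e15)
  expect_gt(aN[["a2"]], 0)
})

test_that("positive stem decay certificate bounds the simulated decay", {
  # dose chosen so the certified rate is resolvable over a 100 h window
  N <- 6.1e7
  p <- model_parameters(N = N)
  a2 <- cure_decay_rates(p, N)[["a2"]]
  expect_gt(a2, 0)
  # the certificate bounds S' <= -a2 hS(K2) fS(xmax) S once the immune
  # chain rests on the cure branch
  xmax <- tgfb_qss(p$K1, p$K2, p)
  rate <- a2 / (p$hS + p$K2) *
    (p$aSbeta + p$eSbeta * (1 - p$aSbeta) / (xmax + p$eSbeta))
  eq <- cure_equilibrium(p)
  init <- eq$state
  init[["S"]] <- 1e6
  traj <- simulate_gbm(p, init, t_end = 100)
  bound <- 1e6 * exp(-rate * traj$times * (1 - 1e-3))
  expect_true(all(traj$states[, "S"] <= bound))
})

test_that("dissipativity constants certify the published calibration", {
  d <- dissipativity_constants(p_tab)
  expect_equal(d$delta, .001)   # min{r1, r2, muC, mubeta, mugamma, muMI, muMII}
  expect_equal(d$a1, 1e5)       # r1 K1
  # linear domination of the logistic term on [0, K1]
  T <- seq(0, p_tab$K1, length.out = 1e4)
  expect_true(all(p_tab$r1 * T * (1 - T / p_tab$K1) <= d$a1 - d$b1 * T + 1e-9))
  S <- seq(0, p_tab$K2, length.out = 1e4)
  expect_true(all(p_tab$r2 * S * (1 - S / p_tab$K2) <= d$a2 - d$b2 * S + 1e-9))
})

test_that("global-cure certificate is dose-monotone and correct at the ends", {
  th <- compute_thresholds(p_tab, mode = "paper")
  expect_false(verify_global_cure(p_tab, 0, n_grid = 128))
  expect_true(verify_global_cure(p_tab, th$Ncure * (1 + 1e-6),
                                 n_grid = 128))
  ladder <- c(0, 1e6, 1e10, 1e12, 1e13, 1e14, 3e14, 7e14,
              th$Ncure * (1 + 1e-6), 1e16)
  flags <- vapply(ladder, function(N)
    verify_global_cure(p_tab, N, n_grid = 128), logical(1))
  expect_true(all(diff(as.integer(flags)) >= 0))
  expect_true(flags[10])
})
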