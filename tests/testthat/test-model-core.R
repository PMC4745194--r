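test_that("default parameters reproduce the published calibration", {
  p <- model_parameters()
  expect_equal(p$r1, .001)
  expect_equal(p$K1, 1e8)
  expect_equal(p$aS, .1 * p$aT)
  expect_equal(p$gbeta, 6.3945e4)
  expect_equal(p$eS, p$eT)
  expect_equal(p$hS, p$hT)
  expect_equal(p$N, 0)
})

test_that("parameter and state invariants are enforced", {
  expect_error(model_parameters(r1 = -1), "negative")
  expect_error(model_parameters(muC = 0), "strictly positive")
  expect_error(model_parameters(aTbeta = 1.5), "\\[0, 1\\]")
  expect_error(system_state(T = -1), "nonnegative")
  expect_error(gbm_rhs(c(Inf, 0, 0, 0, 0, 0, 0), model_parameters()),
               "non-finite")
})

test_that("concrete right-hand side matches direct substitution", {
  p <- model_parameters()
  s <- system_state(70, 30, 250, 50, 50, 50, 50)
  r <- gbm_rhs(s, p)
  # C decouples: dC/dt = -muC C + N = -.007 * 250
  expect_equal(r[["C"]], -1.75)
  # dFgamma/dt = agammaC C - mugamma Fgamma = 1.02e-4 * 250 - .102 * 50
  expect_equal(r[["Fgamma"]], -5.0745)
  # at the origin every interaction vanishes except basal TGF-beta inflow
  # and basal MHC-I expression
  r0 <- gbm_rhs(rep(0, 7), p)
  expect_equal(r0[["Fbeta"]], 6.3945e4)
  expect_equal(r0[["MI"]], p$gMI)
  expect_equal(unname(r0[c("T", "S", "C", "Fgamma", "MII")]), rep(0, 5))
})

test_that("abstract and concrete right-hand sides agree on random states", {
  p <- model_parameters(N = 1)
  f <- kronik_forms(p)
  set.seed(101)
  for (i in 1:100) {
    s <- random_state(p)
    a <- abstract_rhs(s, f)
    b <- gbm_rhs(s, p)
    expect_lt(max(abs(a - b) / pmax(abs(b), 1)), 1e-12)
  }
})

test_that("abstract sign contracts hold on the boundary", {
  f <- kronik_forms(model_parameters())
  f$alpha <- function(T, S) 0 * T * S
  r <- abstract_rhs(c(0, 30, 250, 50, 50, 50, 50), f)
  expect_equal(r[["T"]], 0)          # T' proportional to T when alpha = 0
  f2 <- kronik_forms(model_parameters(N = 0))
  r2 <- abstract_rhs(c(70, 30, 0, 50, 50, 50, 50), f2)
  expect_gte(r2[["C"]], 0)           # recruitment only, C cannot go negative
})

test_that("nonnegative orthant is invariant at the boundary", {
  p <- model_parameters(N = 1)
  set.seed(7)
  for (i in 1:30) {
    s <- as.numeric(random_state(p))
    j <- sample(7, 1)
    s[j] <- 0
    r <- gbm_rhs(s, p)
    expect_gte(r[[j]], 0)
  }
})

test_that("fast-TGF-beta reduction sits on the slow manifold", {
  p <- model_parameters()
  expect_equal(tgfb_qss(0, 0, p), 9135)              # gbeta / mubeta
  expect_equal(tgfb_qss(p$K1, p$K2, p), 64577.5 / 7) # 9225.357 pg
  # reduced rates equal full-system rates whenever Fbeta is at x*
  set.seed(11)
  for (i in 1:20) {
    s <- as.numeric(random_state(p))
    s[4] <- tgfb_qss(s[1], s[2], p)
    red <- reduced_tgfb_rhs(s[-4], p)
    full <- gbm_rhs(s, p)
    expect_equal(unname(red),
                 unname(full[c("T", "S", "C", "Fgamma", "MI", "MII")]))
  }
})

test_that("rhs at the cure state vanishes to solver precision", {
  for (N in c(0, 1, 1.08783e15)) {
    p <- model_parameters(N = N)
    eq <- cure_equilibrium(p)
    scale <- max(1, max(abs(eq$state)))
    expect_lte(max(abs(gbm_rhs(eq$state, p))), 1e-10 * scale)
  }
})
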