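test_that("CTL compartment follows its exact exponential when untreated", {
  sc <- scenario("fig1")
  traj <- simulate_gbm(sc$params, sc$init, t_end = 100)
  n <- nrow(traj$states)
  expect_equal(traj$times[n], 100)
  expect_lt(abs(traj$states[n, "C"] - 250 * exp(-.007 * 100)), .01)
})

test_that("scenario definitions carry the published conditions", {
  s1 <- scenario("fig1")
  expect_equal(s1$init[["T"]], 70)
  expect_equal(s1$init[["S"]], 30)
  expect_equal(s1$params$N, 0)
  s2 <- scenario("fig2")
  expect_equal(s2$init[["C"]], 2.5e10)
  expect_equal(s2$params$N, 1)
  s3 <- scenario("fig3")
  expect_equal(s3$init[["T"]], 7e5)
  expect_equal(s3$init[["S"]], 3e5)
  expect_equal(s3$params$N, 1.08783e15)
  expect_error(scenario("fig4"), "configuration error")
})

test_that("trajectories stay in the nonnegative orthant", {
  set.seed(21)
  p <- model_parameters(N = 1)
  for (i in 1:20) {
    init <- random_state(p)
    traj <- simulate_gbm(p, init, t_end = 200, n_out = 200)
    scale <- pmax(apply(abs(traj$states), 2, max), 1)
    expect_true(all(t(traj$states) >= -1e-10 * scale))
  }
})

test_that("state sum respects the dissipativity ceiling on all scenarios", {
  for (nm in c("fig1", "fig2", "fig3")) {
    sc <- scenario(nm)
    expect_true(w_bound_holds(sc$params, sc$init, sc$t_end, n_out = 300))
  }
})

test_that("state sum respects the ceiling on seeded perturbed calibrations", {
  fx <- generate_fixtures(seed = 20260925)
  init <- scenario("fig1")$init
  for (p in fx$perturbed)
    expect_true(w_bound_holds(p, init, t_end = 500, n_out = 120))
})

test_that("halving the tolerances leaves scenario endpoints unchanged", {
  for (nm in c("fig1", "fig2", "fig3")) {
    sc <- scenario(nm)
    a <- simulate_gbm(sc$params, sc$init, sc$t_end, n_out = 200)
    b <- simulate_gbm(sc$params, sc$init, sc$t_end, n_out = 200,
                      rtol = .5e-10, atol_cells = .5e-40,
                      atol_other = .5e-12)
    fa <- a$states[nrow(a$states), c("T", "S")]
    fb <- b$states[nrow(b$states), c("T", "S")]
    # relative above one cell, absolute below: sub-cell populations are
    # numerically unconstrained and biologically meaningless
    expect_lt(max(abs(fa - fb) / pmax(abs(fa), 1)), 1e-4)
  }
})

test_that("reduced flow keeps its invariant axis and limit set", {
  p <- model_parameters()
  ax <- simulate_reduced(p, c(0, 30), N = 0, t_end = 1000, n_out = 100)
  expect_true(all(ax$states[, "T"] == 0))
  r <- simulate_reduced(p, c(70, 30), N = 0, t_end = 20000, n_out = 200)
  fin <- r$states[nrow(r$states), ]
  eqs <- coexistence_equilibria(p, N = 0, n_grid = 128)
  d <- sqrt(((eqs$T - fin[["T"]]) / p$K1)^2 + ((eqs$S - fin[["S"]]) / p$K2)^2)
  expect_lt(min(d), 1e-6)
})

test_that("outcome classification follows the cell-threshold taxonomy", {
  sc <- scenario("fig1")
  short <- simulate_gbm(sc$params, sc$init, t_end = 500, n_out = 200)
  expect_equal(classify_outcome(short), "undecided")   # still growing
  expect_error(classify_outcome(list()), "invalid")
})
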