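# Shared generators for property-style tests.

# A random functional_forms bundle satisfying the structural (A2) contracts,
# including the abstract normalizations hT(0) = hS(0) = 1.
random_a2_forms <- function() {
  r1 <- runif(1, .01, .5); r2 <- runif(1, .01, .5)
  K1 <- runif(1, 50, 200); K2 <- runif(1, 20, 100)
  ra <- runif(1, .01, .2)
  aTx <- runif(1, .2, .9); aSx <- runif(1, .2, .9)
  eTx <- runif(1, 1, 10); eSx <- runif(1, 1, 10)
  aT <- runif(1, .5, 2); aS_ <- aT * runif(1, .05, .5)
  eT <- runif(1, 1, 10); eS <- eT
  hTc <- runif(1, 10, 100); hSc <- runif(1, 10, 100)
  aC <- runif(1, .1, 1); eC <- runif(1, 1, 10)
  bC <- runif(1, .1, .9)
  gx <- runif(1, .5, 5); ax <- runif(1, .01, .1)
  ay <- runif(1, .1, 1)
  gu <- runif(1, .2, 2); au <- runif(1, .5, 3); eu <- runif(1, 1, 10)
  av <- runif(1, .5, 3); ev <- runif(1, 1, 10); ex <- runif(1, 1, 10)
  mu <- c(C = runif(1, .05, .5), x = runif(1, .5, 3), y = runif(1, .1, 1),
          u = runif(1, .05, .5), v = runif(1, .05, .5))
  N <- runif(1, 1, 10)
  functional_forms(
    alpha = function(T, S) ra * (S / K2) * (T / K1) * (K1 - T),
    R1 = function(T) r1 * (1 - T / K1),
    R2 = function(S) r2 * (1 - S / K2),
    fT = function(x) aTx + (1 - aTx) * eTx / (x + eTx),
    fS = function(x) aSx + (1 - aSx) * eSx / (x + eSx),
    gT = function(u) aT * u / (u + eT),
    gS = function(u) aS_ * u / (u + eS),
    hT = function(T) hTc / (hTc + T),
    hS = function(S) hSc / (hSc + S),
    fC = function(w) aC * w / (w + eC),
    gC = function(x) bC + (1 - bC) * ex / (x + ex),
    fx = function(w) gx + ax * w,
    fy = function(C) ay * C,
    fu = function(y) gu + au * y / (y + eu),
    fv = function(x) ex / (x + ex),
    gv = function(y) av * y / (y + ev),
    mu = mu, N = N,
    scales = c(T = K1, S = K2, C = N / mu[["C"]], x = gx / mu[["x"]],
               y = 1, u = 1, v = 1))
}

# Tumor-free cure state of an abstract bundle (closed-form chain).
abstract_cure_state <- function(forms) {
  mu <- forms$mu
  Cs <- forms$N / mu[["C"]]
  xs <- forms$fx(0) / mu[["x"]]
  ys <- forms$fy(Cs) / mu[["y"]]
  us <- forms$fu(ys) / mu[["u"]]
  vs <- forms$fv(xs) * forms$gv(ys) / mu[["v"]]
  c(T = 0, S = 0, C = Cs, Fbeta = xs, Fgamma = ys, MI = us, MII = vs)
}

# Random nonnegative state with realistic component magnitudes.
random_state <- function(p = model_parameters()) {
  system_state(T = runif(1, 0, p$K1), S = runif(1, 0, p$K2),
               C = runif(1, 0, 1e6), Fbeta = runif(1, 0, 2e4),
               Fgamma = runif(1, 0, 1e3), MI = runif(1, 0, 300),
               MII = runif(1, 0, 200))
}

# Agreement with a value the source prints to few significant figures:
# within rel of the printed value, or rounding to the printed precision
# reproduces it exactly.
expect_printed <- function(x, printed, digits, rel = 1e-3) {
  ok <- abs(x - printed) / abs(printed) < rel ||
    identical(signif(x, digits), printed)
  expect_true(ok, label = sprintf("%.8g agrees with printed %.8g",
                                  x, printed))
}

# Sign-scan root oracle on a dense grid: strict sign changes, plus the
# upper endpoint when the function vanishes there exactly.
sign_scan_roots <- function(f, lower, upper, n = 1e6) {
  grid <- seq(lower, upper, length.out = n + 1)
  v <- f(grid)
  idx <- which(v[-length(v)] * v[-1] < 0)
  roots <- (grid[idx] + grid[idx + 1]) / 2
  if (v[length(v)] == 0) roots <- c(roots, upper)
  roots
}

# Does W(t) = sum of all compartments respect the dissipativity ceiling
# max(W(0), A/delta) along a simulated trajectory?
w_bound_holds <- function(params, init, t_end, ...) {
  traj <- simulate_gbm(params, init, t_end, ...)
  d <- dissipativity_constants(params, C0 = init[["C"]])
  W <- rowSums(traj$states)
  ceiling <- max(sum(init), d$A / d$delta) * (1 + 1e-6)
  max(W) <= ceiling
}
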