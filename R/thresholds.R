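# Treatment-threshold calculus: kill-pressure maps G1/G2, their inverses,
# minimal doses, amplification factors, and the sufficient cure dose.

# Hyperbolic TGF-beta suppression factors evaluated at a TGF-beta level x.
fbar_T <- function(x, p) p$aTbeta + p$eTbeta * (1 - p$aTbeta) / (x + p$eTbeta)
fbar_S <- function(x, p) p$aSbeta + p$eSbeta * (1 - p$aSbeta) / (x + p$eSbeta)

# IFN-gamma level of the cure branch as a function of the infusion rate N,
# and the MHC-I production rate X(N) / steady state MI*(N) it induces.
cure_Fgamma <- function(N, p) p$agammaC * N / (p$mugamma * p$muC)

mhc1_production <- function(N, p) {
  Fg <- cure_Fgamma(N, p)
  p$gMI + p$aMIgamma * Fg / (Fg + p$eMIgamma)
}

mhc1_steady <- function(N, p) mhc1_production(N, p) / p$muMI

# Effective MHC-I coordinate fed into the kill activation, by mode.
# "paper": the production rate X(N) -- the reading that reproduces every
# printed threshold value. "consistent": the steady state X(N)/muMI that the
# dynamics actually relax to.
mhc1_effective <- function(N, p, mode) {
  switch(mode,
         paper = mhc1_production(N, p),
         consistent = mhc1_steady(N, p),
         stop("mode must be 'paper' or 'consistent'"))
}

#' Treatment-induced kill pressure on each tumor compartment
#'
#' `kill_pressure_T(N)` (the map G1) and `kill_pressure_S(N)` (G2) give the
#' per-unit-kill-susceptibility pressure `g(u*(N)) C*(N)` that a constant
#' CTL infusion `N` exerts on the tumor-cell and stem-cell compartments on
#' the cure branch, where `C* = N/muC` and `u*` is the MHC-I coordinate
#' induced through the IFN-gamma chain. Both maps are strictly increasing
#' in `N`, which makes the dose thresholds well defined via inversion.
#'
#' Two conventions for the MHC-I coordinate are supported: `mode = "paper"`
#' uses the MHC-I production rate
#' `X(N) = gMI + aMIgamma Fgamma*/(Fgamma* + eMIgamma)` directly inside the
#' Michaelis--Menten activation, the convention under which the published
#' worked example evaluates; `mode = "consistent"` uses the MHC-I steady
#' state `X(N)/muMI`, the coordinate the simulated dynamics actually reach.
#'
#' @param N Infusion rate(s), cells/h (vectorized, nonnegative).
#' @param params A [model_parameters()] record.
#' @param mode `"paper"` (default) or `"consistent"`.
#' @return Kill pressure (h^-1 per suppression unit), same length as `N`.
#' @examples
#' kill_pressure_T(1, model_parameters())
#' @export
kill_pressure_T <- function(N, params, mode = "paper") {
  if (any(!is.finite(N)) || any(N < 0)) stop("N must be finite and >= 0")
  u <- mhc1_effective(N, params, mode)
  params$aT * u / (u + params$eT) * N / params$muC
}

#' @rdname kill_pressure_T
#' @export
kill_pressure_S <- function(N, params, mode = "paper") {
  if (any(!is.finite(N)) || any(N < 0)) stop("N must be finite and >= 0")
  u <- mhc1_effective(N, params, mode)
  params$aS * u / (u + params$eS) * N / params$muC
}

#' Invert a strictly increasing map by bracketed bisection
#'
#' Doubles the bracket upward from `[0, 1]` until the target is enclosed,
#' then bisects to a relative tolerance of `1e-12`. Used to invert the kill
#' pressures G1/G2 when converting growth-rate targets into doses.
#'
#' @param g A strictly increasing scalar function of a nonnegative argument.
#' @param target Value to invert at; must satisfy `target >= g(0)`.
#' @param rel_tol Relative tolerance on the returned argument.
#' @param max_upper Bracket ceiling; exceeding it raises an inversion error.
#' @return The `N` with `g(N) = target`.
#' @export
invert_monotone <- function(g, target, rel_tol = 1e-12, max_upper = 1e30) {
  g0 <- g(0)
  if (!is.finite(target) || target < g0)
    stop("inversion error: target ", format(target),
         " is below g(0) = ", format(g0))
  if (target == g0) return(0)
  hi <- 1
  while (g(hi) < target) {
    hi <- hi * 2
    if (hi > max_upper)
      stop("inversion error: bracket exceeded ", format(max_upper),
         " without enclosing target")
  }
  lo <- if (hi > 1) hi / 2 else 0
  # classic bisection; g increasing so g(lo) <= target <= g(hi)
  for (i in 1:2000) {
    mid <- (lo + hi) / 2
    if (g(mid) < target) lo <- mid else hi <- mid
    if ((hi - lo) <= rel_tol * max(hi, 1e-300)) break
  }
  (lo + hi) / 2
}

# Dense-grid maximization with local refinement: evaluates f on an n-point
# uniform grid over [lower, upper], then polishes the best bracket with
# Brent's method (stats::optimize) to relative tolerance rel_tol.
grid_maximize <- function(f, lower, upper, n = 1e5, rel_tol = 1e-10) {
  xs <- seq(lower, upper, length.out = n)
  fx <- f(xs)
  i <- which.max(fx)
  lo <- xs[max(i - 1L, 1L)]
  hi <- xs[min(i + 1L, length(xs))]
  o <- stats::optimize(f, c(lo, hi), maximum = TRUE,
                       tol = max(rel_tol * (upper - lower), 1e-14))
  if (o$objective >= fx[i]) {
    list(arg = o$maximum, value = o$objective)
  } else {
    list(arg = xs[i], value = fx[i])
  }
}

#' Dose thresholds for the coexistence system
#'
#' Computes the complete dose calculus for eliminating both tumor
#' compartments:
#' * `Nmin_T = G1^-1(r1 / fbar_T(gbeta/mubeta))` and
#'   `Nmin_S = G2^-1((r2 - ralpha K1/(4 K2)) / fbar_S(gbeta/mubeta))`, the
#'   minimal doses below which the cure state is locally unstable to the
#'   respective compartment;
#' * the amplification factors `aleph_T`, `aleph_S`: how much the kill
#'   pressure at the minimal dose must be scaled so the per-capita balance
#'   is negative across the whole invariant box, computed by maximizing the
#'   growth-to-kill ratio over `[0, K1]` (resp. `[0, K2]`) on a dense grid
#'   with local refinement;
#' * the sufficient doses `Nthr_T = G1^-1(G1(Nmin_T) aleph_T)`,
#'   `Nthr_S = G2^-1(G2(Nmin_S) aleph_S)`, and
#'   `Ncure = max(Nthr_T, Nthr_S)`, beyond which the cure state is globally
#'   asymptotically stable;
#' * the recurrence-submodel thresholds from [recurrence_thresholds()].
#'
#' In `mode = "paper"` the stem-cell maximand carries an extra factor `S`
#' (`R2(S) S (hS + S) / fbar_S(K1, S)`), the reading under which the
#' published example evaluates; `mode = "consistent"` drops that factor,
#' mirroring the tumor-compartment maximand exactly.
#'
#' @param params A [model_parameters()] record.
#' @param mode `"paper"` (default) or `"consistent"`; see
#'   [kill_pressure_T()].
#' @param n_grid Dense-grid size for the maximizations.
#' @return A list of class `"threshold_report"` with fields `Nmin_T`,
#'   `Nmin_S`, `aleph_T`, `aleph_S`, `Nthr_T`, `Nthr_S`, `Ncure`,
#'   `target_T`, `target_S` (the two inversion arguments),
#'   `recurrence_Nmin`, `recurrence_Nthr`, and `mode`.
#' @examples
#' \donttest{
#' compute_thresholds(model_parameters())
#' }
#' @export
compute_thresholds <- function(params, mode = "paper", n_grid = 1e5) {
  p <- params
  G1 <- function(N) kill_pressure_T(N, p, mode)
  G2 <- function(N) kill_pressure_S(N, p, mode)
  x0 <- tgfb_qss(0, 0, p)                       # gbeta / mubeta

  target_T <- p$r1 / fbar_T(x0, p)
  target_S <- (p$r2 - p$ralpha * p$K1 / (4 * p$K2)) / fbar_S(x0, p)
  if (target_S < 0)
    stop("stem-cell inversion target negative: differentiation outflow ",
         "exceeds growth; Nmin_S undefined")
  Nmin_T <- invert_monotone(G1, target_T)
  Nmin_S <- invert_monotone(G2, target_S)

  # growth-to-kill ratios over the invariant box, S (resp. T) pinned at its
  # carrying capacity where the suppression is strongest
  mT <- function(T) {
    (p$r1 * (1 - T / p$K1) + p$ralpha * p$K1) * (p$hT + T) /
      (target_T * fbar_T(tgfb_qss(T, p$K2, p), p))
  }
  mS <- function(S) {
    base <- p$r2 * (1 - S / p$K2) * (p$hS + S) /
      (target_S * fbar_S(tgfb_qss(p$K1, S, p), p))
    if (mode == "paper") base * S else base
  }
  aleph_T <- grid_maximize(mT, 0, p$K1, n = n_grid)$value
  aleph_S <- grid_maximize(mS, 0, p$K2, n = n_grid)$value

  Nthr_T <- invert_monotone(G1, target_T * aleph_T)
  Nthr_S <- invert_monotone(G2, target_S * aleph_S)

  rec <- recurrence_thresholds(p, mode = mode, n_grid = n_grid)

  structure(list(Nmin_T = Nmin_T, Nmin_S = Nmin_S,
                 aleph_T = aleph_T, aleph_S = aleph_S,
                 Nthr_T = Nthr_T, Nthr_S = Nthr_S,
                 Ncure = max(Nthr_T, Nthr_S),
                 target_T = target_T, target_S = target_S,
                 recurrence_Nmin = rec$Nmin, recurrence_Nthr = rec$Nthr,
                 mode = mode),
            class = "threshold_report")
}

#' Dose thresholds for the recurrence submodel
#'
#' With the tumor-cell compartment already eliminated (`T = 0`), the
#' stem-cell balance reduces to `S' = S L_N(S)` with
#' `L_N(S) = R2(S) - G(N) H(S)`, `H(S) = fbar_S(S)/(hS + S)`. This computes
#' `Nmin = G^-1(r2 / fbar_S(gbeta/mubeta))`, the dose above which `S = 0`
#' is locally stable, the amplification factor
#' `aleph = max_S R2(S) (hS + S) / (G(Nmin) fbar_S(S))`, and the sufficient
#' dose `Nthr = G^-1(G(Nmin) aleph)` beyond which `L_N < 0` on all of
#' `[0, K2]` and the recurrence-free state is globally stable.
#'
#' @inheritParams compute_thresholds
#' @return List with fields `Nmin`, `aleph`, `Nthr`, `mode`.
#' @export
recurrence_thresholds <- function(params, mode = "paper", n_grid = 1e5) {
  p <- params
  G <- function(N) kill_pressure_S(N, p, mode)
  x0 <- tgfb_qss(0, 0, p)
  target <- p$r2 / fbar_S(x0, p)
  Nmin <- invert_monotone(G, target)
  m <- function(S) {
    p$r2 * (1 - S / p$K2) * (p$hS + S) /
      (target * fbar_S(tgfb_qss(0, S, p), p))
  }
  aleph <- grid_maximize(m, 0, p$K2, n = n_grid)$value
  list(Nmin = Nmin, aleph = aleph,
       Nthr = invert_monotone(G, target * aleph), mode = mode)
}

# S-balance of the recurrence submodel, vectorized in S.
recurrence_L <- function(S, N, params, mode = "paper") {
  p <- params
  p$r2 * (1 - S / p$K2) -
    kill_pressure_S(N, p, mode) *
    fbar_S(tgfb_qss(0, S, p), p) / (p$hS + S)
}

#' @export
print.threshold_report <- function(x, ...) {
  cat("Treatment-dose thresholds (mode: ", x$mode, ")\n", sep = "")
  cat(sprintf("  Nmin_T  = %.6g cells/h   (inversion target %.6g)\n",
              x$Nmin_T, x$target_T))
  cat(sprintf("  Nmin_S  = %.6g cells/h   (inversion target %.6g)\n",
              x$Nmin_S, x$target_S))
  cat(sprintf("  aleph_T = %.6g          aleph_S = %.6g\n",
              x$aleph_T, x$aleph_S))
  cat(sprintf("  Nthr_T  = %.6g cells/h   Nthr_S  = %.6g cells/h\n",
              x$Nthr_T, x$Nthr_S))
  cat(sprintf("  Ncure   = %.6g cells/h\n", x$Ncure))
  cat(sprintf("  recurrence submodel: Nmin = %.6g, Nthr = %.6g\n",
              x$recurrence_Nmin, x$recurrence_Nthr))
  invisible(x)
}
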