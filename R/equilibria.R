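# Equilibria of the full and reduced systems: cure, recurrence, coexistence.

# Bracketed bisection for a continuous scalar function with a sign change on
# [lo, hi]. Returns the midpoint of the final bracket.
bisect_root <- function(f, lo, hi, rel_tol = 1e-12, max_iter = 2000) {
  flo <- f(lo); fhi <- f(hi)
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  if (sign(flo) == sign(fhi))
    stop("root-not-found error: no sign change on bracket [",
         format(lo), ", ", format(hi), "]")
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    if ((hi - lo) <= rel_tol * max(abs(hi), 1e-300)) break
  }
  (lo + hi) / 2
}

label_from_eigenvalues <- function(ev, tol_factor = 1e-12) {
  rho <- max(abs(ev), 1e-300)
  re <- Re(ev)
  if (any(abs(re) < tol_factor * rho)) return("marginal")
  if (all(re < 0)) "stable" else "unstable"
}

#' Cure-state equilibrium of the concrete model
#'
#' The tumor-free equilibrium in closed form: `T = S = 0`, `C* = N/muC`,
#' `Fbeta* = gbeta/mubeta`, `Fgamma* = agammaC C*/mugamma`,
#' `MI* = (gMI eMIgamma + (gMI + aMIgamma) Fgamma*) /
#' (muMI (eMIgamma + Fgamma*))`, and
#' `MII* = fv(Fbeta*) gv(Fgamma*) / muMII`. Its stability is classified from
#' the numerical eigenvalues of the Jacobian at the point.
#'
#' @param params A [model_parameters()] record; the treatment rate is
#'   `params$N`.
#' @return A list of class `"equilibrium_point"` with fields `state`
#'   (a [system_state()]), `residual` (max-norm of the right-hand side at
#'   the state), `eigenvalues` (7 complex values, decreasing real part) and
#'   `label` (`"stable"`, `"unstable"` or `"marginal"`).
#' @examples
#' cure_equilibrium(model_parameters())       # untreated: unstable
#' @export
cure_equilibrium <- function(params) {
  p <- params
  mus <- c(p$muC, p$mubeta, p$mugamma, p$muMI, p$muMII)
  if (any(mus <= 0)) stop("all death rates must be strictly positive")
  Cs <- p$N / p$muC
  Fb <- p$gbeta / p$mubeta
  Fg <- p$agammaC * Cs / p$mugamma
  MI <- (p$gMI * p$eMIgamma + (p$gMI + p$aMIgamma) * Fg) /
    (p$muMI * (p$eMIgamma + Fg))
  MII <- p$aMIIgamma * Fg / (Fg + p$eMIIgamma) *
    (p$aMIIbeta + p$eMIIbeta * (1 - p$aMIIbeta) / (Fb + p$eMIIbeta)) /
    p$muMII
  st <- system_state(T = 0, S = 0, C = Cs, Fbeta = Fb, Fgamma = Fg,
                     MI = MI, MII = MII)
  resid <- max(abs(gbm_rhs(st, p)))
  scale <- max(1, max(abs(st)))
  if (resid > 1e-8 * scale)
    stop("cure equilibrium residual ", format(resid),
         " exceeds contract 1e-8 * ", format(scale))
  ev <- cure_eigenvalues(p, method = "numeric")
  structure(list(state = st, residual = resid, eigenvalues = ev,
                 label = label_from_eigenvalues(ev)),
            class = "equilibrium_point")
}

#' @export
print.equilibrium_point <- function(x, ...) {
  cat("Equilibrium (", x$label, "), residual ", format(x$residual), "\n",
      sep = "")
  print(unclass(x$state))
  cat("eigenvalue real parts:",
      paste(format(Re(x$eigenvalues), digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' CTL level at a persistence equilibrium
#'
#' For fixed tumor burdens `(T, S)` the CTL balance at equilibrium reads
#' `H(C) = fC((T + S) v*(C)) gC(x*) - muC C + N = 0` where `x*` and `v*`
#' follow the steady-state chain. `H` is strictly decreasing with
#' `H(0) = fC(0) gC(x*) + N >= 0`, so the positive root is unique; it is
#' found by doubling the bracket and bisecting.
#'
#' @param T,S Fixed tumor and stem-cell populations (cells).
#' @param forms A [functional_forms()] bundle.
#' @param N Infusion rate; defaults to `forms$N`.
#' @return The unique root `C_p` (cells).
#' @export
solve_recruitment_C <- function(T, S, forms, N = forms$N) {
  f <- forms; mu <- f$mu
  xp <- f$fx(T + S) / mu[["x"]]
  H <- function(C) {
    yp <- f$fy(C) / mu[["y"]]
    vp <- f$fv(xp) * f$gv(yp) / mu[["v"]]
    f$fC((T + S) * vp) * f$gC(xp) - mu[["C"]] * C + N
  }
  if (H(0) <= 0) return(0)
  hi <- 1
  while (H(hi) > 0) {
    hi <- hi * 2
    if (hi > 1e30)
      stop("root-not-found error: no sign change below 1e30")
  }
  bisect_root(H, if (hi > 1) hi / 2 else 0, hi, rel_tol = 1e-12)
}

#' Recurrence equilibria of the reduced stem-cell submodel
#'
#' Finds all roots of `L_N(S) = R2(S) - G(N) H(S)` on `(0, K2]`, the
#' stem-cell balance after tumor-cell elimination, by a uniform sign scan
#' refined with bisection. A root is `"stable"` when `L_N` crosses downward
#' (positive to its left, negative to its right), `"unstable"` on an upward
#' crossing, and `"marginal"` on a tangential touch; with `L_N(0) > 0` the
#' transversal roots alternate starting from a stable one.
#'
#' @param params A [model_parameters()] record.
#' @param N Infusion rate (cells/h).
#' @param mode Kill-pressure convention, see [kill_pressure_T()].
#' @param n_scan Number of scan intervals over `(0, K2]`.
#' @return A data frame with columns `S` and `stability`; zero rows when
#'   the submodel has no positive equilibrium.
#' @export
recurrence_equilibria <- function(params, N, mode = "consistent",
                                  n_scan = 1e4) {
  p <- params
  L <- function(S) recurrence_L(S, N, p, mode)
  grid <- seq(0, p$K2, length.out = n_scan + 1)
  vals <- L(grid)
  roots <- numeric(0)
  eps <- 1e-12 * max(abs(vals), 1)
  for (i in seq_len(n_scan)) {
    a <- vals[i]; b <- vals[i + 1]
    if (abs(b) <= eps) {
      if (i == n_scan) roots <- c(roots, grid[i + 1])   # endpoint zero
    } else if (abs(a) > eps && sign(a) != sign(b)) {
      roots <- c(roots, bisect_root(L, grid[i], grid[i + 1]))
    }
  }
  roots <- roots[roots > 0]
  if (!length(roots))
    return(data.frame(S = numeric(0), stability = character(0)))
  roots <- sort(unique(roots))
  h <- pmax(1e-6 * p$K2, 1e-9)
  slope <- (L(pmin(roots + h, p$K2 * (1 + 1e-9))) - L(pmax(roots - h, 0))) /
    (2 * h)
  stab <- ifelse(abs(slope) < 1e-14 * max(abs(vals)), "marginal",
                 ifelse(slope < 0, "stable", "unstable"))
  data.frame(S = roots, stability = stab)
}

# Per-capita balances of the reduced two-compartment flow:
#   T' = T M1(T, S),  S' = S M2(T, S)
# with CTLs, IFN-gamma and MHC-I at their cure-branch steady states.
coexistence_M1 <- function(T, S, N, params, mode = "consistent") {
  p <- params
  p$r1 * (1 - T / p$K1) + p$ralpha * (S / p$K2) * (p$K1 - T) / p$K1 -
    kill_pressure_T(N, p, mode) *
    fbar_T(tgfb_qss(T, S, p), p) / (p$hT + T)
}

coexistence_M2 <- function(T, S, N, params, mode = "consistent") {
  p <- params
  p$r2 * (1 - S / p$K2) - p$ralpha * (T / p$K2) * (p$K1 - T) / p$K1 -
    kill_pressure_S(N, p, mode) *
    fbar_S(tgfb_qss(T, S, p), p) / (p$hS + S)
}

#' Coexistence equilibria of the reduced two-compartment flow
#'
#' Locates all intersections of the nullclines `M1 = 0` and `M2 = 0` on
#' `(0, K1] x (0, K2]` by scanning a uniform grid for cells in which both
#' per-capita balances change sign, then polishing each candidate with a
#' damped Newton iteration (finite-difference 2x2 Jacobian). Stability is
#' classified from the eigenvalues of the Jacobian of `(T M1, S M2)` at the
#' refined point.
#'
#' @param params A [model_parameters()] record.
#' @param N Infusion rate (cells/h).
#' @param mode Kill-pressure convention, see [kill_pressure_T()].
#' @param n_grid Grid resolution per axis (>= 100).
#' @return Data frame with columns `T`, `S`, `stability`; zero rows when no
#'   coexistence equilibrium exists.
#' @export
coexistence_equilibria <- function(params, N, mode = "consistent",
                                   n_grid = 512) {
  if (n_grid < 100) stop("grid resolution must be at least 100")
  p <- params
  M1 <- function(T, S) coexistence_M1(T, S, N, p, mode)
  M2 <- function(T, S) coexistence_M2(T, S, N, p, mode)
  Tg <- seq(0, p$K1, length.out = n_grid + 1)
  Sg <- seq(0, p$K2, length.out = n_grid + 1)
  m1 <- outer(Tg, Sg, M1)
  m2 <- outer(Tg, Sg, M2)

  sgn <- function(m) {
    # sign with exact zeros treated as straddling both signs
    lo <- m < 0 | m == 0
    hi <- m > 0 | m == 0
    list(lo = lo, hi = hi)
  }
  cell_change <- function(m) {
    s <- sgn(m)
    n <- n_grid
    anylo <- s$lo[1:n, 1:n] | s$lo[2:(n + 1), 1:n] |
      s$lo[1:n, 2:(n + 1)] | s$lo[2:(n + 1), 2:(n + 1)]
    anyhi <- s$hi[1:n, 1:n] | s$hi[2:(n + 1), 1:n] |
      s$hi[1:n, 2:(n + 1)] | s$hi[2:(n + 1), 2:(n + 1)]
    anylo & anyhi
  }
  cand <- which(cell_change(m1) & cell_change(m2), arr.ind = TRUE)
  if (!nrow(cand))
    return(data.frame(T = numeric(0), S = numeric(0),
                      stability = character(0)))

  newton2 <- function(T0, S0) {
    z <- c(T0, S0)
    hT0 <- p$K1 / n_grid; hS0 <- p$K2 / n_grid
    for (it in 1:100) {
      F <- c(M1(z[1], z[2]), M2(z[1], z[2]))
      if (all(abs(F) <= 1e-12)) break
      dT <- max(1e-6 * abs(z[1]), 1e-9 * hT0)
      dS <- max(1e-6 * abs(z[2]), 1e-9 * hS0)
      J <- cbind(
        c(M1(z[1] + dT, z[2]) - M1(z[1] - dT, z[2]),
          M2(z[1] + dT, z[2]) - M2(z[1] - dT, z[2])) / (2 * dT),
        c(M1(z[1], z[2] + dS) - M1(z[1], z[2] - dS),
          M2(z[1], z[2] + dS) - M2(z[1], z[2] - dS)) / (2 * dS))
      step <- tryCatch(solve(J, F), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) return(NULL)
      # damp to stay within one grid cell per move
      lim <- max(abs(step[1]) / hT0, abs(step[2]) / hS0, 1)
      z <- z - step / lim
      z[1] <- min(max(z[1], 0), p$K1)
      z[2] <- min(max(z[2], 0), p$K2)
    }
    if (max(abs(c(M1(z[1], z[2]), M2(z[1], z[2])))) > 1e-8) return(NULL)
    z
  }

  pts <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    z <- newton2((Tg[i] + Tg[i + 1]) / 2, (Sg[j] + Sg[j + 1]) / 2)
    if (!is.null(z) && z[1] > 0 && z[2] > 0) pts[[length(pts) + 1]] <- z
  }
  if (!length(pts))
    return(data.frame(T = numeric(0), S = numeric(0),
                      stability = character(0)))
  m <- do.call(rbind, pts)
  keep <- rep(TRUE, nrow(m))
  for (a in seq_len(nrow(m))) {
    if (!keep[a]) next
    for (b in seq_len(nrow(m))) {
      if (b <= a || !keep[b]) next
      if (abs(m[a, 1] - m[b, 1]) <= 1e-6 * p$K1 &&
          abs(m[a, 2] - m[b, 2]) <= 1e-6 * p$K2) keep[b] <- FALSE
    }
  }
  m <- m[keep, , drop = FALSE]

  stab <- character(nrow(m))
  for (k in seq_len(nrow(m))) {
    T0 <- m[k, 1]; S0 <- m[k, 2]
    fT <- function(T, S) T * M1(T, S)
    fS <- function(T, S) S * M2(T, S)
    dT <- max(1e-6 * T0, 1e-9 * p$K1)
    dS <- max(1e-6 * S0, 1e-9 * p$K2)
    J <- matrix(c(
      (fT(T0 + dT, S0) - fT(T0 - dT, S0)) / (2 * dT),
      (fT(T0, S0 + dS) - fT(T0, S0 - dS)) / (2 * dS),
      (fS(T0 + dT, S0) - fS(T0 - dT, S0)) / (2 * dT),
      (fS(T0, S0 + dS) - fS(T0, S0 - dS)) / (2 * dS)), 2, 2, byrow = TRUE)
    stab[k] <- label_from_eigenvalues(eigen(J, only.values = TRUE)$values,
                                      tol_factor = 1e-9)
  }
  ord <- order(m[, 1], m[, 2])
  data.frame(T = m[ord, 1], S = m[ord, 2], stability = stab[ord])
}
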