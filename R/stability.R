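# Jacobians, cure-state spectra, decay-rate certificates, dissipativity,
# and the grid certificate for global stability of the cure state.

#' Jacobian of the system at a state
#'
#' Central finite differences with per-component relative step `1e-6`
#' (absolute floor `1e-8`). `model` may be a [model_parameters()] record
#' (concrete system, [gbm_rhs()]) or a [functional_forms()] bundle
#' (abstract system, [abstract_rhs()]). For the concrete system
#' `method = "analytic"` returns the exact Jacobian, against which the
#' finite-difference variant is validated.
#'
#' @param state Numeric state vector of length 7.
#' @param model Parameters or forms.
#' @param method `"fd"` (default) or `"analytic"` (concrete model only).
#' @return A 7x7 numeric matrix with rows/columns in state order.
#' @export
jacobian_at <- function(state, model, method = c("fd", "analytic")) {
  method <- match.arg(method)
  s <- as_state(state)
  if (any(!is.finite(s))) stop("non-finite state component")
  if (method == "analytic") {
    if (!inherits(model, "gbm_params") && is.null(model$r1))
      stop("analytic Jacobian is available for the concrete model only")
    return(jacobian_gbm_analytic(s, model))
  }
  rhs <- if (inherits(model, "functional_forms"))
    function(z) abstract_rhs(z, model)
  else function(z) gbm_rhs(z, model)
  J <- matrix(0, 7, 7, dimnames = list(state_names(), state_names()))
  for (i in 1:7) {
    h <- max(1e-8, 1e-6 * abs(s[i]))
    up <- s; up[i] <- s[i] + h
    dn <- s; dn[i] <- s[i] - h
    J[, i] <- (rhs(up) - rhs(dn)) / (2 * h)
  }
  if (any(!is.finite(J))) stop("non-finite Jacobian entries")
  J
}

# Exact Jacobian of the concrete system.
jacobian_gbm_analytic <- function(s, p) {
  T <- s[["T"]]; S <- s[["S"]]; C <- s[["C"]]
  Fb <- s[["Fbeta"]]; Fg <- s[["Fgamma"]]; MI <- s[["MI"]]

  phiT <- p$aTbeta + p$eTbeta * (1 - p$aTbeta) / (Fb + p$eTbeta)
  phiS <- p$aSbeta + p$eSbeta * (1 - p$aSbeta) / (Fb + p$eSbeta)
  dphiT <- -p$eTbeta * (1 - p$aTbeta) / (Fb + p$eTbeta)^2
  dphiS <- -p$eSbeta * (1 - p$aSbeta) / (Fb + p$eSbeta)^2
  gT <- p$aT * MI / (MI + p$eT)
  gS <- p$aS * MI / (MI + p$eS)
  dgT <- p$aT * p$eT / (MI + p$eT)^2
  dgS <- p$aS * p$eS / (MI + p$eS)^2
  qT <- T / (p$hT + T); dqT <- p$hT / (p$hT + T)^2
  qS <- S / (p$hS + S); dqS <- p$hS / (p$hS + S)^2

  J <- matrix(0, 7, 7, dimnames = list(state_names(), state_names()))
  # T' = r1 T (1 - T/K1) + ralpha (S/K2)(T/K1)(K1 - T) - gT phiT C qT
  J["T", "T"] <- p$r1 * (1 - 2 * T / p$K1) +
    p$ralpha * (S / p$K2) * (1 - 2 * T / p$K1) - gT * phiT * C * dqT
  J["T", "S"] <- p$ralpha * (T / p$K1) * (p$K1 - T) / p$K2
  J["T", "C"] <- -gT * phiT * qT
  J["T", "Fbeta"] <- -gT * dphiT * C * qT
  J["T", "MI"] <- -dgT * phiT * C * qT
  # S' = r2 S (1 - S/K2) - alpha - gS phiS C qS
  J["S", "T"] <- -p$ralpha * (S / p$K2) * (1 - 2 * T / p$K1)
  J["S", "S"] <- p$r2 * (1 - 2 * S / p$K2) -
    p$ralpha * (T / p$K1) * (p$K1 - T) / p$K2 - gS * phiS * C * dqS
  J["S", "C"] <- -gS * phiS * qS
  J["S", "Fbeta"] <- -gS * dphiS * C * qS
  J["S", "MI"] <- -dgS * phiS * C * qS
  # C' = -muC C + N
  J["C", "C"] <- -p$muC
  # Fbeta' = gbeta + abetaT T + abetaS S - mubeta Fbeta
  J["Fbeta", "T"] <- p$abetaT
  J["Fbeta", "S"] <- p$abetaS
  J["Fbeta", "Fbeta"] <- -p$mubeta
  # Fgamma' = agammaC C - mugamma Fgamma
  J["Fgamma", "C"] <- p$agammaC
  J["Fgamma", "Fgamma"] <- -p$mugamma
  # MI' = gMI + aMIgamma Fg/(Fg + eMIgamma) - muMI MI
  J["MI", "Fgamma"] <- p$aMIgamma * p$eMIgamma / (Fg + p$eMIgamma)^2
  J["MI", "MI"] <- -p$muMI
  # MII' = aMIIgamma Fg/(Fg + eMIIgamma) fv(Fb) - muMII MII
  fv <- p$aMIIbeta + p$eMIIbeta * (1 - p$aMIIbeta) / (Fb + p$eMIIbeta)
  J["MII", "Fgamma"] <- p$aMIIgamma * p$eMIIgamma /
    (Fg + p$eMIIgamma)^2 * fv
  J["MII", "Fbeta"] <- p$aMIIgamma * Fg / (Fg + p$eMIIgamma) *
    (-p$eMIIbeta * (1 - p$aMIIbeta) / (Fb + p$eMIIbeta)^2)
  J["MII", "MII"] <- -p$muMII
  J
}

#' Eigenvalues of the cure state
#'
#' For the concrete model, `method = "numeric"` returns the eigenvalues of
#' the analytic Jacobian evaluated at the closed-form cure state. The
#' Jacobian at the cure state is reducible: five eigenvalues are the death
#' rates `-muC, -mubeta, -mugamma, -muMI, -muMII`, and the remaining two
#' are the tumor and stem-cell invasion rates
#' `r1 - fT(x*) gT(u*) hT(0) C*` and `r2 - fS(x*) gS(u*) hS(0) C*`, which
#' `method = "closed"` returns directly (for the concrete kill form
#' `hT(0) = 1/hT`).
#'
#' @param params A [model_parameters()] record.
#' @param N Infusion rate; defaults to `params$N`.
#' @param method `"numeric"` or `"closed"`.
#' @return Seven eigenvalues sorted by decreasing real part.
#' @export
cure_eigenvalues <- function(params, N = params$N,
                             method = c("numeric", "closed")) {
  method <- match.arg(method)
  p <- params; p$N <- N
  if (method == "closed") {
    Cs <- N / p$muC
    xs <- p$gbeta / p$mubeta
    us <- mhc1_steady(N, p)
    ev <- c(p$r1 - fbar_T(xs, p) * p$aT * us / (us + p$eT) * Cs / p$hT,
            p$r2 - fbar_S(xs, p) * p$aS * us / (us + p$eS) * Cs / p$hS,
            -p$muC, -p$mubeta, -p$mugamma, -p$muMI, -p$muMII)
  } else {
    Cs <- N / p$muC
    Fb <- p$gbeta / p$mubeta
    Fg <- p$agammaC * Cs / p$mugamma
    MI <- (p$gMI * p$eMIgamma + (p$gMI + p$aMIgamma) * Fg) /
      (p$muMI * (p$eMIgamma + Fg))
    MII <- p$aMIIgamma * Fg / (Fg + p$eMIIgamma) *
      (p$aMIIbeta + p$eMIIbeta * (1 - p$aMIIbeta) / (Fb + p$eMIIbeta)) /
      p$muMII
    st <- c(T = 0, S = 0, C = Cs, Fbeta = Fb, Fgamma = Fg, MI = MI,
            MII = MII)
    ev <- eigen(jacobian_gbm_analytic(st, p), only.values = TRUE)$values
  }
  ev[order(-Re(ev))]
}

#' Closed-form cure eigenvalues of an abstract system
#'
#' For a [functional_forms()] bundle the Jacobian at the tumor-free state
#' reduces to the five death rates plus the two invasion rates
#' `R1(0) - fT(x*) gT(u*) hT(0) C*` and `R2(0) - fS(x*) gS(u*) hS(0) C*`
#' with the cure-branch chain `C* = N/muC`, `x* = fx(0)/mux`,
#' `y* = fy(C*)/muy`, `u* = fu(y*)/muu`. When `hT(0) = hS(0) = 1` this is
#' the canonical abstract spectrum.
#'
#' @param forms A [functional_forms()] bundle.
#' @param N Infusion rate; defaults to `forms$N`.
#' @return Seven eigenvalues sorted by decreasing real part.
#' @export
cure_eigenvalues_closed <- function(forms, N = forms$N) {
  f <- forms; mu <- f$mu
  Cs <- N / mu[["C"]]
  xs <- f$fx(0) / mu[["x"]]
  ys <- f$fy(Cs) / mu[["y"]]
  us <- f$fu(ys) / mu[["u"]]
  ev <- c(f$R1(0) - f$fT(xs) * f$gT(us) * f$hT(0) * Cs,
          f$R2(0) - f$fS(xs) * f$gS(us) * f$hS(0) * Cs,
          -mu[["C"]], -mu[["x"]], -mu[["y"]], -mu[["u"]], -mu[["v"]])
  ev[order(-Re(ev))]
}

#' Local stability of the cure state
#'
#' For the concrete model, tests whether the largest real part of the cure
#' spectrum is negative (tolerance `1e-12` times the spectral radius; within
#' tolerance the verdict is `NA`, "marginal"). For an abstract bundle, the
#' two invasion-rate inequalities are evaluated in closed form. The margin
#' is the distance of the leading real part from zero.
#'
#' @param model Parameters or forms.
#' @param N Infusion rate; defaults to the model's own.
#' @return List with `stable` (logical, `NA` if marginal) and `margin`
#'   (h^-1, positive when stable).
#' @export
is_cure_stable <- function(model, N = NULL) {
  if (inherits(model, "functional_forms")) {
    if (is.null(N)) N <- model$N
    ev <- cure_eigenvalues_closed(model, N)
  } else {
    if (is.null(N)) N <- model$N
    ev <- cure_eigenvalues(model, N, method = "numeric")
  }
  lead <- max(Re(ev))
  rho <- max(abs(ev), 1e-300)
  stable <- if (abs(lead) < 1e-12 * rho) NA else lead < 0
  list(stable = stable, margin = -lead)
}

#' Exponential decay-rate certificates for the tumor compartments
#'
#' At treatment `N`, bounds the per-capita growth of each compartment by
#' its worst case over the invariant box:
#' `a1 = gT(u*) C* - (r1 + ralpha K1^2/4) / (hT(K1) fT(x_max))` and
#' `a2 = gS(u*) C* - r2 / (hS(K2) fS(x_max))`, with
#' `x_max = (gbeta + abetaT K1 + abetaS K2)/mubeta` the largest TGF-beta
#' level on the box and `u*` the cure-branch MHC-I steady state. Positive
#' values certify `T' <= -a1 T` and `S' <= -a2 S`, i.e. exponential decay.
#' For the concrete kill form `hT(K1) = 1/(hT + K1)`.
#'
#' @param params A [model_parameters()] record.
#' @param N Infusion rate; defaults to `params$N`.
#' @return Named vector `c(a1, a2)` (h^-1).
#' @export
cure_decay_rates <- function(params, N = params$N) {
  p <- params
  Cs <- N / p$muC
  us <- mhc1_steady(N, p)
  xmax <- tgfb_qss(p$K1, p$K2, p)
  a1 <- p$aT * us / (us + p$eT) * Cs -
    (p$r1 + p$ralpha * p$K1^2 / 4) * (p$hT + p$K1) / fbar_T(xmax, p)
  a2 <- p$aS * us / (us + p$eS) * Cs -
    p$r2 * (p$hS + p$K2) / fbar_S(xmax, p)
  c(a1 = a1, a2 = a2)
}

#' Dissipativity constants of the system
#'
#' Builds the explicit constants in the dissipativity inequality
#' `grad(W) . F <= A - delta W` for the state sum
#' `W = T + S + C + Fbeta + Fgamma + MI + MII`: the linear logistic bounds
#' `R1(T) T <= a1 - b1 T` with `a1 = r1 K1`, `b1 = r1` (valid because
#' `r1 T (1 - T/K1) <= r1 K1 - r1 T` is `(T - K1)^2 >= 0`), analogously for
#' the stem-cell compartment; supremum bounds on every inflow; and
#' `delta = min(b1, b2, muC, mubeta, mugamma, muMI, muMII)`. Along any
#' trajectory `W(t) <= max(W(0), A/delta)`, so the dynamics have a compact
#' global attractor.
#'
#' @param params A [model_parameters()] record.
#' @param C0 Initial CTL count, which enters the IFN-gamma inflow bound
#'   through `Cmax = max(N/muC, C0)`.
#' @return List of class `"dissipativity_constants"` with fields `a1`,
#'   `b1`, `a2`, `b2`, `c_max`, `fbar_x`, `fbar_y`, `fbar_u`, `fbar_v`,
#'   `A`, and `delta`.
#' @export
dissipativity_constants <- function(params, C0 = 0) {
  p <- params
  c_max <- 0   # the concrete CTL equation has no recruitment term
  Cmax <- max((c_max + p$N) / p$muC, C0)
  fbar_x <- p$gbeta + p$abetaT * p$K1 + p$abetaS * p$K2
  fbar_y <- p$agammaC * Cmax
  fbar_u <- p$gMI + p$aMIgamma
  fbar_v <- p$aMIIgamma          # sup fv gv <= fv(0) sup gv
  delta <- min(p$r1, p$r2, p$muC, p$mubeta, p$mugamma, p$muMI, p$muMII)
  A <- p$r1 * p$K1 + p$r2 * p$K2 + c_max + p$N +
    fbar_x + fbar_y + fbar_u + fbar_v
  structure(list(a1 = p$r1 * p$K1, b1 = p$r1,
                 a2 = p$r2 * p$K2, b2 = p$r2,
                 c_max = c_max, fbar_x = fbar_x, fbar_y = fbar_y,
                 fbar_u = fbar_u, fbar_v = fbar_v,
                 A = A, delta = delta),
            class = "dissipativity_constants")
}

#' @export
print.dissipativity_constants <- function(x, ...) {
  cat("Dissipativity certificate: grad(W).F <= A - delta W\n")
  cat(sprintf("  A = %.6g, delta = %.6g, A/delta = %.6g\n",
              x$A, x$delta, x$A / x$delta))
  invisible(x)
}

#' Grid certificate for global stability of the cure state
#'
#' Verifies the sufficient condition for global cure on the reduced
#' two-compartment flow: `L1(T, S) + ralpha K1 < 0` and `L2(T, S) < 0`
#' everywhere on a uniform grid over `[0, K1] x [0, K2]`, where
#' `L1 = R1(T) - G1(N) fbar_T(T, S)/(hT + T)` and `L2` analogously. When
#' both hold, every orbit of the bounding comparison system decays to the
#' origin, so the cure state attracts globally.
#'
#' @param params A [model_parameters()] record.
#' @param N Infusion rate (cells/h).
#' @param n_grid Grid resolution per axis (>= 128).
#' @param mode Kill-pressure convention, see [kill_pressure_T()].
#' @return `TRUE` if the certificate holds on the grid, else `FALSE`.
#' @export
verify_global_cure <- function(params, N, n_grid = 512, mode = "paper") {
  if (n_grid < 128) stop("grid resolution must be at least 128")
  p <- params
  Tg <- seq(0, p$K1, length.out = n_grid)
  Sg <- seq(0, p$K2, length.out = n_grid)
  x <- outer(Tg, Sg, function(T, S) tgfb_qss(T, S, p))
  G1 <- kill_pressure_T(N, p, mode)
  G2 <- kill_pressure_S(N, p, mode)
  L1 <- p$r1 * (1 - Tg / p$K1) - G1 * fbar_T(x, p) / (p$hT + Tg)
  L2 <- p$r2 * rep(1 - Sg / p$K2, each = n_grid) -
    G2 * fbar_S(x, p) / (p$hS + rep(Sg, each = n_grid))
  all(L1 + p$ralpha * p$K1 < 0) && all(L2 < 0)
}
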