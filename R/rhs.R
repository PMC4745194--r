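#' Right-hand side of the concrete glioblastoma model
#'
#' Evaluates the time derivatives of the seven-variable
#' glioblastoma--cancer-stem-cell--immunotherapy system at a state, exactly
#' as the model is written: logistic tumor and stem-cell growth, a
#' differentiation flux `ralpha (S/K2)(T/K1)(K1 - T)` from stem cells into
#' tumor cells, CTL kill terms with Michaelis--Menten MHC-I activation
#' `a u/(u + e)`, hyperbolic TGF-beta suppression
#' `abeta + ebeta (1 - abeta)/(Fbeta + ebeta)`, and access-limited saturation
#' `T/(hT + T)`; constant CTL inflow `N` with linear death; affine TGF-beta
#' and linear IFN-gamma production; saturating MHC-I/II expression.
#'
#' @param state Numeric state vector, see [system_state()].
#' @param params A [model_parameters()] record (the infusion rate is
#'   `params$N`).
#' @return Named numeric vector of the seven rates (units of each component
#'   per hour).
#' @examples
#' p <- model_parameters()
#' gbm_rhs(system_state(70, 30, 250, 50, 50, 50, 50), p)
#' @export
gbm_rhs <- function(state, params) {
  s <- as_state(state)
  if (any(!is.finite(s))) stop("non-finite state component")
  p <- params
  T <- s[["T"]]; S <- s[["S"]]; C <- s[["C"]]
  Fb <- s[["Fbeta"]]; Fg <- s[["Fgamma"]]
  MI <- s[["MI"]]; MII <- s[["MII"]]

  alpha  <- p$ralpha * (S / p$K2) * (T / p$K1) * (p$K1 - T)
  killT  <- p$aT * MI / (MI + p$eT) *
    (p$aTbeta + p$eTbeta * (1 - p$aTbeta) / (Fb + p$eTbeta)) *
    C * T / (p$hT + T)
  killS  <- p$aS * MI / (MI + p$eS) *
    (p$aSbeta + p$eSbeta * (1 - p$aSbeta) / (Fb + p$eSbeta)) *
    C * S / (p$hS + S)

  c(T      = p$r1 * T * (1 - T / p$K1) + alpha - killT,
    S      = p$r2 * S * (1 - S / p$K2) - alpha - killS,
    C      = -p$muC * C + p$N,
    Fbeta  = p$gbeta + p$abetaT * T + p$abetaS * S - p$mubeta * Fb,
    Fgamma = p$agammaC * C - p$mugamma * Fg,
    MI     = p$gMI + p$aMIgamma * Fg / (Fg + p$eMIgamma) - p$muMI * MI,
    MII    = p$aMIIgamma * Fg / (Fg + p$eMIIgamma) *
      (p$aMIIbeta + p$eMIIbeta * (1 - p$aMIIbeta) / (Fb + p$eMIIbeta)) -
      p$muMII * MII)
}

#' Right-hand side of the abstract tumor-immune system
#'
#' Evaluates the abstract seven-variable system for an arbitrary
#' [functional_forms()] bundle. With `forms = kronik_forms(params)` this
#' agrees with [gbm_rhs()] to machine precision, term for term.
#'
#' @param state Numeric state vector, see [system_state()].
#' @param forms A [functional_forms()] bundle (death rates and the constant
#'   inflow `N` live inside it).
#' @return Named numeric vector of the seven rates.
#' @export
abstract_rhs <- function(state, forms) {
  s <- as_state(state)
  if (any(!is.finite(s))) stop("non-finite state component")
  f <- forms
  T <- s[["T"]]; S <- s[["S"]]; C <- s[["C"]]
  x <- s[["Fbeta"]]; y <- s[["Fgamma"]]; u <- s[["MI"]]; v <- s[["MII"]]
  mu <- f$mu
  a <- f$alpha(T, S)
  c(T      = a + f$R1(T) * T - f$fT(x) * f$gT(u) * f$hT(T) * C * T,
    S      = f$R2(S) * S - a - f$fS(x) * f$gS(u) * f$hS(S) * C * S,
    C      = f$fC((T + S) * v) * f$gC(x) - mu[["C"]] * C + f$N,
    Fbeta  = f$fx(T + S) - mu[["x"]] * x,
    Fgamma = f$fy(C) - mu[["y"]] * y,
    MI     = f$fu(y) - mu[["u"]] * u,
    MII    = f$fv(x) * f$gv(y) - mu[["v"]] * v)
}

#' Quasi-steady-state level of TGF-beta
#'
#' TGF-beta turnover (`mubeta = 7` per hour at the default calibration) is
#' much faster than every other compartment, so on the slow time scale it
#' tracks its equilibrium `x* = fx(T + S) / mubeta`. This helper returns
#' that level.
#'
#' @param T,S Tumor and stem-cell populations (cells).
#' @param params A [model_parameters()] record.
#' @return TGF-beta level (pg).
#' @examples
#' tgfb_qss(0, 0, model_parameters())   # gbeta / mubeta = 9135 pg
#' @export
tgfb_qss <- function(T, S, params) {
  if (params$mubeta <= 0) stop("mubeta must be strictly positive")
  (params$gbeta + params$abetaT * T + params$abetaS * S) / params$mubeta
}

#' Right-hand side of the fast-TGF-beta reduced system
#'
#' Substitutes the quasi-steady-state TGF-beta level [tgfb_qss()] into the
#' full system and drops the TGF-beta equation, leaving six state variables
#' `(T, S, C, Fgamma, MI, MII)`. The suppression factors become
#' `fbar(T, S) = f(fx(T + S)/mubeta)` evaluated along the slow manifold.
#'
#' @param state Numeric vector of length 6 named
#'   `T, S, C, Fgamma, MI, MII` (or positional in that order).
#' @param params A [model_parameters()] record.
#' @return Named numeric vector of the six reduced rates.
#' @export
reduced_tgfb_rhs <- function(state, params) {
  nm <- c("T", "S", "C", "Fgamma", "MI", "MII")
  if (!is.numeric(state) || length(state) != 6)
    stop("reduced state must be a numeric vector of length 6")
  if (!is.null(names(state)) && all(nm %in% names(state)))
    state <- state[nm]
  state <- stats::setNames(as.numeric(state), nm)
  xs <- tgfb_qss(state[["T"]], state[["S"]], params)
  full <- gbm_rhs(c(state[["T"]], state[["S"]], state[["C"]], xs,
                    state[["Fgamma"]], state[["MI"]], state[["MII"]]),
                  params)
  full[c("T", "S", "C", "Fgamma", "MI", "MII")]
}
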