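#' Pluggable functional forms of the abstract tumor-immune system
#'
#' The abstract model leaves its sixteen interaction functions free, subject
#' to structural assumptions (see [check_A1()] / [check_A2()]). A
#' `functional_forms` bundle collects them, together with the death-rate
#' vector and the constant CTL inflow, so the same machinery can evaluate
#' either the abstract system or the concrete glioblastoma instantiation.
#'
#' The functions and their roles (x = TGF-beta, y = IFN-gamma, u = MHC-I,
#' v = MHC-II, w = total MHC-II burden (T+S)v):
#' * `alpha(T, S)`: differentiation flux from stem cells to tumor cells.
#' * `R1(T)`, `R2(S)`: per-capita logistic-type growth.
#' * `fT(x)`, `fS(x)`: TGF-beta suppression of CTL kill (decreasing from 1).
#' * `gT(u)`, `gS(u)`: MHC-I dependence of CTL kill (increasing from 0).
#' * `hT(T)`, `hS(S)`: tumor-access saturation of the kill term.
#' * `fC(w)`: CTL recruitment; `gC(x)`: TGF-beta suppression of recruitment.
#' * `fx(T + S)`: TGF-beta production; `fy(C)`: IFN-gamma production.
#' * `fu(y)`: MHC-I expression; `fv(x)`, `gv(y)`: MHC-II expression factors.
#'
#' @param alpha,R1,R2,fT,fS,gT,gS,hT,hS,fC,gC,fx,fy,fu,fv,gv Vectorized
#'   real-valued functions as described above; each must be finite and
#'   nonnegative on the nonnegative orthant.
#' @param mu Named death-rate vector with entries `C`, `x`, `y`, `u`, `v`
#'   (all strictly positive, h^-1).
#' @param N Constant CTL infusion rate (cells h^-1).
#' @param scales Optional named vector of characteristic magnitudes for
#'   `T`, `S`, `C`, `x`, `y`, `u`, `v`, used by the assumptions checker to
#'   place its evaluation grids.
#' @return A list of class `"functional_forms"`.
#' @seealso [kronik_forms()] for the concrete glioblastoma instantiation.
#' @export
functional_forms <- function(alpha, R1, R2, fT, fS, gT, gS, hT, hS,
                             fC, gC, fx, fy, fu, fv, gv,
                             mu, N = 0, scales = NULL) {
  fns <- list(alpha = alpha, R1 = R1, R2 = R2, fT = fT, fS = fS,
              gT = gT, gS = gS, hT = hT, hS = hS, fC = fC, gC = gC,
              fx = fx, fy = fy, fu = fu, fv = fv, gv = gv)
  notfun <- names(fns)[!vapply(fns, is.function, logical(1))]
  if (length(notfun))
    stop("missing or non-function form(s): ", paste(notfun, collapse = ", "))
  need <- c("C", "x", "y", "u", "v")
  if (is.null(names(mu)) || !all(need %in% names(mu)))
    stop("mu must be a named vector with entries C, x, y, u, v")
  mu <- mu[need]
  if (any(mu <= 0)) stop("all death rates must be strictly positive")
  if (!is.finite(N) || N < 0) stop("N must be finite and nonnegative")
  if (is.null(scales))
    scales <- c(T = 1e8, S = 1e7, C = 1e4, x = 1e4, y = 1e3, u = 1e2,
                v = 1e2)
  structure(c(fns, list(mu = mu, N = N, scales = scales)),
            class = "functional_forms")
}

#' Concrete glioblastoma forms (Kronik-type instantiation)
#'
#' Builds the `functional_forms` bundle whose abstract right-hand side
#' reproduces, term for term, the concrete seven-equation glioblastoma
#' model simulated by [gbm_rhs()]: logistic growth for both tumor
#' compartments, Michaelis--Menten MHC-I kill activation, hyperbolic
#' TGF-beta suppression, a `1/(h + population)` access-limited kill factor,
#' constant CTL inflow (no recruitment term, `fC = 0`), affine TGF-beta
#' production, and linear IFN-gamma production.
#'
#' Note that the concrete kill factor `hT(T) = 1/(hT + T)` is the printed
#' form of the model and does not satisfy the abstract normalization
#' `hT(0) = 1`; the assumptions checker flags this deliberately.
#'
#' @param params A [model_parameters()] record.
#' @return A `functional_forms` bundle.
#' @export
kronik_forms <- function(params) {
  p <- params
  # fx sees only the total burden T + S, so the abstract bundle can only
  # reproduce the concrete model exactly when both secretion rates agree
  if (p$abetaT != p$abetaS)
    warning("abetaT != abetaS: fx(T + S) uses abetaT; ",
            "abstract and concrete right-hand sides will differ")
  functional_forms(
    alpha = function(T, S) p$ralpha * (S / p$K2) * (T / p$K1) * (p$K1 - T),
    R1 = function(T) p$r1 * (1 - T / p$K1),
    R2 = function(S) p$r2 * (1 - S / p$K2),
    fT = function(x) p$aTbeta + p$eTbeta * (1 - p$aTbeta) / (x + p$eTbeta),
    fS = function(x) p$aSbeta + p$eSbeta * (1 - p$aSbeta) / (x + p$eSbeta),
    gT = function(u) p$aT * u / (u + p$eT),
    gS = function(u) p$aS * u / (u + p$eS),
    hT = function(T) 1 / (p$hT + T),
    hS = function(S) 1 / (p$hS + S),
    fC = function(w) 0 * w,
    gC = function(x) 1 + 0 * x,
    fx = function(w) p$gbeta + p$abetaT * w,
    fy = function(C) p$agammaC * C,
    fu = function(y) p$gMI + p$aMIgamma * y / (y + p$eMIgamma),
    fv = function(x) p$aMIIbeta +
      p$eMIIbeta * (1 - p$aMIIbeta) / (x + p$eMIIbeta),
    gv = function(y) p$aMIIgamma * y / (y + p$eMIIgamma),
    mu = c(C = p$muC, x = p$mubeta, y = p$mugamma, u = p$muMI, v = p$muMII),
    N = p$N,
    scales = c(T = p$K1, S = p$K2,
               C = max(p$N / p$muC, 1e4),
               x = p$gbeta / p$mubeta,
               y = max(p$agammaC * max(p$N / p$muC, 1e4) / p$mugamma,
                       p$eMIgamma, p$eMIIgamma),
               u = (p$gMI + p$aMIgamma) / p$muMI,
               v = p$aMIIgamma / p$muMII))
}
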