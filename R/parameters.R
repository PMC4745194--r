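#' Model parameters for the GBM / cancer-stem-cell immunotherapy system
#'
#' Constructs the full parameter record of the seven-variable
#' glioblastoma--cancer-stem-cell--immunotherapy model. Defaults are the
#' published, biologically calibrated values (all rates per hour, populations
#' in cells, cytokines in pg, receptor densities in receptors per cell).
#' The record is a flat named list of class `"gbm_params"`; derived quantities
#' are never stored in it.
#'
#' @param r1 Tumor-cell logistic growth rate (h^-1).
#' @param K1 Tumor-cell carrying capacity (cells).
#' @param aT Maximal CTL kill rate of tumor cells (h^-1).
#' @param eT MHC-I Michaelis constant for tumor kill (rec cell^-1).
#' @param aTbeta Residual kill fraction under saturating TGF-beta
#'   (dimensionless, in \[0, 1\]).
#' @param eTbeta TGF-beta suppression constant for tumor kill (pg).
#' @param hT Tumor-access saturation constant of the kill term (cells).
#' @param r2 Cancer-stem-cell logistic growth rate (h^-1).
#' @param K2 Cancer-stem-cell carrying capacity (cells).
#' @param ralpha Rate at which stem cells differentiate into tumor cells
#'   (h^-1).
#' @param aS,eS,aSbeta,eSbeta,hS Stem-cell analogues of `aT`, `eT`, `aTbeta`,
#'   `eTbeta`, `hT`.
#' @param muC CTL death rate (h^-1).
#' @param gbeta Basal TGF-beta production (pg h^-1).
#' @param abetaT,abetaS TGF-beta production per tumor / stem cell
#'   (pg cell^-1 h^-1).
#' @param mubeta TGF-beta degradation rate (h^-1).
#' @param gMI Basal MHC-I expression rate (rec cell^-1 h^-1).
#' @param aMIgamma IFN-gamma-stimulated MHC-I expression rate
#'   (rec cell^-1 h^-1).
#' @param eMIgamma IFN-gamma Michaelis constant for MHC-I expression (pg).
#' @param muMI MHC-I decay rate (h^-1).
#' @param aMIIgamma IFN-gamma-stimulated MHC-II expression rate
#'   (rec cell^-1 h^-1).
#' @param eMIIgamma IFN-gamma Michaelis constant for MHC-II expression (pg).
#' @param aMIIbeta Residual MHC-II expression under saturating TGF-beta
#'   (dimensionless, in \[0, 1\]).
#' @param eMIIbeta TGF-beta suppression constant for MHC-II expression (pg).
#' @param muMII MHC-II decay rate (h^-1).
#' @param agammaC IFN-gamma production per CTL (pg cell^-1 h^-1).
#' @param mugamma IFN-gamma degradation rate (h^-1).
#' @param N Constant CTL infusion rate (cells h^-1); `0` means no treatment.
#'
#' @return A named list of class `"gbm_params"`.
#' @examples
#' p <- model_parameters()           # published defaults, N = 0
#' p <- model_parameters(N = 1)      # add a unit infusion rate
#' @export
model_parameters <- function(r1 = .001, K1 = 1e8,
                             aT = .12, eT = 50, aTbeta = .69, eTbeta = 1e4,
                             hT = 5e8,
                             r2 = .1, K2 = 1e7, ralpha = .006,
                             aS = .1 * .12, eS = 50, aSbeta = .69,
                             eSbeta = 1e4, hS = 5e8,
                             muC = .007,
                             gbeta = 6.3945e4, abetaT = 5.75e-6,
                             abetaS = 5.75e-6, mubeta = 7,
                             gMI = 1.44, aMIgamma = 2.88, eMIgamma = 3.38e5,
                             muMI = .0144,
                             aMIIgamma = 8660, eMIIgamma = 1420,
                             aMIIbeta = .012, eMIIbeta = 1e5, muMII = .0144,
                             agammaC = 1.02e-4, mugamma = .102,
                             N = 0) {
  p <- list(r1 = r1, K1 = K1, aT = aT, eT = eT, aTbeta = aTbeta,
            eTbeta = eTbeta, hT = hT, r2 = r2, K2 = K2, ralpha = ralpha,
            aS = aS, eS = eS, aSbeta = aSbeta, eSbeta = eSbeta, hS = hS,
            muC = muC, gbeta = gbeta, abetaT = abetaT, abetaS = abetaS,
            mubeta = mubeta, gMI = gMI, aMIgamma = aMIgamma,
            eMIgamma = eMIgamma, muMI = muMI, aMIIgamma = aMIIgamma,
            eMIIgamma = eMIIgamma, aMIIbeta = aMIIbeta,
            eMIIbeta = eMIIbeta, muMII = muMII, agammaC = agammaC,
            mugamma = mugamma, N = N)
  validate_parameters(p)
  structure(p, class = "gbm_params")
}

#' @rdname model_parameters
#' @details `parameter_names()` returns the canonical field names, in order.
#' @export
parameter_names <- function() {
  c("r1", "K1", "aT", "eT", "aTbeta", "eTbeta", "hT",
    "r2", "K2", "ralpha", "aS", "eS", "aSbeta", "eSbeta", "hS",
    "muC", "gbeta", "abetaT", "abetaS", "mubeta",
    "gMI", "aMIgamma", "eMIgamma", "muMI",
    "aMIIgamma", "eMIIgamma", "aMIIbeta", "eMIIbeta", "muMII",
    "agammaC", "mugamma", "N")
}

validate_parameters <- function(p) {
  miss <- setdiff(parameter_names(), names(p))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  vals <- unlist(p[parameter_names()])
  if (any(!is.finite(vals)))
    stop("non-finite parameter(s): ",
         paste(parameter_names()[!is.finite(vals)], collapse = ", "))
  if (any(vals < 0))
    stop("negative parameter(s): ",
         paste(parameter_names()[vals < 0], collapse = ", "))
  strict <- c("K1", "K2", "muC", "mubeta", "mugamma", "muMI", "muMII")
  bad <- strict[unlist(p[strict]) <= 0]
  if (length(bad))
    stop("parameter(s) must be strictly positive: ",
         paste(bad, collapse = ", "))
  frac <- c("aTbeta", "aSbeta", "aMIIbeta")
  out <- frac[unlist(p[frac]) > 1]
  if (length(out))
    stop("parameter(s) must lie in [0, 1]: ", paste(out, collapse = ", "))
  invisible(p)
}

#' @export
print.gbm_params <- function(x, ...) {
  cat("GBM/CSC immunotherapy model parameters\n")
  v <- unlist(x[parameter_names()])
  print(v, digits = 6)
  invisible(x)
}

#' System state of the seven-variable model
#'
#' A state is a named, nonnegative numeric vector with components
#' `T` (tumor cells), `S` (cancer stem cells), `C` (CTLs),
#' `Fbeta` (TGF-beta, pg), `Fgamma` (IFN-gamma, pg),
#' `MI` and `MII` (MHC class I/II receptor densities, rec cell^-1).
#'
#' @param T,S,C,Fbeta,Fgamma,MI,MII Nonnegative components.
#' @return Named numeric vector of length 7, class `"gbm_state"`.
#' @examples
#' system_state(T = 70, S = 30, C = 250, Fbeta = 50, Fgamma = 50,
#'              MI = 50, MII = 50)
#' @export
system_state <- function(T = 0, S = 0, C = 0, Fbeta = 0, Fgamma = 0,
                         MI = 0, MII = 0) {
  s <- c(T = T, S = S, C = C, Fbeta = Fbeta, Fgamma = Fgamma,
         MI = MI, MII = MII)
  if (any(!is.finite(s))) stop("non-finite state component")
  if (any(s < 0)) stop("state components must be nonnegative")
  structure(s, class = c("gbm_state", "numeric"))
}

state_names <- function() c("T", "S", "C", "Fbeta", "Fgamma", "MI", "MII")

# Coerce a numeric vector (named or positional) to the canonical order.
as_state <- function(x) {
  if (!is.numeric(x) || length(x) != 7)
    stop("state must be a numeric vector of length 7")
  if (!is.null(names(x)) && all(state_names() %in% names(x)))
    x <- x[state_names()]
  stats::setNames(as.numeric(x), state_names())
}
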