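# Numerical certification of the structural assumption lists (A1), (A2)
# for a functional_forms bundle. Grid-based falsification: a "pass" means
# no violation was found on the evaluation grid, not a proof.

# log-spaced grid over [0, 1e3 * scale] with 0 prepended
assumption_grid <- function(scale, n = 512) {
  scale <- max(scale, 1e-12)
  c(0, 10^seq(log10(scale) - 6, log10(scale) + 3, length.out = n - 1))
}

fmt_witness <- function(var, x, val) {
  sprintf("%s = %.6g -> %.6g", var, x, val)
}

# Monotonicity on a grid; returns NULL or a witness string.
wit_monotone <- function(f, grid, var, decreasing = FALSE) {
  v <- f(grid)
  if (any(!is.finite(v)))
    return(fmt_witness(var, grid[which(!is.finite(v))[1]],
                       v[which(!is.finite(v))[1]]))
  d <- diff(v)
  tol <- 1e-12 * max(abs(v), 1)
  bad <- if (decreasing) which(d > tol) else which(d < -tol)
  if (!length(bad)) return(NULL)
  i <- bad[1]
  sprintf("%s: f(%.6g) = %.6g but f(%.6g) = %.6g", var,
          grid[i], v[i], grid[i + 1], v[i + 1])
}

# Bounded above/limit existence: value at 1e6*scale within 1% of the value
# at 1e5*scale (Cauchy-type saturation test).
wit_bounded <- function(f, scale, var) {
  v1 <- f(1e5 * scale); v2 <- f(1e6 * scale)
  if (!is.finite(v2)) return(fmt_witness(var, 1e6 * scale, v2))
  if (abs(v2 - v1) > .01 * max(abs(v1), 1e-12))
    return(sprintf("%s not saturating: f(%.3g) = %.6g, f(%.3g) = %.6g",
                   var, 1e5 * scale, v1, 1e6 * scale, v2))
  NULL
}

# Nonnegativity and finiteness on the grid.
wit_nonneg <- function(f, grid, var) {
  v <- f(grid)
  bad <- which(!is.finite(v) | v < 0)
  if (!length(bad)) return(NULL)
  fmt_witness(var, grid[bad[1]], v[bad[1]])
}

# At-most-linear growth via increments at the domain far end: an affine
# function has |f(10X) - f(X)| = 9 |f(X) - f(0)| <= 10 |f(X) - f(0)|.
wit_at_most_linear <- function(f, scale, var) {
  X <- 1e5 * scale
  v0 <- f(0); v1 <- f(X); v2 <- f(10 * X)
  if (!is.finite(v2)) return(fmt_witness(var, 10 * X, v2))
  if (abs(v2 - v1) > 10 * abs(v1 - v0) + 1e-9 * (1 + abs(v1)))
    return(sprintf(
      "%s superlinear: |f(%.3g) - f(%.3g)| = %.6g > 10 |f(%.3g) - f(0)| = %.6g",
      var, 10 * X, X, abs(v2 - v1), X, 10 * abs(v1 - v0)))
  NULL
}

new_report_row <- function(id, description, status, witness = "") {
  data.frame(id = id, description = description, status = status,
             witness = witness, stringsAsFactors = FALSE)
}

finish_report <- function(rows, grid_desc) {
  rep <- do.call(rbind, rows)
  attr(rep, "grid") <- grid_desc
  class(rep) <- c("assumption_report", "data.frame")
  rep
}

#' @export
print.assumption_report <- function(x, ...) {
  cat("Assumption check (", attr(x, "grid") %||% "subset", ")\n", sep = "")
  df <- as.data.frame(x)
  if (!is.null(df$witness)) df$witness[df$witness == ""] <- "-"
  print(df, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' Check the boundedness/monotonicity assumptions (A1)
#'
#' Certifies, by finite sampling on log-spaced grids, the first assumption
#' list of the abstract model: at-most-linear growth of the logistic terms,
#' monotonicity of every interaction function in the stated direction, and
#' saturation (boundedness) where required. All verdicts are grid-relative:
#' this is a falsifier, not a prover, and every `fail` row carries a
#' concrete witness point.
#'
#' @param forms A [functional_forms()] bundle.
#' @param n_grid Points per axis (>= 3; default 512), log-spaced over
#'   `[0, 1e3 x scale]` per variable.
#' @return An `"assumption_report"` data frame with columns `id`,
#'   `description`, `status` (`pass`/`fail`/`not-applicable`), `witness`.
#' @export
check_A1 <- function(forms, n_grid = 512) {
  if (n_grid < 3) stop("grid size must be at least 3")
  f <- forms; sc <- f$scales
  gT_ <- assumption_grid(sc[["T"]], n_grid)
  gS_ <- assumption_grid(sc[["S"]], n_grid)
  gx <- assumption_grid(sc[["x"]], n_grid)
  gy <- assumption_grid(sc[["y"]], n_grid)
  gu <- assumption_grid(sc[["u"]], n_grid)
  gw <- assumption_grid(sc[["T"]] * sc[["v"]], n_grid)
  rows <- list()
  add <- function(id, desc, wit) {
    rows[[length(rows) + 1]] <<- new_report_row(
      id, desc, if (is.null(wit)) "pass" else "fail",
      if (is.null(wit)) "" else wit)
  }

  add("A1.1", "R1, R2 at most linear",
      wit_at_most_linear(f$R1, sc[["T"]], "R1") %||%
        wit_at_most_linear(f$R2, sc[["S"]], "R2"))
  # alpha monotone along each axis, probed on a handful of section lines
  wa <- NULL
  for (s0 in sc[["S"]] * c(.1, .5, 1)) {
    wa <- wa %||% wit_monotone(function(T) f$alpha(T, s0), gT_,
                               sprintf("alpha(., S=%.3g)", s0))
  }
  for (t0 in sc[["T"]] * c(.1, .5, 1)) {
    wa <- wa %||% wit_monotone(function(S) f$alpha(t0, S), gS_,
                               sprintf("alpha(T=%.3g, .)", t0))
  }
  add("A1.2", "alpha increasing in T and S", wa)
  add("A1.3", "fT, fS decreasing, bounded below; gT, gS increasing, bounded above",
      (wit_monotone(f$fT, gx, "fT", decreasing = TRUE) %||%
       wit_monotone(f$fS, gx, "fS", decreasing = TRUE) %||%
       wit_nonneg(f$fT, gx, "fT") %||% wit_nonneg(f$fS, gx, "fS") %||%
       wit_monotone(f$gT, gu, "gT") %||% wit_monotone(f$gS, gu, "gS") %||%
       wit_bounded(f$gT, sc[["u"]], "gT") %||%
       wit_bounded(f$gS, sc[["u"]], "gS")))
  add("A1.4", "hT, hS decreasing, bounded below",
      (wit_monotone(f$hT, gT_, "hT", decreasing = TRUE) %||%
       wit_monotone(f$hS, gS_, "hS", decreasing = TRUE) %||%
       wit_nonneg(f$hT, gT_, "hT") %||% wit_nonneg(f$hS, gS_, "hS")))
  add("A1.5", "fC increasing, bounded above; gC decreasing, bounded below",
      (wit_monotone(f$fC, gw, "fC") %||%
       wit_bounded(f$fC, sc[["T"]] * sc[["v"]], "fC") %||%
       wit_monotone(f$gC, gx, "gC", decreasing = TRUE) %||%
       wit_nonneg(f$gC, gx, "gC")))
  add("A1.6", "N nonnegative and bounded",
      if (is.finite(f$N) && f$N >= 0) NULL
      else sprintf("N = %.6g", f$N))
  add("A1.7", "fx, fy increasing",
      (wit_monotone(f$fx, gT_, "fx") %||%
       wit_monotone(f$fy, assumption_grid(sc[["C"]], n_grid), "fy")))
  add("A1.8", "fu increasing, bounded above",
      (wit_monotone(f$fu, gy, "fu") %||% wit_bounded(f$fu, sc[["y"]], "fu")))
  add("A1.9", "gv increasing, bounded above; fv decreasing, bounded below",
      (wit_monotone(f$gv, gy, "gv") %||% wit_bounded(f$gv, sc[["y"]], "gv") %||%
       wit_monotone(f$fv, gx, "fv", decreasing = TRUE) %||%
       wit_nonneg(f$fv, gx, "fv")))
  finish_report(rows, sprintf("A1, %d-point log grids", n_grid))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check the biological assumptions (A2)
#'
#' Certifies the second assumption list for a bundle against a parameter
#' record: vanishing of the logistic terms at their carrying capacities,
#' the product form of the differentiation flux, normalizations at zero,
#' existence and positivity of the saturation limits (tested at
#' `1e6 x scale` against `1e5 x scale`), and decay of the kill-access and
#' MHC-II suppression factors. The concrete glioblastoma bundle
#' deliberately fails item 6 (`hT(0) = 1/hT`, not 1) and item 11 (`fv`
#' saturates at `aMIIbeta > 0`): the printed model is authoritative for
#' simulation, the abstract contracts for this checker. Item 7 is
#' `not-applicable` when the bundle has no CTL recruitment (`fC = 0`).
#'
#' @inheritParams check_A1
#' @param params A [model_parameters()] record supplying `K1`, `K2`,
#'   `ralpha` for the structural items.
#' @return An `"assumption_report"` data frame.
#' @export
check_A2 <- function(forms, params, n_grid = 512) {
  if (n_grid < 3) stop("grid size must be at least 3")
  f <- forms; p <- params; sc <- f$scales
  gx <- assumption_grid(sc[["x"]], n_grid)
  gy <- assumption_grid(sc[["y"]], n_grid)
  gu <- assumption_grid(sc[["u"]], n_grid)
  gT_ <- seq(0, p$K1, length.out = n_grid)
  gS_ <- seq(0, p$K2, length.out = n_grid)
  rows <- list()
  add <- function(id, desc, wit) {
    rows[[length(rows) + 1]] <<- new_report_row(
      id, desc, if (is.null(wit)) "pass" else
        if (identical(wit, NA_character_)) "not-applicable" else "fail",
      if (is.null(wit) || identical(wit, NA_character_)) "" else wit)
  }
  near <- function(a, b, tol = 1e-9) abs(a - b) <= tol * max(abs(b), 1)

  add("A2.1", "R1, R2 decreasing with R(K) = 0, R(0) > 0",
      (wit_monotone(f$R1, gT_, "R1", decreasing = TRUE) %||%
       wit_monotone(f$R2, gS_, "R2", decreasing = TRUE) %||%
       (if (!near(f$R1(p$K1), 0, 1e-12)) fmt_witness("R1", p$K1, f$R1(p$K1))
        else NULL) %||%
       (if (!near(f$R2(p$K2), 0, 1e-12)) fmt_witness("R2", p$K2, f$R2(p$K2))
        else NULL) %||%
       (if (f$R1(0) <= 0) fmt_witness("R1", 0, f$R1(0)) else NULL) %||%
       (if (f$R2(0) <= 0) fmt_witness("R2", 0, f$R2(0)) else NULL)))
  # product form of the differentiation flux on a coarse section grid
  walpha <- NULL
  Tc <- seq(0, p$K1, length.out = 33); Sc <- seq(0, p$K2, length.out = 33)
  av <- outer(Tc, Sc, f$alpha)
  ref <- outer(Tc, Sc, function(T, S)
    p$ralpha * (S / p$K2) * (T / p$K1) * (p$K1 - T))
  bad <- which(abs(av - ref) > 1e-9 * pmax(abs(ref), 1), arr.ind = TRUE)
  if (nrow(bad))
    walpha <- sprintf("alpha(%.6g, %.6g) = %.6g, expected %.6g",
                      Tc[bad[1, 1]], Sc[bad[1, 2]],
                      av[bad[1, 1], bad[1, 2]], ref[bad[1, 1], bad[1, 2]])
  add("A2.2", "alpha(T,S) = ralpha (S/K2)(T/K1)(K1 - T)", walpha)
  add("A2.3", "fT, fS decreasing from 1 to positive limits",
      ((if (!near(f$fT(0), 1)) fmt_witness("fT", 0, f$fT(0)) else NULL) %||%
       (if (!near(f$fS(0), 1)) fmt_witness("fS", 0, f$fS(0)) else NULL) %||%
       wit_monotone(f$fT, gx, "fT", decreasing = TRUE) %||%
       wit_monotone(f$fS, gx, "fS", decreasing = TRUE) %||%
       wit_bounded(f$fT, sc[["x"]], "fT") %||%
       wit_bounded(f$fS, sc[["x"]], "fS") %||%
       (if (f$fT(1e6 * sc[["x"]]) <= 0)
          fmt_witness("fT", 1e6 * sc[["x"]], f$fT(1e6 * sc[["x"]]))
        else NULL)))
  add("A2.4", "gT, gS increasing from 0 to positive limits",
      ((if (!near(f$gT(0), 0, 1e-12)) fmt_witness("gT", 0, f$gT(0))
        else NULL) %||%
       (if (!near(f$gS(0), 0, 1e-12)) fmt_witness("gS", 0, f$gS(0))
        else NULL) %||%
       wit_monotone(f$gT, gu, "gT") %||% wit_monotone(f$gS, gu, "gS") %||%
       wit_bounded(f$gT, sc[["u"]], "gT") %||%
       wit_bounded(f$gS, sc[["u"]], "gS") %||%
       (if (f$gT(1e6 * sc[["u"]]) <= 0) "gT limit not positive" else NULL)))
  wgs <- NULL
  upos <- gu[gu > 0]
  cmp <- f$gS(upos) < f$gT(upos)
  if (!all(cmp))
    wgs <- sprintf("u = %.6g: gS = %.6g >= gT = %.6g", upos[!cmp][1],
                   f$gS(upos[!cmp][1]), f$gT(upos[!cmp][1]))
  add("A2.5", "gS(u) < gT(u) for u > 0", wgs)
  add("A2.6", "hT, hS decreasing from 1 to 0",
      ((if (!near(f$hT(0), 1)) fmt_witness("hT", 0, f$hT(0)) else NULL) %||%
       (if (!near(f$hS(0), 1)) fmt_witness("hS", 0, f$hS(0)) else NULL) %||%
       wit_monotone(f$hT, assumption_grid(sc[["T"]], n_grid), "hT",
                    decreasing = TRUE) %||%
       (if (f$hT(1e6 * sc[["T"]]) > 1e-3 * max(f$hT(0), 1e-12))
          fmt_witness("hT", 1e6 * sc[["T"]], f$hT(1e6 * sc[["T"]]))
        else NULL)))
  gw <- assumption_grid(sc[["T"]] * sc[["v"]], n_grid)
  if (max(abs(f$fC(gw))) == 0) {
    add("A2.7", "fC increasing from 0, fC'(0) > 0, fC' -> 0",
        NA_character_)
  } else {
    h0 <- 1e-6 * sc[["T"]] * sc[["v"]]
    slope0 <- (f$fC(h0) - f$fC(0)) / h0
    far <- 1e6 * sc[["T"]] * sc[["v"]]
    slopef <- (f$fC(far * (1 + 1e-6)) - f$fC(far)) / (far * 1e-6)
    add("A2.7", "fC increasing from 0, fC'(0) > 0, fC' -> 0",
        ((if (!near(f$fC(0), 0, 1e-12)) fmt_witness("fC", 0, f$fC(0))
          else NULL) %||%
         wit_monotone(f$fC, gw, "fC") %||%
         wit_bounded(f$fC, sc[["T"]] * sc[["v"]], "fC") %||%
         (if (slope0 <= 0) sprintf("fC'(0) = %.6g", slope0) else NULL) %||%
         (if (abs(slopef) > 1e-3 * slope0)
            sprintf("fC' at %.3g = %.6g, not vanishing", far, slopef)
          else NULL)))
  }
  add("A2.8", "gC decreasing from 1 to a positive bound",
      ((if (!near(f$gC(0), 1)) fmt_witness("gC", 0, f$gC(0)) else NULL) %||%
       wit_monotone(f$gC, gx, "gC", decreasing = TRUE) %||%
       (if (f$gC(1e6 * sc[["x"]]) <= 0)
          fmt_witness("gC", 1e6 * sc[["x"]], f$gC(1e6 * sc[["x"]]))
        else NULL)))
  # affine TGF-beta production, linear IFN-gamma production
  ws <- NULL
  wgrid <- seq(0, p$K1 + p$K2, length.out = 65)
  fxv <- f$fx(wgrid)
  d2 <- diff(diff(fxv))
  if (max(abs(d2)) > 1e-9 * max(abs(fxv), 1))
    ws <- sprintf("fx not affine near w = %.6g", wgrid[which.max(abs(d2))])
  else if (f$fx(0) <= 0) ws <- fmt_witness("fx", 0, f$fx(0))
  else if (fxv[2] <= fxv[1]) ws <- "fx slope not positive"
  if (is.null(ws)) {
    cg <- seq(0, sc[["C"]], length.out = 65)
    fyv <- f$fy(cg)
    if (abs(fyv[1]) > 1e-12) ws <- fmt_witness("fy", 0, fyv[1])
    else if (max(abs(diff(diff(fyv)))) > 1e-9 * max(abs(fyv), 1))
      ws <- "fy not linear"
  }
  add("A2.9", "fx affine with positive basal level; fy linear through 0", ws)
  add("A2.10", "fu(0) > 0 increasing to a finite limit",
      ((if (f$fu(0) <= 0) fmt_witness("fu", 0, f$fu(0)) else NULL) %||%
       wit_monotone(f$fu, gy, "fu") %||% wit_bounded(f$fu, sc[["y"]], "fu")))
  add("A2.11", "fv decreasing from 1 to 0",
      ((if (!near(f$fv(0), 1)) fmt_witness("fv", 0, f$fv(0)) else NULL) %||%
       wit_monotone(f$fv, gx, "fv", decreasing = TRUE) %||%
       (if (f$fv(1e6 * sc[["x"]]) > 1e-3 * max(f$fv(0), 1e-12))
          fmt_witness("fv", 1e6 * sc[["x"]], f$fv(1e6 * sc[["x"]]))
        else NULL)))
  slope_far <- (f$gv(1e6 * sc[["y"]] * (1 + 1e-6)) - f$gv(1e6 * sc[["y"]])) /
    (1e6 * sc[["y"]] * 1e-6)
  slope_0 <- (f$gv(1e-6 * sc[["y"]]) - f$gv(0)) / (1e-6 * sc[["y"]])
  add("A2.12", "gv increasing from 0 to a limit with vanishing slope",
      ((if (!near(f$gv(0), 0, 1e-12)) fmt_witness("gv", 0, f$gv(0))
        else NULL) %||%
       wit_monotone(f$gv, gy, "gv") %||%
       wit_bounded(f$gv, sc[["y"]], "gv") %||%
       (if (slope_0 <= 0) sprintf("gv'(0) = %.6g", slope_0) else NULL) %||%
       (if (abs(slope_far) > 1e-3 * slope_0)
          sprintf("gv' not vanishing: %.6g", slope_far) else NULL)))
  add("A2.13", "treatment N constant and nonnegative",
      if (is.finite(f$N) && f$N >= 0) NULL else sprintf("N = %.6g", f$N))
  finish_report(rows, sprintf("A2, %d-point grids", n_grid))
}
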