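# Stiff integration of the full 7-variable system, the reduced
# 2-compartment flow, long-run outcome classification, and the three
# worked-example treatment scenarios.

default_initial_state <- function() {
  system_state(T = 70, S = 30, C = 250, Fbeta = 50, Fgamma = 50,
               MI = 50, MII = 50)
}

# Output grid: linear through the first hour to resolve the kill transient,
# geometric afterwards to span slow regrowth, >= n_out points in total.
sample_times <- function(t_end, n_out = 1000) {
  if (t_end <= 1) return(seq(0, t_end, length.out = max(n_out, 2)))
  n_geo <- max(n_out - 20, 2)
  unique(sort(c(seq(0, 1, length.out = 21),
                exp(seq(0, log(t_end), length.out = n_geo)))))
}

#' Integrate the full seven-variable system
#'
#' Adaptive stiff-capable integration (lsoda) of the concrete model. The
#' tolerances default to a tight relative tolerance with a very small
#' absolute tolerance on the two cell compartments, because under strong
#' treatment the populations traverse extremely small values from which
#' they can later regrow; clipping them at an ordinary absolute tolerance
#' would distort recurrence timing.
#'
#' @param params A [model_parameters()] record (treatment rate `params$N`).
#' @param init Initial [system_state()]; defaults to the worked-example
#'   conditions (70, 30, 250, 50, 50, 50, 50).
#' @param t_end Integration horizon (h).
#' @param rtol Relative tolerance.
#' @param atol_cells Absolute tolerance for `T` and `S` (cells).
#' @param atol_other Absolute tolerance for the remaining five components.
#' @param n_out Minimum number of output sample times.
#' @param method deSolve integrator name.
#' @return A list of class `"gbm_trajectory"`: `times`, `states` (matrix,
#'   one row per time, columns in state order), `params`, `diagnostics`.
#' @examples
#' \donttest{
#' traj <- simulate_gbm(model_parameters(), t_end = 100)
#' tail(traj$states[, "C"], 1)   # 250 exp(-.007 * 100) = 124.14
#' }
#' @export
simulate_gbm <- function(params, init = default_initial_state(), t_end,
                         rtol = 1e-10, atol_cells = 1e-40,
                         atol_other = 1e-12, n_out = 1000,
                         method = "lsoda") {
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be positive")
  init <- as_state(init)
  if (any(init < 0)) stop("initial state must be nonnegative")
  atol <- c(atol_cells, atol_cells, rep(atol_other, 5))
  times <- sample_times(t_end, n_out)
  deriv <- function(t, y, parms) list(gbm_rhs(y, parms))
  out <- deSolve::ode(y = init, times = times, func = deriv,
                      parms = params, method = method,
                      rtol = rtol, atol = atol, maxsteps = 100000)
  if (any(!is.finite(out)))
    stop("integration error: non-finite values in solver output; ",
         "diagnostics: ", paste(utils::capture.output(
           deSolve::diagnostics(out)), collapse = " "))
  states <- out[, state_names(), drop = FALSE]
  structure(list(times = out[, "time"], states = states, params = params,
                 diagnostics = list(rtol = rtol, atol = atol,
                                    method = method,
                                    istate = attr(out, "istate"),
                                    rstate = attr(out, "rstate"))),
            class = "gbm_trajectory")
}

#' @export
print.gbm_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("gbm trajectory: %d samples over [0, %g] h\n", n,
              x$times[n]))
  cat("final state:\n")
  print(x$states[n, ])
  invisible(x)
}

#' Integrate the reduced two-compartment flow
#'
#' Integrates `T' = T M1(T, S)`, `S' = S M2(T, S)`, the tumor/stem-cell
#' flow with CTLs, IFN-gamma and MHC-I held at their cure-branch steady
#' states and TGF-beta at quasi-steady state. Its equilibria are the points
#' returned by [coexistence_equilibria()].
#'
#' @param params A [model_parameters()] record.
#' @param init Length-2 vector `c(T, S)`.
#' @param N Infusion rate; defaults to `params$N`.
#' @param t_end Horizon (h).
#' @param mode Kill-pressure convention, see [kill_pressure_T()].
#' @param rtol,atol Solver tolerances.
#' @param n_out Minimum number of output sample times.
#' @return List with `times` and `states` (columns `T`, `S`).
#' @export
simulate_reduced <- function(params, init, N = params$N, t_end,
                             mode = "consistent", rtol = 1e-10,
                             atol = 1e-40, n_out = 1000) {
  if (length(init) != 2 || any(init < 0))
    stop("init must be a nonnegative vector c(T, S)")
  times <- sample_times(t_end, n_out)
  deriv <- function(t, y, parms) {
    list(c(y[1] * coexistence_M1(y[1], y[2], N, parms, mode),
           y[2] * coexistence_M2(y[1], y[2], N, parms, mode)))
  }
  out <- deSolve::ode(y = c(T = init[1], S = init[2]), times = times,
                      func = deriv, parms = params, method = "lsoda",
                      rtol = rtol, atol = atol, maxsteps = 100000)
  if (any(!is.finite(out)))
    stop("integration error: non-finite values in reduced-system output")
  list(times = out[, "time"], states = out[, c("T", "S"), drop = FALSE])
}

#' Classify the long-run outcome of a trajectory
#'
#' Reads the final sample of a trajectory and labels it `"cure"`
#' (`T < threshold` and `S < threshold`), `"recurrence"`
#' (`T < threshold <= S`), or `"coexistence"` (both at or above threshold).
#' If either population still moves by more than 10% (relative, measured
#' above the one-cell floor) over the last 10% of the horizon, the outcome
#' is `"undecided"`. Sub-threshold populations are compared on an absolute
#' scale: relative change among fractions of a cell is biologically
#' meaningless.
#'
#' @param traj A `"gbm_trajectory"` from [simulate_gbm()].
#' @param cell_threshold Population below which a compartment counts as
#'   eliminated (cells; default one cell).
#' @return One of `"cure"`, `"recurrence"`, `"coexistence"`, `"undecided"`.
#' @export
classify_outcome <- function(traj, cell_threshold = 1) {
  if (!inherits(traj, "gbm_trajectory") || !length(traj$times))
    stop("empty or invalid trajectory")
  times <- traj$times
  n <- length(times)
  t_end <- times[n]
  i90 <- which.min(abs(times - .9 * t_end))
  final <- traj$states[n, c("T", "S")]
  prev <- traj$states[i90, c("T", "S")]
  relchange <- abs(final - prev) / pmax(abs(final), cell_threshold)
  if (any(relchange > .10)) return("undecided")
  T_end <- final[["T"]]; S_end <- final[["S"]]
  if (T_end < cell_threshold && S_end < cell_threshold) "cure"
  else if (T_end < cell_threshold) "recurrence"
  else if (S_end < cell_threshold) "undecided"   # tumor without stem pool
  else "coexistence"
}

#' Worked-example treatment scenarios
#'
#' The three published treatment regimes:
#' * `fig1` -- no treatment (`N = 0`), initial state
#'   (70, 30, 250, 50, 50, 50, 50), horizon 10,000 h: both tumor
#'   compartments grow to carrying capacity (coexistence).
#' * `fig2` -- `N = 1` with a large initial CTL load `C(0) = 2.5e10`,
#'   horizon 5,000 h: tumor cells are eliminated but stem cells regrow
#'   (recurrence).
#' * `fig3` -- `N = 1.08783e15` (the sufficient cure dose) with large
#'   initial tumor burdens `T(0) = 7e5`, `S(0) = 3e5`, horizon 1,000 h:
#'   rapid cure.
#'
#' Horizons are classification defaults, not published values; the fig2
#' recurrence label is horizon-relative because tumor cells also regrow on
#' much longer time scales.
#'
#' @param name One of `"fig1"`, `"fig2"`, `"fig3"`.
#' @return List with `name`, `params` (treatment rate included), `init`,
#'   and `t_end`.
#' @examples
#' sc <- scenario("fig1")
#' \donttest{
#' traj <- simulate_gbm(sc$params, sc$init, sc$t_end)
#' classify_outcome(traj)
#' }
#' @export
scenario <- function(name = c("fig1", "fig2", "fig3")) {
  if (length(name) > 1 || !name %in% c("fig1", "fig2", "fig3"))
    stop("configuration error: unknown scenario '",
         paste(name, collapse = ","),
         "' (expected fig1, fig2 or fig3)")
  base <- default_initial_state()
  switch(name,
    fig1 = list(name = "fig1", params = model_parameters(N = 0),
                init = base, t_end = 10000),
    fig2 = list(name = "fig2", params = model_parameters(N = 1),
                init = system_state(T = 70, S = 30, C = 2.5e10,
                                    Fbeta = 50, Fgamma = 50, MI = 50,
                                    MII = 50),
                t_end = 5000),
    fig3 = list(name = "fig3",
                params = model_parameters(N = 1.08783e15),
                init = system_state(T = 7e5, S = 3e5, C = 250,
                                    Fbeta = 50, Fgamma = 50, MI = 50,
                                    MII = 50),
                t_end = 1000))
}

#' Run a worked-example scenario
#'
#' Convenience wrapper: build the scenario and integrate it.
#'
#' @param name Scenario name, see [scenario()].
#' @param ... Passed to [simulate_gbm()] (tolerances, output grid).
#' @return A `"gbm_trajectory"`.
#' @export
run_scenario <- function(name, ...) {
  sc <- scenario(name)
  simulate_gbm(sc$params, sc$init, sc$t_end, ...)
}
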