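# Configuration files, trajectory/report serialization, and seeded fixtures.

config_keys <- function() {
  c("parameters", "init", "t_end", "mode", "rtol", "atol_cells",
    "atol_other", "out", "seed")
}

#' Build, load and write run configurations
#'
#' A run configuration bundles everything a simulation or threshold run
#' needs: the parameter record (including the treatment rate `N`), the
#' initial state, the horizon, the threshold mode, solver tolerances, an
#' output path and a seed (used only for fixture generation). On disk it is
#' a JSON object with exactly these keys; unknown keys are rejected by
#' name, and missing parameter fields are filled from the published
#' defaults.
#'
#' @param params A [model_parameters()] record.
#' @param init Initial [system_state()].
#' @param t_end Horizon (h).
#' @param mode Threshold mode, `"paper"` or `"consistent"`.
#' @param rtol,atol_cells,atol_other Solver tolerances, see
#'   [simulate_gbm()].
#' @param out Optional output path.
#' @param seed Optional integer seed.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(params = model_parameters(),
                       init = default_initial_state(),
                       t_end = 10000, mode = "paper", rtol = 1e-10,
                       atol_cells = 1e-40, atol_other = 1e-12,
                       out = NULL, seed = NULL) {
  validate_parameters(params)
  if (!mode %in% c("paper", "consistent"))
    stop("mode must be 'paper' or 'consistent'")
  structure(list(parameters = params, init = as_state(init),
                 t_end = t_end, mode = mode, rtol = rtol,
                 atol_cells = atol_cells, atol_other = atol_other,
                 out = out, seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @param path File path of the JSON configuration.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), config_keys())
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  pr <- raw$parameters
  if (is.null(pr)) pr <- list() else pr <- as.list(pr)
  unknown_p <- setdiff(names(pr), parameter_names())
  if (length(unknown_p))
    stop("unknown parameter key(s): ", paste(unknown_p, collapse = ", "))
  nonnum <- names(pr)[!vapply(pr, function(v)
    is.numeric(v) && length(v) == 1, logical(1))]
  if (length(nonnum))
    stop("non-numeric parameter value(s): ", paste(nonnum, collapse = ", "))
  pr <- lapply(pr, as.numeric)
  params <- do.call(model_parameters, pr)   # missing keys -> defaults
  init <- if (is.null(raw$init)) default_initial_state() else {
    iv <- as.list(raw$init)
    unknown_i <- setdiff(names(iv), state_names())
    if (length(unknown_i))
      stop("unknown init key(s): ", paste(unknown_i, collapse = ", "))
    do.call(system_state, lapply(iv, as.numeric))
  }
  run_config(params = params, init = init,
             t_end = as.numeric(raw$t_end %||% 10000),
             mode = raw$mode %||% "paper",
             rtol = as.numeric(raw$rtol %||% 1e-10),
             atol_cells = as.numeric(raw$atol_cells %||% 1e-40),
             atol_other = as.numeric(raw$atol_other %||% 1e-12),
             out = raw$out, seed = raw$seed)
}

#' @rdname run_config
#' @param cfg A `"run_config"` object.
#' @export
write_config <- function(cfg, path) {
  x <- list(parameters = as.list(unclass(cfg$parameters)),
            init = as.list(unclass(cfg$init)),
            t_end = cfg$t_end, mode = cfg$mode, rtol = cfg$rtol,
            atol_cells = cfg$atol_cells, atol_other = cfg$atol_other)
  if (!is.null(cfg$out)) x$out <- cfg$out
  if (!is.null(cfg$seed)) x$seed <- cfg$seed
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Write a trajectory as CSV
#'
#' One header line `t,T,S,C,F_beta,F_gamma,M_I,M_II`, then one row per
#' sample time, every number with 17 significant digits.
#'
#' @param traj A `"gbm_trajectory"` from [simulate_gbm()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("t,T,S,C,F_beta,F_gamma,M_I,M_II", con)
  m <- cbind(traj$times, traj$states)
  lines <- apply(m, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, con)
  invisible(path)
}

#' Write a threshold report as JSON
#'
#' Serializes every field of a `"threshold_report"` (doses, amplification
#' factors, inversion targets, recurrence-submodel values and the mode
#' flag) with full double precision, so a re-read reproduces the report
#' bit for bit.
#'
#' @param report A `"threshold_report"` from [compute_thresholds()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
threshold_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Deterministic fixture set for property testing
#'
#' Builds the three worked-example scenario configurations plus `n_perturb`
#' parameter records in which every kinetic rate of the published set is
#' multiplied by an independent log-uniform factor in `[0.5, 2]`,
#' deterministically from the seed. Carrying capacities, Michaelis
#' constants and the dimensionless suppression floors are left untouched so
#' every perturbed record still satisfies the parameter invariants.
#'
#' @param seed Integer seed.
#' @param n_perturb Number of perturbed parameter records.
#' @return List with elements `fig1`, `fig2`, `fig3` (run configs) and
#'   `perturbed` (list of parameter records).
#' @export
generate_fixtures <- function(seed, n_perturb = 20) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed == round(seed))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  rates <- c("r1", "aT", "r2", "ralpha", "aS", "muC", "gbeta", "abetaT",
             "abetaS", "mubeta", "gMI", "aMIgamma", "muMI", "aMIIgamma",
             "muMII", "agammaC", "mugamma")
  perturbed <- lapply(seq_len(n_perturb), function(i) {
    p <- as.list(model_parameters())
    fac <- exp(stats::runif(length(rates), log(.5), log(2)))
    for (k in seq_along(rates)) p[[rates[k]]] <- p[[rates[k]]] * fac[k]
    do.call(model_parameters, p[parameter_names()])
  })
  cfgs <- lapply(c("fig1", "fig2", "fig3"), function(nm) {
    sc <- scenario(nm)
    run_config(params = sc$params, init = sc$init, t_end = sc$t_end,
               seed = seed)
  })
  names(cfgs) <- c("fig1", "fig2", "fig3")
  c(cfgs, list(perturbed = perturbed))
}
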