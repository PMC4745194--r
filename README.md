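# gbmcsc

Tumor-immune dynamics of glioblastoma multiforme with cancer stem cells
under CTL immunotherapy: simulation, equilibrium and stability analysis, and
the treatment-dose calculus that separates tumor persistence from a globally
stable cure.

## The problem

Glioblastoma sits in tissue too delicate for aggressive surgery or
chemotherapy, so immunotherapy — infusing alloreactive cytotoxic T
lymphocytes (CTLs) at a constant rate `N` — is a natural treatment route.
Under the cancer stem cell hypothesis the tumor hides a small self-renewing
compartment `S` alongside the bulk tumor cells `T`; a dose that clears `T`
but not `S` produces *recurrence*, because the surviving stem cells
repopulate the tumor. This package is for modelers who want to ask, for a
concrete calibrated system: **how much treatment is enough — for the tumor,
and for the stem cells?**

## The model

Seven coupled ODEs (all rates per hour): tumor cells `T` and stem cells `S`
grow logistically with carrying capacities `K1 = 1e8`, `K2 = 1e7`; stem
cells differentiate into tumor cells at a flux
`alpha(T,S) = ralpha (S/K2)(T/K1)(K1 - T)`; CTLs `C` are infused at rate `N`
and die at rate `muC`; the kill terms

    aT * MI/(MI+eT) * [aTbeta + eTbeta(1-aTbeta)/(Fbeta+eTbeta)] * C T/(hT+T)

are activated by MHC class I (`MI`), suppressed by TGF-beta (`Fbeta`), and
access-limited in the tumor mass. IFN-gamma (`Fgamma`, produced by CTLs)
drives MHC expression; TGF-beta (produced by the tumor) suppresses it. Stem
cells are ten-fold harder to kill (`aS = 0.1 aT`), which is exactly why the
stem-cell dose thresholds dominate.

The analysis is built on the strictly increasing *kill pressures*
`G1(N), G2(N)` that a dose exerts on each compartment along the cure branch.
The package computes, by bisection inversion and grid-refined maximization:

- `Nmin_T, Nmin_S` — minimal doses below which the cure state is locally
  unstable (the compartment can invade);
- `aleph_T, aleph_S` — amplification factors: worst-case growth-to-kill
  ratios over the invariant box;
- `Nthr_T = G1^-1(G1(Nmin_T) aleph_T)`, `Nthr_S` likewise, and
  `Ncure = max(Nthr_T, Nthr_S)` — the sufficient dose beyond which the cure
  state is globally asymptotically stable (certified on a grid by
  `verify_global_cure()`).

## Worked example

The published calibration is the default parameter record. The full dose
calculus:

```r
library(gbmcsc)
compute_thresholds(model_parameters())
#> Treatment-dose thresholds (mode: paper)
#>   Nmin_T  = 0.00244575 cells/h   (inversion target 0.0011737)
#>   Nmin_S  = 2.07888 cells/h   (inversion target 0.0997645)
#>   aleph_T = 3.60322e+17          aleph_S = 1.4866e+15
#>   Nthr_T  = 3.10199e+14 cells/h   Nthr_S  = 1.08783e+15 cells/h
#>   Ncure   = 1.08783e+15 cells/h
#>   recurrence submodel: Nmin = 2.44575, Nthr = 4.31891e+08
```

Reading this: a dose of only `0.0024` CTLs/h already destabilizes the
tumor-cell compartment, but `2.08` CTLs/h are needed before stem cells stop
invading, and a guaranteed global cure needs `N > 1.09e15` CTLs/h — driven
entirely by the stem-cell side (`Ncure = Nthr_S`). The recurrence submodel
line gives the same calculus restricted to the `T = 0` axis.

The three treatment regimes of the worked example:

```r
sc <- scenario("fig2")          # N = 1, large initial CTL load C(0) = 2.5e10
traj <- simulate_gbm(sc$params, sc$init, sc$t_end)
classify_outcome(traj)
#> [1] "recurrence"
traj$states[nrow(traj$states), c("T", "S")]
#> final T = 2e-203 cells, S = 1e+07 cells
```

The CTL load wipes out the tumor cells (`T` far below one cell at 5,000 h)
but the stem-cell pool regrows to carrying capacity — recurrence. `fig1`
(`N = 0`) gives coexistence at both carrying capacities; `fig3`
(`N = 1.08783e15`, the computed cure dose) clears both compartments within
hours. The cure state itself, with its spectrum:

```r
cure_equilibrium(model_parameters(N = 1.08783e15))
#> Equilibrium (stable), residual 0.125
#>            T            S            C        Fbeta       Fgamma           MI          MII
#>            0            0 1.554043e+17         9135 1.554043e+14          300 5.516545e+05
#> eigenvalue real parts: -7.000e-03, -1.440e-02, -1.440e-02, -1.020e-01, -7.000e+00, -2.724e+06, -2.724e+07
```

Other entry points: `recurrence_equilibria()` / `coexistence_equilibria()`
(root finding with stability flags), `cure_decay_rates()` and
`dissipativity_constants()` (analytic certificates), `check_A1()` /
`check_A2()` (numerical certification of the abstract model's structural
assumptions), `kronik_forms()` / `abstract_rhs()` (the pluggable abstract
system). A thin command-line surface lives in `inst/cli/gbmcsc.R`
(`simulate`, `scenario`, `thresholds`, `stability`, `check-assumptions`),
driven by JSON configurations (`load_config()` / `write_config()`).

See the methods vignette (`vignettes/gbmcsc-methods.Rmd`) for the model
assumptions, the two threshold computation modes, and every numerical
choice.

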