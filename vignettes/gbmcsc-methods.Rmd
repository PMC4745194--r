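---
title: "Methods: tumor-immune dynamics with cancer stem cells and treatment thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor-immune dynamics with cancer stem cells and treatment thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbmcsc)
```

## The model

`gbmcsc` implements a seven-variable ODE model of glioblastoma multiforme
under cytotoxic-T-lymphocyte (CTL) immunotherapy, in which the tumor is split
into differentiated tumor cells $T$ and self-renewing cancer stem cells $S$.
The remaining state variables are the CTL population $C$, the
immunosuppressive cytokine TGF-$\beta$ ($F_\beta$), the immunostimulatory
cytokine IFN-$\gamma$ ($F_\gamma$), and the MHC class I/II receptor densities
$M_I$, $M_{II}$ that gate CTL killing and recruitment.

The concrete system evaluated by `gbm_rhs()` is

$$
\begin{aligned}
T' &= r_1 T\Big(1-\tfrac{T}{K_1}\Big)
   + r_\alpha \tfrac{S}{K_2}\tfrac{T}{K_1}(K_1-T)
   - \frac{a_T M_I}{M_I+e_T}
     \Big(a_{T,\beta}+\frac{e_{T,\beta}(1-a_{T,\beta})}{F_\beta+e_{T,\beta}}\Big)
     \frac{CT}{h_T+T},\\
S' &= r_2 S\Big(1-\tfrac{S}{K_2}\Big)
   - r_\alpha \tfrac{S}{K_2}\tfrac{T}{K_1}(K_1-T)
   - \frac{a_S M_I}{M_I+e_S}
     \Big(a_{S,\beta}+\frac{e_{S,\beta}(1-a_{S,\beta})}{F_\beta+e_{S,\beta}}\Big)
     \frac{CS}{h_S+S},\\
C' &= -\mu_C C + N, \qquad
F_\beta' = g_\beta + a_{\beta,T}T + a_{\beta,S}S - \mu_\beta F_\beta, \qquad
F_\gamma' = a_{\gamma,C} C - \mu_\gamma F_\gamma,\\
M_I' &= g_{M_I} + \frac{a_{M_I,\gamma}F_\gamma}{F_\gamma+e_{M_I,\gamma}}
      - \mu_{M_I}M_I, \qquad
M_{II}' = \frac{a_{M_{II},\gamma}F_\gamma}{F_\gamma+e_{M_{II},\gamma}}
  \Big(a_{M_{II},\beta}+\frac{e_{M_{II},\beta}(1-a_{M_{II},\beta})}
  {F_\beta+e_{M_{II},\beta}}\Big) - \mu_{M_{II}}M_{II}.
\end{aligned}
$$

Two biological mechanisms drive everything of interest. First, stem cells
both self-renew (logistic, rate $r_2$) and differentiate into tumor cells at
a flux $\alpha(T,S) = r_\alpha (S/K_2)(T/K_1)(K_1-T)$ that shuts off as the
tumor compartment fills; this is what makes recurrence possible: a treatment
that clears $T$ but not $S$ leaves a reservoir that repopulates the tumor.
Second, the CTL kill terms are gated twice — activated by MHC-I with
Michaelis–Menten saturation and suppressed hyperbolically by TGF-$\beta$ —
and are access-limited through $1/(h+{\rm population})$, so per-capita kill
pressure falls as the tumor grows. Stem cells are intrinsically harder to
kill ($a_S = 0.1\,a_T$), which is why the dose sufficient to eliminate them
exceeds the dose sufficient for tumor cells alone.

The same machinery also evaluates an *abstract* version of the system
(`abstract_rhs()` with a `functional_forms()` bundle of sixteen interaction
functions), which is how the structural-assumption checker and the
closed-form spectral results are exercised on arbitrary compliant models.
`kronik_forms()` instantiates the bundle so that the abstract and concrete
right-hand sides agree term for term; the test suite asserts that agreement
to $10^{-12}$ relative on random states.

All rates are per hour, populations in cells, cytokines in pg, receptor
densities in receptors per cell. The default `model_parameters()` record is
the published, biologically calibrated set (e.g. $r_1 = 10^{-3}\,h^{-1}$,
$K_1=10^8$ cells, $\mu_\beta = 7\,h^{-1}$, $g_\beta = 6.3945\times10^4$
pg/h); the treatment rate $N$ (cells/h of infused CTLs) is the single control
parameter of the analysis.

## Quasi-steady-state reduction and the reduced flow

TGF-$\beta$ turnover ($\mu_\beta = 7\,h^{-1}$) is two to three orders of
magnitude faster than every other compartment, so on the slow time scale
$F_\beta$ tracks $x^\ast = (g_\beta + a_{\beta,T}T + a_{\beta,S}S)/\mu_\beta$
(`tgfb_qss()`, `reduced_tgfb_rhs()`). With treatment constant, $C$, $F_\gamma$
and $M_I$ relax exponentially to a cure-branch chain
$C^\ast = N/\mu_C$,
$F_\gamma^\ast = a_{\gamma,C}C^\ast/\mu_\gamma$,
$M_I^\ast = f_u(F_\gamma^\ast)/\mu_{M_I}$, leaving a planar flow

$$T' = T\,M_1(T,S), \qquad S' = S\,M_2(T,S)$$

(`simulate_reduced()`), whose zeros are the cure, recurrence and coexistence
equilibria. `coexistence_equilibria()` locates nullcline intersections on
$(0,K_1]\times(0,K_2]$ by a $512\times512$ sign-change scan refined with a
damped Newton iteration, and classifies each point from the eigenvalues of
the $2\times2$ Jacobian of $(T M_1, S M_2)$. `recurrence_equilibria()` does
the one-dimensional analogue for the $T=0$ submodel: a $10^4$-interval sign
scan with bisection; a root is stable when the balance
$L_N(S) = R_2(S) - G(N)H(S)$ crosses downward. Tangential touches (no sign
change) are reported as `marginal` and excluded from the alternation rule,
which presumes transversal crossings.

## The dose calculus

The analysis rests on the *kill pressure* a constant infusion exerts on each
compartment along the cure branch,

$$G_1(N) = g_T(u^\ast(N))\,C^\ast(N), \qquad
  G_2(N) = g_S(u^\ast(N))\,C^\ast(N),$$

both strictly increasing in $N$ and hence invertible
(`kill_pressure_T/S()`, `invert_monotone()`; bisection with bracket
doubling, relative tolerance $10^{-12}$). `compute_thresholds()` then builds:

* **Minimal doses.**
  $N_{\min,T} = G_1^{-1}\!\big(r_1/\bar f_T(g_\beta/\mu_\beta)\big)$ and
  $N_{\min,S} = G_2^{-1}\!\big((r_2 - r_\alpha K_1/4K_2)/\bar
  f_S(g_\beta/\mu_\beta)\big)$, below which the respective compartment can
  invade the cure state. The stem-cell target subtracts the worst-case
  differentiation outflow $r_\alpha K_1/4K_2$, the maximum of the flux per
  stem cell over the tumor axis.
* **Amplification factors.** $\aleph_T$ is the maximum over $T\in[0,K_1]$ of
  the growth-to-kill ratio
  $(R_1(T)+r_\alpha K_1)(h_T+T)\big/\big(G_1(N_{\min,T})\,\bar
  f_T(T,K_2)\big)$, with the companion compartment pinned at carrying
  capacity where TGF-$\beta$ suppression is strongest, and $\aleph_S$
  analogously over $[0,K_2]$. Maximization is by a $10^5$-point dense grid
  with Brent refinement of the best bracket (relative tolerance $10^{-10}$);
  the tumor maximand peaks at the boundary $T=K_1$, the stem maximand in the
  interior near $K_2/2$, so both code paths are exercised.
* **Sufficient doses.** $N_{thr,T} = G_1^{-1}(G_1(N_{\min,T})\,\aleph_T)$,
  $N_{thr,S}$ analogously, and $N_{cure} = \max(N_{thr,T}, N_{thr,S})$.
  Above $N_{cure}$, the certified comparison system has
  $L_1 + r_\alpha K_1 < 0$ and $L_2 < 0$ on the whole invariant box, which
  `verify_global_cure()` checks directly on a $512\times512$ grid; the test
  suite asserts that the certificate is monotone in $N$ and flips exactly
  where the calculus says it should.

With the default calibration this yields $N_{\min,T} = 2.446\times10^{-3}$,
$N_{\min,S} = 2.0789$, $\aleph_T = 3.603\times10^{17}$,
$\aleph_S = 1.487\times10^{15}$, $N_{thr,T} = 3.102\times10^{14}$ and
$N_{cure} = N_{thr,S} = 1.088\times10^{15}$ cells/h — the thresholds the
acceptance script recomputes at run time.

### The two computation modes

Two readings of the MHC-I coordinate entering $G_1, G_2$ are defensible, and
the package exposes both:

* `mode = "paper"` (default) feeds the MHC-I *production rate*
  $X(N) = g_{M_I} + a_{M_I,\gamma}F_\gamma^\ast/(F_\gamma^\ast+e_{M_I,\gamma})$
  into the Michaelis–Menten kill activation, and uses the stem-cell maximand
  $R_2(S)\,S\,(h_S+S)/\bar f_S(K_1,S)$. This is the only reading we found
  that reproduces every printed value of the published worked example, and
  it is therefore the default.
* `mode = "consistent"` uses the MHC-I *steady state* $X(N)/\mu_{M_I}$ — the
  coordinate the simulated dynamics actually relax to — and the symmetric
  stem maximand without the extra factor $S$. It is the mode that matches
  `simulate_gbm()` quantitatively and is the default for the equilibrium
  finders and the reduced flow.

The published example also contains one internal inconsistency: the sentence
stating $G_1(N_{\min,T}) = .00245$ conflicts with the displayed inversion,
which implies $G_1(N_{\min,T}) = .00117$. The package uses
$G_1(N_{\min,T}) = r_1/\bar f_T(g_\beta/\mu_\beta)$, the value consistent
with the displayed formula and with the printed $N_{thr,T}$.

The recurrence submodel thresholds (`recurrence_thresholds()`) follow the
same normalize-amplify-invert pattern on the $T=0$ axis. Their minimal dose
is normalized with the abstract convention $h_S(0)=1$; the amplification
step uses the instantiated kill form, so the resulting $N_{thr}$ still
guarantees $L_N < 0$ on all of $[0,K_2]$ — the property the tests check —
independently of that normalization choice.

## Stability certificates

* `cure_equilibrium()` returns the tumor-free state in closed form and
  classifies it from the numerical spectrum of the analytic Jacobian. The
  Jacobian at the cure state is reducible, so the spectrum is the five death
  rates plus two invasion rates; `cure_eigenvalues(method = "closed")` and
  `cure_eigenvalues_closed()` (abstract) return these directly, and the
  tests require closed-form/numerical agreement to $10^{-8}$ relative on
  fifty random compliant bundles.
* `cure_decay_rates()` evaluates the printed exponential-decay certificates
  $a_1 = g_T(u^\ast)C^\ast - (r_1+r_\alpha K_1^2/4)/(h_T(K_1)f_T(x_{\max}))$
  and $a_2 = g_S(u^\ast)C^\ast - r_2/(h_S(K_2)f_S(x_{\max}))$ exactly as
  stated, including the $r_\alpha K_1^2/4$ term whose dimensional status is
  ambiguous (a per-capita reading would give $r_\alpha K_1/4$); positivity
  of $a_2$ is the certificate. The *rate* the inequality actually implies
  for the dynamics is the rescaled $a_2\,h_S(K_2)\,f_S(x_{\max})$, and that
  is the decay bound the simulation test verifies.
* `dissipativity_constants()` assembles the explicit constants of
  $\nabla W\cdot F \le A - \delta W$ for the state sum $W$, using the
  algebraically exact logistic domination $R_1(T)T \le r_1K_1 - r_1T$. The
  ceiling $W(t) \le \max(W(0), A/\delta)$ is asserted along every scenario
  trajectory and twenty seeded random calibrations.

Eigenvalue labels use the tolerance policy: a real part within
$10^{-12}\times$ (spectral radius) of zero is `marginal`; otherwise the sign
decides `stable`/`unstable`.

## Assumption checking

`check_A1()`/`check_A2()` certify the structural contracts of the abstract
model on log-spaced grids (default 512 points per axis over
$[0, 10^3\times{\rm scale}]$). They are falsifiers, not provers: `pass`
means no violation was found on the grid, and every `fail` carries a
re-assertable witness point. Boundedness is tested as saturation — the value
at $10^6\times$ scale within 1% of the value at $10^5\times$ scale — and
at-most-linear growth through far-end increments, which tolerates affine
forms. Derivative conditions (e.g. a vanishing recruitment slope) are tested
by finite differences; no symbolic reasoning is attempted.

Three contracts deliberately fail on the concrete model: the differentiation
flux is not monotone in $T$ beyond $K_1/2$; the printed kill form
$1/(h_T+T)$ has $h_T(0) = 2\times10^{-9}$, not 1; and the MHC-II suppression
factor saturates at $a_{M_{II},\beta} = .012$, not 0. The package corrects
none of these: the concrete system is authoritative for simulation, the
abstract contracts for the checker, and both behaviors are exposed. The CTL
recruitment contract is reported `not-applicable` because the concrete CTL
equation has constant inflow and no recruitment term.

## Numerical choices

* **Integration.** `deSolve::ode` (lsoda) with relative tolerance
  $10^{-10}$; absolute tolerance $10^{-40}$ on $T$ and $S$ and $10^{-12}$
  elsewhere. The extreme cell tolerance matters: in the recurrence regime
  the tumor compartment falls far below one cell and later regrows, so an
  ordinary absolute floor would distort recurrence timing. There is no
  extinction cutoff in the dynamics — the one-cell threshold lives only in
  `classify_outcome()`.
* **Output grid.** Linear through the first hour (kill transient), then
  geometric to the horizon, at least 1000 samples.
* **Outcome classification.** At the final time: cure if $T,S<1$ cell,
  recurrence if $T<1\le S$, coexistence if both $\ge 1$; `undecided` if
  either population changes by more than 10% over the last 10% of the
  horizon. Relative change and endpoint comparisons are measured above a
  one-cell floor: relative differences among fractions of a cell are
  numerically unconstrained (they sit below any achievable absolute
  tolerance) and biologically meaningless. The same convention is used by
  the solver-convergence test, which requires the final $(T,S)$ to move by
  less than $10^{-4}$ (relative above one cell) when both tolerances are
  halved.
* **Root finding.** All scalar roots use bracketed bisection (the balances
  are monotone or sign-scanned first); the bracket for the CTL balance
  doubles up to $10^{30}$ before reporting failure. Coexistence points are
  polished by damped Newton steps limited to one grid cell per move and
  accepted only when both per-capita balances are below $10^{-8}$.
* **Horizons.** 10,000 h (untreated), 5,000 h (recurrence regime), 1,000 h
  (cure dose). The source publication does not state integration horizons;
  these defaults are long enough for the classification to stabilize, and
  the recurrence label is horizon-relative — tumor cells also regrow on a
  much longer time scale.

## Scenario fixtures and what the tests do and do not show

`generate_fixtures()` emits the three scenario configurations plus twenty
parameter records with every kinetic rate scaled by an independent
log-uniform factor in $[0.5, 2]$ — a realistic spread for rate constants
that are themselves order-of-magnitude estimates. Capacities, Michaelis
constants and the dimensionless suppression floors are left untouched so the
records keep their biological meaning. These perturbations probe the
*structural* guarantees (dissipativity, orthant invariance, monotone kill
pressure), which hold for any admissible calibration. They do not emulate
patient heterogeneity, measurement noise, delayed or time-varying dosing, or
spatial structure; passing tests therefore support the mathematical claims
of the model, not its clinical calibration.

## Known limitations

* The thresholds are sufficient, not necessary: the calculus deliberately
  ignores CTL recruitment and amplifies worst cases over the whole box, so
  $N_{cure}$ can exceed the dose at which simulated trajectories already
  reach cure by many orders of magnitude.
* `mode = "paper"` reproduces the published numbers but uses a kill
  coordinate $\mu_{M_I}$-fold smaller than the dynamics'; cross-mode
  comparisons of absolute dose values are therefore not meaningful.
* The assumption checker cannot prove monotonicity or limits, only fail to
  falsify them on its grids.
* Time-varying treatment $N(t)$, delays, and stochastic or spatial variants
  are out of scope.
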