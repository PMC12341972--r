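---
title: "Predicting metabolic regulation by pathway-controlled optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting metabolic regulation by pathway-controlled optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

pcoflux treats a metabolic network as a thermodynamic system. Each
reversible reaction $j$ with signed stoichiometric coefficients
$\gamma_{ij}$ and equilibrium constant $K_j$ experiences a thermodynamic
force

$$f_j(n) = K_j \prod_i n_i^{-\gamma_{ij}},$$

where $n_i$ are molecule counts. In the maximum-path-entropy (Marcelin)
formulation the kinetic prefactors of the factorized mass-action rate are
set to a common constant, so the net flux is determined by the force alone:

$$J_j = \alpha_j\left(f_j - \frac{1}{f_j}\right),$$

with an activity coefficient $\alpha_j \in [0,1]$ modelling enzyme-level
regulation ($\alpha = 1$ unregulated, $\alpha = 0$ shut off). This is a
deliberate idealization: it does not reproduce true kinetics or time
scales, but it identifies the most probable flux/concentration
configuration compatible with the stoichiometry and the boundary
conditions, and regulation enters as a single interpretable scalar per
reaction.

Boundary conditions are imposed by partitioning the metabolites: fixed
(boundary) species $I_f$ are pinned at prescribed concentrations —
nutrients, waste products, energy and redox couples — while variable
species $I_v$ relax. All internal state is kept as natural-log molecule
counts $\eta_i = \ln n_i$; with the default cell volume of 1 fL a 1.0 mM
concentration corresponds to $\eta = 13.308$, which doubles as the default
physiological cap $\eta_{\max}$ on every variable metabolite. The volume is
a modelling choice (`unit_context()`), selected because it identifies the
1 mM solvent-capacity cap with that round log-count bound; any other volume
merely shifts all $\eta$ and (for reactions with nonzero net molecularity)
$\log K$, and `convert_log_K_units()` keeps forces invariant under that
shift.

A steady state requires the flux vector to lie in the nullspace of the
variable-rows stoichiometric matrix $S_v$. pcoflux parameterizes this space
with an orthonormal SVD basis $B$ ($y = B\beta$), which makes the
projection onto steady-state flux space the plain matrix $BB^T$. The rank
cut-off is $10^{-10}$ times the largest singular value, and basis column
signs are normalized so the decomposition is reproducible.

## Implicit regulation: the reducibility certificate

Solving for $(\eta, y, \alpha)$ jointly is numerically hostile: the map
from flux to the log mass-action quotient that carries it,

$$\hat y_j = \log K_j + \mathrm{sgn}(y_j)\left[\log 2\alpha_j -
  \log\!\left(|y_j| + \sqrt{y_j^2 + 4\alpha_j^2}\right)\right],$$

has sensitivity $1/\sqrt{y^2 + 4\alpha^2}$, unbounded as flux and activity
vanish together — and realistic solutions contain reactions with both at
$10^{-9}$ next to fluxes of $10^3$. The key observation is that $\alpha$
need not be represented at all: a flux $y_j$ is realizable at state $\eta$
by *some* admissible activity iff it does not exceed the unregulated flux
and agrees with it in sign,

$$|y_j| \le |J_j(\eta, 1)|, \qquad (\log K_j - g_j)\,y_j \ge 0,$$

with $g = S^T\eta$. `reducibility_certificate()` checks these per reaction
(together with the equivalent force-displacement bound
$|g_j - \log K_j| \ge |h_j|$, $h_j = \mathrm{sgn}(y_j)[\log 2 -
\log(|y_j| + \sqrt{y_j^2+4})]$), and `recover_activities()` reconstructs
$\alpha_j = y_j / J_j(\eta, 1)$ afterwards. Certificate inequalities carry
an absolute slack of $10^{-6}$: the optimizer runs at tolerance $10^{-7}$
and its output must not be rejected at its own precision. The division is
guarded — an unregulated flux below $10^{-30}$ with target flux below
$10^{-12}$ maps to $\alpha = 0$ (an equilibrium-pinned reaction carrying no
flux); the same tiny denominator with a non-negligible target is an
infeasibility, never an $\alpha > 1$.

## The optimization problem

Pathway-controlled optimization maximizes total flux through a designated
growth set $G$ (biomass-polymerizing reactions) over $(\eta_v, \beta)$,
subject to the certificate conditions, $\eta_i \le \eta_{\max}$ for
variable metabolites and $\eta_i = \bar\eta_i$ for fixed ones. The
force-displacement bound is an "either/or" condition in the flux sign, so
the program linearizes it with a big-M pair

$$g_j - \log K_j \ge h_j - u_j M, \qquad
  g_j - \log K_j \le h_j + (1 - u_j) M,$$

with $M = 100$ and a switching variable $u_j \in [0,1]$ pinned to
$(\mathrm{sgn}(y_j)+1)/2$ through a smooth signum
$\tilde{\mathrm{sgn}}(x) = \lambda x / (\lambda|x| + \epsilon)$. Two
parameter pairs are used: $\lambda = 10^{50}, \epsilon = 10^{-50}$ inside
the $h_j$ definition (a near-exact signum, so the force bound is tight
except in an interval of width $\sim 10^{-100}$ around zero flux) and
$\lambda = 1, \epsilon = 10^{-50}$ for $u_j$, whose flux-derivative is then
effectively zero — $u$ behaves as a constant on each sign branch, selected
by the initialization. Because both definitions are explicit functions of
$y$, the implementation substitutes them rather than carrying $h$ and $u$
as separate decision variables; the program handle
(`build_pco_program()`) still enumerates them as definitional equalities.

Solutions need not be unique: reactions that do not feed the growth set can
often trade flux against concentration without moving the objective. All
comparisons in the test-suite therefore target the objective value and the
validation certificate, not individual fluxes.

## Initialization

Convergence of any interior method on this nonconvex program hinges on
starting with the flux signs right. The initialization (i) projects the
objective gradient (the 0/1 indicator of $G$) onto the steady-state space,
$y_g = BB^T \mathbf{1}_G$; (ii) solves the bound-constrained least-squares
problem

$$\min_\eta \left\| \mathrm{sgn}(-y_g) \circ (S^T\eta - \log K) - s
\right\|^2, \quad s \ge 0,\ \eta_v \le \eta_{\max},\ \eta_f = \bar\eta,$$

which seeks log counts whose driving forces all point along $y_g$. The
slack has the closed-form optimum $s_j = \max(r_j, 0)$, leaving a smooth
convex objective $\sum_j \min(r_j, 0)^2$ minimized by bounded quasi-Newton
iterations from the least-squares equilibrium point $S_v^T \eta \approx
\log K - S_f^T\bar\eta$ (the least-norm solution is used when $S^T$ is rank
deficient). A zero residual certifies that small fluxes along $y_g$ are
feasible at $\eta_0$. The zero-residual set is typically a whole region,
and its boundary can leave a growth-carrying reaction exactly at
equilibrium — a start from which every flux cap on the growth path is
zero. When the residual vanishes, a tie-break pass therefore moves $\eta$
toward interior points whose sign margins reach a few log units, weighting
each reaction by its component in $y_g$, while a large penalty keeps the
residual at zero. (iii) Initial fluxes are $y_0 = -\zeta\,BB^T(S^T\eta_0
- \log K)$ with $\zeta = 10$; the scale pushes fluxes away from the origin
so fewer of them change sign during the solve. $u$ starts at
$(\mathrm{sgn}(y_{0,j})+1)/2$, i.e. $1/2$ — branch undecided — for
zero-flux starts.

## The interior-point solver

No off-the-shelf interior-point NLP code is a package dependency; the
solver is part of pcoflux. It is a relaxed log-barrier method with
continuation:

* Inequality constraints $c_k(x) \ge 0$ enter as $\mu\,\psi_\delta(c_k)$,
  where $\psi_\delta$ is $-\log c$ above a threshold $\delta$ and its
  $C^1$ quadratic extension below. The extension tolerates the slightly
  infeasible iterates that the big-M start can produce.
* $\delta$ is held at $\min(\mu, 10^{-4})$ rather than tracking $\mu$.
  This matters: constraint displacements live on a log scale while the
  growth objective is exponential in them, so a loose quadratic extension
  can be out-run by the objective and the iterates diverge into deep
  violation. A gross-violation safeguard additionally reverts any
  continuation step whose iterate violates the true constraints by more
  than 0.5.
* Each barrier subproblem is solved by bounded L-BFGS followed by a damped
  projected-Newton refinement (finite-difference Hessian over the analytic
  gradient, eigenvalue-modified to be positive definite, backtracking line
  search). The barrier Hessian is stiff near the central path and
  quasi-Newton line searches alone stall there; at the problem sizes this
  solver targets (up to a few hundred variables) the explicit Hessian is
  cheap.
* Stage 1 runs the big-M program with $\mu: 10^{-2} \to 10^{-6}$ to settle
  the flux directions. Stage 2 fixes the signs $\sigma = \mathrm{sgn}(y)$
  (zero fluxes inherit the sign of their driving force) and drives
  $\mu \to 10^{-9}$ on the smooth sign-fixed program, whose per-reaction
  constraints are $\sigma_j y_j \ge 0$ and $\sigma_j y_j \le
  2\sinh(\sigma_j(\log K_j - g_j))$ — the certificate in closed form. The
  $\sinh$ argument is clamped at $\pm 30$ (caps beyond $\sim 5\times
  10^{12}$ are never active) to avoid overflow.
* Final candidates — the polished point, the stage-1 point, and
  certificate-feasible scalings of $y_0$ and $y_g$ at $\eta_0$ — are
  screened by the certificate and activity recovery; the best feasible
  objective wins. The scaled-start candidates guarantee an accepted
  solution never falls below the feasible part of its own initialization.
  Sub-tolerance fluxes are snapped to exact zero when doing so stays in the
  nullspace, so equilibrium-pinned reactions report $y = 0, \alpha = 0$
  rather than barrier residue.

The solve is deterministic: the initialization has no random component, and
the seed in `pco_settings()` exists only to pin any future randomized
fallback.

Every accepted solution is re-validated from scratch
(`validate_solution()`): nullspace residual of the fluxes, activity bounds,
the flux-inversion residual $\|S^T\eta - \hat y(y, \alpha)\|_\infty$ on
reactions with non-negligible activity, thermodynamic sign consistency,
bound satisfaction, and stationarity of the regulated dynamics.

## The MCA baseline

The comparison method regulates only to cap concentrations. From the
unregulated steady state (damped Newton on the mass-balance residual in
$\eta$; the Jacobian $S_v\,\mathrm{diag}(\partial J/\partial g)\,S_v^T$ is
analytic, with a stiff-ODE integration fallback when Newton stalls), the
loop repeatedly: finds variable metabolites above the cap (default 1.0 mM);
targets the worst violator by log ratio; scores each reaction by the
violation-weighted sum of its concentration control coefficients
$C_{ij} = \partial \ln n_i / \partial \ln \alpha_j$ over all violating
metabolites (restricted, when possible, to reactions that positively
control the target); and multiplies the winning activity by a reduction
factor. Control coefficients are central finite differences in
$\ln \alpha$ with relative step 0.05, re-solving the steady state at
$\alpha_j e^{\pm 0.05}$; $\alpha_j = 0$ columns cannot be perturbed
downward in log and are zero by convention. The reduction factor 0.5 and
the first-index tie-break are configurable loop parameters — the
literature behind this baseline fixes the selection rule but not the step
size, so both are exposed and logged in the returned trace. The maximum
violation is not guaranteed to decrease monotonically step by step; the
loop terminates when all variable log counts sit within $10^{-6}$ of the
cap or the iteration cap (default 100) is reached, in which case a partial
result with the trace and a warning is returned.

## Synthetic networks and the oracle

`generate_network()` builds chain, branch, cycle and sparse random
topologies. Every metabolite first receives a standard chemical potential
$\mu_i \sim N(0, \texttt{potential\_scale}^2)$ and equilibrium constants
are derived as $\log K_j = -\sum_i \gamma_{ij}\mu_i$, so the free-energy
landscape is exact by construction and $\log K$ telescopes to zero around
every cycle (Wegscheider consistency) — independently random constants
would create perpetual-motion cycles that make the steady-state problem
vacuous. Fixed boundary species are displaced from their natural abundance
$e^{-\mu}$ by `drive` log units (sources up, sinks down, default 3,
i.e. roughly a 20-fold concentration displacement) to create a
non-equilibrium driving force of the moderate size typical of catabolic
spans; growth defaults to the terminal sink reaction. These fixtures
emulate the thermodynamic structure of real models — consistent free
energies, boundary-driven flux, competing branches — but not their scale,
cofactor stoichiometry, or biological pathway structure, so passing tests
demonstrate correctness of the optimization machinery, not biological
fidelity.

`brute_force_pco()` is the independent reference for instances with at most
two free metabolites and nullspace dimension at most two. For fixed $\eta$
the certificate confines each flux to a signed interval
$[0,\ 2\sinh(\log K_j - g_j)]$ (or its mirror), so the inner problem is an
exact linear program in $\beta$, solved by vertex enumeration. The outer
search over the free log counts combines three deterministic passes: a
full-range grid (65 points per dimension) refined around the eight best
well-separated candidates down to a step below $10^{-6}$; a scan-and-refine
along every *cap-balance locus* $d_i = \pm d_j$ (the displacements
$d_j = \log K_j - g_j$ are affine in $\eta_v$, so these are lines in two
dimensions and points in one) — the landscape frequently consists of broad
plateaus carrying narrow tent-shaped peaks exactly where two flux caps
balance, which axis-aligned grids cannot resolve; and a final
derivative-free polish (Brent in 1D, Nelder–Mead in 2D) of the incumbent.

### Problem sizes used in the tests

The test-suite and the acceptance script run the full pipeline on panels of
ten seeded toy networks (2–4 free plus fixed metabolites, 2–6 reactions),
$10^5$-sample formula-equivalence sweeps, and MCA runs on two-reaction
overshoot chains; these sizes keep the whole suite within a few minutes on
one CPU while exercising every code path, and the oracle's exactness — not
instance size — is what carries the evidence. Nothing in the
implementation is specific to these sizes: the solver's explicit-Hessian
refinement is enabled up to a few hundred decision variables, beyond which
the quasi-Newton pass runs alone.

## Numerical conventions and edge cases

* $\mathrm{sgn}(0) = 0$ exactly; the smooth signum appears only where the
  optimization needs differentiability.
* $\alpha_j = 0$ removes a reaction; $\hat y$ is undefined there (callers
  branch) and $\hat y(0, 0)$ returns $\log K$ by convention, flagged with
  a `degenerate` attribute.
* `y_hat()` defaults to the sign-split stable form; the textbook direct
  form is available (`form = "direct"`) but suffers catastrophic
  cancellation for large positive flux, which is the reason the stable
  form exists. `y_hat_sensitivity()` reports the magnitude
  $1/\sqrt{y^2+4\alpha^2}$; the signed derivative is its negative.
* All force/flux arithmetic happens in log space before exponentiation;
  overflow produces a signed infinity with a warning rather than silent
  `NaN`s.
* Equilibrium constants can be supplied in count units (default) or mM
  (`log_K_units = "mM"` on load), since upstream free-energy tools report
  concentration-unit constants and the supplied model files do not always
  say which convention they use.

## Known limitations

* The barrier program is nonconvex; the solver finds the optimum reliably
  on the tested instance family but carries no global guarantee. Candidate
  screening ensures a returned "optimal" solution is at least feasible,
  certified, and no worse than the feasible start.
* The smooth-signum constraints are not twice continuously differentiable
  at zero flux; the Newton refinement uses finite-difference curvature and
  tolerates the kink, but reactions whose optimal flux sits exactly at a
  sign change can slow convergence.
* Activity recovery is not unique when a reaction's flux and unregulated
  flux both vanish; the package reports $\alpha = 0$ and makes no attempt
  to enumerate the equivalence class of regulations.
* The MCA loop inherits the step-size arbitrariness of its reduction
  factor; different factors give different (all cap-satisfying) terminal
  regulations.
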