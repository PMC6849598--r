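---
title: "Quantifying trophic interaction modifications: models, metrics and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying trophic interaction modifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timweb)
```

## The modelling framework

`timweb` represents a community as a set of coupled ordinary differential
equations for species biomass densities. A producer $i$ grows logistically,

$$\dot N_i = N_i\,(r_i - s_i N_i) - \textstyle\sum_{\text{out}} F,$$

and a consumer $j$ converts incoming consumption at efficiency
$\varepsilon$ while dying at a constant per-capita rate (plus optional
self-limitation),

$$\dot N_j = \textstyle\sum_{\text{in}} \varepsilon F
  - \sum_{\text{out}} F - d_j N_j - s_j N_j^2.$$

The flux $F$ through a link is a functional response: linear ($a R C$),
Holling type II ($a R C / (1 + a h R)$), or Beddington–DeAngelis
($a R C / (1 + a h R + w C)$). Consumers with linear mortality and
producers with logistic self-limitation are the minimal closure that
admits both stable interior equilibria and limit cycles in a three-species
chain, which is exactly the behavioural range the metric suite has to
cover.

A **trophic interaction modification (TIM)** attaches a modifier species
$k$ to one link $(i, j)$: a single functional-response parameter
(attack rate by default; handling time or interference optionally) is
multiplied by a modification term $f(c, K)$, where $K$ is the modifier's
density and $c = c_{ijk}$ the modification parameter. Four forms are
shipped, chosen to span the qualitative families used in the modelling
literature — unbounded, bounded below, saturating, and thresholded:

| form | $f(c, K)$ | behaviour |
| --- | --- | --- |
| `exponential` (default) | $e^{cK}$ | sign-symmetric, always positive |
| `linear_clipped` | $\max(0,\,1 + cK)$ | linear, floored at 0 |
| `hyperbolic` | $1 + cK$ for $c \ge 0$; $1/(1 + \lvert c\rvert K)$ for $c < 0$ | strictly positive one-parameter family |
| `sigmoid` | $1 + c\,K^s/(K^s + m^s)$ | thresholded, midpoint $m$, steepness $s$; needs $c > -1$ |

Every form is exactly $1$ at $c = 0$, so a zero-strength TIM is *bitwise*
equivalent to no TIM — a property the tests assert with `identical()`, not
with a tolerance. The exponential is the default because it is the only
form that is smooth, strictly positive, and symmetric under sign reversal
of $c$. The hyperbolic form's piecewise definition keeps a single signed
parameter while guaranteeing positivity for all $K \ge 0$; the price is a
kink in $c$ (not in $K$) at $c = 0$.

Modifiers come in two modes. A **dynamic** modifier is a state variable;
a **forced** (cue) modifier is held at a fixed density, mirroring
experiments that impose a modification without trophically coupling the
modifier to the system. A forced TIM at density $x$ produces the identical
term to a dynamic one evaluated at modifier density $x$.

When several TIMs target the same parameter of the same link their terms
**multiply**. Other combination hypotheses exist (e.g. dominance or
saturation of cues); the combiner is deliberately one small function
(`combined_modification`) so alternatives can be swapped in without
touching anything else.

## The metric suite

All metrics except the bare parameter $c$ are properties of the TIM *at a
system state* — usually the interior equilibrium. `compute_all_metrics`
fills one report; inapplicable fields are absent rather than zero.

**Flux change.** The link flux is evaluated twice at the *same* state:
once as-is and once with the focal TIM's term forced to 1. "Forced to 1"
is interpreted per-TIM: other TIMs on the link and the modifier's own
trophic role stay active, so the measure isolates one modification and
composes under multiple TIMs. The ratio is oriented unmodified/modified,
so a strengthened interaction ($f > 1$) gives a ratio below one.

**Change in the resource equilibrium ($B_{CR}$ ratio).** The biomass
conversion ratio of an interaction can be computed from equilibrium
resource densities; its TIM-induced change reduces to
$I^{*}/I^{*}_{c=0}$ — the resource equilibrium with the TIM over the
equilibrium with the TIM's strength zeroed. Both equilibria are solved
independently from the same initial guess and must be interior-feasible;
failure on either side is an explicit, named error. On the analytically
solvable Lotka–Volterra cue model (`lv_cue_model`) the ratio is exactly
$e^{-cK}$, which the tests verify to $10^{-6}$ across a $(c, K)$ grid.
Only the equilibrium-ratio form is implemented; a parameter-based variant
exists in the interaction-strength literature but requires quantities this
framework does not otherwise carry.

**Coefficient of variation.** For non-stationary systems the CV of the
modification term along a trajectory window, $\sigma_f/\mu_f$, with
time-weighted (trapezoidal) moments so the solver's output grid does not
bias the estimate. The default window discards the first half of the span
as transient — the framework states no burn-in rule of its own, and half
the span is a conservative default that the caller can override. A CV of
zero at a stable fixed point, and $\tfrac{1/\sqrt 2}{2} \approx 0.3536$
for a sinusoidal term $2 + \sin t$ over whole periods, are the two
calibration points in the tests.

**Jacobian elements (the TMII metric).** The pairwise trait-mediated
framing quantifies the modifier's *direct effect on each interactor*:
$\partial \dot I/\partial K$ and $\partial \dot J/\partial K$, i.e. the
modifier's column of the community matrix. It requires the modifier to be
a state coordinate (a forced cue has no column).

**Jacobian sensitivity.** The TIM-centric alternative differentiates the
*interaction* rather than the interactors:
$\partial A_{ij}/\partial K$ and $\partial A_{ji}/\partial K$, mixed
second partials of the right-hand side. These are **direct partials**: $K$
is perturbed as a coordinate at the evaluation state with no
re-equilibration. The equilibrium-shift component of a TIM's influence is
deliberately a separate question, answered by the sweep (below), so that
each metric remains well defined at a single state. This metric is
identically zero when $c = 0$, whatever the modifier's trophic links.

**Net-effects sensitivity.** Replacing $A$ by the net-effects matrix
$-A^{-1}$ (combined direct and indirect press-perturbation effects) gives
$\partial(-A^{-1})_{ij}/\partial K$, computed via
$d(-A^{-1})/dK = A^{-1}\,(\partial A/\partial K)\,A^{-1}$. Because
indirect pathways enter, this is generically nonzero even at $c = 0$ when
the modifier is trophically connected — the density-mediated shadow of a
modification. One caveat discovered during verification: "generically"
excludes degenerate topologies. In a chain whose top predator has strictly
linear mortality, the consumer diagonal entries of $A$ vanish at
equilibrium and with them the $(i,j)$ and $(j,i)$ entries of the
sensitivity, *identically in the parameters*. The shipped demonstration of
the direct-vs-density-mediated split therefore gives the predator a small
self-limitation term (`pred_self_lim = 0.05`), which breaks the degeneracy
without changing anything qualitative.

## Equilibria and derivatives: numerical choices

*Root finding.* `find_equilibrium` runs a damped Newton iteration on
$\dot N = 0$ with a line search on the residual norm. Steps that would
leave the positive orthant are shrunk, not clamped: the origin is an exact
root of every model, and clamped steps were observed to collapse iterates
onto it. A guess that is already a fixed point is returned as-is (so the
extinction state is reachable by asking for it); otherwise convergence to
a boundary (extinction) root triggers the restart policy — up to 20
log-uniform random positive guesses from a seeded generator — because the
interior root is the target. If all restarts fail, a dynamics-informed
fallback integrates the model briefly and re-seeds Newton from the
attractor's endpoint and late-window mean; this reliably enters interior
basins that are small in the Newton map but large in the flow. Results
always carry `converged`, `feasible` (all densities $> 10^{-8}$) and the
residual; non-convergence is never silent.

*Differentiation.* The Jacobian is available two ways: symbolically, by
differentiating the closed-form right-hand side built as R expressions
(`stats::D`), and by central differences with the standard first-derivative
step $h = \varepsilon^{1/3}\max(\lvert x\rvert, 1)$ per coordinate
(one-sided with a warning on the density-0 boundary, which is the domain
edge). Piecewise forms are differentiated on the branch active at the
evaluation state. The nested (second-derivative) difference for
$\partial A/\partial K$ uses a larger outer step, $10^{-4}\times$ scale:
the inner Jacobian carries rounding error of order $\varepsilon^{2/3}$,
and balancing that against truncation moves the optimum well above the
first-derivative step. Symbolic and difference paths are compared on
seeded random models in the tests (agreement to $10^{-5}$ for the
Jacobian, $10^{-4}$ for the sensitivities). Near-singular community
matrices (condition number above $10^{12}$, or a caller-supplied bound)
raise a conditioning error rather than returning amplified noise; the
verification scripts use a stricter $10^{7}$ bound because finite
differences cannot certify the identity beyond it.

*Stability margin.* Eigenvalue real parts within $10^{-7}$ of zero are
classified `marginal`, separating the neutrally stable Lotka–Volterra
centre from decisive classifications.

*Integration.* Trajectories use `deSolve::ode` (lsoda) at tolerances
$10^{-8}/10^{-10}$, evaluating the right-hand side on the clamped state
and holding boundary species with negative rates at zero (clamp events are
counted). `classify_dynamics` inspects the second half of the span:
extinction and divergence (cap $10^{8}$) first, then a per-species
relative amplitude threshold of 1% — robust to numerical ripple —
distinguishes rest from oscillation. Persistent bounded oscillation is
attributed by the interior equilibrium's spectrum: decisively unstable
means a limit cycle (`cycling`), a neutral spectrum means `marginal`.

## The demonstration systems

The original three-system comparison depends on supplementary parameter
values that are not part of this package's sources, so the demos are
package-defined constants with the same *structure*, and every claim made
about them is a property the test suite itself verifies rather than a
number carried over:

- `chain_linear` — plant–herbivore–predator with linear consumption
  ($r = 1$, plant self-limitation $0.05$, $a_1 = 0.5$, $a_2 = 0.4$,
  $\varepsilon = 0.5$, $d = 0.1$), predator modifies the plant–herbivore
  attack rate exponentially. Stable interior equilibrium
  $(15, 0.5, 9.125)$ at $c = 0$.
- `chain_nonlinear` — same topology with Holling II links. The starting
  parameter set (handling time $0.2$, plant self-limitation $0.05$) proved
  *unstable* at $c = 0$ under verification; the frozen defaults are
  $h = 0.1$ and plant self-limitation $0.2$, which give a stable interior
  equilibrium at $c = 0$, feasible equilibria across the whole shipped
  sweep grid $c \in [-1, 1]$, and a monotone modification term alongside
  non-monotone flux-difference and net-sensitivity columns — the
  qualitative point of the metric comparison.
- `aphid_parasitoid` — two hosts sharing one parasitoid, host 1's density
  shielding host 2 (exponential TIM, $c = -0.5$, on the parasitoid's
  attack on host 2). Purely exponential host growth leaves this topology
  without a generic interior equilibrium (one parasitoid density cannot
  balance two independent host growth rates), so the hosts are logistic —
  the structural point, a modification *between* host–parasitoid links, is
  unaffected. Which parameter the TIM modifies is exposed as configuration
  (`tim_affected_parameter`) rather than asserted.
- `build_stabilization_demo` — an enriched Rosenzweig–MacArthur pair
  ($r = 1$, $s = 0.05$, $a = h = 1$, $\varepsilon = 0.5$, $d = 0.3$) that
  cycles at $c = 0$ (leading eigenvalue $+0.24$), with the consumer's own
  density reducing its attack rate. The scan over $c \in [0, -1]$ shows
  the classification flipping to a stable point between $c = -0.1$ and
  $-0.2$, in agreement with the sign of the leading eigenvalue — a
  TIM-driven stabilisation of a cycling system. It is a representative of
  that phenomenon, not a replication of any specific published
  parameterisation.

## Synthetic experiments and what they do (not) show

`generate_random_chain` rejection-samples tri-trophic chains from
documented parameter ranges until the TIM-free model has a feasible,
stable interior equilibrium, and attaches a TIM of the top predator on the
bottom link. It is the fixture generator for the property-based tests
(null-TIM equivalence, oracle agreement), seeded and reproducible.

`generate_fr_experiment` emulates short-term functional response trials
crossing prey and modifier densities — the experimental design that makes
TIM parameters identifiable. Consumption rates are the true TIM-modified
surface times multiplicative lognormal noise in the mean-one
parameterisation ($\mathbb E[\text{observed}] = \text{true}$), so the
synthetic experiments are unbiased by construction. The default design
(5 prey × 5 modifier levels × 10 replicates, CV 5%) recovers the
modification parameter with a median relative error around 1–2%
(`fit_tim_model`: Levenberg–Marquardt with seeded multi-start, bounds
$a > 0$, $h \ge 0$, $c$ free).

What passing these tests shows is that the *pipeline* is consistent: data
generated from the model family are fitted correctly by the model family.
Real feeding trials violate the emulation in known ways — prey depletion
within trials, non-lognormal and density-dependent error, modifier
behaviour that is itself dynamic, and model misspecification of the TIM
form — none of which the generator imitates. Conclusions about real
systems need the experimental caveats, not just these checks.

## Problem sizes

The shipped verification uses 100 random chains for the dynamical
equivalence property, 50 for each derivative-oracle comparison, a 21-point
sweep grid, an 11-point stabilisation grid, and 20 replicate noisy
experiments of $n = 250$ observations — sizes at which every property is
decisively resolved while the whole suite remains quick to run on a single
core.

## Known limitations

- Modifications of modifications (a TIM targeting another TIM), delayed or
  cue-state-variable modifications, stochastic dynamics, and stage
  structure are out of scope; modifications act instantaneously through
  the functional response.
- All sensitivity metrics are local (linearisation at a state); they say
  nothing about large perturbations.
- The multiplicative combiner for simultaneous TIMs is a default, not a
  law; evidence for alternatives should replace it via
  `combined_modification`.
- Metric values at near-singular community matrices are refused rather
  than extrapolated; sweeps flag and skip non-converged or infeasible
  grid points rather than interpolating across folds.
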