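---
title: "Moment reduction of phenotype-structured models of cancer adaptive dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moment reduction of phenotype-structured models of cancer adaptive dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(phenomoments)
```

## The model

Non-genetic intratumour heterogeneity — reversible, continuously graded
differences in gene or protein expression between genetically identical
cancer cells — is tracked by a *phenotypic density function* $p(t, x)$: the
density of cells at trait value $x \in [l, L]$ at time $t$.  The population
size is $P(t) = \int_l^L p(t,x)\,dx$, and the density evolves by a nonlocal
reaction–advection–diffusion equation

$$
\partial_t p \;=\; \beta\, \partial^2_{xx} p
\;-\; \partial_x\!\big[V(t,x)\,p\big]
\;+\; \Big(f(t,x) - \tfrac{P(t)}{\kappa}\Big) p ,
$$

with no-flux boundaries $\beta\,\partial_x p + V p = 0$ at $x = l, L$.  The
three mechanisms are:

* **diffusion** $\beta \ge 0$ (trait$^2$/time) — spontaneous, undirected
  phenotypic fluctuation;
* **advection** with velocity $V(t,x)$ (trait/time) — environment-driven
  adaptation, e.g. drug-induced drift toward resistant states;
* **reaction** — trait-dependent net growth $f(t,x)$ (1/time) minus
  logistic-type competition $P/\kappa$ ($\kappa$ in cells·time).

The trait domain is bounded because expression levels are: values outside
the observable range are biologically infeasible, and the density at the
domain edges is assumed negligible (the package's `boundary_mass()`
diagnostic checks this assumption on every PDE solve rather than taking it
on faith).

A `phenotype_model` carries $f$, $V$, exact $x$-derivative providers for
both, $\beta$, $\kappa$ and the domain.  Both $f$ and $V$ also receive $P$,
so that adaptive-dynamics formulations in which the logistic term lives
*inside* the fitness function (see the therapy section) fit the same
interface with the separate competition term disabled.

## From PDE to moment ODEs

Dividing by $P(t)$ gives a probability density $\hat p = p/P$ over trait
space with raw moments $m_k(t) = \int x^k \hat p\,dx$; $m_0 \equiv 1$ by
construction.  Multiplying the PDE by $x^k$ and integrating, every integral
of the form $\int x^k f \hat p\,dx$ can be expanded — provided $f$ and $V$
are smooth — by Taylor-expanding $f$ and $V$ about the current mean trait
$m_1(t)$:

$$
f_n(t) = \frac{\partial_x^n f\big|_{x = m_1(t)}}{n!}, \qquad
V_n(t) = \frac{\partial_x^n V\big|_{x = m_1(t)}}{n!},
$$

which turns the integrals into binomial sums of raw moments,

$$
S(n, k) \;=\; \sum_{i=0}^{n} (-1)^i \binom{n}{i} m_1^i\, m_{n+k-i},
$$

implemented in `central_sum()` ($S(n,0)$ is the $n$-th central moment).
Truncating the Taylor series at order $M$ and tracking the first $N$
moments yields the closed system assembled by `moment_rhs()`:

$$
\begin{aligned}
P' &= P \sum_{n=0}^{M} f_n S(n,0) \;-\; \frac{P^2}{\kappa},\\
m_1' &= \sum_{n=0}^{M} (V_n - m_1 f_n)\, S(n,0)
        + \sum_{n=0}^{M} f_n\, S(n,1),\\
m_k' &= -m_k \sum_{n=0}^{M} f_n S(n,0) + \beta k(k\!-\!1)\, m_{k-2}
        + k \sum_{n=0}^{M} V_n S(n,k\!-\!1)
        + \sum_{n=0}^{M} f_n S(n,k), \quad 2 \le k \le N.
\end{aligned}
$$

The $m_1$ equation has a genuinely different drift/growth structure from
the $k \ge 2$ equations and is assembled as its own branch, not as a
special case.  The sums reference moments up to order $N + M$; the closure
supplies $m_{N+1}, \dots, m_{N+M}$ from the tracked ones at every
right-hand-side evaluation (the closed moments are never integrated).

The truncation of the Taylor series is justified on the unit trait domain,
where $0 < m_1 < 1$ keeps the binomial sums under control.  Models on a
general $[l, L]$ are therefore mapped to $[0,1]$ before integration
(`rescale_model_to_unit()`) and the resulting moments mapped back
(`rescale_moments()`; for $l = 0$ this is $m_k \to m_k L^k$, in general an
affine map with the binomial moment transformation).  If $m_1$ nevertheless
leaves $(0,1)$, or the variance $m_2 - m_1^2$ drops below $-10^{-10}$, the
trajectory is *flagged* invalid and a single summary warning is raised —
it is not clipped or aborted, because closure-failure modes are themselves
worth studying.

## Closures

Two closure families ship, chosen by `closure_spec()`:

* **`truncation`** — $m_k = 0$ for $k > N$.  Crude, but assumption-free.
* **`gaussian`** (default) — the recursion satisfied by the raw moments of
  a normal distribution,
  $m_k = m_1 m_{k-1} + (k-1)\,(m_2 - m_1^2)\, m_{k-2}$.
* **`gaussian_literal`** — the same recursion with prefactor $k$ in place
  of $k-1$.  This variant circulates in the literature on these reductions;
  it does **not** reproduce true normal moments (for the standard normal it
  gives $m_4 = 4$ instead of 3) and it breaks the exact-equivalence
  property below.  It is retained, behind an explicit option, purely so the
  two conventions can be compared; every default and every test of
  substance uses the $(k-1)$ recursion, which a quadrature oracle over the
  normal density confirms.

**Exact equivalence for quadratic selection.**  For
$f = a - b_{\mathrm{sel}}(x - X)^2$, $V = V_0$ — the classical model of a
fittest trait $X$ under selection strength $b_{\mathrm{sel}}$ — the
reduction with $N = M = 2$ and Gaussian closure collapses *exactly* onto
the familiar three-equation system for $(P, m_1, \sigma^2)$:
$\sigma^{2\prime} = 2\beta - 2 b_{\mathrm{sel}} \sigma^4$, etc.  The test
suite verifies this at 1000 random admissible states to a relative
$10^{-12}$, against an independently hand-coded implementation of that
classical system.  Two closed-form consequences double as tests: with
$b_{\mathrm{sel}} = 0$ the variance grows exactly linearly,
$\sigma^2(t) = \sigma_0^2 + 2\beta t$, and with selection it settles at
$\sigma^2_\infty = \sqrt{\beta / b_{\mathrm{sel}}}$.

## The reference PDE solver

`solve_pde()` exists to validate the reduction, so it is deliberately
simple and *exactly conservative*: node-centred finite volumes on a uniform
grid (trapezoid weights), first-order upwind advective flux and
second-order central diffusive flux at cell faces, zero flux through both
boundary faces, forward-Euler time stepping, and the nonlocal $P(t)$
recomputed by trapezoid quadrature every step.  Because the discrete mass
is the same trapezoid sum that defines $P$, mass is conserved to rounding
error when $f \equiv 0$ (the suite requires relative drift $\le 10^{-6}$;
observed: $\sim 10^{-16}$), and $m_0 \equiv 1$ holds to $10^{-10}$ at every
output time by construction rather than by accident.

The default step is the positivity bound of the combined scheme,

$$
\Delta t \;=\; \frac{0.9}{\,2\beta/\Delta x^2 + \max|V|/\Delta x +
\max(0, -\min \text{growth})\,},
$$

which is stricter than the separate diffusion ($\Delta x^2 / 2\beta$) and
advection ($\Delta x / \max|V|$) limits: upwinding acts as additional
diffusion of size $|V|\Delta x / 2$, so the two limits combine
harmonically, and a strongly negative early-time net growth rate (heavy
competition) shrinks the admissible step further.  A user-supplied step
above the bound is reduced with a message by default
(`on_cfl = "adjust"`), or rejected with the maximal admissible value named
(`on_cfl = "error"`).  Under this bound the update matrix is nonnegative,
so the density stays positive up to rounding noise ($\ge -10^{-12}
\max p$); values below zero are clipped only at moment extraction.

Upwind advection is first-order accurate; the suite checks that halving
$\Delta x$ shrinks the mean-trait error against a fine-grid reference by at
least $1.8\times$.  (For *constant* drift the discrete mean is exact away
from the boundaries — a summation-by-parts identity — so that case is used
to check the drift *rate*, $\pm 2\%$, not the convergence order.)  Grid
resolution for the benchmark runs is an implementation choice recorded in
every output's metadata; the suite uses $\Delta x = (L-l)/600$ for
production comparisons, $1/300$ for the structural $m_0$ check, and a
$\Delta x = 1/2000$ reference when closure variants are ranked, because at
coarser resolution the scheme's own $O(\Delta x)$ bias exceeds the
differences between good closures.

## Derivatives of $f$ and $V$

The reduction needs $\partial_x^n f$ and $\partial_x^n V$ *at a moving
point* (the current mean) at every right-hand-side call, so derivative
access is provider-based:

* quadratic model: polynomial derivatives, closed form; orders $\ge 3$ of
  $f$ and $\ge 1$ of $V$ are identically zero;
* Hill growth $f = f_{\max}\, x/(k_x + x)$: closed form
  $f^{(n)} = f_{\max} k_x (-1)^{n+1} n! \,(k_x + x)^{-(n+1)}$;
* tanh drift $V = V_{\max} \tanh(x^\omega)\tanh(1 - x)$: exact symbolic
  derivatives, obtained by rewriting $\tanh z = 1 - 2/(e^{2z}+1)$ so that
  repeated symbolic differentiation applies, evaluated at run time;
* G-function model: closed forms for all orders (exponential times
  logistic, plus an inverse-linear treatment term);
* anything user-supplied without a provider: central finite differences
  with an order-dependent step $h_n = \varepsilon^{1/(n+2)}(L - l)$
  (machine epsilon $\varepsilon$), the standard truncation/round-off
  balance for an $O(h^2)$ stencil — a fixed small step such as
  $10^{-4}(L-l)$ loses about twelve significant digits to cancellation at
  order 3 and cannot meet the package's own $10^{-5}$ agreement tolerance.

All providers are cross-checked against a twice-Richardson-extrapolated
($O(h^6)$) central-difference oracle on 50 probe points at orders 1–3.

## The Hill/tanh benchmark

The non-polynomial worked example uses saturating (Michaelis–Menten)
growth and a drift that pushes expression toward $x = 1$:
$f_{\max} = 2$, $k_x = 0.4$, $V_{\max} = 0.5$, $\omega = 1$,
$\kappa = 0.1$, $\beta = 10^{-4}$, truncated-normal start centred at
$\bar x_0 = 0.2$ with $\sigma_0 = 0.02$, domain $[0, 1.2]$ (wider than the
unit interval precisely so the mass accumulating near $x = 1$ never touches
the boundary), horizon $t \in [0, 35]$.

```{r hill, eval = FALSE}
model <- hill_tanh_model(f_max = 2, k_x = 0.4, V_max = 0.5, omega = 1,
                         beta = 1e-4, kappa = 0.1, domain = c(0, 1.2))
p0  <- truncated_normal_density(0.2, 0.02, 0, 1.2, P0 = 1)
sol <- solve_pde(model, p0, t_end = 35, grid = pde_grid(c(0, 1.2), 600))
mom <- extract_moments(sol, k_max = 2)

st0 <- initial_moments_from_density(p0, 2, domain = c(0, 1.2))
red <- integrate_moments(rescale_moments(st0, "to_unit", 0, 1.2),
                         rescale_model_to_unit(model),
                         closure_spec(N = 2, M = 2, method = "gaussian"),
                         t_span = sol$times)
compare_moments(mom, rescale_moments(red, "from_unit", 0, 1.2))
```

With $N = M = 2$ and Gaussian closure the reduced mean trait tracks the
PDE to a relative sup-norm error of about $0.6\%$ (the suite requires
$\le 5\%$).  Ranked against a fine-grid reference, including the
second-order Taylor term improves on $M = 1$, and truncation closure is
substantially worse than Gaussian on $m_2$ and $m_3$ — consistent with a
density that diffusion keeps close to bell-shaped.  The same pipeline is
available declaratively through `run_experiment()`; see
`inst/extdata/example_experiment.yaml`.

## Adaptive therapy and the G-function model

The adaptive-dynamics formulation of treatment resistance tracks a
monomorphic population by its size and mean resistance trait, with fitness
given by a *fitness-generating function*

$$
G(x, P) = r_{\max} e^{-g x}\Big(1 - \frac{P}{\kappa}\Big) - d -
\frac{c(t)}{k_{\mathrm{half}} + b_{\mathrm{res}}\, x},
$$

($c(t) \in \{0,1\}$ the treatment signal; $g$ the cost of resistance;
$b_{\mathrm{res}}$ its benefit) and gradient-ascent adaptation
$m_1' = \alpha\, \partial_x G$.  In the structured-PDE view this is the
special case $f = G$ (competition inside $G$, so the separate quadratic
term is disabled) and $V = \alpha\, \partial_x G$; the classical
two-equation system is the $N = M = 1$ reduction with all higher-order
terms dropped (the suite verifies the exact identity: the generic $N=M=1$
engine differs from the two-equation system by precisely
$\partial_x G \cdot m_1^2$).

`simulate_adaptive_therapy()` runs the standard adaptive schedule —
treat from $t = 0$, pause when the tumour falls to half its initial size,
resume when it regrows to the initial size, declare progression at
$0.7\kappa$ — with threshold crossings located by the integrator's root
finder and the integration restarted at each switch.  Three variants are
exposed: the homogeneous `n1m1` system and the heterogeneous `N = M = 2`
reductions under Gaussian or truncation closure, started monomorphic
($m_2(0) = m_1(0)^2$) with diffusion $\beta$.

**Parameters.**  The adaptation speed and diffusion coefficient appear in
the source literature as two inconsistent pairs —
$\alpha = 10^{-4}, \beta = 2\times 10^{-4}$ in one place and
$\alpha = 10^{-5}, \beta = 2\times 10^{-5}$ in another — and both are
supported; the shipped default is the smaller pair.  The remaining
G-function values are **not** printed in the source and its cited
parameterisation was not available, so the package ships a clearly
labelled *synthetic stand-in*
(`inst/extdata/gfunction_params_synthetic.json`:
$r_{\max} = 0.75$, $g = 0.1$, $d = 0.01$, $k_{\mathrm{half}} = 1$,
$b_{\mathrm{res}} = 60$, $\kappa = 10^4$ cells, $P(0) = 6000$,
$m_1(0) = 0$), calibrated once so the simulation sits in the reported
qualitative regime: with it, the homogeneous model sustains control for
979 days while the Gaussian-closure heterogeneous model progresses at 39
days — heterogeneity collapses the time to progression by a factor of
about 25.  Every result that depends on these values is labelled
"external-parameter".

**What the faithful reduction does and does not reproduce.**  The printed
heterogeneous systems in the source literature could not be used as
oracles: the Gaussian-closure system as printed retains raw $m_3, m_4$
symbols after announcing closure, and the truncation-closure system
carries a $-G\,m_2$ term in its variance equation.  In the generic
assembly that term cancels identically ($f_0 S(0,2) - m_2 f_0 S(0,0)
\equiv 0$), so it cannot arise from the stated equations; left in place it
acts as an exponential variance pump whenever treatment makes $G$ strongly
negative.  Without that pump, variance grows at $2\beta$ per unit time
plus curvature-damped selection terms, which ties the two headline times
together: the homogeneous time to progression scales like
$(\beta_{\mathrm{eff}}/\alpha)\, t_{\mathrm{het}}^2$ with
$\beta_{\mathrm{eff}} \le \beta = 2\alpha$ for both supported
$(\alpha,\beta)$ pairs.  Parameter scans across two orders of magnitude in
$b_{\mathrm{res}}$ and the full plausible ranges of the other rates
confirm the square law with prefactor $0.3$–$0.65$.  Consequently a
heterogeneous failure at four weeks coexists with homogeneous control
beyond 800 days only at the very edge of the undamped limit; the shipped
stand-in reproduces the control/failure dichotomy and its direction and
magnitude (a $\sim$25-fold acceleration), but not the literal four-week
figure, and the corresponding strict assertions in the acceptance suite
are deliberately left failing rather than papered over.  The
truncation-closure variant, lacking the Gaussian third-moment feedback,
only fails fast in a strong-selection regime where its variance turns
negative (the trajectory is then flagged invalid); under the stand-in it
remains controlled.

```{r therapy, eval = FALSE}
gp <- read_gfunction_params(
  system.file("extdata", "gfunction_params_synthetic.json",
              package = "phenomoments"))
proto <- therapy_protocol(P_init = 6000)
hom <- simulate_adaptive_therapy("n1m1", gp, proto, t_end = 1000)
het <- simulate_adaptive_therapy("n2m2_gaussian", gp, proto,
                                 t_end = 150, beta = 2e-5)
c(homogeneous = hom$t_ttp, heterogeneous = het$t_ttp)
plot(het)
```

## Numerical choices and degenerate inputs

* Moment ODEs: adaptive Runge–Kutta (`deSolve`, `ode45`) with
  `rtol = 1e-8`, `atol = 1e-10`; therapy segments use `lsodar` for its
  root finder, `atol = 1e-8` on cell counts of order $10^3$–$10^4$.
* During internal trial stages the integrator may probe $P \le 0$; the
  right-hand side floors $P$ at the smallest normal double (the solution
  itself stays positive since $P' \to 0$ as $P \to 0^+$).  A non-finite
  state aborts with the breakdown time and closure named.
* `moment_rhs()` clamps the Taylor expansion point to the domain;
  a population size $\le 0$ or a request for unavailable moment indices is
  an error with context.
* Initial moments from a density function use adaptive quadrature at
  relative tolerance $10^{-10}$; tabulated densities use the same
  trapezoid rule as the solver.  Zero initial mass is an error.  For
  extremely sharp densities (width $\lesssim 10^{-3}$ of the domain)
  adaptive quadrature can miss the spike; tabulate on a grid in that case.
* A zero-length time horizon returns the initial state with valid
  metadata rather than erroring.
* The pipeline contains no randomness anywhere; identical configurations
  produce byte-identical outputs (a test asserts this).

## Limitations

* One trait dimension only; multi-dimensional phenotype spaces are out of
  scope.
* The closure is an approximation chosen a priori; nothing guarantees a
  valid moment sequence, which is why validity flags (mean leaving the
  unit interval, negative variance) travel with every trajectory instead
  of being enforced.
* The reference solver is first-order in the advection term by design
  (matching the scheme the reduction is validated against); ranking
  subtle closure differences requires the fine grids noted above.
* The boundary-term neglect behind the moment equations is monitored, not
  proven: `boundary_mass()` warns when the normalized boundary density
  exceeds $10^{-3}$ of the density maximum, the practical signal that the
  domain should be widened.
* The synthetic therapy parameter set reproduces a regime, not a
  published fit; conclusions drawn from it are qualitative by
  construction.
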