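---
title: "Methods: radical-pair quantum yields by stochastic Schrödinger propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radical-pair quantum yields by stochastic Schrödinger propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpsse)
```

## The model

A radical pair is two unpaired electron spins, one per radical, coupled to
a set of magnetic nuclei. Its reactive spin dynamics are governed by the
Liouville–von Neumann equation with Haberkorn recombination,

$$\frac{d\hat\rho}{dt} = -i[\hat H,\hat\rho] - \{\hat K,\hat\rho\},
\qquad \hat K(t) = \sum_\Theta \frac{k_\Theta(t)}{2}\,\hat P_\Theta,$$

where $\hat P_\Theta$ projects onto the electronic singlet or one of the
three triplet states and $k_\Theta$ is the (possibly time-dependent) rate
of the reaction removing population from state $\Theta$. Energies are
expressed as angular frequencies (internally rad/µs). The spin Hamiltonian
contains the electron Zeeman terms, electron–nuclear hyperfine couplings
(isotropic constants or full 3×3 tensors), the electron exchange
interaction and the dipolar tensor:

$$\hat H = \sum_{i=1,2}\Big[g_i\mu_B \mathbf{B}\cdot\hat{\mathbf S}_i/\hbar
 + \sum_k \hat{\mathbf S}_i\cdot\mathbf A_{ik}\cdot\hat{\mathbf I}_{ik}\Big]
 - J\,(2\hat{\mathbf S}_1\cdot\hat{\mathbf S}_2 + \tfrac12)
 + \hat{\mathbf S}_1\cdot\mathbf D\cdot\hat{\mathbf S}_2 .$$

**Exchange convention.** With the sign above the singlet–triplet gap is
$2J$. Because half the literature quotes $2J$ rather than $J$ (and sign
conventions differ), `exchange_term()` requires an explicit key (`J_MHz`,
`twoJ_mT`, ...). The 2J resonance of an exchange-coupled pair appears at
$B = 2J$ in field units, which is how the wire example pins the convention
observably.

**Units.** Couplings given in mT are converted with the free-electron
gyromagnetic ratio ($g = 2.0023$ by default, $\mu_B/\hbar$ from CODATA);
MHz quantities are multiplied by $2\pi$. Times at the user surface are ns,
rates µs⁻¹.

Instead of propagating $\hat\rho$ (dimension $16Z^2$ real numbers for
nuclear dimension $Z$), the package propagates state vectors under the
stochastic Schrödinger equation with the non-Hermitian generator
$\Omega(t) = -i\hat H(t) - \hat K(t)$; the shrinking norm carries the
reaction. The quantum yield of channel $\Theta$ from initial electronic
state $\Theta_\mathrm{init}$ and the maximally mixed nuclear state
$\hat 1/Z$ is

$$\Phi_\Theta = \int_0^\infty k_\Theta(t)\,
\frac{1}{Z}\operatorname{Tr}_\mathrm{nuc}
\langle\psi(t)|\hat P_\Theta|\psi(t)\rangle\,dt .$$

Two trace-evaluation modes are provided:

* **direct** (`yield_direct`): all $Z$ nuclear basis states are
  propagated; exact, cost $\mathcal O(Z)$ propagations.
* **stochastic** (`yield_stochastic`): $M$ SU($Z$) coherent states —
  complex vectors with i.i.d. Gaussian components, normalized, hence
  uniform on the unit hypersphere — replace the basis sum. Because
  $\mathbb E[|Z\rangle\langle Z|] = \hat 1/Z$, each sample is an unbiased
  trace estimate; the estimator reports the sample standard error over the
  $M$ per-sample yields. Sampling is counter-based (sample $m$ depends
  only on the base seed and $m$), so results are reproducible and
  insensitive to how many samples run. For small $Z$ the variance gain is
  limited and `yield_stochastic` warns when $M > Z$.

Mixed initial electronic states are handled by combining runs, not inside
the propagator.

## Propagation and numerical choices

Each step applies $e^{\Omega\,\delta t}$ with $\Omega$ frozen over the
step (first-order Magnus). Three backends implement the exponential
action: dense scaling-and-squaring (used automatically up to dimension
256, where it is both fastest and exact to roundoff — for a static
generator the propagator is built once and reused), Arnoldi, and Lanczos
(valid only for purely anti-Hermitian generators, i.e. no reaction; the
package warns and falls back to Arnoldi otherwise). The Krylov stopping
rule uses the standard residual estimate
$|h_{m+1,m}\,[e^{\delta t H_m}]_{m,1}|\le\varepsilon$ with subspace cap 30
and recursive time-splitting on non-convergence; the default
$\varepsilon = 10^{-6}$–$10^{-8}$ favours accuracy over speed.

For time-dependent generators the default evaluates $\Omega$ at the step
start (zero-order hold, matching how tensor trajectories are defined;
globally first order in $\delta t$). `propagator_config(time_eval =
"midpoint")` switches to the exponential midpoint rule, which is higher
order and markedly more accurate at equal step for smoothly driven
systems. The default test step is $\delta t = 1$ ns; production
radical-pair work commonly uses 4 ns, and convergence should always be
checked by halving $\delta t$ (the test suite does exactly this with a
Richardson ratio).

Yield integrals are evaluated by composite Simpson quadrature on the step
grid ($\mathcal O(\delta t^4)$), which is what allows the direct method to
match the dense reference to $10^{-6}$ at $\delta t = 0.25$ ns.

**Tail correction (symmetric rates).** When $k_S = k_T = k_\mathrm{sym}$
is constant, the reaction factorizes as $e^{-k_\mathrm{sym}t}$ times
unitary dynamics, and the truncated yield integral can be completed
geometrically:

$$\Phi_\Theta(\infty) \approx
\frac{\int_0^T k_\mathrm{sym} e^{-k_\mathrm{sym}t} p_\Theta(t)\,dt}
     {1 - e^{-k_\mathrm{sym}T}} .$$

The completion is exact for constant $p_\Theta$ at any $T$; for
oscillatory populations its error decays like $e^{-k_\mathrm{sym}T}$
times the residual phase imbalance. In practice $T \approx 1/k_\mathrm{sym}$
already matches a plain truncation at $T \approx 6$–$10/k_\mathrm{sym}$ to
$10^{-3}$ — the several-fold saving in propagation time that makes long
lifetimes affordable. It also makes $\sum_\Theta\Phi_\Theta = 1$ hold to
quadrature accuracy, which the tests use as a conservation check.
`corrected_yield()` exposes the same formula for externally computed
population series; it refuses asymmetric schemes, for which the
factorization does not hold and plain integration to several lifetimes is
used instead.

## The dense reference solver

`dense_yield`/`dense_trajectory` integrate the full master equation with
`deSolve::zvode` (complex Adams, rtol $10^{-10}$), accumulating the yield
integrals as auxiliary ODE components. ODE integration was chosen over
superoperator exponentiation to avoid $\dim^2\times\dim^2$ memory. The cap
is dimension 256. Every fast path is validated against this solver; the
headline gate in the test suite checks $|\Delta\Phi_S| \le 10^{-6}$ on
randomized systems up to dimension 48 (mixed I = 1/2 and I = 1 nuclei,
random tensors, random field and exchange).

## Time-dependent interactions

Two mechanisms are implemented, mirroring the two physical sources of
time dependence:

* **Driven geometry** (`driven_geometry`, `driven_yield`, `driven_chi`):
  the inter-radical distance oscillates harmonically,
  $r(t) = r_0 - \frac{\Delta_d}{2}(1 - \cos 2\pi\nu_d t)$, and both the
  exchange coupling and the singlet recombination rate follow exponential
  distance laws $J(t) = J_0 e^{-\beta(r-r_0)}$,
  $k_b(t) = k_{b0} e^{-\beta(r-r_0)}$ with a shared $\beta$. The phase
  convention (oscillation between $r_0$ and $r_0-\Delta_d$, starting at
  $r_0$) was chosen so that $\nu_d = 0$ reduces identically to the static
  system; only the period and peak-to-peak amplitude are observable in the
  yields. The built-in `driven_n5` system (one axial I = 1 nucleus with
  principal hyperfine components −2.6/−2.6/49.2 MHz, B = 50 µT,
  $k_{b0} = 2$ µs⁻¹, $k_f = 0.5$ µs⁻¹, $\beta = 1.4$ Å⁻¹, $\Delta_d = 3$ Å,
  $r_0 = 17.8$ Å) reproduces the qualitative driven-pair result: with
  $J_0 = 10$ MHz static exchange suppresses the yield anisotropy
  $\chi = (\Phi_\parallel - \Phi_\perp)/\bar\Phi$, and driving at a few
  MHz restores it ($\chi$ rises from 0.0038 to 0.0073 at
  $\nu_d = 5$ MHz with the package's defaults). $\chi$ is defined with the
  symmetric mean $\bar\Phi = (\Phi_\parallel+\Phi_\perp)/2$ so that it is
  zero iff the yields are equal, flips sign under argument swap, and is
  scale-free; the reported yields for the driven scheme are the
  backward-recombination channel $\int k_b(t)\langle P_S\rangle dt$.

* **Tensor trajectories** (`trajectory_series`, `hamiltonian_at_time`):
  tagged hyperfine or dipolar tensors are replaced by a time series of 3×3
  tensors (MHz) on a uniform grid, held piecewise-constant (zero-order
  hold; the canonical sampling interval is 50 ps, the cadence at which
  MD-derived tensors are typically recomputed). No extrapolation beyond
  the last sample: the propagator refuses to start if the trajectory is
  shorter than the integration window. The text format is tab-separated
  with a `time_ns` column and `<tag>.<xx..zz>` component columns.

## The synthetic fluctuation generator

`generate_fluctuating_tensor` emulates MD/QC tensor time series with a
stationary Ornstein–Uhlenbeck process per component: mean tensor $\mu$,
component standard deviation $\sigma$, correlation time $\tau$, sampled
every 50 ps by default. This captures what matters for spin relaxation —
a stationary Gaussian modulation with a single correlation time — and the
tests verify its mean, variance and autocorrelation against the OU closed
forms. What it deliberately does not capture: multi-timescale protein
dynamics, correlated fluctuations between tensor components or between
nuclei, and conformational jumps. Passing the relaxation tests therefore
demonstrates that fluctuating interactions damp orientation contrast in
the simulator, not that any particular protein does so. With
$\sigma = 5$ MHz and $\tau = 100$ ps on an N5-like tensor (values chosen
once to match the visual scale of published MD-derived hyperfine
fluctuations), the orientation-scan amplitude of a two-nucleus pair drops
from 0.124 (static) to 0.098 (dynamic) over a 1 µs lifetime.

## Problem sizes and limitations

The package constructs operators sparsely (complex operators as pairs of
real sparse matrices; cost per matrix–vector product is proportional to
the number of stored entries) and never densifies above the configurable
dense path. The test suite and the acceptance script run on systems of
dimension 8–64 — one to four nuclei — where the dense oracle is available
and every cross-check is exact; the 12-, 14- and 20-nucleus
flavin/tryptophan rosters are included as constructible systems
(dimensions 55,296 / 221,184 / 21,233,664) with dimension accounting
tested, but figure-scale stochastic scans of them are intentionally out of
test scope. Their anisotropic hyperfine tensors originate in
quantum-chemistry data that the package does not ship; users supply them,
or request clearly-flagged synthetic stand-ins for exercising the
machinery.

Known limitations: only two electrons; nuclear spins limited to I = 1/2
and 1 (rejected loudly otherwise); no nuclear Zeeman or quadrupolar terms;
no g-tensor anisotropy; Haberkorn kinetics only (no Lindblad dephasing or
alternative reaction superoperators); spin-coherent-state sampling is
deliberately not implemented (SU(Z) states need fewer samples); and the
orientation scans rotate the field in the molecular z–x plane with tensors
fixed, which covers axial questions but not full sphere averages.
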