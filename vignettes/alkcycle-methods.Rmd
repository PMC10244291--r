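---
title: "Methods: the calcifier-alkalinity glacial-cycle model and its analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the calcifier-alkalinity glacial-cycle model and its analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(alkcycle)
```

## The model and its assumptions

The model tracks two well-mixed ocean quantities: alkalinity $A$
(mol eq m$^{-3}$) and the calcifier population $C$, integrated as
$P = \ln C$ for numerical stability (the population collapses by many
orders of magnitude between blooms; in log variables the collapse is a
mild linear decay instead of a stiff exponential race to zero):

$$\frac{dA}{dt} = I_0\,(1 + \gamma S(A)) - k(t)\,A\,e^P, \qquad
  \frac{dP}{dt} = k(t)\,A - M.$$

Weathering input $I_0$ (mol eq m$^{-3}$ yr$^{-1}$) supplies alkalinity;
calcifiers grow at rate $kA$ and bury CaCO$_3$, removing alkalinity at
rate $kAC$; sedimentation removes calcifiers at rate $M$ (yr$^{-1}$).
The change of variables is exact: trajectories in $(A, P)$ map
one-to-one onto the $(A, C)$ form, which the test suite asserts at
random states.

Two extensions drive everything the package studies:

* **Bounded positive weathering feedback.** The input is modulated by
  $1 + \gamma S(A)$ with
  $S(A) = \tfrac{2}{\pi}\arctan\!\big(\tfrac{\pi (A - A_0)}{2 z_0}\big)$:
  glacial (high-$A$) states receive up to $(1+\gamma) I_0$, interglacial
  states as little as $(1-\gamma) I_0$ — physically, exposed continental
  shelves during glacials enhance carbonate weathering. The arctan
  saturates because shelves are finite; $z_0$ sets where it saturates and
  fixes the midpoint slope $S'(A_0) = 1/z_0$. The bounds prevent runaway
  but do not themselves set the sawtooth shape or its period.
* **Periodic astronomical forcing** on the reaction rate,
  $k(t) = k_0 (1 + \alpha\cos(2\pi t/T))$, with $T = 40$ kyr (obliquity)
  by default and a two-component extension
  $k_0(1 + \alpha_1\cos(2\pi t/T_1) + \alpha_2\cos(2\pi t/T_2))$ for
  mixed obliquity + precession experiments. Phases are zero at $t = 0$
  and are never reset by feedback-schedule events.

Standard parameters (`alk_params()` defaults): $I_0 = 4\times10^{-6}$,
$k_0 = 0.05$, $M = 0.1$, $A_0 = 2.0$, $z_0 = 0.1$. Units: "mM eq" is
read as mol eq m$^{-3}$, which makes the equilibrium
$A^* = M/k_0 = 2.0$ coincide with $A_0$, so $S(A^*) = 0$ and the
equilibrium $(A^*, C^*) = (2, 4\times10^{-5})$ is independent of
$\gamma$. $P$ is the log of the numeric value of $C$ in these units.
Time is in years throughout.

## Local analysis

With $\alpha = 0$ the Jacobian at the equilibrium is

$$J = \begin{pmatrix} I_0\gamma/z_0 - k_0 C^* & -k_0 A^* C^* \\
                      k_0 & 0 \end{pmatrix},$$

so $\det J = k_0 M C^* = 2\times10^{-7}$ independently of $\gamma$, and
the trace crosses zero at the supercritical Hopf threshold
$\gamma_H = k_0 z_0 / M = 0.05$ (`hopf_threshold()`; the closed form is
verified against a numeric eigenvalue scan, and supercriticality —
a small stable limit cycle just above threshold — is verified by
simulation rather than by first-Lyapunov-coefficient algebra). Below
threshold, perturbations spiral in with period
$2\pi/\sqrt{\det J - (\mathrm{tr} J)^2/4} \approx 14.05$ kyr
(`linear_internal_period()`), essentially independent of $\gamma$.

Beyond the threshold the cycle grows into a relaxation sawtooth whose
**internal period** $T_0(\gamma)$ (the asymptotic periodicity at
$\alpha = 0$) rises roughly linearly: about 37 kyr at $\gamma = 0.06$,
55 kyr at $0.07$, 89 kyr at $0.09$, 120 kyr at $\approx 0.11$, 136 kyr
at $0.12$. Under forcing, the **average duration** $D(\gamma)$ locks
onto integer multiples of $T$ across finite $\gamma$ plateaus — the
Devil's staircase.

## Numerical choices

* **Solver.** `deSolve::lsoda` on a compiled C right-hand side, default
  `rtol = atol = 1e-12`. The contract that matters is not the solver
  identity but stability of the observables: halving the tolerances (or
  the output spacing) changes periodicity estimates by far less than
  0.1%, which the suite checks. Tolerance failures and early stops are
  errors, never silently loosened; non-finite states abort with the last
  valid time.
* **Breakpoints.** A step (or the kinks of a ramp) in $\gamma(t)$ is an
  integration restart point, so the discontinuity is never smoothed
  across a step. A ramp with $\Delta t = 0$ is exactly a step.
* **Output grid.** `resample_dt = 100` yr, two orders of magnitude below
  the shortest internal period. Peak *times* are refined by parabolic
  interpolation through the three samples around each extremum, giving
  periodicity noise of tens of years rather than the grid spacing; the
  sampled extremum *value* is kept as is, because value interpolation at
  the sawtooth kink would bias amplitudes. Offsets larger than half a
  grid step indicate a kink and are not applied.
* **Peak detection.** Alternating extrema of $A$; adjacent extremum
  pairs whose height difference is below `prominence_frac = 0.01` of the
  overall alkalinity range are pruned smallest-first. This passes an
  exact synthetic sawtooth, a sinusoid, and a 1%-ripple fixture, and
  leaves model-scale sawtooths untouched. Boundary-truncated cycles are
  dropped; each amplitude pairs a maximum with the following minimum.
* **Asymptotic periodicity.** Mean of the final 50 inter-maximum
  intervals. The reference protocol uses a 100-Myr horizon; the estimate
  is insensitive to the horizon once transients (10--30 Myr) have
  passed, so tests and the acceptance script use 20--150 Myr as each
  experiment requires, trading nothing but wall time. A convergence
  diagnostic flags trailing spreads above 5% of the mean — which also
  flags unlocked and high-order-locked states whose cycle lengths
  alternate (e.g. the 17:5 state at $\gamma = 0.12$, period pattern
  139.6/133.6/136.6/136.5/133.7 kyr averaging 136.0).
* **Initial conditions.** The model's long-run metrics do not depend on
  the start except through basin selection (below); the default is the
  equilibrium with $A$ perturbed by $+0.05$.

## Multistability and the staircase protocol

Near the upper end of each locking plateau, locked and unlocked
attractors coexist. At $\gamma = 0.12$, $\alpha = 0.003$ the exactly
locked 3:1 (120-kyr) orbit is stable but coexists with a 17:5 state at
136 kyr; near-equilibrium cold starts find the latter, while a system
whose feedback strength rises gradually through the plateau structure —
the RFL regime the model is about — arrives on the former. At
$\gamma = 0.09$ the 2:1 (80-kyr) lock coexists with an unlocked
quasiperiodic state near 87 kyr reached from some distant starts.

`staircase()` therefore seeds each grid point from the final state of
the previous one (`continue = TRUE`), emulating a slow upward ramp.
With a grid step of 0.005 and the 100-Myr reference horizon this sweep
passes through each plateau in turn and yields the 40/80/120-kyr
correspondence at $\gamma = 0.06/0.09/0.12$. Coarse grids combined with
short horizons can land mid-transition or skip a plateau onto the
coexisting unlocked state; the per-point convergence flags report this.
The unforced $T_0$, by contrast, is a property of the unique unforced
limit cycle and is continuation-independent.

## Orbits, Floquet analysis, and envelope fits

Locked orbits are fixed points of the $n$-period stroboscopic map
(forcing phase 0 as the section). `find_periodic_orbit()` applies
Newton iteration with the variational matrix
($d\Phi/dt = J(t)\Phi$, integrated alongside the base trajectory with
the forced, time-dependent $k(t)$) as the exact map Jacobian, so
unstable orbits — e.g. the 40-kyr orbit continued from $\gamma = 0.06$
to $0.09$ — are found as readily as stable ones. Every monodromy
computation carries the Liouville check
$\det\Phi = \exp\int \mathrm{tr} J\,dt$ (relative error $< 10^{-6}$).
The dominant Floquet multiplier $\mu$ gives the e-folding time
$\tau = nT/|\ln|\mu||$.

The same constants are measured independently from transient
periodicity series: the envelope (local maxima of
$|\text{periodicity} - \text{asymptote}|$ over cycle time) is fitted
log-linearly. Window rules: decay fits start where the deviation first
enters the locking basin (below half the inter-plateau gap, 20 kyr for
the standard forcing) and stop when the envelope reaches 10% of its
window-start value or the noise floor (30 yr, a few times the peak-time
refinement error); growth fits stop where the deviation exceeds the
half-gap, beyond which the escape is no longer governed by the
linearised orbit dynamics. Fits with under five envelope points, or a
slope contradicting the requested direction, are errors rather than
numbers.

For the standard forcing the two routes agree well within a factor 1.5:
decay onto the 40-kyr lock 7.95 Myr (envelope) vs 7.81 Myr (Floquet);
growth away from it after a step to $\gamma = 0.09$ 3.31 vs 3.24 Myr;
decay onto the 80-kyr lock 7.01 vs 7.13 Myr; growth after a step to
$0.12$ 6.60 vs 6.77 Myr.

## Delay metrics for feedback steps

The delayed response is quantified in `step_experiment()` two ways,
because "the periodicity has shifted" admits two readings:

* `transition_delay` — time from the step until 20 consecutive cycles
  have the *new* nearest forcing multiple (band-free: the periodicity
  now oscillates around the new plateau). This matches the visually
  evident jump (≈ 12 Myr for the 0.06 → 0.09 step).
* `settle_delay` — time until 20 consecutive cycles lie within 2% of
  the new locked periodicity $nT$ (≈ 28 Myr for the same step). This is
  dominated by the final exponential tail, so it moves by one decay
  time ($\sim$8 Myr) for every factor-of-e change of the band width —
  a tighter band definition lengthens it without any change in the
  dynamics.

Both are reported; censoring (no sustained post-step lock within the
horizon, as when the post-step state is high-order locked) is explicit.
Slow ramps (`ramp_experiment()`) add roughly the ramp duration to the
delay once $\Delta t$ reaches $10^7$ yr, and only very slow ramps
($\sim10^8$ yr) through two plateaus visit the intermediate multiple;
fast ramps skip it.

## Chaos indicator

`largest_lyapunov()` propagates a tangent vector with per-forcing-period
Benettin renormalisation, discarding the first 20% of the horizon, and
reports the slope of cumulative log-stretch versus time (the endpoint
average is biased by the strongly non-normal stretching bursts within
each sawtooth cycle; the regression averages them out). Spiral sinks
give the linear rate $(I_0\gamma/z_0 - k_0C^*)/2$; locked states give
small negative exponents consistent with their Floquet multipliers. At
these parameters clearly positive exponents ($\sim10^{-5}$ yr$^{-1}$)
appear around $\alpha \approx 0.02$ at $\gamma = 0.07$; at
$\alpha = 0.008$--$0.012$ the sweep instead shows robust locking and
high-order locked states with large cycle-to-cycle spread — the
staircase loses its clean structure without a positive exponent at the
reference feedback strengths.

## What the simulations do and do not show

All inputs are generated by the simulator itself; there is no external
data path. The model is a two-variable caricature: no carbonate
speciation (CO$_2$/DIC/pH), no ice dynamics, no stochastic forcing, no
quasi-periodic astronomical solution — so quantitative agreement with
proxy records is out of scope, and conclusions are about the dynamical
mechanism (RFL with a finite response time), not about calibrated Earth
history. Known limitations worth keeping in mind:

* Delay metrics beyond the jump time depend on the locking-band
  convention (see above), and basin selection at high $\gamma$ depends
  on the path taken through parameter space; both are surfaced in the
  outputs rather than hidden.
* The internal period at the top of the studied range is steeper than a
  strict linear extrapolation from mid-range would suggest
  ($T_0(0.12) \approx 136$ kyr, with $T_0 = 120$ kyr attained near
  $\gamma \approx 0.11$).
* Envelope fits need several e-folds of clean exponential regime; very
  short transients or states hovering at the noise floor are rejected
  rather than fitted.
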