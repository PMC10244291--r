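# alkcycle

Glacial–interglacial cycles can be described as sawtooth oscillations of
the ocean carbon cycle: continental weathering slowly supplies alkalinity
(mostly as Ca²⁺) to the ocean, and episodic blooms of calcifying plankton
bury it abruptly as CaCO₃, driving the reverse sawtooth seen in ice-core
CO₂. `alkcycle` simulates and analyses a two-variable calcifier–alkalinity
model of this oscillation, aimed at the dynamics behind the
Mid-Pleistocene Transition (MPT): the shift of the dominant glacial cycle
length from ~40 kyr to ~100 kyr about 1 Myr ago, interpreted here as
*ramping with frequency locking* (RFL) — a slow increase of the cycle's
internal period that makes the system hop between integer multiples of the
astronomical forcing period — with a *delayed* response of order millions
of years.

## The model

States: alkalinity `A` (mol eq m⁻³) and log calcifier biomass `P = ln C`:

    dA/dt = I0 (1 + γ S(A)) − k(t) A e^P
    dP/dt = k(t) A − M

with a bounded weathering feedback (finite continental shelves)

    S(A) = (2/π) arctan( π (A − A0) / (2 z0) )

and periodic (Milankovitch) forcing on the calcifier reaction rate

    k(t) = k0 (1 + α cos(2π t / T)).

Standard parameters: `I0 = 4e-6`, `k0 = 0.05`, `M = 0.1`, `A0 = 2.0`,
`z0 = 0.1`, `T = 40` kyr (obliquity); the equilibrium is
`A* = M/k0 = 2`, `C* = I0/M = 4e-5`.

The package provides, in plain R with a compiled right-hand side:

- **Local analysis** — equilibrium, analytic Jacobian, the supercritical
  Hopf threshold `γ_H = k0 z0 / M = 0.05` (closed form + eigenvalue
  scan), and the linearised internal period `2π/Im λ ≈ 14` kyr.
- **Integration** (`simulate_model`) — adaptive stiff-capable `lsoda`
  with schedule breakpoints honoured exactly and uniform resampling.
- **Cycle metrics** (`detect_cycles`, `asymptotic_periodicity`,
  `staircase`) — per-cycle periodicity/amplitude from peak detection,
  the internal period T0 (unforced) and average duration D (forced), and
  the Devil's staircase of locking plateaus.
- **Stability machinery** (`find_periodic_orbit`,
  `floquet_multipliers`, `envelope_time_constant`, `largest_lyapunov`)
  — Newton search for locked orbits on the stroboscopic map (stable or
  unstable), Floquet multipliers/e-folding times from the monodromy
  matrix, exponential envelope fits to transient periodicity series, and
  a Benettin Lyapunov exponent.
- **Experiments** (`step_experiment`, `ramp_experiment`,
  `forcing_comparison`) — feedback steps and ramps with delay metrics,
  and 20- vs 40-kyr (and mixed) forcing comparisons.
- A thin CLI (`inst/cli/alkcycle`) with `simulate`, `staircase`, `step`,
  `ramp`, `floquet`, `envelope` and `compare-forcing` subcommands.

## Worked example

```r
library(alkcycle)

p <- alk_params()                      # standard parameter set
hopf_threshold(p)                      # 0.05
linear_internal_period(p) / 1e3        # 14.04966  (kyr)

# self-sustained sawtooth beyond the bifurcation
asymptotic_periodicity(p, gamma = 0.07, alpha = 0, horizon = 2e7)
#> Asymptotic periodicity: 55369 yr (mean of final 50 cycles)
#>   trailing spread 0.27%; converged: TRUE; below Hopf: FALSE

# frequency locking under a 40-kyr forcing of amplitude 0.003
asymptotic_periodicity(p, gamma = 0.09, alpha = 0.003, horizon = 5e7)
#> Asymptotic periodicity: 80000 yr (mean of final 50 cycles)

# the delayed transition: step gamma 0.06 -> 0.09 halfway through
ex <- step_experiment(0.06, 0.09, alpha = 0.003, t_c = 5e7,
                      horizon = 1.5e8)
ex
#> Feedback step experiment: gamma 0.06 -> 0.09, alpha = 0.003
#>   pre-step lock: n = 1 (40 kyr);  post-step lock: n = 2 (80 kyr)
#>   transition delay (arrival at new multiple): 11.83 Myr
#>   settling delay (within 2% band): 27.77 Myr
#>   fit_pre_decay: tau = 7.95 Myr (r^2 = 0.994)
#>   fit_post_growth: tau = 3.31 Myr (r^2 = 0.997)
#>   fit_post_decay: tau = 7.14 Myr (r^2 = 0.993)
```

The step experiment shows the RFL signature: the cycle length stays
locked at 40 kyr long after the feedback strengthens, escapes the old
(now unstable) orbit with an exponentially growing periodicity envelope
(τ ≈ 3.3 Myr, cross-checked by the Floquet multiplier of the continued
orbit), and settles onto the 80-kyr lock roughly 10 Myr after the
parameter change — the cause of a periodicity shift can predate the
shift itself by millions of years.

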