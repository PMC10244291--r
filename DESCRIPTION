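Package: alkcycle
Title: Calcifier-Alkalinity Model of Glacial Cycles with Feedback and
    Frequency Locking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a two-variable ocean carbon-cycle model in which
    calcifier populations and ocean alkalinity generate sawtooth
    glacial-interglacial oscillations.  A bounded (arctan) positive
    weathering feedback of strength gamma lengthens the internal period
    of the cycles, and a periodic astronomical forcing on the calcifier
    growth rate entrains the cycle duration to integer multiples of the
    forcing period (frequency locking, Devil's staircase).  The package
    provides closed-form local analysis of the equilibrium (Jacobian,
    supercritical Hopf threshold, linearised internal period),
    stiff-capable long time integration with a compiled right-hand side,
    cycle metrics from peak detection (periodicity, amplitude, internal
    period T0 and average duration D), location of locked periodic orbits
    by Newton iteration on the stroboscopic map, Floquet multipliers and
    e-folding time constants from the variational (monodromy) system,
    exponential envelope fits to transient periodicity series, a largest
    Lyapunov exponent, and scripted feedback-step, feedback-ramp and
    forcing-comparison experiments that exhibit ramping with frequency
    locking and the delayed periodicity response.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
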