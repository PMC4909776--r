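Package: snnvent
Title: Bio-Inspired Spiking Neural Network Controller for Closed-Loop
    Ventilatory Assistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a closed-loop ventilatory control system built around a
    small spiking neural network inspired by the pontine-medullary respiratory
    network. The controller uses leaky integrate-and-fire neurons coupled by a
    two-branch kinetic (bound-receptor-fraction) synapse model, updated in
    discrete 0.5 ms steps with bit-faithful fixed-point arithmetic emulating a
    digital hardware datapath, alongside a floating-point oracle backend. The
    controller is coupled to a computational model of rat breathing (native
    sawtooth drive with injury attenuation, damped-spring lung mechanics,
    CO2 metabolism, and a breath-by-breath dynamical respiratory-rate
    mechanism). Includes reference open- and closed-loop network rosters,
    simplified spike-timing-dependent plasticity, sensor spike encoders,
    breath segmentation and respiratory metrics, connectivity-density
    accounting, and experiment harnesses for open-loop rhythm generation,
    bit-width accuracy sweeps, and closed-loop adaptation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
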