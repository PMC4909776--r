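# snnvent

A simulator for closed-loop ventilatory assistance driven by a bio-inspired
spiking neural network (SNN), coupled to a computational model of rat
breathing.

High cervical spinal cord injury can interrupt the drive from the brainstem
respiratory network to the diaphragm. Electrical diaphragmatic pacing can
restore ventilation, but open-loop stimulators impose a fixed pattern that
must be re-titrated by hand and cannot follow changing metabolic demand. A
closed-loop controller that senses lung volume and CO₂ and adapts its
stimulation on-line could track demand the way the intact respiratory
network does. This package is a software laboratory for one such
controller: a seven-to-ten-neuron SNN patterned on the pontine–medullary
respiratory circuit, simulated bit-faithfully to a fixed-point digital
datapath, breathing a model rat in real-time-equivalent 0.5 ms steps. It
is aimed at researchers in neuroprosthetics, computational neuroscience,
and neuromorphic hardware who want to study controller–plant dynamics
before committing to hardware or animals.

## The models in brief

**Neurons** are leaky integrate-and-fire units on the membrane displacement
from rest *v*:

    τ_m dv/dt = −v + Σᵢ Pᵢ rᵢ,      spike when v ≥ θ, then 1 refractory step

with the leak ratio τ_m/dt = 8 implemented as a right shift by 3.
**Synapses** follow a two-branch kinetic receptor model: the bound-receptor
fraction *r* obeys dr/dt = α(1−r) − βr during the transmitter pulse and
dr/dt = −βr after, discretized as r′ = B·r + A (rising, A = dt·α,
B = 1 − dt·(α+β)) and r′ = C·r (decay, C = 1 − dt·β). Pᵢ is the signed
*absolute synaptic strength potential* — synaptic strength and input
resistance folded into one number, and the quantity that plasticity
adapts. The fixed-point backend stores *r* as an unsigned 0.18 word and
A, B, C as 14-bit fractions with truncating multiplies, mirroring the
hardware datapath; a double-precision oracle backend runs the identical
schedule for comparison.

**The plant** combines a spaced-sawtooth native drive (attenuated by a
weighted injury factor *wi*), linear summation of native and stimulated
activation through a saturating recruitment map, damped-spring lung
mechanics with non-linear stiffness, continuous CO₂ production/clearance
mass balance, and a breath-by-breath dynamical respiratory-rate mechanism
that holds the CO₂ amount at its eupneic baseline. Calibration pins the
eupneic operating point at 56 breaths/min and 2 mL tidal volume.

**The closed loop**: lung volume and a slow CO₂ signal are rate-coded into
three tonic sensor neurons (Vol_spk, C1_spk, C2_spk); the follower
neuron's spike count over the trailing 20 steps, divided by 20, is the
stimulation ratio delivered to the muscle; simplified spike-timing-
dependent plasticity (a two-sided step kernel) trims the tagged connection
strengths every step.

See `vignettes/ventilatory-control.Rmd` for the full account, including
every calibrated value and the reasoning behind it.

## Worked example

```r
library(snnvent)

kinetic_table()              # the five synapse kinetics and their A, B, C
#>   set alpha beta  r_inf tau_r_ms      A      B      C
#> 1   1    58    5 0.9206   15.873 0.0290 0.9685 0.9975
#> ...
#> 5   5   900  100 0.9000    1.000 0.4500 0.5000 0.9500

# calibrate the rat model to its eupneic definition and let it breathe
plant <- calibrate_plant()
run <- run_plant(plant, wi = 1, mbc = 1, duration_s = 60)
breath_summary(run$records)
#> eupnea: RR 56.0 breaths/min, Vt 2.00 mL, minute ventilation 112 mL/min

# 80% injury, controller off: shallow and fast
inj <- run_plant(plant, wi = 0.8, mbc = 1, duration_s = 60)
normalized_rr(inj$records, run$records)
#> RR 63.5, Vt 1.72 mL -> normalized RR 1.13

# switch the closed-loop controller on at t = 15 s
cfg <- reference_config("closed_loop")
sc  <- scenario("assist", wi = 0.8, controller_mode = "closed_loop",
                controller_on_t = 15, duration_s = 70)
cl  <- run_scenario(sc, plant, cfg, plasticity = reference_plasticity(),
                    p_inj = reference_p_inj(0.8, 1))
#> controller on: RR 55.6, Vt 1.75 mL, normalized RR 0.99, CV 0.06%
```

The controller restores the breathing rate of the injured model to within
1% of the non-injured rate, with the rate variability far below the 4%
"constant rate" criterion. `run_scenario()` returns full per-step traces
(volume, CO₂, stimulation, activation, adapted strengths) plus per-breath
records; `write_trace_csv()` and `write_summary_json()` export them.

Other entry points: `run_network()` for the bare SNN with probes,
`open_loop_rr()` for the autonomous complete-injury rhythm,
`bit_accuracy_sweep()` for the datapath-width study,
`connectivity_stats()` for the density accounting, and
`calibrate_theta()` / `inst/scripts/calibrate_reference.R` for the sweeps
that fixed the shipped operating point. Network rosters serialize to YAML
(`inst/extdata/` holds the references).

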