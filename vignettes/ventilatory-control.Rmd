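---
title: "Models and methods: a spiking-network controller in closed loop with a rat breathing model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(snnvent)
```

`snnvent` simulates a closed-loop ventilatory assistance system: a small
spiking neural network (SNN) controller, modelled bit-faithfully to a
fixed-point digital datapath, coupled at a shared 0.5 ms step to a
computational model of rat breathing. This vignette documents the models,
the parameters that matter, the calibration procedures, and the design
choices made where the design was genuinely open.

## The controller

### Neuron and synapse models

Each controller neuron is a leaky integrate-and-fire (LIF) unit. The state
variable `v` is the displacement of the membrane voltage from rest, so rest
and the post-spike reset are both `v = 0` and no absolute voltages appear
anywhere. One discrete step is

```
v[t+1] = v[t] + (TPP[t] - v[t]) / 2^leak_shift
```

with `leak_shift = 3`: the leak ratio `tau_m/dt = 8` is implemented as an
arithmetic right shift by 3 instead of a multiplication, exactly as a
hardware datapath would. A neuron spikes when `v` crosses the threshold
`theta`, then spends one step refractory with `v` held at rest.

Connections use a two-branch kinetic receptor model. Each connection `i`
tracks the fraction of bound receptors `r_i in [0, 1]`. While the
presynaptic transmitter pulse is on,

```
r' = B r + A        (rising branch,  A = dt*alpha, B = 1 - dt*(alpha+beta))
```

and otherwise

```
r' = C r            (decay branch,   C = 1 - dt*beta)
```

the forward-Euler discretization of first-order binding kinetics
`dr/dt = alpha (1 - r) - beta r` (rising) and `dr/dt = -beta r` (decay).
The rising fixed point `A/(1-B)` equals the steady-state bound fraction
`r_inf = alpha/(alpha + beta)` and the rise time constant is
`1/(alpha + beta)`; `kinetic_table()` lists the five available
parameterizations, from slow (set 1, 15.9 ms rise, 200 ms decay) to fast
(set 5, 1 ms rise, 10 ms decay). Because the same `r` serves every event on
a connection, receptor saturation and summation of successive spikes come
for free and no event queue is needed.

A neuron's total postsynaptic potential is the signed weighted sum

```
TPP = sum_i P_i r_i
```

over its incoming connections. `P` is the absolute synaptic strength
potential: the synaptic strength and the input resistance folded into one
dimensionless controller-unit scalar, which is also the quantity that
plasticity adapts.

Each 0.5 ms step has two phases, mirroring the hardware sequencer: the
kinetic phase updates every `r` from the previous step's spike bits; the
spike phase computes every TPP from those fresh `r` values and then every
membrane/spike update. Nothing written within a phase is read in the same
phase, so the result is independent of update order (this is pinned by a
permutation test).

### Fixed-point datapath and the float oracle

The `"fixed"` backend reproduces a hardware datapath: `r` stored as an
unsigned 0.18 fixed-point word (configurable width for the accuracy study),
kinetic constants A, B, C as unsigned 14-bit fractions, products truncated
(floored) back to the storage format, and the membrane carried in a signed
format with the same fraction width plus 16 integer bits of headroom —
enough that the largest reference strength (|P| = 8000) at `r = 1` cannot
overflow an 8-input accumulation; sums saturate rather than wrap.
Truncation-toward-negative-infinity is used throughout (the natural
behaviour of dropping low bits in two's complement); rounding is available
but not the default. The `"float"` backend runs the identical update
schedule in double precision and serves as the independent oracle.

The two backends produce bit-identical spike rasters from a common start
until a threshold-grazing step, where a quantization difference of order
`2^-14` in a kinetic constant decides a spike one step earlier or later and
the trajectories phase-slip. For the reference network this first happens
after several hundred steps. After the slip the two backends remain
rhythm-equivalent (same period within ~1–2%, same burst ordering) but not
spike-identical; the tests therefore assert raster identity over the first
500 steps plus rhythm agreement within 2%, not indefinite identity. Note
that a bound such as a few least-significant bits on `|r_float - r_fixed|`
cannot hold over long horizons: quantizing A, B, C to 14 bits shifts the
rising-branch fixed point by up to `2^-14/(1-B)`, which for the slow
kinetic sets is about `2e-3` — two orders of magnitude above an 18-bit LSB.

### The reference rosters

The open-loop controller is a 7-neuron core: the primary inhibitory
oscillator I_dec/E_dec (early-inspiratory and post-inspiratory analogues),
the transition neurons IE (inspiration-to-expiration) and EI
(expiration-to-inspiration), tonic triggers I_decTON and EI_TON, and a
tonic drive neuron ON excited by an external line while the system is on.
The 16 connection strengths and kinetic-set assignments are the reference
parameterization built by `build_open_loop()`; the connectivity-grid labels
(Edec_TON, Edec_OUT, ...) are accepted as aliases, with Edec_TON identified
as the IE neuron since it is the sole trigger of E_dec. An optional
follower extension adds the premotor neuron I_inc, whose trailing-20-step
spike count divided by 20 is the stimulation ratio delivered to the muscle:
0 spikes = 0, 10 = 0.5, 20 = 1, resolution 1/20 at the refractory-limited
1 kHz ceiling.

The closed-loop roster (`build_closed_loop()`) adds three tonic sensor
neurons: Vol_spk (rate-coded lung volume), C1_spk (CO2 excess over
baseline) and C2_spk (CO2 deficit), with eight connections into the core
and — in the follower variant — a volume-gated drive onto I_inc. None of
these strengths are part of the printed reference grid; they are package
calibration values (see below).

`connectivity_stats()` reproduces the density accounting: open loop
C = 16 + 1 external trigger = 17, N = 7, maximum fan-in 3, giving 34.6%
all-to-all density (printed densities are truncated, not rounded, to one
decimal — 17/49 = 34.69% prints as 34.6); closed loop C = 24 internal,
N = 10, MaxC = 4, giving 24.0% all-to-all and 30.0% against the 8-input
hardware budget.

## The plant: a rat breathing model

Five components advance at the controller step (forward Euler throughout):

* **Native drive.** A spaced sawtooth of the breath phase: a linear ramp
  over the inspiratory fraction of the cycle (default 0.4), silence over
  the rest. The weighted injury factor `wi` scales it: 1 intact, 0.9/0.8/
  0.75 incomplete injury, 0 complete injury.
* **Activation.** Native and stimulated drive sum linearly and clip at 1,
  then pass through a monotone, mildly saturating recruitment map
  `(1 - exp(-k a))/(1 - exp(-k))` with `k = 0.15` (near-linear; a stand-in
  for a motor-unit recruitment model that is not reconstructible from its
  description). Mild saturation makes the injured tidal-volume loss
  slightly less than proportional to `wi`, which is the physiologically
  expected direction.
* **Mechanics.** A damped spring with non-linear stiffening,
  `m x'' = F_max rec(a) - c x' - k(x) x`, stiffness growing above a knee
  displacement. Lung volume is linearly proportional to the diaphragm
  displacement (`vol_gain` = 2 mL per unit). The spring is critically
  damped with a ~10 ms time constant so volume tracks the drive closely;
  this matters because the CO2 equilibrium is only well-conditioned if
  minute ventilation rises with rate (a sluggish spring makes Vt fall
  almost 1:1 as RR rises and the equilibrium degenerates).
* **Metabolism.** CO2 mass is produced at rate `mbc * MBC0` (the demand
  multiplier `mbc` is 1 at baseline, 1.11/1.17 for the +11%/+17%
  conditions; MBC0's absolute unit is arbitrary) and cleared continuously
  in proportion to expired flow times the current CO2 amount. Per-breath
  exhalation is the integral of this continuous form. Because a whole
  tidal volume leaves in one burst, per-breath clearance is exponential —
  `exp(-k_ex Vt)` retention — not linear, which the calibration must (and
  does) respect. A bookkeeping identity
  `co2 = co2(0) + produced - cleared` holds exactly at every step.
* **Dynamical respiratory rate.** The native pace is set at each breath
  boundary: a linear feed-forward `RR = a + b*mbc` (fitted by simulation,
  below) times a correction factor that integrates the relative error of
  the past breath's mean CO2 against baseline. At equilibrium the
  correction forces mean CO2 back to baseline, so the settled rate is
  wherever clearance balances production — this single mechanism yields
  both the demand response (RR tracks `mbc`) and the injury response
  (shallower breaths force a faster rate).

A low-pass-filtered CO2 copy (3 s time constant, an end-tidal-like
measure) feeds the chemoreceptor encoders, because the instantaneous CO2
amount swings by tens of percent within every breath and a spike code of
that swing would carry phase, not demand.

### Calibration

`calibrate_plant()` pins the eupneic operating point — 56 breaths/min and
2 mL tidal volume — with three deterministic stages: a secant iteration on
`F_max` to the target tidal volume at the fixed eupneic rate; a secant
iteration on the clearance gain `k_ex` so that the *simulated* steady
breath-mean CO2 equals baseline (the linearized value `production/flow` is
only the starting point, because of the exponential per-breath clearance);
and `calibrate_rr_regression()`, which finds the settled rate of the
CO2-holding mechanism at several demand multipliers and fits the
least-squares line through the points. Calibration is a fixed point of
itself (idempotence is tested). The fitted line puts the +11% and +17%
demand rates near 62 and 66 breaths/min, emerging from the CO2 balance
rather than being programmed in.

## Closing the loop

Per step: plant sensors are encoded into tonic spike trains (deterministic
clocked-divider rate code, so runs are bit-reproducible; a seeded Bernoulli
variant exists) → the network advances one step, with the on-line
plasticity applied to tagged connections → the follower window count
becomes the stimulation ratio → activation combines native and stimulated
drive → mechanics, metabolism, and the breath-boundary rate mechanism
close the loop. A controller-off run is step-identical to the bare plant,
and a closed-loop run with the drive forced to zero matches it exactly on
the plant side (both pinned by tests).

### How the closed loop assists

The closed-loop controller is triggered by Vol_spk activity. Two unprinted
design choices shape the reference behaviour, both fixed by the calibration
script and labelled as such:

* **Expiratory coordination.** Vol_spk excites IE strongly (1280, matching
  the scale of the ON drive it replaces) through a steep volume transfer
  (silent below 1.1 mL, saturating by 1.9 mL), so IE fires near each
  volume peak and launches the expiratory E_dec burst in phase with native
  exhalation. Triggering is self-regulating: a late previous burst leaves
  more residual inhibition and delays the next trigger less than a
  too-early one would.
* **Inspiratory boost.** The follower I_inc is driven by a volume-gated
  line from Vol_spk (tagged `P_inj`), with the EI route reduced to a
  sub-threshold bias. The stimulation therefore amplifies the native
  inspiratory effort in phase and cannot burst during the expiratory
  pause: I_inc needs the volume gate, is held down by E_dec during
  expiration (medium-speed kinetics: firm hold, full release in ~0.2 s),
  and its self-excitation is kept below the self-sustaining level so the
  burst cannot latch. The gated-boost strength is the per-scenario
  injury/demand parameter (`reference_p_inj()`): roughly 500 controller
  units at 90% native drive rising to ~1000 at 75%, chosen so the settled
  assisted rate sits near the non-injured rate.

With the boost restoring tidal volume, the plant's own CO2 mechanism
lowers the rate back toward baseline; the controller never imposes a
breathing rate. C1/C2 provide weak demand-side modulation (CO2 excess
shortens expiration and supports inspiration; deficit does the opposite);
they are deliberately weak because strong chemo drives destabilize the
core's phase structure.

### Plasticity

The simplified spike-timing-dependent rule is a two-sided step kernel: each
causal pre-then-post pairing within a 20-step window adds `a_plus`, each
anti-causal pairing subtracts `a_minus`, strengths clamp to a range, and
updates apply every computation step (during the kinetic phase slot).
There is no exponential decay inside the window — the minimal reading of
"simplified". Two rules ship (`reference_plasticity()`): the
rhythm-frequency node P_f (IE to E_dec, clamp 4000–6000 around the grid
value) and the amplitude node P_a (the follower self-excitation, clamp
40–160). Magnitudes are small: adaptation trims the operating point by a
few percent over tens of breaths rather than driving the behaviour. The
injury-level strengths P_inj are *not* learned on-line — they are a
per-scenario configuration table, and a meta-rule that would learn them is
out of scope.

## Calibrated reference values and how they were found

The spike threshold `theta` and the transmitter pulse length are not part
of the reference parameterization and had to be fixed by calibration
(`calibrate_theta()`, with the full sweep in
`inst/scripts/calibrate_reference.R`). Two findings from the sweep:

* With a one-step transmitter pulse, the core's relaxation rhythm cannot
  run slower than ~90–110 bursts/min for any threshold: the slow kinetic
  sets simply cannot accumulate enough inhibition per spike. A 24-step
  (12 ms) pulse lets receptor pools saturate during bursts, deepening the
  slow-inhibition swings; with `theta = 100` and the tuned frequency
  strength `P_f = 7000` the autonomous rhythm sits in the rat eupneic band
  (~65 breaths/min) with near-zero cycle-to-cycle variation.
* `P_f` is the designated frequency knob: on the reference sweep the
  autonomous rate falls monotonically as `P_f` grows (a stronger
  expiratory ignition builds deeper, longer-lasting inhibition). The
  closed loop runs at the grid value 5000, where the expiratory burst fits
  comfortably inside a native cycle even at +17% demand.

The bit-width study (`bit_accuracy_sweep()`) reruns the complete-injury
open loop across receptor-fraction widths {16, 18, 20, 32} and the `P_f`
sweep, reporting each width's maximum rate deviation from the 32-bit
reference. The deviation shrinks (16-bit is off by a couple of breaths per
minute; 18- and 20-bit by a few tenths), which is the rationale for the
18-bit reference format.

## Problem sizes and numerical choices

* Step: 0.5 ms everywhere (2 kHz); plant integration shares it. Spring
  eigenvalues (~1e2/s) are far inside the Euler stability region.
* Test-suite runs use 15–70 s of simulated time per scenario and the
  acceptance script 90 s, enough for ~15–70 breaths — an order of
  magnitude more than the trailing-10 windows the summary statistics need.
* Breath segmentation places boundaries at volume minima with hysteresis
  of 25% of the running amplitude (robust to 1% additive noise by test);
  a flat trace yields no breaths rather than an error.
* The CV of RR uses the population (divide-by-n) standard deviation over
  the trailing 10 breaths; "constant rate" is CV < 4%. Stabilization is
  the first breath whose CV is below threshold *and stays below to run
  end*, since transient CV peaks precede settling.
* All randomness (noise fixtures, the Bernoulli encoder variant) flows
  from the scenario seed; the core loop is deterministic and two runs with
  the same configuration are bit-identical.

## What the synthetic reference emulates — and does not

The eupneic reference waveform (`generate_fixtures()`) is the calibrated
plant driven by the intact sawtooth: 56 breaths/min, 2 mL, with optional
1% additive noise. It stands in for an experimental volume recording and
reproduces its summary statistics by construction, not its waveform
morphology: a real rat trace has breath-to-breath variability, baseline
drift, cardiogenic oscillations and a rounded expiratory profile that the
model's brisk passive recovery lacks. Tests passing against this generator
therefore validate the control loop and the statistics pipeline, not
waveform-level realism.

Known limitations, deliberately accepted: no O2 dynamics or blood-gas
transport; no electrode, pulse-train or charge model (the stimulation
ratio itself is the muscle drive); a single neuron per population (the
follower in particular would benefit from being a population — its
20-level drive resolution is coarse); the respiratory-rate CV of the model
is near zero at steady state, unlike a real animal's; and the
injury-support table `reference_p_inj()` is calibration, standing where a
meta-plasticity rule could eventually learn the mapping on-line.
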