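---
title: "Modelling an evolvable-OECT pattern classifier: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling an evolvable-OECT pattern classifier: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoect)
```

## The system being simulated

`evoect` is a phenomenological simulator of a neuromorphic binary classifier
built from *evolvable* organic electrochemical transistors (EOECTs). An
EOECT channel is formed in situ by electropolymerization: voltage pulses
above a threshold deposit conducting polymer and raise the channel
conductance, which is non-volatile and can only ever *increase*. Reading is
done below the threshold, where the device is an ohmic resistor, so weights
are interrogated non-destructively.

A signed synaptic weight cannot be stored in one increase-only conductance,
so each pixel of the classifier uses the **two-wire representation**: two
channels, EOECT+ with conductance $G_1$ and EOECT− with conductance $G_2$,
driven by a complementary voltage pair. The pixel current for input
$x \in \{+1, -1\}$ at read voltage $V$ is

$$ I_{\mathrm{pixel}} = x\, V (G_1 - G_2), $$

so the effective weight is $w = G_1 - G_2$, which can take either sign and
can be moved in either direction by growing one channel or the other. All
16 pixel outputs of the 4×4 array are wired to a single ammeter; the sign
of the summed current against the natural zero boundary classifies the
input pattern. The classifier output can further drive an organic
electrochemical neuron (OECN) that converts a positive current into a
cathodic spike train for nerve stimulation, and stays silent for negative
current.

## Device model

**Growth law.** The hardware characterization gives two anchors: a channel
first percolates on the *second* 1 s / 0.5 V write pulse at 0.4 µS, and
reaches 145 µS after 20 pulses. No functional form between them is
published, so the default law is the power law

$$ G(n) = G_2 \,(n-1)^{\gamma}, \qquad n \ge 2, \qquad G(n<2)=0 , $$

with $\gamma = \ln(145/0.4)/\ln 19 \approx 2.0014$ calibrated by
`calibrate_growth()` so that both anchors are reproduced exactly, and the
no-channel-after-one-pulse observation holds by construction. The law is
pluggable (`register_growth_law()`): the package also ships a `"linear"`
idealization $G(n) = g_{\mathrm{step}}\, n$ with equal increments and no
percolation threshold, which makes training algebra exactly solvable (the
dot-product and Hamming-linearity identities in the test suite use it as a
closed-form oracle).

**Writes and reads.** `write_pulse()` is a no-op below the
polymerization threshold `v_poly` (0.5 V); at or above it the pulse counter
advances and the conductance moves to the growth-law value, never
decreasing. `read_current()` returns $vG$ and refuses $|v| \ge$ `v_poly`,
because a supra-threshold read would write. The default read voltage is
50 mV.

**Gate modulation.** The channel is p-type in a hybrid
accumulation–depletion mode: −0.5 V gate enhances the drain current 12×,
+0.5 V suppresses it 3500×. Only the two factors are published, not the
shape, so `gate_transfer_ratio()` interpolates piecewise-exponentially,
$m(v_g) = e^{-\kappa v_g}$ with separate $\kappa$ on each side calibrated
from the two factors. This is the simplest monotone form through all three
anchor points ($m(0)=1$); the reference gate voltages are configuration
parameters because the published characterization does not print them
numerically.

**Retention drift.** Dry-state resistance creeps up by 1% in 9.5 h. The
model is linear in stored time relative to the last write,
$R(t) = R_0 (1 + r t)$ with $r = 0.01/9.5\ \mathrm{h^{-1}}$, accumulated
additively through the state's `age_h` so that successive drift calls
compose exactly (19 h gives 2.0%, not 2.01%). Wet-state and short-term
gate-induced dynamics are deliberately out of scope.

**Device-to-device variability.** Each device carries one fixed
multiplicative factor drawn at fabrication from a unit-mean lognormal with
coefficient of variation `cv_device` = 0.07, matching the 7% current spread
measured across a 32-transistor array at 5 pulses. A single per-device
factor (rather than per-pulse noise) keeps pulse sequences deterministic
per device while reproducing array-level spread; the Monte-Carlo test
recovers CV = 0.070 ± 0.002 at $n = 10^4$. Note that the *sample* CV of one
32-device array scatters around 7% with a standard error of roughly 0.9
percentage points — individual simulated arrays land anywhere between
about 5% and 9%.

## Array, reading and classification

`read_pixel()` implements the two reading modes: for $x=+1$, $+v$ on
EOECT+ and $-\alpha v$ on EOECT−; for $x=-1$ the voltages are swapped. The
asymmetry parameter $\epsilon$ models the doping imbalance under negative
applied voltage (a device then conducts with factor $1-\epsilon$), and
$\alpha$ is the compensating scale on the negative input;
`calibrate_negative_scale()` solves for the $\alpha$ that makes a pattern
and its inverse read with equal magnitude (numerically, by root-finding on
actual reads — with $\epsilon = 0$ it returns 1). Defaults are the ideal
$\epsilon = 0$, $\alpha = 1$.

`classify()` compares the summed current to the zero boundary with an
explicit dead band: exactly zero (or within `tol`) is reported as
`"indeterminate"` rather than silently assigned to a class. This matters
for fresh arrays, whose reads are exactly zero.

Random initialization draws an independent uniform pulse count (default
2–5) and variability factor for each of the 32 channels; the lower bound
must be ≥ 2 because a one-pulse channel has not percolated and would make
"random weight" degenerate.

## Training protocols

**One-shot hardware iteration.** One training iteration applies two
one-second writing passes to all pixels: the positive-class pattern is
written in the positive mode and the negative-class pattern in the
negative mode, each with background writes (so every pixel receives one
pulse per pass, on the device dictated by the pattern and polarity). On a
fresh array this separates the trained pair deterministically: under the
power law the devices pulsed by *both* passes reach two pulses and
percolate at 0.4 µS while singly-pulsed devices stay at zero, which yields
read currents of ±0.18 µA for the left-position letter pair. From a random
initialization, one iteration corrects the classification in ≈ 99.7% of
draws (measured over 2000 seeds); the remainder need a second iteration.
The package treats this as initialization-dependent and the end-to-end
harnesses simply iterate until the pair separates.

**Touchpad protocol.** Pressing a key emits 100 ms spikes at a 200 ms
period for the duration of the press, so `touchpad_session()` converts
press durations to `ceiling(duration / period)` pulses; the 5 V source
through the 82 kΩ/10 kΩ divider delivers ≈ 0.543 V per spike, above the
0.5 V threshold. Only traced keys are written (no background). With
per-key spike counts randomized over 1–7, both letters still classify
correctly in > 99% of trials — the robustness the touchpad demonstration
relies on.

**Quantized LMS.** `lms_step_quantized()` is the idealized
error-proportional counterpart (the hardware protocol only ever uses
fixed-pulse writes): the error $e$ against a ±1 µA target maps to desired
per-pixel weight changes $\Delta w_i = \eta\, e\, x_i / 16$, realized under
the two-wire rule — positive demands pulse EOECT+, negative EOECT− — with
the integer pulse count (up to a cap, default 5) whose predicted
growth-law increment best matches $|\Delta w_i|$, ties broken toward fewer
pulses (less irreversible material). The default $\eta = 20$ µS µA⁻¹ is
$1/v$ at the 50 mV read voltage, i.e. the step that would exactly cancel
the error if increments were continuous; smaller values leave demands
inside the quantizer dead zone and larger ones overshoot persistently,
both degrading convergence. Because single-pulse increments grow with the
pulse count under the power law, a still-misclassified pattern can reach a
state where *every* demand rounds to zero pulses; the step then escapes
the stall by writing one pulse to the targeted device with the smallest
realizable increment, which provably moves the output toward the target.
With these defaults the six-letter set (linearly separable) converges
within 10 epochs from most random initializations, typically in 2.

## Neuron stage

The OECN's published operating points are 1 Hz at 0.5 µA and 2.5 Hz at
5 µA injected, with no response to negative current. "Proportional" firing
through those two anchors is affine, not proportional, so
`spike_frequency()` interpolates affinely between them, clamps at
$f_{\max}$ above the range, extrapolates the same affine segment between 0
and $i_{\min}$ (floored at zero), and is hard-rectified at $i \le 0$. The
sub-threshold region below 0.5 µA is unreported in the characterization;
the extrapolate-and-floor choice is flagged as unvalidated.

Spike timing follows an integrate-then-fire convention: the phase advances
at the instantaneous frequency and the first spike occurs one full
inter-spike interval after current onset, so constant drive of frequency
$f$ over duration $T$ yields exactly $\lfloor Tf \rfloor$ regular spikes.
Each spike is rendered on a 1 kHz-sampled trace as a negative-going
Gaussian pulse with 0.47 V peak and 100 ms full width at half maximum
(10 samples across the half-width at the default rate); waveform
measurements interpolate the half-level crossings linearly so the FWHM is
recovered to well under one sample period.

The transimpedance bridge is a linear, sign-preserving gain;
`default_bridge_gain()` sizes it so the trained positive-class letter's
read current maps exactly to $i_{\max}$, driving the neuron at 2.5 Hz
while negative classifier outputs stay below threshold. The contraction
proxy is a sliding-window spike count — a deliberate signal-level stub for
an actuated muscle response, not a biomechanical model.

## Experiment runners and what the simulations do (and do not) show

`run_three_phase()` reproduces the three-phase protocol: random
initialization, then one-shot iterations on the left, right and rotated
letter pairs with a four-read characterization of all six fixtures after
each phase (error bars require `noise_rel > 0`; the default is
deterministic reads). The right-position and rotated fixtures are derived
geometrically — one-column translation and 90° clockwise rotation of the
left forms, whose key sets ({1,2,3,6,10,14} for T, {3,7,9,11,13,14,15} for
J) are the published ones. Two behaviours are initialization-dependent and
are reported rather than guaranteed: each just-trained pair classifies
correctly in ≈ 90% of seeds at the default single pulse per pass (always,
at 2 pulses), and the set of correctly classified fixtures grows
monotonically across training phases in ≈ 60% of seeds — training a new
placement can break an earlier, untargeted one. The published single-run
narrative shows the favourable outcome; the simulator makes the spread
visible.

`run_biointerface()` presents the trained pair alternately (five each,
2 s on at 20 s intervals by default), reads, bridges, spikes and evaluates
the contraction proxy per window; it refuses untrained arrays. Across 100
seeded replicates with default variability, every positive-letter window
spikes and no negative-letter window does — the separation is structural
(sign of the read current) rather than marginal.

The synthetic generator emulates fabrication spread (lognormal per-device
factors), random initialization, and optional read noise. It does **not**
emulate electrochemical kinetics, electrolyte or wiring parasitics,
wet-state drift, short-term gate transients, or any biology downstream of
the cuff electrode — passing tests demonstrate the *logic* of the
two-wire increase-only classifier and its actuation chain under realistic
parameter spread, not device physics or in-vivo outcomes.

## Numerical and reproducibility choices

* Units are fixed package-wide: µS, µA, V, s, h. Conversions happen only
  at I/O boundaries.
* Every stochastic entry point takes an explicit integer seed
  (`init_random()`, `grow_device_population()`, the runners) and records
  it in its output; replaying a logged seed reproduces currents bitwise.
* Constant-drive spike times are computed in closed form (no integration
  drift); time-varying drives integrate phase at the waveform sampling
  rate.
* JSON state and log files store numbers at 15 significant digits —
  round-trips are exact to ~10⁻¹⁵ relative, which the tests treat as
  lossless.
* Problem sizes in the shipped tests — 10⁴-device variability Monte
  Carlo, 10³ random-array read-oracle comparisons, 10³ touchpad trials,
  10² biointerface replicates — were chosen as the smallest runs whose
  sampling error is well inside the asserted tolerances.

## Known limitations

* The growth law between the two calibration anchors is an assumption;
  only the anchors and monotonicity are constrained by measurement.
* Gate modulation voltages (±0.5 V defaults) are configuration guesses at
  unpublished axis values; only the 12× / 3500× factors are calibrated.
* The LMS trainer is an idealization the hardware never ran; its stall
  escape and learning-rate default are algorithmic choices of this
  package.
* Unbounded conductance growth: no ceiling is modelled (none is
  reported); an optional clamp would be needed for long training runs.
* The contraction proxy is a windowed spike count in arbitrary units and
  carries no physiological content.
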