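# evoect

Simulation of a pattern classifier built from **evolvable organic
electrochemical transistors** (EOECTs), for researchers in neuromorphic
bioelectronics who want to study hardware-constrained learning and
classifier-to-nerve actuation protocols entirely in software.

An EOECT stores a synaptic weight as the conductance of a channel that is
electropolymerized in place: supra-threshold voltage pulses grow the
channel (the weight can only *increase*), while sub-threshold reads are
ohmic and non-destructive. A signed weight is represented by the two-wire
scheme — a pair of channels per pixel, read with complementary voltages —
so the pixel current for input `x ∈ {+1, −1}` is

```
I_pixel = x · V · (G1 − G2)
```

and the 16 pixel currents of a 4×4 array sum at a single output. The sign
of the total against the natural zero boundary classifies the pattern; a
Widrow–Hoff (LMS) style training step routes fixed write pulses to EOECT+
or EOECT− depending on the desired weight direction. Downstream, an
organic electrochemical neuron converts a positive classifier current into
a cathodic spike train (affine f–I curve, 1–2.5 Hz over 0.5–5 µA; 0.47 V /
100 ms spikes) and stays silent for negative current.

The package provides:

* `device_params()`, `write_pulse()`, `read_current()`,
  `gate_transfer_ratio()`, `apply_drift()` — a calibrated single-device
  model (pulse-driven power-law growth, 7% device-to-device spread, 1%
  resistance drift per 9.5 h dry storage);
* `synapse_array()`, `init_random()`, `read_pattern()`, `classify()`,
  `write_pattern()` — the 16-pixel two-wire array;
* `one_shot_iteration()`, `touchpad_session()`, `lms_step_quantized()` —
  hardware-faithful and idealized increase-only training;
* `spike_frequency()`, `simulate_spike_train()`, `contraction_proxy()` —
  the spiking output stage;
* `pattern_library()`, `run_three_phase()`, `run_biointerface()` —
  the six T/J letter fixtures and end-to-end experiment runners with
  replayable logs;
* a thin command-line interface (`inst/cli/evoect.R`) over the same
  functions.

See the methods vignette (`vignettes/evoect-methods.Rmd`) for the models,
their assumptions, and the design decisions.

## Worked example

Grow one ideal device to the top of its calibrated range, then train a
fresh array on the left-position letter pair and run the biointerface
sequence:

```r
library(evoect)

params <- device_params(cv_device = 0)          # ideal: no variability
st <- write_pulse(new_eoect(), params, v = 0.5, n = 20)
print(st)
#> EOECT state: g = 145 uS after 20 pulses (age 0 h, dev x1.000)
read_current(st, params, 0.05)                  # 50 mV read
#> [1] 7.25                                     # uA, ohmic: V x G

lib <- pattern_library()
print(lib$T_left)
#> T_left
#> ###.
#> .#..
#> .#..
#> .#..

arr <- synapse_array(params)
arr <- one_shot_iteration(arr, lib$T_left, lib$J_left, pulses = 1)
read_pattern(arr, lib$T_left)                   # +0.18 uA -> "positive"
read_pattern(arr, lib$J_left)                   # -0.18 uA -> "negative"

log <- run_biointerface(arr)                    # five T + five J, 2 s / 20 s
log[1:4, c("pattern", "i_classifier_uA", "class", "f_Hz", "n_spikes",
           "contraction_peak")]
#>   pattern i_classifier_uA    class f_Hz n_spikes contraction_peak
#> 1  T_left            0.18 positive  2.5        5                5
#> 2  J_left           -0.18 negative  0.0        0                0
#> 3  T_left            0.18 positive  2.5        5                5
#> 4  J_left           -0.18 negative  0.0        0                0
```

One training iteration separates the pair: the T read is +0.18 µA (each
doubly-pulsed device percolates at 0.4 µS; 9 pixels contribute at 50 mV),
the bridge maps it to the top of the neuron's range, and every 2 s T
window carries 5 spikes at 2.5 Hz while J windows stay silent — the
selective-actuation behaviour the hardware demonstrates on a nerve.

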