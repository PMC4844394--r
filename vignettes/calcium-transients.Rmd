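---
title: "Modeling elicitor-induced calcium transients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling elicitor-induced calcium transients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(elicitCa)
```

## The system being modeled

Suspension-cultured plant cells expressing cytosolic aequorin respond to
chitin-derived elicitors (here penta-*N*-acetylchitopentaose, Ch5) with
a single cytosolic Ca²⁺ transient: a lag of about 50 s after elicitor
addition, a rise to peak within one to two minutes, a slower decay, and
a return to baseline roughly seven minutes after elicitation. Peak
amplitude grows monotonically with dose over a very wide range (tens of
picomolar to hundreds of micromolar), and a second elicitation delivered
right after the first response has ended is strongly suppressed — a
refractory behavior whose severity depends on the first dose in an
over-proportional way.

`elicitCa` packages three things around this phenomenology: a
mechanistic ODE model of the store-release machinery, a calibration
layer mapping aequorin luminescence to Ca²⁺, and a synthetic-data
generator emulating the luminometer experiments so that every analysis
stage can be exercised and tested without measured data.

## The mechanistic model and its assumptions

The model is a two-variable Li–Rinzel-type reduction: cytosolic Ca²⁺
`Ci` and a slow inactivation gate `h`. Release from the internal store
(taken to be the vacuole, with store/cytosol volume ratio `c1 = 0.1`)
passes through an IPx-gated channel with open probability

$$O = \left(\frac{IPx}{IPx + d_{ipx}}\right)^3
      \left(\frac{Ci}{Ci + d_{act}}\right)^3 h^3,$$

so release is cooperatively activated by both the second messenger and
by Ca²⁺ itself (CICR) and shut off by the slow gate. The balance

$$\frac{dCi}{dt} = J_{chan} + J_{leak} - J_{pump} \,(+ J_{in}), \qquad
\frac{dh}{dt} = a\,(Ci + d_{inh})\left(\frac{d_{inh}}{Ci + d_{inh}} - h\right)$$

uses a Hill-type pump (`v_store`, `k_store`), a passive leak (`p_l`)
and the channel flux, all driven by the gradient factor
`c0 − (1 + c1)·Ci` that vanishes when cytosol and store equilibrate at
`Ci = c0/(1 + c1)` (6.82 µM at the defaults). Assumptions worth
spelling out:

* **No buffering.** Free and bound Ca²⁺ are not distinguished; the
  buffering scale factor of the original two-pool formulation is
  deliberately omitted.
* **`c0` is constant even when `j_in > 0`.** A constant influx should
  slowly grow the total pool; the equations keep `c0` fixed. The model
  is implemented exactly as written — simulations with and without
  `j_in` differ very little over a single transient, which is why the
  inconsistency is tolerable — and `include_jin = FALSE` gives the
  isolated-cell system.
* **The initial state is not a rest point.** The prescribed initial
  values `(ci0 = 2, h0 = 0.1562)` do not solve the steady-state
  equations; the state relaxes toward ~0.6 µM during the first minute
  of an unstimulated run. We keep the prescribed values as defaults
  (they are part of the parameterization) and expose
  `equilibrate = TRUE` for users who want to start from the true
  unstimulated steady state instead. For this reason peak amplitudes in
  the analysis layer are always measured relative to the immediately
  pre-stimulus level, not to `ci0`.
* **Receptor signaling is a black box.** The stimulus is a normalized
  IPx concentration, not a receptor model. The power-law transfer
  function `y(x) = A (x − x0)^p` (defaults `A = 8328.75`, `x0 = 0.06`,
  `p = 3.57`) summarizes everything between elicitor perception and
  store activation. Its printed coefficients are *not* numerically
  consistent with the matched amplitude/dose pairs used in the
  two-stimulus experiments (the formula gives `y(1) ≈ 6658`, while the
  pair tables match amplitude 1 to 480 µM). We do not attempt to
  reconcile them: both pathways are exposed
  (`transfer_forward()`/`transfer_inverse()` and
  `ch5_reference_pairs()` with `amplitude_for_dose()`), and the
  matched-pair lookup is the default for emulating experiments.

### Stimulus shape

The pulse form applied in the original simulations is shown but not
defined; we use rectangular pulses of given amplitude, onset and
duration, with an optional linear edge ramp (default 0 s) for users who
want a smooth stimulus. Pulses must not overlap.

### Numerical choices

Integration uses the adaptive Dormand–Prince pair (`deSolve` method
`"ode45"`) with `rtol = 1e-6`, `atol = 1e-9` and a 1 s step cap, and the
integrator is restarted at every pulse edge so no step straddles a
stimulus discontinuity. Halving both tolerances moves the reported peak
by far less than 0.1% (this is asserted in the test suite). Output is
returned on a regular grid (default 1 s) plus the edge times.
Trajectories are checked post hoc: `h` must stay in [0, 1] and `ci`
non-negative within solver tolerance, and `ci` exceeding the
zero-gradient concentration by more than 0.1% raises a blow-up warning.

```{r simulate}
stim <- stimulus_protocol(1, onset = 60, duration = 420)
traj <- simulate_transient(model_parameters(), stim, t_span = c(0, 600),
                           include_jin = FALSE)
max(traj$ci)
plot(traj$time, traj$ci, type = "l", xlab = "time (s)",
     ylab = "cytosolic Ca2+ (uM)")
```

The full-amplitude seven-minute stimulus yields a peak of about 5.6 µM —
within 10% of the ~6 µM scale of the measured maximal-dose response,
which is the tolerance we adopt for this check since the stimulus shape
is under-specified and the target is reported qualitatively.

### Refractory behavior

With raised channel permeability (`p_ipx = 200`) and no influx, a
half-amplitude second pulse applied one minute after the end of the
first (onsets 60 s and 540 s, both 420 s long) recovers only ~8% of the
first peak: the gate `h` collapses during the first transient and its
recovery time scale `1/(a·(Ci + d_inh))` is of the order of hours at
resting Ca²⁺. The inactivation dissociation constant `d_inh` is the
sensitive parameter: raising it both speeds recovery and raises the
gate's equilibrium, progressively releasing the second response.

```{r refractory}
vapply(c(0.02, 0.04, 0.08), function(dinh)
  model_refractory(model_parameters(p_ipx = 200, j_in = 0,
                                    d_inh = dinh))$ratio, numeric(1))
```

### The original oscillatory regime

The adapted parameter set is excitable — one transient per stimulus —
because `a` is three orders of magnitude slower than in the original
gonadotroph parameterization. With the classic constants re-expressed
in this package's two-variable form, sustained IPx produces repetitive
spiking, which is the regime the reduction was built for. This is a
demonstration, not an assertion the package depends on:

```{r oscillations}
p_osc <- model_parameters(p_ipx = 6, p_l = 0.11, v_store = 0.9,
                          k_store = 0.1, d_ipx = 0.13, d_act = 0.08234,
                          d_inh = 0.45, a = 0.2, c0 = 2, c1 = 0.185,
                          j_in = 0, ci0 = 0.3, h0 = 0.8)
sustained <- stimulus_protocol(0.5, onset = 0, duration = 600)
osc <- simulate_transient(p_osc, sustained, t_span = c(0, 600), dt = 0.5)
plot(osc$time, osc$ci, type = "l", xlab = "time (s)",
     ylab = "Ca2+ (uM)")
```

(Here the normalized stimulus amplitude 0.5 is read directly as an IPx
concentration of 0.5 µM; roughly 40 spikes appear over a 500 s window
once the initial transient has passed.)

## Aequorin calibration

The luminometer records counts `L_i` per sampling interval and, after a
terminal CaCl₂ discharge, the total light `L_tot`. The remaining
dischargeable light after sample `i` is
`L_max,i = L_tot − (L_1 + … + L_i)` — counts up to *and including* `i`,
matching the cumulative expression of the calibration protocol. The
ratiometric relation

$$Ca = \frac{r + r\,K_{TR} - 1}{K_R\,(1 - r)}, \qquad
r = (L_i/L_{max,i})^{1/n}$$

with `K_R = 7.23e6 M⁻¹`, `K_TR = 120`, `n = 2.99` is the standard
model-B form of the aequorin calibration literature. Because the source
protocol cites but does not print the formula, we verify it by an exact
round-trip property against the generator's forward model rather than
against a printed number. Edge cases are explicit: `r = 1/(1 + K_TR)`
maps to exactly zero Ca²⁺; smaller ratios would give negative
concentrations and are clamped to zero and flagged `below_detection`;
ratios at or approaching 1 mean the aequorin pool is exhausted and
raise a saturation error with the offending index. Counts are treated
as per-interval quantities with the interval length recorded in the
trace.

## The synthetic-data generator

The generator is a statistical stand-in for the cell-culture
experiments, *not* a mechanistic forward model: it exists so that the
calibration and analysis layers can be tested against known ground
truth. What it emulates, and how:

* **Transient shape.** Baseline plus a dead time (`lag = 50` s) and a
  normalized difference of exponentials
  `exp(−s/decay_tau) − exp(−s/rise_tau)`. Only shape *features* are on
  record (50 s lag, peak within 1–2 min, ~7 min total duration, rise
  faster than decay), not curve tables, so the time constants were
  chosen once to land inside those features: `rise_tau = 25` s,
  `decay_tau = 120` s put the kernel argmax at
  `ln(decay/rise)·rise·decay/(decay − rise) ≈ 49.5` s after response
  onset (≈100 s after elicitation) and the 10%-of-peak return at
  ≈404 s after elicitation.
* **Dose response.** A Hill curve in dose with a shallow exponent
  (`dose_hill = 0.25`, `dose_ec50 = 0.048` µM) so that responses grade
  visibly across the seven-decade 48 pM–480 µM range, normalized so the
  maximal dose of 480 µM yields exactly `peak_at_max_dose = 6` µM —
  the anchor shared with the mechanistic model.
* **Desensitization.** A second response is scaled by
  `1/(1 + 12·(dose1/480)^0.15)`. The exponent is deliberately smaller
  than `dose_hill`, which is what makes a weak first dose suppress the
  second response over-proportionally (the first and second
  dose-response curves do not sum to a constant); the strength makes
  the multiplier 0.077 after a maximal first dose, i.e. a nearly
  completely suppressed second response.
* **Read-out noise.** The Ca²⁺ truth is pushed through the exact
  inverse of the calibration (per-sample expected counts
  `pool·f/(1 + f)` with `f = r^n`, sequentially depleting the aequorin
  pool of 10⁶ counts) and then Poisson-sampled. `l_tot` equals the
  initial pool — the terminal discharge emits the remainder. A
  Gaussian-on-Ca mode and a fully noise-free mode exist for tests.
  Exactly-zero Ca²⁺ is treated as below the detection floor and emits
  no counts, so zero round-trips to zero through the clamped inverse.
* **Replication and determinism.** Three replicates per condition (the
  recorded design), each with a sub-seed drawn deterministically from
  the experiment seed; identical (design, config, seed) reproduce the
  experiment byte-for-byte.

What the generator does *not* emulate: replicate-to-replicate
variability magnitudes (the recorded error bars are graphical only, so
generator variance is configurable but not calibrated), drift or
artifacts in the luminometer baseline, cell-to-cell heterogeneity, and
any mechanistic aequorin kinetics. Passing tests on synthetic data
therefore show that the pipeline recovers what the generator encodes —
they do not validate the biology of real traces.

```{r generator}
cfg <- synthetic_config(noise_model = "none")
tr <- make_transient(480, config = cfg)
extract_features(tr, cfg$onset)
```

## Feature extraction and analysis stages

The descriptive features are defined operationally (the onset-detection
rule behind the reported lag is not on record, so ours is declared and
configurable): baseline is the median of a 60 s pre-elicitation window;
the onset is the first crossing of
`baseline + max(5% of peak-above-baseline, 3×MAD of the baseline)`;
duration runs from elicitation to the first post-peak return below
`baseline + 10% of peak-above-baseline`. On noise-free traces the
extracted lag/peak/duration match the generator's analytic truth to
within one sample / 0.1%, and perturbing the thresholds by ±20% moves
the lag by at most two samples.

`dose_response()` calibrates every trace, extracts peaks and aggregates
mean ± sd per dose (descriptive statistics only — no inferential tests,
matching the design of the emulated experiments). For two-stimulus
designs, `refractory_analysis()` measures the second peak against the
immediately pre-second-stimulus level, since the first transient has
almost but not exactly returned to baseline at the second onset;
measuring against the global baseline would contaminate the second
amplitude with residual first-response decay. The first peak uses the
immediately pre-first-stimulus level for the same reason (the model's
initial state is not a rest point). The inter-stimulus interval
defaults to 420 s and is configurable.

```{r doseresponse}
exp <- generate_experiment(design_dose_series(), synthetic_config(seed = 1))
dose_response(exp)
refractory_analysis(generate_experiment(design_double_elicitation(),
                                        synthetic_config(seed = 1)))
```

## Problem sizes and known limitations

All simulations in the examples and tests run on 1 s output grids over
10–20 minute spans (600–1200 points) — the scale of the emulated
luminometer recordings — and complete in fractions of a second each.

Limitations to keep in mind: the model is spatially homogeneous (no
compartmental or PDE structure, no nuclear/cytosolic deconvolution of
the aequorin signal); no other ion fluxes (K⁺, H⁺, Cl⁻) are modeled;
the transfer function is elicitor-specific and the shipped calibration
applies to Ch5 only; `h0 = 0.1562` is taken as prescribed although it
is not the resting gate value for `ci0 = 2` (its provenance is not on
record); and parameter values are effective, in arbitrary units
anchored to seconds and micromolar — they were found by optimization
against recorded transients, not measured in vivo.
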