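# elicitCa

Simulation and analysis of elicitor-induced cytosolic Ca²⁺ transients in
plant cell cultures.

When a plant cell recognizes a pathogen-associated molecular pattern
(PAMP) such as the chitin fragment penta-*N*-acetylchitopentaose (Ch5),
one of the earliest defense events is a transient rise of cytosolic Ca²⁺
released from internal stores. `elicitCa` models this transient with an
adapted two-variable Li–Rinzel system, calibrates aequorin luminescence
recordings into Ca²⁺ concentrations, and provides the analysis stages
(feature extraction, dose-response, two-stimulus refractory analysis)
needed to compare model and measurement — exercised end-to-end on a
seeded synthetic-data generator that emulates the luminometer
experiments, so the whole pipeline is testable without any download.

## The model

Cytosolic Ca²⁺ (`Ci`, µM) exchanges with an internal store (the vacuole,
volume ratio `c1` relative to the cytosol, so the store content is
`CER = (C0 − Ci)/c1`) through three fluxes plus an optional constant
plasma-membrane influx:

```
dCi/dt = J_chan + J_leak − J_pump (+ J_in)
J_chan = p_IPx · O(IPx, Ci, h) · (C0 − (1 + c1)·Ci)
J_leak = p_L · (C0 − (1 + c1)·Ci)
J_pump = v_store · Ci² / (k_store² + Ci²)
O      = (IPx/(IPx + d_IPx))³ · (Ci/(Ci + d_act))³ · h³
dh/dt  = a · (Ci + d_inh) · (d_inh/(Ci + d_inh) − h)
```

`O` is the open probability of the IPx-gated release channel —
cooperative IPx binding, Ca²⁺ activation (calcium-induced calcium
release) and slow Ca²⁺-dependent inactivation through the gate `h`. The
stimulus is a normalized IPx pulse train (amplitude in [0, 1]); a fitted
power-law transfer function `y(x) = 8328.75·(x − 0.06)^3.57` stands in
for the unmodeled receptor-to-store signaling and links normalized
amplitude to Ch5 concentration.

Aequorin luminescence is calibrated ratiometrically: with the remaining
dischargeable light `L_max,i = L_tot − Σ_{j≤i} L_j` and
`r = (L_i/L_max,i)^(1/n)`, the Ca²⁺ concentration is
`Ca = (r + r·K_TR − 1) / (K_R·(1 − r))` with K_R = 7.23×10⁶ M⁻¹,
K_TR = 120, n = 2.99.

## Worked example

```r
library(elicitCa)

# full-amplitude 7-minute elicitation of an isolated cell
stim <- stimulus_protocol(1, onset = 60, duration = 420)
traj <- simulate_transient(model_parameters(), stim,
                           t_span = c(0, 600), include_jin = FALSE)
max(traj$ci)
#> [1] 5.571797

# synthetic maximal-dose trace and its descriptive features
cfg <- synthetic_config(noise_model = "none")
trace <- make_transient(480, config = cfg)
extract_features(trace, cfg$onset)
#> Response: baseline 0.1 uM, lag 51 s, time-to-peak 100 s, peak 6 uM, duration 404 s

# two-pulse refractory simulation (raised permeability, isolated cell)
model_refractory()$ratio
#> [1] 0.08233574

# dose-response over the emulated 48 pM - 480 uM Ch5 series
exp <- generate_experiment(design_dose_series(), synthetic_config(seed = 1))
dose_response(exp)
#>      dose mean_peak     sd_peak n
#> 1 4.8e-05  1.037805 0.004778361 3
#> 2 4.8e-03  2.433072 0.010867117 3
#> 3 4.8e-01  4.251525 0.006737597 3
#> 4 4.8e+00  5.041857 0.006979130 3
#> 5 4.8e+01  5.643691 0.015076712 3
#> 6 2.4e+02  5.927295 0.014629206 3
#> 7 4.8e+02  6.063876 0.016327084 3
```

The simulated peak of ~5.6 µM sits within 10% of the ~6 µM scale of the
measured maximal-dose response. The refractory ratio of 0.082 says a
half-amplitude second stimulus applied right after a full-amplitude
first one recovers only ~8% of the first peak — the refractory behavior
carried by the slowly recovering inactivation gate. The dose-response
table shows peak Ca²⁺ (µM above baseline, mean ± sd over 3 replicates)
rising monotonically over seven decades of elicitor concentration.

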