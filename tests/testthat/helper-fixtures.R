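# Shared fixtures: a single 7-minute full-amplitude elicitation and the
# default parameter set, reused across test files.
default_stim <- function() stimulus_protocol(1, onset = 60, duration = 420)

# Noise-free generator configuration (Poisson noise off) for exactness checks.
noisefree_config <- function(...) synthetic_config(noise_model = "none", ...)
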