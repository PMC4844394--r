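#' Configuration of the synthetic experiment generator
#'
#' The generator emulates luminometer recordings of elicitor-induced
#' cytosolic Ca2+ transients in aequorin-expressing cell suspensions: a
#' dead time (`lag`) between elicitation and response onset, an asymmetric
#' transient (rise faster than decay) built from a difference of
#' exponentials, a saturating dose-amplitude curve anchored so the
#' maximal dose (480 uM) peaks at `peak_at_max_dose`, dose-dependent
#' desensitization of a second response, and conversion to counting-noise
#' luminescence through the aequorin forward model with pool depletion.
#'
#' Defaults reproduce the descriptive features of the emulated
#' experiments: 50 s onset lag, time-to-peak within 2 min, return to
#' baseline about 7 min after elicitation, 6 uM peak at the maximal dose,
#' 3 replicates per condition and 1 s sampling.
#'
#' @param seed integer seed controlling all generator randomness.
#' @param baseline_ca resting cytosolic Ca2+ (uM).
#' @param lag dead time between elicitation and response onset (s).
#' @param rise_tau,decay_tau time constants of the double-exponential
#'   kernel (s); `rise_tau < decay_tau` gives the observed asymmetry.
#' @param peak_at_max_dose peak amplitude above baseline at the maximal
#'   dose of 480 uM (uM).
#' @param dose_ec50 half-maximal dose of the amplitude curve (uM).
#' @param dose_hill Hill exponent of the amplitude curve; shallow values
#'   span the wide (48 pM - 480 uM) dose range.
#' @param desens_strength,desens_power parameters of the desensitization
#'   multiplier `1 / (1 + desens_strength * (dose1/480)^desens_power)`;
#'   `desens_power < dose_hill` makes a weak first dose suppress the
#'   second response over-proportionally.
#' @param aequorin_pool total dischargeable light (counts).
#' @param noise_model `"poisson_counts"` (counting noise on luminescence),
#'   `"gaussian_ca"` (additive noise on the Ca2+ trace) or `"none"`.
#' @param ca_noise_sd standard deviation of the Gaussian Ca2+ noise (uM).
#' @param replicates replicates per design row.
#' @param dt sampling interval (s).
#' @param onset elicitation time within each recording (s); the preceding
#'   samples are the monitored baseline.
#' @return An object of class `synth_config`.
#' @export
synthetic_config <- function(seed = 1L, baseline_ca = 0.1, lag = 50,
                             rise_tau = 25, decay_tau = 120,
                             peak_at_max_dose = 6, dose_ec50 = 0.048,
                             dose_hill = 0.25, desens_strength = 12,
                             desens_power = 0.15, aequorin_pool = 1e6,
                             noise_model = c("poisson_counts", "gaussian_ca",
                                             "none"),
                             ca_noise_sd = 0.05, replicates = 3L, dt = 1,
                             onset = 60) {
  noise_model <- match.arg(noise_model)
  stopifnot(lag >= 0, rise_tau > 0, decay_tau > 0, replicates >= 1,
            desens_strength >= 0, desens_power > 0, baseline_ca >= 0,
            peak_at_max_dose > 0, dose_ec50 > 0, dose_hill > 0,
            aequorin_pool > 0, dt > 0, onset >= 0, ca_noise_sd >= 0)
  if (rise_tau >= decay_tau)
    stop("rise_tau must be < decay_tau (rise faster than decay)")
  structure(list(seed = as.integer(seed), baseline_ca = baseline_ca,
                 lag = lag, rise_tau = rise_tau, decay_tau = decay_tau,
                 peak_at_max_dose = peak_at_max_dose, dose_ec50 = dose_ec50,
                 dose_hill = dose_hill, desens_strength = desens_strength,
                 desens_power = desens_power, aequorin_pool = aequorin_pool,
                 noise_model = noise_model, ca_noise_sd = ca_noise_sd,
                 replicates = as.integer(replicates), dt = dt,
                 onset = onset, max_dose = 480),
            class = "synth_config")
}

#' Peak Ca2+ amplitude for an elicitor dose
#'
#' Saturating Hill curve in dose, normalized so the maximal dose of
#' 480 uM yields exactly `peak_at_max_dose`:
#' `amp(d) = a_max * d^hill / (d^hill + ec50^hill)` with
#' `a_max = peak_at_max_dose / hill_fraction(480)`.
#'
#' @param dose elicitor concentration(s) in uM, >= 0.
#' @param config a [synthetic_config()].
#' @return Peak amplitude(s) above baseline (uM).
#' @export
dose_amplitude <- function(dose, config = synthetic_config()) {
  if (any(!is.finite(dose)) || any(dose < 0)) stop("dose must be >= 0")
  hill <- function(d) ifelse(d == 0, 0,
                             d^config$dose_hill /
                               (d^config$dose_hill + config$dose_ec50^config$dose_hill))
  config$peak_at_max_dose / hill(config$max_dose) * hill(dose)
}

#' Desensitization multiplier after a first elicitation
#'
#' The factor by which a first dose scales the amplitude of a second
#' response: `1 / (1 + desens_strength * (dose1/480)^desens_power)`.
#' Equals 1 at zero first dose, decreases monotonically, and is below 0.1
#' after a maximal (480 uM) first dose, so a strong first elicitation
#' nearly completely suppresses the second response. Because the power is
#' smaller than the dose-amplitude Hill exponent, weak first doses have an
#' over-proportional suppressive effect.
#'
#' @param dose1 first elicitor dose(s) in uM, >= 0.
#' @param config a [synthetic_config()].
#' @return Multiplier(s) in `[0, 1]`.
#' @export
desensitize <- function(dose1, config = synthetic_config()) {
  if (any(!is.finite(dose1)) || any(dose1 < 0)) stop("dose1 must be >= 0")
  1 / (1 + config$desens_strength *
         (dose1 / config$max_dose)^config$desens_power)
}

# Normalized double-exponential kernel: 0 at s = 0, unit peak at
# transient_peak_time(), decaying with decay_tau.
transient_kernel <- function(s, rise_tau, decay_tau) {
  ts <- transient_peak_time(rise_tau, decay_tau)
  norm <- exp(-ts / decay_tau) - exp(-ts / rise_tau)
  out <- numeric(length(s))
  pos <- s > 0
  out[pos] <- (exp(-s[pos] / decay_tau) - exp(-s[pos] / rise_tau)) / norm
  out
}

#' Peak time of the double-exponential transient kernel
#'
#' Closed-form argmax of `exp(-s/decay) - exp(-s/rise)`:
#' `s* = log(decay/rise) * rise * decay / (decay - rise)`.
#'
#' @param rise_tau,decay_tau kernel time constants (s).
#' @return Time from response onset to the kernel peak (s).
#' @export
transient_peak_time <- function(rise_tau, decay_tau) {
  stopifnot(rise_tau > 0, decay_tau > rise_tau)
  log(decay_tau / rise_tau) * rise_tau * decay_tau / (decay_tau - rise_tau)
}

#' Generate a synthetic elicitor-induced Ca2+ transient
#'
#' Baseline plus a dose-scaled double-exponential transient starting
#' `lag` seconds after the elicitation at `onset`. Deterministic unless
#' `noise = TRUE` and the configured noise model is `"gaussian_ca"`, in
#' which case Gaussian noise is added from the current RNG state (the
#' result is clamped at 0).
#'
#' @param dose elicitor dose (uM).
#' @param onset elicitation time (s); defaults to `config$onset`.
#' @param config a [synthetic_config()].
#' @param t_end trace end time (s).
#' @param noise logical; apply the configured Ca-level noise.
#' @param amp_scale extra multiplier on the transient amplitude (used for
#'   desensitized second responses).
#' @return A [ca_trace()].
#' @export
make_transient <- function(dose, onset = config$onset,
                           config = synthetic_config(), t_end = onset + 600,
                           noise = FALSE, amp_scale = 1) {
  times <- seq(0, t_end, by = config$dt)
  amp <- dose_amplitude(dose, config) * amp_scale
  ca <- config$baseline_ca +
    amp * transient_kernel(times - onset - config$lag,
                           config$rise_tau, config$decay_tau)
  if (noise && config$noise_model == "gaussian_ca")
    ca <- pmax(ca + stats::rnorm(length(ca), 0, config$ca_noise_sd), 0)
  ca_trace(times = times, ca = ca)
}

#' Convert a Ca2+ trace to a synthetic luminescence trace
#'
#' Exact forward model of the ratiometric calibration with sequential
#' aequorin-pool depletion: for each sample the luminescence fraction
#' `f_i = r_i^n` (with `r_i = (1 + k_r*Ca) / (1 + k_tr + k_r*Ca)`)
#' determines the expected counts `pool_i * f_i / (1 + f_i)`, which are
#' then drawn from a Poisson distribution when `noise_model` is
#' `"poisson_counts"` (otherwise kept exact), and removed from the pool.
#' `l_tot` equals the initial pool: the terminal discharge emits the
#' remainder. Noise-free output round-trips through
#' [luminescence_to_ca()].
#'
#' @param ca a [ca_trace()] in uM.
#' @param consts a [calibration_constants()] object.
#' @param config a [synthetic_config()]; supplies the pool and noise model.
#' @param noise logical; apply Poisson counting noise (uses the current
#'   RNG state).
#' @return A [luminescence_trace()]; if the pool is exhausted before the
#'   trace ends, the trace carries attribute `saturated = TRUE`.
#' @export
ca_to_luminescence <- function(ca, consts = calibration_constants(),
                               config = synthetic_config(),
                               noise = config$noise_model == "poisson_counts") {
  stopifnot(inherits(ca, "ca_trace"))
  ca_M <- ca$ca * 1e-6
  r <- (1 + consts$k_r * ca_M) / (1 + consts$k_tr + consts$k_r * ca_M)
  f <- r^consts$n
  f[ca_M == 0] <- 0  # below the detection floor: no counts, so zero Ca round-trips
  n <- length(f)
  counts <- numeric(n)
  pool <- config$aequorin_pool
  saturated <- FALSE
  for (i in seq_len(n)) {
    mu <- pool * f[i] / (1 + f[i])
    li <- if (noise) min(stats::rpois(1L, mu), pool) else mu
    counts[i] <- li
    pool <- pool - li
    if (pool <= 0) { saturated <- TRUE; pool <- 0 }
  }
  out <- luminescence_trace(times = ca$times, counts = counts,
                            l_tot = config$aequorin_pool, dt = config$dt)
  if (saturated) attr(out, "saturated") <- TRUE
  out
}

#' Experiment designs emulating the dose-response and refractory assays
#'
#' `design_dose_series()` is the single-elicitation dose series spanning
#' 48 pM to 480 uM; `design_double_elicitation()` is the two-stimulus
#' design with a variable first dose and a fixed 240 uM second dose
#' applied after an inter-stimulus interval of about 7 min.
#'
#' @param doses first-elicitation doses (uM).
#' @param dose2 fixed second dose (uM).
#' @param interval inter-stimulus interval (s).
#' @return A data.frame with columns `dose1`, `dose2` (NA for
#'   single-elicitation rows) and `interval`.
#' @export
design_dose_series <- function(doses = c(4.8e-5, 4.8e-3, 0.48, 4.8, 48,
                                         240, 480)) {
  data.frame(dose1 = doses, dose2 = rep(NA_real_, length(doses)),
             interval = rep(NA_real_, length(doses)))
}

#' @rdname design_dose_series
#' @export
design_double_elicitation <- function(doses = c(4.8e-5, 4.8, 480),
                                      dose2 = 240, interval = 420) {
  data.frame(dose1 = doses, dose2 = dose2, interval = interval)
}

#' Generate a full synthetic experiment
#'
#' For every design row, generates `config$replicates` luminescence traces
#' with independent sub-seeds plus the noise-free ground truth: the exact
#' Ca2+ trace and its analytic features (lag, time-to-peak, peak and
#' duration derived from the kernel). Second transients are scaled by
#' [desensitize()] applied to the first dose. Identical
#' `(design, config)` yield identical experiments.
#'
#' @param design a data.frame as returned by [design_dose_series()] or
#'   [design_double_elicitation()].
#' @param config a [synthetic_config()].
#' @param consts a [calibration_constants()] object.
#' @return An object of class `ca_experiment`: a list with elements
#'   `design`, `config`, `traces` (list indexed `[[row]][[replicate]]` of
#'   [luminescence_trace()]s), `truth` (per-row noise-free [ca_trace()]
#'   and feature list) and `seeds` (sub-seed matrix).
#' @export
generate_experiment <- function(design, config = synthetic_config(),
                                consts = calibration_constants()) {
  stopifnot(is.data.frame(design),
            all(c("dose1", "dose2", "interval") %in% names(design)))
  nrows <- nrow(design)
  out <- list(design = design, config = config,
              traces = vector("list", nrows), truth = vector("list", nrows))
  if (nrows == 0L) {
    out$seeds <- matrix(integer(0), 0, 0)
    return(structure(out, class = "ca_experiment"))
  }
  double <- !is.na(design$dose2)
  if (any(double & (is.na(design$interval) | design$interval <= 0)))
    stop("double-elicitation rows need a positive inter-stimulus interval")
  set.seed(config$seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             nrows * config$replicates),
                  nrow = nrows)
  for (i in seq_len(nrows)) {
    d1 <- design$dose1[i]
    if (double[i]) {
      onset2 <- config$onset + design$interval[i]
      t_end <- onset2 + 600
      tr1 <- make_transient(d1, config$onset, config, t_end)
      tr2 <- make_transient(design$dose2[i], onset2, config, t_end,
                            amp_scale = desensitize(d1, config))
      truth_ca <- ca_trace(tr1$times,
                           tr1$ca + (tr2$ca - config$baseline_ca))
    } else {
      t_end <- config$onset + 600
      truth_ca <- make_transient(d1, config$onset, config, t_end)
    }
    out$truth[[i]] <- list(ca = truth_ca,
                           features = kernel_truth_features(d1, config),
                           features2 = if (double[i])
                             kernel_truth_features(design$dose2[i], config,
                               amp_scale = desensitize(d1, config))
                           else NULL)
    out$traces[[i]] <- lapply(seq_len(config$replicates), function(k) {
      set.seed(seeds[i, k])
      ca_k <- truth_ca
      if (config$noise_model == "gaussian_ca")
        ca_k <- ca_trace(truth_ca$times,
                         pmax(truth_ca$ca +
                                stats::rnorm(length(truth_ca$ca), 0,
                                             config$ca_noise_sd), 0))
      ca_to_luminescence(ca_k, consts, config,
                         noise = config$noise_model == "poisson_counts")
    })
  }
  out$seeds <- seeds
  structure(out, class = "ca_experiment")
}

# Analytic ground-truth features of a generated transient, relative to the
# elicitation time: lag is the configured dead time, the peak sits at the
# kernel argmax, and the duration runs until the kernel decays back below
# 10% of the peak (bisection on the decay flank).
kernel_truth_features <- function(dose, config, amp_scale = 1,
                                  return_frac = 0.10) {
  amp <- dose_amplitude(dose, config) * amp_scale
  ts <- transient_peak_time(config$rise_tau, config$decay_tau)
  if (amp <= 0)
    return(list(baseline = config$baseline_ca, lag = NA_real_,
                time_to_peak = NA_real_, peak = 0, duration = NA_real_))
  f <- function(s) transient_kernel(s, config$rise_tau, config$decay_tau) -
    return_frac
  ret <- stats::uniroot(f, c(ts, ts + 30 * config$decay_tau),
                        tol = 1e-9)$root
  list(baseline = config$baseline_ca, lag = config$lag,
       time_to_peak = config$lag + ts, peak = amp,
       duration = config$lag + ret)
}

#' @export
print.ca_experiment <- function(x, ...) {
  cat("Synthetic experiment: ", nrow(x$design), " design row(s) x ",
      x$config$replicates, " replicate(s), noise model '",
      x$config$noise_model, "', seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic experiment to luminometer CSV files plus a manifest
#'
#' Each trace goes to `row<r>_rep<k>.csv` in the luminometer dialect of
#' [write_luminometer_csv()]; `manifest.json` records the design, the
#' generator configuration, the sub-seeds and the per-row ground-truth
#' features.
#'
#' @param experiment a `ca_experiment`.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "ca_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (i in seq_along(experiment$traces))
    for (k in seq_along(experiment$traces[[i]])) {
      f <- file.path(dir, sprintf("row%d_rep%d.csv", i, k))
      write_luminometer_csv(experiment$traces[[i]][[k]], f)
      files[[length(files) + 1L]] <- list(row = i, replicate = k,
                                          path = basename(f))
    }
  manifest <- list(design = experiment$design,
                   config = unclass(experiment$config),
                   seeds = experiment$seeds,
                   truth_features = lapply(experiment$truth, function(tr)
                     tr[c("features", "features2")]),
                   files = files)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", matrix = "rowmajor")
  invisible(mpath)
}
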