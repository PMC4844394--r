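#' Dose-response analysis of an experiment
#'
#' Calibrates every luminescence trace to Ca2+ ([luminescence_to_ca()]),
#' extracts the peak response above baseline ([extract_features()]) and
#' aggregates mean and standard deviation over replicates per dose.
#' Traces that fail calibration are excluded with a logged reason.
#'
#' @param experiment a `ca_experiment` from [generate_experiment()] with
#'   single-elicitation rows.
#' @param consts a [calibration_constants()] object.
#' @param thresholds a [feature_thresholds()] list.
#' @return An object of class `dose_response`: a data.frame with columns
#'   `dose` (uM), `mean_peak`, `sd_peak` (uM) and `n`; excluded traces (if
#'   any) are listed in attribute `"excluded"`.
#' @export
dose_response <- function(experiment, consts = calibration_constants(),
                          thresholds = feature_thresholds()) {
  stopifnot(inherits(experiment, "ca_experiment"))
  cfg <- experiment$config
  excluded <- list()
  rows <- lapply(seq_len(nrow(experiment$design)), function(i) {
    peaks <- numeric(0)
    for (k in seq_along(experiment$traces[[i]])) {
      feat <- tryCatch({
        ca <- luminescence_to_ca(experiment$traces[[i]][[k]], consts)
        extract_features(ca, cfg$onset, thresholds)
      }, error = function(e) {
        excluded[[length(excluded) + 1L]] <<-
          list(row = i, replicate = k, reason = conditionMessage(e))
        NULL
      })
      if (!is.null(feat)) peaks <- c(peaks, feat$peak)
    }
    data.frame(dose = experiment$design$dose1[i],
               mean_peak = mean(peaks),
               sd_peak = if (length(peaks) > 1L) stats::sd(peaks) else 0,
               n = length(peaks))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("dose_response", "data.frame"),
            excluded = excluded)
}

#' Refractory (double-elicitation) analysis of an experiment
#'
#' For a design in which every row carries a first dose and the same fixed
#' second dose, extracts the first- and second-response peaks per
#' replicate and aggregates them per first dose. The first peak is
#' measured against the pre-first-stimulus baseline over the window up to
#' the second onset; the second peak is measured against the immediately
#' pre-second-stimulus level, so residual decay of the first transient
#' does not contaminate the second amplitude.
#'
#' @inheritParams dose_response
#' @return An object of class `refractory_table`: a data.frame with
#'   columns `dose1`, `dose2`, `first_mean`, `first_sd`, `second_mean`,
#'   `second_sd` and `n`.
#' @export
refractory_analysis <- function(experiment, consts = calibration_constants(),
                                thresholds = feature_thresholds()) {
  stopifnot(inherits(experiment, "ca_experiment"))
  design <- experiment$design
  if (any(is.na(design$dose2)))
    stop("refractory analysis needs a second stimulus in every design row")
  if (length(unique(design$dose2)) != 1L)
    stop("the second dose must be constant across design rows")
  cfg <- experiment$config
  rows <- lapply(seq_len(nrow(design)), function(i) {
    onset2 <- cfg$onset + design$interval[i]
    p1 <- numeric(0); p2 <- numeric(0)
    for (k in seq_along(experiment$traces[[i]])) {
      ca <- luminescence_to_ca(experiment$traces[[i]][[k]], consts)
      f1 <- extract_features(ca, cfg$onset, thresholds, window_end = onset2)
      f2 <- extract_features(ca, onset2, thresholds)
      p1 <- c(p1, f1$peak); p2 <- c(p2, f2$peak)
    }
    data.frame(dose1 = design$dose1[i], dose2 = design$dose2[i],
               first_mean = mean(p1),
               first_sd = if (length(p1) > 1L) stats::sd(p1) else 0,
               second_mean = mean(p2),
               second_sd = if (length(p2) > 1L) stats::sd(p2) else 0,
               n = length(p1))
  })
  structure(do.call(rbind, rows),
            class = c("refractory_table", "data.frame"))
}

#' Two-pulse refractory simulation with the mechanistic model
#'
#' Runs the adapted calcium-release model under a two-pulse stimulus and
#' reports the first- and second-peak amplitudes, each relative to the
#' level immediately before its pulse. The default settings are the
#' refractory simulation regime: raised channel permeability
#' (`p_ipx = 200`), no plasma-membrane influx, full-amplitude first pulse
#' and half-amplitude second pulse applied after the first response has
#' ended.
#'
#' @param params a [model_parameters()] object.
#' @param amplitudes length-2 normalized amplitudes of the two pulses.
#' @param onsets length-2 pulse onsets (s).
#' @param durations length-2 pulse durations (s).
#' @param include_jin logical; include the plasma-membrane influx.
#' @param ... passed to [simulate_transient()].
#' @return A list with `first_peak`, `second_peak` (uM above the
#'   respective pre-pulse level), `ratio` (second/first) and the
#'   `trajectory`.
#' @export
model_refractory <- function(params = model_parameters(p_ipx = 200, j_in = 0),
                             amplitudes = c(1, 0.5), onsets = c(60, 540),
                             durations = c(420, 420), include_jin = FALSE,
                             ...) {
  stopifnot(length(amplitudes) == 2L, length(onsets) == 2L,
            length(durations) == 2L)
  stim <- stimulus_protocol(amplitudes, onsets, durations)
  t_end <- onsets[2] + durations[2] + 240
  traj <- simulate_transient(params, stim, t_span = c(0, t_end),
                             include_jin = include_jin, ...)
  base1 <- traj$ci[max(which(traj$time < onsets[1]))]
  base2 <- traj$ci[max(which(traj$time < onsets[2]))]
  w1 <- traj$time >= onsets[1] & traj$time < onsets[2]
  w2 <- traj$time >= onsets[2]
  first <- max(traj$ci[w1]) - base1
  second <- max(traj$ci[w2]) - base2
  list(first_peak = first, second_peak = second, ratio = second / first,
       trajectory = traj)
}

#' Compare a simulated trajectory against a measured Ca2+ trace
#'
#' Resamples both series onto their common time support (linear
#' interpolation at the finer of the two grids) and reports the peak
#' error, the time-to-peak error and the RMSE over the overlap window.
#'
#' @param simulated a `ca_trajectory` (or [ca_trace()]).
#' @param measured a [ca_trace()].
#' @return A list with `peak_error` (uM, simulated minus measured),
#'   `peak_rel_error`, `time_to_peak_error` (s), `rmse` (uM) and the
#'   overlap `window` (s).
#' @export
compare_trace <- function(simulated, measured) {
  sim <- if (inherits(simulated, "ca_trajectory")) as_ca_trace(simulated)
         else simulated
  stopifnot(inherits(sim, "ca_trace"), inherits(measured, "ca_trace"))
  lo <- max(min(sim$times), min(measured$times))
  hi <- min(max(sim$times), max(measured$times))
  if (lo >= hi) stop("trace time ranges do not overlap")
  dt <- min(stats::median(diff(sim$times)), stats::median(diff(measured$times)))
  grid <- seq(lo, hi, by = dt)
  s <- stats::approx(sim$times, sim$ca, xout = grid)$y
  m <- stats::approx(measured$times, measured$ca, xout = grid)$y
  list(peak_error = max(s) - max(m),
       peak_rel_error = (max(s) - max(m)) / max(m),
       time_to_peak_error = grid[which.max(s)] - grid[which.max(m)],
       rmse = sqrt(mean((s - m)^2)),
       window = c(lo, hi))
}

#' Run a named analysis stage and write its artifacts
#'
#' Orchestration surface over the package's stages. Each stage writes CSV
#' tables and/or JSON reports under `out_dir` and returns its main result
#' invisibly. Stages: `"simulate"` (mechanistic trajectory under a
#' stimulus protocol), `"synth"` (generate and write a synthetic
#' experiment), `"calibrate"` (luminometer CSV to Ca2+ CSV),
#' `"dose_response"`, `"refractory"` (on a generated experiment) and
#' `"compare"` (model vs synthetic truth at the maximal dose).
#'
#' @param stage one of the stage names above.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for stages that generate data.
#' @param params a [model_parameters()] object.
#' @param stimulus a [stimulus_protocol()] (stage `"simulate"`).
#' @param design a design data.frame (stages `"synth"`,
#'   `"dose_response"`, `"refractory"`).
#' @param config a [synthetic_config()]; its seed is overridden by `seed`.
#' @param consts a [calibration_constants()] object.
#' @param lum_csv input luminometer CSV path (stage `"calibrate"`).
#' @param include_jin logical, passed to the simulation stages.
#' @return The stage result, invisibly.
#' @export
run_protocol <- function(stage = c("simulate", "synth", "calibrate",
                                   "dose_response", "refractory", "compare"),
                         out_dir = ".", seed = 1L,
                         params = model_parameters(),
                         stimulus = stimulus_protocol(1, 60, 420),
                         design = NULL,
                         config = synthetic_config(),
                         consts = calibration_constants(),
                         lum_csv = NULL, include_jin = FALSE) {
  stage <- match.arg(stage)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config$seed <- as.integer(seed)
  res <- switch(stage,
    simulate = {
      end <- max(stimulus_edges(stimulus)) + 120
      traj <- simulate_transient(params, stimulus, t_span = c(0, end),
                                 include_jin = include_jin)
      write_trajectory(traj, file.path(out_dir, "trajectory.csv"))
      traj
    },
    synth = {
      if (is.null(design)) design <- design_dose_series()
      exp <- generate_experiment(design, config, consts)
      write_experiment(exp, out_dir)
      exp
    },
    calibrate = {
      if (is.null(lum_csv)) stop("stage 'calibrate' needs lum_csv")
      ca <- luminescence_to_ca(read_luminometer_csv(lum_csv), consts)
      utils::write.csv(data.frame(time_s = ca$times, ca_uM = ca$ca),
                       file.path(out_dir, "calibrated.csv"),
                       row.names = FALSE)
      ca
    },
    dose_response = {
      if (is.null(design)) design <- design_dose_series()
      exp <- generate_experiment(design, config, consts)
      dr <- dose_response(exp, consts)
      utils::write.csv(as.data.frame(dr),
                       file.path(out_dir, "dose_response.csv"),
                       row.names = FALSE)
      dr
    },
    refractory = {
      if (is.null(design)) design <- design_double_elicitation()
      exp <- generate_experiment(design, config, consts)
      rt <- refractory_analysis(exp, consts)
      jsonlite::write_json(as.data.frame(rt),
                           file.path(out_dir, "refractory.json"),
                           dataframe = "rows", digits = NA)
      rt
    },
    compare = {
      traj <- simulate_transient(params, stimulus, t_span = c(0, 600),
                                 include_jin = include_jin)
      truth <- make_transient(config$max_dose, config$onset, config)
      cmp <- compare_trace(traj, truth)
      jsonlite::write_json(cmp[c("peak_error", "peak_rel_error",
                                 "time_to_peak_error", "rmse")],
                           file.path(out_dir, "comparison.json"),
                           auto_unbox = TRUE, digits = NA)
      cmp
    })
  invisible(res)
}
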