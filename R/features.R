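#' Thresholds for trace feature extraction
#'
#' @param onset_frac fraction of the peak-above-baseline that defines the
#'   response onset crossing.
#' @param return_frac fraction of the peak-above-baseline below which the
#'   trace counts as returned to baseline.
#' @param noise_k multiple of the baseline noise (MAD) that the onset
#'   threshold must at least exceed.
#' @param baseline_window length (s) of the pre-elicitation window used
#'   for the baseline median and noise estimate.
#' @return A named list of thresholds.
#' @export
feature_thresholds <- function(onset_frac = 0.05, return_frac = 0.10,
                               noise_k = 3, baseline_window = 60) {
  stopifnot(onset_frac > 0, return_frac > 0, noise_k >= 0,
            baseline_window > 0)
  list(onset_frac = onset_frac, return_frac = return_frac,
       noise_k = noise_k, baseline_window = baseline_window)
}

#' Extract descriptive features from a Ca2+ trace
#'
#' Operational definitions of the quantities used to describe
#' elicitor-induced transients, all measured relative to the elicitation
#' time: `baseline` is the median of the pre-elicitation window; the
#' response onset is the first time the trace exceeds
#' `baseline + max(onset_frac * peak_above_baseline, noise_k * MAD)`;
#' `lag` is onset minus elicitation; `time_to_peak` runs from elicitation
#' to the maximum; `duration` runs from elicitation to the first time
#' after the peak that the trace falls back below
#' `baseline + return_frac * peak_above_baseline`. A trace whose
#' peak-above-baseline does not clear the noise threshold is reported as a
#' non-response (`peak = 0`, lag/time-to-peak/duration `NA`,
#' `responded = FALSE`).
#'
#' @param trace a [ca_trace()] covering the elicitation time with a
#'   preceding baseline window.
#' @param elicitation_time time of elicitor addition (s).
#' @param thresholds a [feature_thresholds()] list.
#' @param window_end optional end (s) of the response search window, e.g.
#'   the onset of a following stimulus.
#' @return An object of class `trace_features`: a list with `baseline`
#'   (uM), `lag` (s), `time_to_peak` (s), `peak` (uM above baseline),
#'   `duration` (s) and `responded` (logical).
#' @export
extract_features <- function(trace, elicitation_time,
                             thresholds = feature_thresholds(),
                             window_end = NULL) {
  stopifnot(inherits(trace, "ca_trace"))
  t <- trace$times; ca <- trace$ca
  if (elicitation_time <= min(t) || elicitation_time > max(t))
    stop("trace must cover the elicitation time with a preceding baseline")
  pre <- t < elicitation_time & t >= elicitation_time - thresholds$baseline_window
  if (!any(pre)) stop("no samples in the baseline window")
  baseline <- stats::median(ca[pre])
  noise <- stats::mad(ca[pre])

  win <- t >= elicitation_time &
    (if (is.null(window_end)) TRUE else t < window_end)
  tw <- t[win]; cw <- ca[win]
  peak_above <- max(cw) - baseline
  onset_thr <- baseline + max(thresholds$onset_frac * peak_above,
                              thresholds$noise_k * noise)
  if (peak_above <= 0 || max(cw) <= onset_thr) {
    return(structure(list(baseline = baseline, lag = NA_real_,
                          time_to_peak = NA_real_, peak = 0,
                          duration = NA_real_, responded = FALSE),
                     class = "trace_features"))
  }
  i_on <- which(cw > onset_thr)[1]
  i_pk <- which.max(cw)
  ret_thr <- baseline + thresholds$return_frac * peak_above
  after <- seq_along(cw) > i_pk
  i_ret <- which(after & cw < ret_thr)[1]
  structure(list(baseline = baseline,
                 lag = tw[i_on] - elicitation_time,
                 time_to_peak = tw[i_pk] - elicitation_time,
                 peak = peak_above,
                 duration = if (is.na(i_ret)) NA_real_
                            else tw[i_ret] - elicitation_time,
                 responded = TRUE),
            class = "trace_features")
}

#' @export
print.trace_features <- function(x, ...) {
  if (!x$responded) {
    cat("No response (baseline ", signif(x$baseline, 4), " uM)\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(paste0("Response: baseline %.4g uM, lag %.4g s, ",
                     "time-to-peak %.4g s, peak %.4g uM, duration %.4g s\n"),
              x$baseline, x$lag, x$time_to_peak, x$peak, x$duration))
  invisible(x)
}
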