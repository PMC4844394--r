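#' Aequorin calibration constants
#'
#' Constants of the ratiometric luminescence-to-Ca2+ relationship:
#' `k_r` (1/M), the dimensionless `k_tr`, and the cooperativity exponent
#' `n`. Defaults are the experimentally fitted values used with
#' cytosolically targeted aequorin.
#'
#' @param k_r association-rate-like constant (1/M), > 0.
#' @param k_tr dimensionless constant, > 0.
#' @param n cooperativity exponent, > 0.
#' @return An object of class `aeq_consts`.
#' @export
calibration_constants <- function(k_r = 7.23e6, k_tr = 120, n = 2.99) {
  stopifnot(k_r > 0, k_tr > 0, n > 0)
  structure(list(k_r = k_r, k_tr = k_tr, n = n), class = "aeq_consts")
}

#' Luminometer trace container
#'
#' Luminescence counts per sampling interval together with the total
#' discharge light `l_tot` (the light emitted over the whole experiment
#' including the terminal CaCl2 discharge of the remaining aequorin).
#' `l_tot` must cover at least the summed counts; the remaining
#' dischargeable light at any time is what the ratiometric calibration
#' divides by.
#'
#' @param times sampling times (s), strictly increasing.
#' @param counts non-negative luminescence per interval (arbitrary light
#'   units).
#' @param l_tot total discharge light (same units), >= `sum(counts)`.
#' @param dt sampling interval (s); defaults to the median time step.
#' @return An object of class `lum_trace`.
#' @export
luminescence_trace <- function(times, counts, l_tot, dt = NULL) {
  stopifnot(length(times) == length(counts), length(times) >= 1L)
  if (any(!is.finite(times)) || is.unsorted(times, strictly = TRUE))
    stop("times must be finite and strictly increasing")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and >= 0")
  if (!is.finite(l_tot) || l_tot < sum(counts))
    stop("l_tot must be finite and >= sum(counts)")
  if (is.null(dt)) dt <- if (length(times) > 1L) stats::median(diff(times)) else 1
  structure(list(times = times, counts = counts, l_tot = l_tot, dt = dt),
            class = "lum_trace")
}

#' @export
print.lum_trace <- function(x, ...) {
  cat("Luminescence trace: ", length(x$counts), " samples, dt = ", x$dt,
      " s, sum(counts)/l_tot = ", signif(sum(x$counts) / x$l_tot, 3),
      "\n", sep = "")
  invisible(x)
}

#' Calcium trace container
#'
#' @param times sampling times (s), strictly increasing.
#' @param ca cytosolic Ca2+ concentrations (uM), finite and >= 0.
#' @return An object of class `ca_trace`.
#' @export
ca_trace <- function(times, ca) {
  stopifnot(length(times) == length(ca))
  if (any(!is.finite(times)) || is.unsorted(times, strictly = TRUE))
    stop("times must be finite and strictly increasing")
  if (any(!is.finite(ca)) || any(ca < 0))
    stop("ca must be finite and >= 0")
  structure(list(times = times, ca = ca), class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat("Ca2+ trace: ", length(x$ca), " samples on [", min(x$times), ", ",
      max(x$times), "] s; max = ", signif(max(x$ca), 4), " uM\n", sep = "")
  invisible(x)
}

#' Remaining dischargeable light series
#'
#' The remaining aequorin light pool after each sample,
#' `l_max_i = l_tot - (counts_1 + ... + counts_i)`, counts up to and
#' including sample `i`. Non-increasing by construction; a negative value
#' means the recorded counts exceed the discharge total and is an error.
#'
#' @param trace a [luminescence_trace()].
#' @return Numeric vector of the same length as `trace$counts`.
#' @export
lmax_series <- function(trace) {
  stopifnot(inherits(trace, "lum_trace"))
  lmax <- trace$l_tot - cumsum(trace$counts)
  if (any(lmax < 0))
    stop("inconsistent discharge: cumulative counts exceed l_tot at index ",
         which(lmax < 0)[1])
  lmax
}

#' Ratiometric conversion from luminescence ratio to Ca2+ concentration
#'
#' Converts `r = (L_i / L_max_i)^(1/n)` into a calcium concentration via
#' `Ca = (r + r * k_tr - 1) / (k_r * (1 - r))` (in M). Negative numerators
#' (low light, below the detection floor) are clamped to 0 with a
#' `"below_detection"` attribute marking the affected entries. The
#' relation diverges as `r -> 1`: ratios at or above `1 - 1e-12` signal
#' aequorin exhaustion and raise an error.
#'
#' @param r dimensionless ratio-derived quantity in `[0, 1)`; vectorized.
#' @param consts a [calibration_constants()] object.
#' @return Ca2+ concentration(s) in M.
#' @export
ratio_to_ca <- function(r, consts = calibration_constants()) {
  stopifnot(inherits(consts, "aeq_consts"))
  if (any(!is.finite(r)) || any(r < 0)) stop("r must be finite and >= 0")
  if (any(r >= 1 - 1e-12))
    stop("saturation: luminescence ratio at or above 1 (aequorin exhausted)")
  ca <- (r + r * consts$k_tr - 1) / (consts$k_r * (1 - r))
  below <- ca < 0
  ca[below] <- 0
  if (any(below)) attr(ca, "below_detection") <- which(below)
  ca
}

#' Convert a luminescence trace to a calcium trace
#'
#' The per-sample pipeline: counts -> remaining pool `L_max_i`
#' ([lmax_series()]) -> ratio `r_i = (L_i / L_max_i)^(1/n)` ->
#' [ratio_to_ca()], with the result reported in uM. A sample with an
#' exhausted pool (`L_max_i` of 0 with non-zero counts would give an
#' infinite ratio) raises a saturation error naming the offending index.
#'
#' @param trace a [luminescence_trace()].
#' @param consts a [calibration_constants()] object.
#' @return A [ca_trace()] in uM; entries clamped at the detection floor
#'   carry over the `"below_detection"` attribute.
#' @export
luminescence_to_ca <- function(trace, consts = calibration_constants()) {
  stopifnot(inherits(trace, "lum_trace"))
  lmax <- lmax_series(trace)
  bad <- lmax <= 0
  if (any(bad))
    stop("saturation: aequorin pool exhausted at index ", which(bad)[1])
  r <- (trace$counts / lmax)^(1 / consts$n)
  if (any(r >= 1 - 1e-12))
    stop("saturation: luminescence ratio at or above 1 at index ",
         which(r >= 1 - 1e-12)[1])
  ca_M <- ratio_to_ca(r, consts)
  out <- ca_trace(times = trace$times, ca = as.numeric(ca_M) * 1e6)
  attr(out, "below_detection") <- attr(ca_M, "below_detection")
  out
}

#' Read or write luminometer CSV exports
#'
#' The dialect is a two-column CSV `time_s, counts`. The discharge total
#' is carried either as a trailing flagged row (empty `time_s`, the total
#' in `counts`) or supplied via `l_tot`; the trailing row takes precedence
#' when both are present in the file.
#'
#' @param path CSV file path.
#' @param l_tot discharge total, used when the file has no trailing row.
#' @param trace a [luminescence_trace()] (for writing).
#' @param ltot_row logical; write the discharge total as a trailing
#'   flagged row.
#' @return `read_luminometer_csv` returns a [luminescence_trace()];
#'   `write_luminometer_csv` returns `path` invisibly.
#' @export
read_luminometer_csv <- function(path, l_tot = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "counts") %in% names(df)))
    stop("luminometer CSV needs columns time_s and counts")
  flag <- is.na(df$time_s)
  if (any(flag)) {
    l_tot <- df$counts[flag][1]
    df <- df[!flag, , drop = FALSE]
  }
  if (is.null(l_tot))
    stop("no discharge total: supply l_tot or include a trailing flagged row")
  luminescence_trace(times = df$time_s, counts = df$counts, l_tot = l_tot)
}

#' @rdname read_luminometer_csv
#' @export
write_luminometer_csv <- function(trace, path, ltot_row = TRUE) {
  stopifnot(inherits(trace, "lum_trace"))
  df <- data.frame(time_s = trace$times, counts = trace$counts)
  if (ltot_row) df <- rbind(df, data.frame(time_s = NA, counts = trace$l_tot))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
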