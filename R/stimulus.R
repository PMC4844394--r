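#' Normalized IPx stimulus protocols
#'
#' A stimulus protocol is a train of non-overlapping pulses of normalized
#' IPx amplitude (between 0 and 1), each with an onset and a duration in
#' seconds. Pulses are rectangular by default; a positive `ramp` replaces
#' the vertical edges with linear ramps of that length (the pulse rises
#' over `[onset, onset+ramp]` and falls over
#' `[onset+duration, onset+duration+ramp]`).
#'
#' @param amplitude numeric vector of normalized amplitudes in `[0, 1]`.
#' @param onset numeric vector of pulse onsets (s), non-decreasing.
#' @param duration numeric vector of pulse durations (s), > 0.
#' @param ramp edge ramp length (s), >= 0; shared by all pulses.
#' @return An object of class `stimulus_protocol`.
#' @examples
#' # the standard single 7-minute full-amplitude elicitation
#' stim <- stimulus_protocol(1, onset = 60, duration = 420)
#' evaluate_stimulus(stim, c(59, 60, 200, 480))
#' @export
stimulus_protocol <- function(amplitude, onset, duration, ramp = 0) {
  n <- length(amplitude)
  stopifnot(length(onset) == n, length(duration) == n, n >= 0)
  if (any(!is.finite(c(amplitude, onset, duration, ramp))))
    stop("stimulus fields must be finite")
  if (any(amplitude < 0 | amplitude > 1))
    stop("pulse amplitudes must lie in [0, 1]")
  if (any(duration <= 0)) stop("pulse durations must be > 0")
  if (ramp < 0) stop("ramp must be >= 0")
  if (n > 1) {
    if (is.unsorted(onset)) stop("pulse onsets must be non-decreasing")
    ends <- onset + duration + ramp
    if (any(ends[-n] > onset[-1])) stop("pulses must not overlap")
  }
  structure(list(pulses = data.frame(amplitude = amplitude, onset = onset,
                                     duration = duration),
                 ramp = ramp),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("Stimulus protocol (", nrow(x$pulses), " pulse(s), ramp = ",
      x$ramp, " s):\n", sep = "")
  print(x$pulses, row.names = FALSE)
  invisible(x)
}

#' Evaluate a stimulus protocol at given times
#'
#' @param protocol a `stimulus_protocol`.
#' @param t numeric vector of times (s).
#' @return Normalized amplitude at each time (0 outside all pulses).
#' @export
evaluate_stimulus <- function(protocol, t) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  out <- numeric(length(t))
  r <- protocol$ramp
  for (i in seq_len(nrow(protocol$pulses))) {
    a <- protocol$pulses$amplitude[i]
    t0 <- protocol$pulses$onset[i]
    t1 <- t0 + protocol$pulses$duration[i]
    if (r > 0) {
      up <- t >= t0 & t < t0 + r
      out[up] <- a * (t[up] - t0) / r
      flat <- t >= t0 + r & t < t1
      out[flat] <- a
      down <- t >= t1 & t < t1 + r
      out[down] <- a * (1 - (t[down] - t1) / r)
    } else {
      out[t >= t0 & t < t1] <- a
    }
  }
  out
}

# Breakpoints where the stimulus is non-smooth; the integrator restarts here.
stimulus_edges <- function(protocol) {
  p <- protocol$pulses
  r <- protocol$ramp
  e <- c(p$onset, p$onset + r, p$onset + p$duration, p$onset + p$duration + r)
  sort(unique(e))
}

#' Transfer function between normalized stimulus and elicitor concentration
#'
#' The receptor-to-store signaling steps between elicitor perception and
#' IPx release are treated as a black box summarized by a fitted power-law
#' transfer function `y(x) = A * (x - x0)^p` mapping the normalized
#' stimulus amplitude `x` to the elicitor (Ch5) concentration `y` it
#' emulates; `y` is 0 at and below the threshold `x0`. Defaults are the
#' calibration fitted for penta-N-acetylchitopentaose (Ch5).
#'
#' @param A scale coefficient (concentration units), > 0.
#' @param x0 normalized threshold, in `[0, 1)`.
#' @param p power exponent, > 0.
#' @return An object of class `transfer_fn`.
#' @export
transfer_function <- function(A = 8328.75, x0 = 0.06, p = 3.57) {
  stopifnot(is.numeric(A), A > 0, is.numeric(x0), x0 >= 0, x0 < 1,
            is.numeric(p), p > 0)
  structure(list(A = A, x0 = x0, p = p), class = "transfer_fn")
}

#' @export
print.transfer_fn <- function(x, ...) {
  cat(sprintf("Transfer function y(x) = %g * (x - %g)^%g\n", x$A, x$x0, x$p))
  invisible(x)
}

#' Convert normalized stimulus amplitude to elicitor concentration
#'
#' @param x normalized amplitude(s) in `[0, 1]`.
#' @param tf a `transfer_fn`.
#' @return Elicitor concentration(s); 0 for `x <= x0`.
#' @export
transfer_forward <- function(x, tf = transfer_function()) {
  stopifnot(inherits(tf, "transfer_fn"))
  if (any(!is.finite(x)) || any(x < 0 | x > 1))
    stop("normalized amplitude must lie in [0, 1]")
  ifelse(x <= tf$x0, 0, tf$A * (x - tf$x0)^tf$p)
}

#' Convert elicitor concentration to normalized stimulus amplitude
#'
#' Algebraic inverse of [transfer_forward()]: `x = x0 + (y/A)^(1/p)`.
#' Doses above the calibrated range (mapping to `x > 1`) are an error.
#'
#' @param y elicitor concentration(s), >= 0.
#' @param tf a `transfer_fn`.
#' @return Normalized amplitude(s).
#' @export
transfer_inverse <- function(y, tf = transfer_function()) {
  stopifnot(inherits(tf, "transfer_fn"))
  if (any(!is.finite(y)) || any(y < 0)) stop("concentration must be >= 0")
  x <- tf$x0 + (y / tf$A)^(1 / tf$p)
  if (any(x > 1))
    stop("dose exceeds the calibrated range of the transfer function")
  x
}

#' Fit a power-law transfer function to amplitude/concentration pairs
#'
#' Least-squares fit of `(A, x0, p)` in log-concentration space,
#' `log(y) = log(A) + p * log(x - x0)`, by Levenberg-Marquardt. Pairs with
#' zero concentration are dropped (they carry no information about the
#' power law above threshold).
#'
#' @param x normalized amplitudes.
#' @param y elicitor concentrations (same length).
#' @param start optional named list with elements `A`, `x0`, `p`.
#' @return A `transfer_fn` with the fit object attached as attribute
#'   `"fit"`.
#' @export
fit_transfer <- function(x, y, start = NULL) {
  keep <- is.finite(x) & is.finite(y) & y > 0
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 3L)
    stop("transfer-function fit requires >= 3 distinct pairs with y > 0")
  if (is.null(start)) {
    x0s <- max(0, 0.5 * min(x))
    sl <- stats::lm(log(y) ~ log(x - x0s))
    start <- list(logA = unname(stats::coef(sl)[1]),
                  p = max(unname(stats::coef(sl)[2]), 0.1),
                  x0 = x0s)
  } else {
    start <- list(logA = log(start$A), p = start$p, x0 = start$x0)
  }
  dat <- data.frame(x = x, ly = log(y))
  fit <- tryCatch(
    minpack.lm::nlsLM(ly ~ logA + p * log(x - x0), data = dat, start = start,
                      lower = c(logA = -Inf, p = 1e-6, x0 = 0),
                      upper = c(logA = Inf, p = Inf, x0 = min(x) - 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("transfer-function fit failed: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  out <- transfer_function(A = exp(unname(cf["logA"])),
                           x0 = unname(cf["x0"]), p = unname(cf["p"]))
  attr(out, "fit") <- fit
  out
}

#' Reference amplitude/concentration pairs for the Ch5 elicitor
#'
#' The normalized stimulus amplitudes and the Ch5 concentrations they were
#' matched to in the double-elicitation experiments: 1 corresponds to
#' 480 uM, 0.5 to 240 uM, 0.11 to 480 nM and 0.06 to 480 pM. This lookup
#' is kept separate from [transfer_forward()] because the fitted formula
#' and the matched pairs are not numerically consistent with one another
#' (the formula gives y(1) of about 6658, not 480); the experiment
#' emulation layer uses the lookup by default.
#'
#' @return A data.frame with columns `x` (normalized amplitude) and
#'   `ch5_uM` (Ch5 concentration, uM).
#' @export
ch5_reference_pairs <- function() {
  data.frame(x = c(0.06, 0.11, 0.5, 1.0),
             ch5_uM = c(4.8e-4, 0.48, 240, 480))
}

#' Normalized stimulus amplitude for a Ch5 dose
#'
#' Maps an elicitor dose (uM) onto a normalized stimulus amplitude, either
#' via the reference lookup (log-dose linear interpolation between the
#' matched pairs of [ch5_reference_pairs()], extrapolated at the ends and
#' clamped to `[0, 1]`; the default) or via the algebraic inverse of the
#' fitted transfer function.
#'
#' @param dose elicitor concentration(s) in uM, >= 0.
#' @param method `"reference"` or `"transfer"`.
#' @param tf transfer function used when `method = "transfer"`.
#' @return Normalized amplitude(s) in `[0, 1]`.
#' @export
amplitude_for_dose <- function(dose, method = c("reference", "transfer"),
                               tf = transfer_function()) {
  method <- match.arg(method)
  if (any(!is.finite(dose)) || any(dose < 0)) stop("dose must be >= 0")
  if (method == "transfer") return(transfer_inverse(dose, tf))
  ref <- ch5_reference_pairs()
  x <- numeric(length(dose))
  pos <- dose > 0
  x[pos] <- stats::approx(log10(ref$ch5_uM), ref$x, xout = log10(dose[pos]),
                          rule = 2)$y
  # linear extrapolation on the end segments, then clamp
  lo <- pos & dose < ref$ch5_uM[1]
  if (any(lo)) {
    s <- (ref$x[2] - ref$x[1]) / (log10(ref$ch5_uM[2]) - log10(ref$ch5_uM[1]))
    x[lo] <- ref$x[1] + s * (log10(dose[lo]) - log10(ref$ch5_uM[1]))
  }
  pmin(pmax(x, 0), 1)
}

#' Read or write a stimulus protocol (YAML/JSON)
#'
#' Serialized as a list of `{amplitude, onset_s, duration_s}` records plus
#' a `ramp_s` scalar.
#'
#' @param protocol a `stimulus_protocol`.
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  x <- list(ramp_s = protocol$ramp,
            pulses = lapply(seq_len(nrow(protocol$pulses)), function(i)
              list(amplitude = protocol$pulses$amplitude[i],
                   onset_s = protocol$pulses$onset[i],
                   duration_s = protocol$pulses$duration[i])))
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
  else if (grepl("\\.json$", path))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else stop("unsupported protocol file extension: ", path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = FALSE)
       else stop("unsupported protocol file extension: ", path)
  stimulus_protocol(
    amplitude = vapply(x$pulses, function(p) p$amplitude, numeric(1)),
    onset = vapply(x$pulses, function(p) p$onset_s, numeric(1)),
    duration = vapply(x$pulses, function(p) p$duration_s, numeric(1)),
    ramp = x$ramp_s)
}
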