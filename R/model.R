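#' Channel open probability at equilibrium
#'
#' Open probability of the IPx-gated release channel, the product of
#' cooperative IPx binding, cooperative Ca2+ activation (calcium-induced
#' calcium release) and the inactivation gate, each to the third power:
#' `O = (ipx/(ipx+d_ipx))^3 * (ci/(ci+d_act))^3 * h^3`.
#'
#' @param ipx IPx concentration (uM), >= 0.
#' @param ci cytosolic Ca2+ (uM), >= 0.
#' @param h inactivation gate in `[0, 1]`.
#' @param params a [model_parameters()] object.
#' @return Open probability in `[0, 1]`; vectorized over the inputs.
#' @export
open_probability <- function(ipx, ci, h, params = model_parameters()) {
  if (any(ipx < 0) || any(ci < 0)) stop("ipx and ci must be >= 0")
  if (any(h < 0 | h > 1)) stop("h must lie in [0, 1]")
  (ipx / (ipx + params$d_ipx))^3 * (ci / (ci + params$d_act))^3 * h^3
}

#' Store fluxes of the calcium-release model
#'
#' The three store fluxes (uM/s): the Hill-type pump into the store
#' `j_pump = v_store * ci^2 / (k_store^2 + ci^2)`, the passive leak down
#' the store gradient `j_leak = p_l * (c0 - (1 + c1) * ci)`, and the
#' channel flux `j_chan = p_ipx * O * (c0 - (1 + c1) * ci)` with `O` from
#' [open_probability()]. The gradient factor `c0 - (1 + c1) * ci` vanishes
#' when cytosol and store are at the same concentration,
#' `ci = c0/(1 + c1)`.
#'
#' @inheritParams open_probability
#' @return Flux in uM/s (vectorized). `flux_pump` is bounded by
#'   `[0, v_store)`; `flux_leak` and `flux_chan` are signed.
#' @export
flux_pump <- function(ci, params = model_parameters()) {
  if (any(ci < 0)) stop("ci must be >= 0")
  params$v_store * ci^2 / (params$k_store^2 + ci^2)
}

#' @rdname flux_pump
#' @export
flux_leak <- function(ci, params = model_parameters()) {
  if (any(ci < 0)) stop("ci must be >= 0")
  params$p_l * (params$c0 - (1 + params$c1) * ci)
}

#' @rdname flux_pump
#' @export
flux_chan <- function(ipx, ci, h, params = model_parameters()) {
  params$p_ipx * open_probability(ipx, ci, h, params) *
    (params$c0 - (1 + params$c1) * ci)
}

#' Steady state of the inactivation gate
#'
#' Equilibrium of the gate equation, `h_inf = d_inh / (ci + d_inh)`:
#' fully de-inactivated (1) at zero Ca2+, half at `ci = d_inh`, and
#' decreasing with cytosolic Ca2+.
#'
#' @inheritParams open_probability
#' @export
h_steady_state <- function(ci, params = model_parameters()) {
  if (any(ci < 0)) stop("ci must be >= 0")
  params$d_inh / (ci + params$d_inh)
}

#' Time derivatives of the calcium-release model
#'
#' The right-hand side of the two-variable system:
#' `dci/dt = j_chan + j_leak - j_pump (+ j_in)` and
#' `dh/dt = a * (ci + d_inh) * (d_inh/(ci + d_inh) - h)`.
#' With `include_jin = FALSE` the constant plasma-membrane influx is
#' omitted (an isolated cell).
#'
#' @param t time (s).
#' @param state named numeric vector or list with `ci` and `h`.
#' @param stimulus a [stimulus_protocol()] giving IPx at time `t`.
#' @param params a [model_parameters()] object.
#' @param include_jin logical; include the `j_in` term.
#' @return Numeric vector `c(dci, dh)`.
#' @export
ca_derivatives <- function(t, state, stimulus, params = model_parameters(),
                           include_jin = TRUE) {
  ci <- state[["ci"]]; h <- state[["h"]]
  if (!is.finite(ci) || !is.finite(h))
    stop("non-finite model state at t = ", t)
  ipx <- evaluate_stimulus(stimulus, t)
  dci <- flux_chan(ipx, ci, h, params) + flux_leak(ci, params) -
    flux_pump(ci, params) + if (include_jin) params$j_in else 0
  dh <- params$a * (ci + params$d_inh) * (h_steady_state(ci, params) - h)
  c(dci = dci, dh = dh)
}

#' Simulate the calcium-release model under a stimulus protocol
#'
#' Integrates the two-variable system with an adaptive explicit
#' Dormand-Prince Runge-Kutta scheme (`deSolve` method `"ode45"`),
#' restarting at every pulse edge so the integrator never steps across a
#' stimulus discontinuity. The trajectory carries the cytosolic Ca2+,
#' the gate, the applied stimulus, the flux decomposition and the derived
#' store concentration `cer = (c0 - ci)/c1`.
#'
#' @param params a [model_parameters()] object; supplies the initial state
#'   `(ci0, h0)`.
#' @param stimulus a [stimulus_protocol()].
#' @param t_span length-2 increasing numeric, start and end time (s).
#' @param dt output grid spacing (s).
#' @param include_jin logical; include the plasma-membrane influx term.
#' @param equilibrate logical; if `TRUE`, first relax the unstimulated
#'   system to its steady state and start the stimulated run from there
#'   instead of from `(ci0, h0)`.
#' @param rtol,atol relative and absolute solver tolerances.
#' @param max_step maximal solver step (s); default 1 s.
#' @param fluxes logical; include the flux columns in the output.
#' @return A `ca_trajectory`: a data.frame with columns `time`, `ci`, `h`,
#'   `ipx`, `cer` and (optionally) `j_chan`, `j_leak`, `j_pump`, `j_in`,
#'   with the parameters, stimulus and solver settings attached as
#'   attributes.
#' @examples
#' stim <- stimulus_protocol(1, onset = 60, duration = 420)
#' traj <- simulate_transient(model_parameters(), stim, t_span = c(0, 600),
#'                            include_jin = FALSE)
#' max(traj$ci)   # peak cytosolic Ca2+, about 6 uM
#' @export
simulate_transient <- function(params = model_parameters(), stimulus,
                               t_span = c(0, 600), dt = 1,
                               include_jin = TRUE, equilibrate = FALSE,
                               rtol = 1e-6, atol = 1e-9, max_step = 1,
                               fluxes = TRUE) {
  stopifnot(inherits(stimulus, "stimulus_protocol"),
            length(t_span) == 2L, t_span[2] > t_span[1], dt > 0)
  y0 <- c(ci = params$ci0, h = params$h0)
  if (equilibrate) y0 <- equilibrate_state(params, include_jin)

  deriv <- function(t, y, parms) {
    list(ca_derivatives(t, y, stimulus, params, include_jin))
  }
  edges <- stimulus_edges(stimulus)
  edges <- edges[edges > t_span[1] & edges < t_span[2]]
  seg <- unique(c(t_span[1], edges, t_span[2]))
  grid <- seq(t_span[1], t_span[2], by = dt)

  out <- NULL
  y <- y0
  for (i in seq_len(length(seg) - 1L)) {
    tt <- sort(unique(c(seg[i], grid[grid > seg[i] & grid < seg[i + 1]],
                        seg[i + 1])))
    o <- tryCatch(
      deSolve::ode(y, tt, deriv, parms = NULL, method = "ode45",
                   rtol = rtol, atol = atol, hmax = max_step),
      error = function(e) stop("ODE integration failed on [", seg[i], ", ",
                               seg[i + 1], "] s: ", conditionMessage(e)))
    if (attr(o, "istate")[1] != 2 && any(!is.finite(o)))
      stop("ODE solver returned non-finite values on segment starting at ",
           seg[i], " s")
    y <- o[nrow(o), c("ci", "h")]
    out <- rbind(out, if (i < length(seg) - 1L) o[-nrow(o), , drop = FALSE]
                      else o)
  }
  out <- as.data.frame(out)
  # keep only the requested output grid (segment edges are solver restarts)
  keep <- out$time %in% grid | out$time %in% seg
  out <- out[keep & !duplicated(out$time), , drop = FALSE]
  rownames(out) <- NULL

  ci_cap <- params$c0 / (1 + params$c1)
  if (any(out$ci > ci_cap * (1 + 1e-3)))
    warning("non-physical blow-up: ci exceeds c0/(1+c1) by more than 0.1%")
  if (any(out$ci < -atol)) warning("ci fell below 0 beyond solver tolerance")
  if (any(out$h < -1e-6 | out$h > 1 + 1e-6))
    warning("gate h left [0, 1] beyond solver tolerance")

  out$ipx <- evaluate_stimulus(stimulus, out$time)
  if (fluxes) {
    out$j_chan <- flux_chan(out$ipx, pmax(out$ci, 0), pmin(pmax(out$h, 0), 1),
                            params)
    out$j_leak <- flux_leak(pmax(out$ci, 0), params)
    out$j_pump <- flux_pump(pmax(out$ci, 0), params)
    out$j_in <- rep(if (include_jin) params$j_in else 0, nrow(out))
  }
  out$cer <- (params$c0 - out$ci) / params$c1
  structure(out,
            class = c("ca_trajectory", "data.frame"),
            params = params, stimulus = stimulus,
            solver = list(method = "ode45", rtol = rtol, atol = atol,
                          max_step = max_step, include_jin = include_jin))
}

# Relax the unstimulated system (ipx = 0) to steady state.
equilibrate_state <- function(params, include_jin = TRUE, t_relax = 2e4) {
  none <- stimulus_protocol(numeric(0), numeric(0), numeric(0))
  deriv <- function(t, y, parms) {
    list(ca_derivatives(t, y, none, params, include_jin))
  }
  o <- deSolve::ode(c(ci = params$ci0, h = params$h0), c(0, t_relax), deriv,
                    parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12)
  y <- o[nrow(o), c("ci", "h")]
  d <- ca_derivatives(t_relax, y, none, params, include_jin)
  if (max(abs(d)) > 1e-6)
    warning("equilibration did not fully converge (max |dy/dt| = ",
            signif(max(abs(d)), 3), ")")
  y
}

#' @export
print.ca_trajectory <- function(x, ...) {
  cat("Calcium trajectory: ", nrow(x), " points on [",
      min(x$time), ", ", max(x$time), "] s; peak ci = ",
      signif(max(x$ci), 4), " uM\n", sep = "")
  invisible(x)
}

#' Convert a simulated trajectory to a plain calcium trace
#'
#' @param x a `ca_trajectory`.
#' @return A [ca_trace()] with the trajectory's times and `ci` series.
#' @export
as_ca_trace <- function(x) {
  stopifnot(inherits(x, "ca_trajectory"))
  ca_trace(times = x$time, ca = x$ci)
}

#' Write or read a simulated trajectory (CSV plus JSON sidecar)
#'
#' The CSV carries columns `time_s`, `ci_uM`, `h`, `ipx` (and flux columns
#' when present); a JSON sidecar at `<path>.json` records the full
#' parameter set, the stimulus protocol and the solver settings for
#' provenance.
#'
#' @param traj a `ca_trajectory`.
#' @param path CSV file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `ca_trajectory` (attributes restored from the sidecar when
#'   it exists).
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "ca_trajectory"))
  df <- data.frame(time_s = traj$time, ci_uM = traj$ci, h = traj$h,
                   ipx = traj$ipx)
  for (cn in c("j_chan", "j_leak", "j_pump", "j_in", "cer"))
    if (!is.null(traj[[cn]])) df[[cn]] <- traj[[cn]]
  utils::write.csv(df, path, row.names = FALSE)
  prot <- attr(traj, "stimulus")
  side <- list(params = unclass(attr(traj, "params")),
               solver = attr(traj, "solver"),
               stimulus = list(ramp_s = prot$ramp,
                               pulses = prot$pulses))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  out <- data.frame(time = df$time_s, ci = df$ci_uM, h = df$h, ipx = df$ipx)
  for (cn in c("j_chan", "j_leak", "j_pump", "j_in", "cer"))
    if (!is.null(df[[cn]])) out[[cn]] <- df[[cn]]
  side_path <- paste0(path, ".json")
  params <- NULL; stim <- NULL; solver <- NULL
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    params <- do.call(model_parameters, as.list(side$params))
    stim <- stimulus_protocol(amplitude = side$stimulus$pulses$amplitude,
                              onset = side$stimulus$pulses$onset,
                              duration = side$stimulus$pulses$duration,
                              ramp = side$stimulus$ramp_s)
    solver <- side$solver
  }
  structure(out, class = c("ca_trajectory", "data.frame"),
            params = params, stimulus = stim, solver = solver)
}
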