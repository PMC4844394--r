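#' Model parameters for the adapted Li-Rinzel calcium-release system
#'
#' Constructs the full parameter set of the two-variable calcium-release
#' model: an inositol-phosphate (IPx) gated channel, a passive leak and a
#' Hill-type pump connect the cytosol to an internal store (the vacuole in
#' plant cells), and a slow gate `h` tracks calcium-dependent channel
#' inactivation. Defaults are the values used for elicitor-induced
#' transients in tobacco cell cultures; units are seconds and micromolar
#' throughout.
#'
#' The total calcium concentration `c0` is partitioned between cytosol and
#' store via the store/cytosol volume ratio `c1`, so the store content is
#' `cer = (c0 - ci)/c1` and the transmembrane gradient term is
#' `c0 - (1 + c1)*ci`.
#'
#' @param p_ipx maximal channel permeability (1/s).
#' @param p_l leak permeability (1/s).
#' @param v_store maximal pump rate into the store (uM/s).
#' @param k_store pump activation constant (uM).
#' @param d_ipx IPx dissociation constant of the channel (uM).
#' @param d_act Ca2+ activation dissociation constant (uM).
#' @param d_inh Ca2+ inactivation dissociation constant (uM); controls
#'   refractory behavior after a transient.
#' @param a inactivation time-scale parameter (1/s).
#' @param c0 total Ca2+ concentration (uM).
#' @param c1 store/cytosol volume ratio (dimensionless, 0 < c1 <= 1).
#' @param j_in constant plasma-membrane influx (uM/s); set to 0 for an
#'   isolated cell.
#' @param ci0 initial cytosolic Ca2+ (uM).
#' @param h0 initial value of the inactivation gate.
#' @return An object of class `ca_params` (a named list).
#' @examples
#' p <- model_parameters()
#' p$c0 / (1 + p$c1)   # cytosolic concentration at zero store gradient
#' @export
model_parameters <- function(p_ipx = 140, p_l = 0.05, v_store = 0.5,
                             k_store = 0.4, d_ipx = 0.1, d_act = 0.02,
                             d_inh = 0.04, a = 0.001, c0 = 7.5, c1 = 0.1,
                             j_in = 0.1, ci0 = 2, h0 = 0.1562) {
  p <- list(p_ipx = p_ipx, p_l = p_l, v_store = v_store, k_store = k_store,
            d_ipx = d_ipx, d_act = d_act, d_inh = d_inh, a = a,
            c0 = c0, c1 = c1, j_in = j_in, ci0 = ci0, h0 = h0)
  validate_parameters(p)
  structure(p, class = "ca_params")
}

validate_parameters <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p)) {
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a finite numeric scalar")
  }
  pos <- c("p_ipx", "p_l", "v_store", "k_store", "d_ipx", "d_act",
           "d_inh", "a", "c0")
  bad <- pos[vapply(pos, function(nm) p[[nm]] <= 0, logical(1))]
  if (length(bad)) stop("parameters must be > 0: ", paste(bad, collapse = ", "))
  if (p$j_in < 0) stop("j_in must be >= 0")
  if (p$c1 <= 0 || p$c1 > 1) stop("c1 must satisfy 0 < c1 <= 1")
  if (p$h0 < 0 || p$h0 > 1) stop("h0 must lie in [0, 1]")
  if (p$ci0 < 0 || p$ci0 > p$c0 / (1 + p$c1))
    stop("ci0 must lie in [0, c0/(1+c1)]")
  invisible(p)
}

#' @export
print.ca_params <- function(x, ...) {
  cat("Adapted Li-Rinzel model parameters (s, uM):\n")
  vals <- unlist(x)
  for (nm in names(vals)) cat(sprintf("  %-8s %g\n", nm, vals[[nm]]))
  invisible(x)
}

#' Read or write model parameters (YAML/JSON)
#'
#' Parameters round-trip through plain YAML or JSON files keyed by field
#' name; the format is chosen from the file extension.
#'
#' @param params a `ca_params` object.
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_parameters` returns `path` invisibly; `read_parameters`
#'   returns a `ca_params` object.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "ca_params"))
  x <- unclass(params)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported parameter file extension: ", path)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else stop("unsupported parameter file extension: ", path)
  do.call(model_parameters, x[names(x) %in% names(formals(model_parameters))])
}
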