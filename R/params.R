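#' Kinetic and fusion parameters of the two-step priming model
#'
#' Bundles all rate constants of the four-state docking scheme together with
#' the per-AP release parameters and the scaling from fractional release to
#' EPSC amplitude. Rates are first-order transition rates between the empty
#' (ES), loosely docked (LS), tightly docked (TS) and labile tightly docked
#' (TSL) states.
#'
#' @param b1 backward un-docking rate LS -> ES, 1/s.
#' @param k1_max saturating maximum of the Ca2+-dependent ES -> LS docking
#'   rate, 1/s. The rate follows a Michaelis-Menten form
#'   \code{k1_max * ca / (ca + K_M)}.
#' @param K_M half-saturation effective \[Ca2+\] of the ES -> LS rate, nM.
#' @param k2_0 LS -> TS forward priming rate at resting \[Ca2+\], 1/s.
#'   Together with \code{b2} it sets the resting tight-state fraction
#'   \code{TS/(TS+LS) = (k2_0/b2) / (1 + k2_0/b2)}.
#' @param s2 linear steepness of the Ca2+ dependence of the LS -> TS rate,
#'   1/(s nM); the rate is \code{max(0, k2_0 + s2 * (ca - ca_rest))}.
#' @param b2 backward rate TS -> LS, 1/s.
#' @param b3 decay time constant with which TSL relaxes back to LS, s.
#'   Note this is a time constant (decay rate \code{1/b3}), unlike b1/b2.
#' @param f_tsl fraction of LS vesicles transferred to TSL by each action
#'   potential, dimensionless in \[0, 1\].
#' @param p_fusion probability that a TS or TSL vesicle fuses upon an action
#'   potential, dimensionless in \[0, 1\].
#' @param n_sites total number of docking sites; scales fractional release to
#'   quantal content.
#' @param q quantal size: EPSC amplitude per released vesicle, pA.
#'
#' @return An object of class \code{"priming_params"} (a validated named
#'   list).
#' @seealso [calcium_params()], [fsin_params()], [olm_params()]
#' @export
#' @examples
#' p <- priming_params(b1 = 0.25, k1_max = 6, K_M = 500, k2_0 = 0.39,
#'                     s2 = 0.02, b2 = 0.5, b3 = 0.04, f_tsl = 0.2,
#'                     p_fusion = 0.6, n_sites = 24, q = 32)
#' p$k2_0 / p$b2  # resting TS/LS ratio
priming_params <- function(b1, k1_max, K_M, k2_0, s2, b2, b3, f_tsl,
                           p_fusion, n_sites = 24, q = 32) {
  p <- list(b1 = b1, k1_max = k1_max, K_M = K_M, k2_0 = k2_0, s2 = s2,
            b2 = b2, b3 = b3, f_tsl = f_tsl, p_fusion = p_fusion,
            n_sites = n_sites, q = q)
  validate_priming_params(p)
  structure(p, class = "priming_params")
}

validate_priming_params <- function(p) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
  }
  for (nm in names(p)) num1(p[[nm]], nm)
  pos <- c("b1", "k1_max", "K_M", "k2_0", "b2", "b3", "n_sites", "q")
  for (nm in pos) {
    if (p[[nm]] <= 0)
      stop(sprintf("'%s' must be strictly positive", nm), call. = FALSE)
  }
  if (p$s2 < 0) stop("'s2' must be non-negative", call. = FALSE)
  for (nm in c("f_tsl", "p_fusion")) {
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop(sprintf("'%s' must lie in [0, 1]", nm), call. = FALSE)
  }
  # in physiological fits TSL relaxation (b3) is much faster than TS
  # un-priming (1/b2); the converse makes the labile state outlive TS
  if (p$b3 >= 1 / p$b2)
    warning("b3 >= 1/b2: labile tight state decays slower than TS un-priming; ",
            "parameter set is not priming-hierarchy-consistent",
            call. = FALSE)
  invisible(p)
}

#' @export
print.priming_params <- function(x, ...) {
  cat("Two-step priming model parameters\n")
  cat(sprintf("  docking    : b1 = %g /s, k1_max = %g /s, K_M = %g nM\n",
              x$b1, x$k1_max, x$K_M))
  cat(sprintf("  priming    : k2_0 = %g /s, s2 = %g /(s nM), b2 = %g /s\n",
              x$k2_0, x$s2, x$b2))
  cat(sprintf("  labile TS  : f_tsl = %g per AP, b3 = %g s\n", x$f_tsl, x$b3))
  cat(sprintf("  release    : p_fusion = %g, n_sites = %g, q = %g pA\n",
              x$p_fusion, x$n_sites, x$q))
  cat(sprintf("  resting TS fraction k2_0/(k2_0 + b2) ... %.3f\n",
              (x$k2_0 / x$b2) / (1 + x$k2_0 / x$b2)))
  invisible(x)
}

#' Effective calcium dynamics parameters
#'
#' The model drives its Ca2+-dependent priming rates with a spatially
#' averaged "effective" \[Ca2+\]: a resting level plus a fixed increment per
#' action potential that decays exponentially. The resting level (50 nM) and
#' per-AP increment (110 nM; 168 nM when AP broadening by 4-AP is modelled)
#' are the constrained values used throughout; the decay time constant is a
#' model choice.
#'
#' @param ca_rest resting effective \[Ca2+\], nM.
#' @param delta_ca increment of effective \[Ca2+\] per action potential, nM.
#' @param tau_ca exponential decay time constant of each increment, s.
#' @return An object of class \code{"calcium_params"}.
#' @export
#' @examples
#' calcium_params()
calcium_params <- function(ca_rest = 50, delta_ca = 110, tau_ca = 0.1) {
  if (!is.numeric(ca_rest) || length(ca_rest) != 1L || ca_rest < 0)
    stop("'ca_rest' must be a single non-negative number")
  if (!is.numeric(delta_ca) || length(delta_ca) != 1L || delta_ca < 0)
    stop("'delta_ca' must be a single non-negative number")
  if (!is.numeric(tau_ca) || length(tau_ca) != 1L || tau_ca <= 0)
    stop("'tau_ca' must be a single positive number")
  structure(list(ca_rest = ca_rest, delta_ca = delta_ca, tau_ca = tau_ca),
            class = "calcium_params")
}

#' @export
print.calcium_params <- function(x, ...) {
  cat(sprintf(
    "Effective [Ca2+]: rest %g nM, +%g nM per AP, tau = %g s\n",
    x$ca_rest, x$delta_ca, x$tau_ca))
  invisible(x)
}

#' Reference parameter sets for the two connection types
#'
#' `fsin_params()` returns the depressing, high-release-probability
#' configuration characteristic of pyramidal cell to fast-spiking
#' interneuron connections: resting tight-state fraction 0.44, fusion
#' probability 0.6, first response about 5 quanta of 32 pA (160 pA).
#' `olm_params()` returns the facilitating, low-release-probability
#' configuration of pyramidal cell to O-LM interneuron connections: resting
#' tight-state fraction 0.07, fusion probability 0.36, first response about
#' 0.5 quanta. The two sets differ only in `k2_0`, `s2` (both about 10-fold
#' lower at O-LM) and `p_fusion`; all other constants are shared.
#'
#' `k2_0` is tied to `b2` by the resting tight-state fraction
#' (`k2_0 = b2 * f/(1 - f)`), and the O-LM `s2` is scaled down by the same
#' factor as `k2_0`.
#'
#' @return A [priming_params()] object.
#' @export
#' @examples
#' ts_fraction(resting_state(fsin_params()))
fsin_params <- function() {
  priming_params(
    b1 = 0.25, k1_max = 6, K_M = 500,
    k2_0 = 0.5 * 0.44 / 0.56, s2 = 0.02, b2 = 0.5,
    b3 = 0.04, f_tsl = 0.2, p_fusion = 0.6,
    n_sites = 24, q = 32)
}

#' @rdname fsin_params
#' @export
olm_params <- function() {
  k2_fsin <- 0.5 * 0.44 / 0.56
  k2_olm <- 0.5 * 0.07 / 0.93
  priming_params(
    b1 = 0.25, k1_max = 6, K_M = 500,
    k2_0 = k2_olm, s2 = 0.02 * k2_olm / k2_fsin, b2 = 0.5,
    b3 = 0.04, f_tsl = 0.2, p_fusion = 0.36,
    n_sites = 28, q = 32)
}

#' Names of the kinetic/fusion parameters that may be freed during fitting
#'
#' Site count and quantal size stay fixed during fitting (data are
#' pre-scaled to quanta), as do the calcium parameters.
#'
#' @return Character vector of parameter names.
#' @export
fittable_params <- function() {
  c("b1", "k1_max", "K_M", "k2_0", "s2", "b2", "b3", "f_tsl", "p_fusion")
}

#' Default box bounds for parameter fitting
#'
#' Rates are bounded in \[1e-3, 1e3\] /s, the half-saturation concentration
#' in \[1, 1e4\] nM, the labile-state time constant in \[1e-3, 1\] s and
#' fractions/probabilities in \[0, 1\]. The shared scaling factor used by
#' [scaled_fit()] is bounded in \[1e-3, 1e3\].
#'
#' @return A named list with elements \code{lower} and \code{upper}.
#' @export
priming_bounds <- function() {
  lower <- c(b1 = 1e-3, k1_max = 1e-3, K_M = 1, k2_0 = 1e-3, s2 = 1e-3,
             b2 = 1e-3, b3 = 1e-3, f_tsl = 0, p_fusion = 0, k2_scale = 1e-3)
  upper <- c(b1 = 1e3, k1_max = 1e3, K_M = 1e4, k2_0 = 1e3, s2 = 1e3,
             b2 = 1e3, b3 = 1, f_tsl = 1, p_fusion = 1, k2_scale = 1e3)
  list(lower = lower, upper = upper)
}

param_units <- function() {
  c(b1 = "1/s", k1_max = "1/s", K_M = "nM", k2_0 = "1/s", s2 = "1/(s*nM)",
    b2 = "1/s", b3 = "s", f_tsl = "fraction", p_fusion = "probability",
    n_sites = "count", q = "pA")
}

#' Read and write model parameter files
#'
#' Parameters are stored as flat JSON with the exact field names of
#' [priming_params()] plus a sibling \code{"units"} block documenting units.
#' Unknown keys are rejected.
#'
#' @param path file path.
#' @param params a [priming_params()] object.
#' @return `read_priming_params()` returns a [priming_params()] object;
#'   `write_priming_params()` returns `path` invisibly.
#' @export
read_priming_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$units <- NULL
  known <- c("b1", "k1_max", "K_M", "k2_0", "s2", "b2", "b3", "f_tsl",
             "p_fusion", "n_sites", "q")
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop("unknown parameter keys in ", path, ": ",
         paste(extra, collapse = ", "))
  missing <- setdiff(known, names(x))
  if (length(missing))
    stop("missing parameter keys in ", path, ": ",
         paste(missing, collapse = ", "))
  do.call(priming_params, as.list(x[known]))
}

#' @rdname read_priming_params
#' @export
write_priming_params <- function(params, path) {
  stopifnot(inherits(params, "priming_params"))
  out <- c(unclass(params), list(units = as.list(param_units())))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
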