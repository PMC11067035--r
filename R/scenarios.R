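#' Pharmacology scenario constraints
#'
#' `apply_4ap()` encodes the action of the K+-channel blocker
#' 4-aminopyridine, which broadens presynaptic action potentials and raises
#' AP-evoked calcium influx: the per-AP effective \[Ca2+\] increment is set
#' from 110 nM to 168 nM while the resting \[Ca2+\] stays at 50 nM and the
#' decay time constant is unchanged. Applied to a [fit_problem()] it swaps
#' the calcium parameters and leaves everything else untouched. The
#' transformation is pure (inputs are never modified) and idempotent.
#'
#' `apply_pdbu_constraints()` encodes the phorbol-ester (PDBU) fitting
#' constraint: PDBU enhances priming without changing AP-evoked calcium, so
#' the calcium parameters are clamped to the control condition and all
#' priming/fusion parameters are left free.
#'
#' @param x a [calcium_params()] object or a [fit_problem()].
#' @return An object of the same type with the scenario constraint applied.
#' @export
#' @examples
#' apply_4ap(calcium_params())$delta_ca  # 168
apply_4ap <- function(x) {
  if (inherits(x, "calcium_params")) {
    return(calcium_params(ca_rest = x$ca_rest, delta_ca = 168,
                          tau_ca = x$tau_ca))
  }
  if (inherits(x, "fit_problem")) {
    x$cap <- apply_4ap(x$cap)
    return(x)
  }
  stop("'x' must be calcium_params or a fit_problem")
}

#' @param problem a [fit_problem()].
#' @param control_cap the control-condition [calcium_params()].
#' @rdname apply_4ap
#' @export
apply_pdbu_constraints <- function(problem,
                                   control_cap = calcium_params()) {
  stopifnot(inherits(problem, "fit_problem"))
  problem$cap <- control_cap
  problem$free <- fittable_params()
  problem
}
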