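#' Calcium-dependent transition rates
#'
#' `k1_rate()` is the ES -> LS docking rate with Michaelis-Menten-like
#' saturation, \code{k1_max * ca / (ca + K_M)}: zero at zero calcium, half
#' of `k1_max` at `ca = K_M`, saturating at `k1_max`. `k2_rate()` is the
#' LS -> TS priming rate with a linear calcium dependence about rest floored
#' at zero, \code{max(0, k2_0 + s2 * (ca - ca_rest))}; at resting calcium it
#' equals `k2_0`.
#'
#' @param ca effective \[Ca2+\], nM (vectorized, non-negative).
#' @param params a [priming_params()] object.
#' @param ca_rest resting effective \[Ca2+\], nM.
#' @return Rate(s), 1/s.
#' @export
#' @examples
#' p <- fsin_params()
#' k1_rate(c(0, p$K_M, 1e9), p)        # 0, k1_max/2, ~k1_max
#' k2_rate(50, p, ca_rest = 50)        # k2_0
k1_rate <- function(ca, params) {
  if (any(!is.finite(ca)) || any(ca < 0))
    stop("'ca' must be non-negative and finite")
  params$k1_max * ca / (ca + params$K_M)
}

#' @rdname k1_rate
#' @export
k2_rate <- function(ca, params, ca_rest = 50) {
  if (any(!is.finite(ca)) || any(ca < 0))
    stop("'ca' must be non-negative and finite")
  pmax(0, params$k2_0 + params$s2 * (ca - ca_rest))
}

#' Effective calcium concentration along a stimulus train
#'
#' Linear superposition of per-AP increments decaying exponentially:
#' \code{ca_rest + sum_(t_j <= t) delta_ca * exp(-(t - t_j)/tau_ca)}. The
#' increment of an AP is included from the AP time onwards (inclusive), i.e.
#' immediately after a single AP the trace reads
#' \code{ca_rest + delta_ca}.
#'
#' @param t time(s) at which to evaluate the trace, s (vectorized).
#' @param ap_times strictly increasing action potential times, s.
#' @param cap a [calcium_params()] object.
#' @return Effective \[Ca2+\] at `t`, nM.
#' @export
#' @examples
#' ca_trace(c(0.005, 0.01), ap_times = c(0, 0.01), cap = calcium_params())
ca_trace <- function(t, ap_times, cap = calcium_params()) {
  if (length(ap_times) && any(diff(ap_times) <= 0))
    stop("'ap_times' must be strictly increasing")
  vapply(t, function(ti) {
    past <- ap_times[ap_times <= ti]
    cap$ca_rest + sum(cap$delta_ca * exp(-(ti - past) / cap$tau_ca))
  }, numeric(1))
}

# Ca2+ trace on a regular grid t = 0, dt, ..., K*dt with APs at grid indices
# ap_steps (0-based). Uses the exact recursion exc[k+1] = exc[k]*exp(-dt/tau)
# + delta at AP steps, which matches ca_trace() to floating-point error.
ca_grid <- function(ap_steps, n_steps, dt, cap) {
  imp <- numeric(n_steps + 1L)
  imp[ap_steps + 1L] <- imp[ap_steps + 1L] + cap$delta_ca
  exc <- as.numeric(stats::filter(imp, exp(-dt / cap$tau_ca),
                                  method = "recursive"))
  cap$ca_rest + exc
}
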