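#' Docking-state occupancy vector
#'
#' Fractional occupancies of the four docking states: empty sites (es),
#' loosely docked (ls), tightly docked (ts) and labile tightly docked (tsl).
#' Components must lie in \[0, 1\] and sum to 1 within 1e-9.
#'
#' @param es,ls,ts,tsl fractional occupancies.
#' @return A named numeric vector of class \code{"state_vector"}.
#' @export
#' @examples
#' state_vector(es = 0.2, ls = 0.5, ts = 0.3)
state_vector <- function(es, ls, ts, tsl = 0) {
  s <- c(es = es, ls = ls, ts = ts, tsl = tsl)
  if (any(!is.finite(s)) || any(s < -1e-12) || any(s > 1 + 1e-12))
    stop("occupancies must lie in [0, 1]")
  if (abs(sum(s) - 1) > 1e-9)
    stop("occupancies must sum to 1 (tolerance 1e-9)")
  structure(s, class = "state_vector")
}

as_state <- function(s) {
  structure(c(es = unname(s[1]), ls = unname(s[2]), ts = unname(s[3]),
              tsl = unname(s[4])), class = "state_vector")
}

#' Time derivative of the docking-state occupancies
#'
#' Continuous inter-AP kinetics of the four-state scheme: docking
#' ES <-> LS at rates k1(ca)/b1, priming LS <-> TS at rates k2(ca)/b2, and
#' first-order relaxation of TSL back to LS with time constant b3. The
#' component sum of the returned derivative is exactly zero (occupancy
#' conservation).
#'
#' @param state a [state_vector()].
#' @param ca effective \[Ca2+\], nM.
#' @param params a [priming_params()] object.
#' @param cap a [calcium_params()] object (supplies the resting \[Ca2+\]
#'   about which the k2 calcium dependence is anchored).
#' @return Named numeric vector \code{(es, ls, ts, tsl)} of rates, 1/s.
#' @export
state_derivative <- function(state, ca, params, cap = calcium_params()) {
  k1 <- k1_rate(ca, params)
  k2 <- k2_rate(ca, params, cap$ca_rest)
  es <- state[["es"]]; ls <- state[["ls"]]
  ts <- state[["ts"]]; tsl <- state[["tsl"]]
  d_es <- -k1 * es + params$b1 * ls
  d_ls <- k1 * es - (params$b1 + k2) * ls + params$b2 * ts + tsl / params$b3
  d_ts <- k2 * ls - params$b2 * ts
  d_tsl <- -tsl / params$b3
  c(es = d_es, ls = d_ls, ts = d_ts, tsl = d_tsl)
}

#' Integrate the docking-state kinetics over an interval
#'
#' Fixed-step integration of [state_derivative()] under an arbitrary
#' calcium trace. Euler's method is the reference scheme used throughout the
#' package; a classical Runge-Kutta 4 scheme is provided as an independent
#' cross-check.
#'
#' @param state starting [state_vector()].
#' @param ca_fn function of time (s) returning effective \[Ca2+\] (nM).
#' @param duration integration time, s (>= 0).
#' @param dt step size, s.
#' @param method `"euler"` or `"rk4"`.
#' @param params,cap model parameters.
#' @param t0 time origin passed to `ca_fn`, s.
#' @return The evolved [state_vector()].
#' @export
#' @examples
#' p <- fsin_params(); cap <- calcium_params()
#' s <- resting_state(p, cap)
#' evolve(s, function(t) cap$ca_rest, duration = 1, dt = 1e-3,
#'        params = p, cap = cap)
evolve <- function(state, ca_fn, duration, dt = 1e-4,
                   method = c("euler", "rk4"), params, cap = calcium_params(),
                   t0 = 0) {
  method <- match.arg(method)
  stopifnot(duration >= 0, dt > 0)
  if (duration == 0) return(as_state(state))
  n <- max(1L, round(duration / dt))
  dt <- duration / n  # land exactly on the end point
  s <- unclass(state)
  deriv <- function(s, t) state_derivative(as_state(s), ca_fn(t), params, cap)
  t <- t0
  for (i in seq_len(n)) {
    if (method == "euler") {
      s <- s + dt * deriv(s, t)
    } else {
      d1 <- deriv(s, t)
      d2 <- deriv(s + dt / 2 * d1, t + dt / 2)
      d3 <- deriv(s + dt / 2 * d2, t + dt / 2)
      d4 <- deriv(s + dt * d3, t + dt)
      s <- s + dt / 6 * (d1 + 2 * d2 + 2 * d3 + d4)
    }
    t <- t0 + i * dt
    if (any(s < -1e-9) || any(s > 1 + 1e-9))
      stop("state occupancy left [0, 1] during integration; reduce dt")
  }
  drift <- sum(s) - 1
  if (abs(drift) > 1e-9)
    stop("occupancy conservation drifted beyond 1e-9; reduce dt")
  as_state(s / sum(s))
}

#' Instantaneous per-AP release and labile-state transfer
#'
#' Applied at each action potential time, in this order: (1) a fraction
#' `p_fusion` of TS and TSL vesicles fuses; fused vesicles vacate their
#' sites, which return to ES; (2) a fraction `f_tsl` of the remaining LS
#' vesicles is transferred to the labile tight state TSL. Transfer after
#' release means vesicles entering TSL cannot fuse on the same AP. Total
#' occupancy is conserved exactly.
#'
#' @param state a [state_vector()].
#' @param params a [priming_params()] object.
#' @return A list with `state` (post-AP [state_vector()]) and `released`
#'   (fused fraction of all sites, dimensionless).
#' @export
#' @examples
#' p <- fsin_params()
#' apply_ap(resting_state(p), p)$released  # p_fusion * resting TS occupancy
apply_ap <- function(state, params) {
  es <- state[["es"]]; ls <- state[["ls"]]
  ts <- state[["ts"]]; tsl <- state[["tsl"]]
  released <- params$p_fusion * (ts + tsl)
  es <- es + released
  ts <- ts * (1 - params$p_fusion)
  tsl <- tsl * (1 - params$p_fusion)
  moved <- params$f_tsl * ls
  ls <- ls - moved
  tsl <- tsl + moved
  list(state = as_state(c(es, ls, ts, tsl)), released = released)
}

#' Resting steady state of the docking scheme
#'
#' Closed-form fixed point at resting calcium: TSL is empty,
#' \code{ts/ls = k2_0/b2} and \code{ls/es = k1(ca_rest)/b1}, normalized to
#' total occupancy 1.
#'
#' @param params a [priming_params()] object.
#' @param cap a [calcium_params()] object.
#' @return A [state_vector()].
#' @export
#' @examples
#' ts_fraction(resting_state(fsin_params()))  # 0.44
resting_state <- function(params, cap = calcium_params()) {
  if (params$b1 == 0 || params$b2 == 0)
    stop("degenerate equilibrium: b1 and b2 must be non-zero")
  r1 <- k1_rate(cap$ca_rest, params) / params$b1
  r2 <- params$k2_0 / params$b2
  v <- c(es = 1, ls = r1, ts = r1 * r2, tsl = 0)
  as_state(v / sum(v))
}

#' Tight-state fraction
#'
#' The proportion of docked vesicles that are fusion-competent at rest:
#' \code{TS / (TS + LS)}. With the O-LM fit this is 0.07; with the FSIN fit
#' 0.44. Multiplied by the fusion probability it gives the vesicular release
#' probability (see [pv()]).
#'
#' @param state a [state_vector()].
#' @return A fraction in \[0, 1\].
#' @export
ts_fraction <- function(state) {
  denom <- state[["ts"]] + state[["ls"]]
  if (denom <= 0) stop("undefined tight-state fraction: ts + ls = 0")
  state[["ts"]] / denom
}
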