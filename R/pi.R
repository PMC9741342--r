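# Discrete PI cadence controller with output saturation and anti-windup.

#' PI controller state
#'
#' A proportional-integral controller shared across stimulation channels: its
#' output `u` (mA) is added to every enabled channel's working amplitude
#' before clipping at the amplitude ceiling. Discrete forward-Euler
#' integration at the control rate; when the output saturates and anti-windup
#' is on, the integrator freezes (conditional integration).
#'
#' Default gains were tuned once against the default synthetic M1 plant so
#' that closed-loop cadence settles within +/-1 rpm of a 35 rpm reference in
#' under 30 s and holds it with fatigue disabled.
#'
#' @param kp Proportional gain (mA per rpm).
#' @param ki Integral gain (mA per rpm s).
#' @param u_max Output ceiling (mA); headroom so baseline + u stays near the
#'   amplitude ceiling (any remainder is clipped at command level).
#' @param anti_windup Freeze the integrator while the output is clipped.
#' @return An object of class `fes_pi` with accumulator `integral` (rpm s)
#'   and last output `u` (mA).
#' @export
pi_config <- function(kp = 2, ki = 0.6, u_max = 55, anti_windup = TRUE) {
  stopifnot(kp >= 0, ki >= 0, u_max > 0)
  structure(list(kp = kp, ki = ki, u_max = u_max,
                 anti_windup = isTRUE(anti_windup),
                 integral = 0, u = 0), class = "fes_pi")
}

#' One PI update
#'
#' Computes the cadence error `e = reference - measured`, integrates it, and
#' returns the updated state with output
#' `u = clip(kp e + ki int e dt, 0, u_max)`. With anti-windup the integrator
#' only commits when the unclipped output lies inside the output range.
#'
#' @param state An [pi_config()] state.
#' @param reference_rpm Reference cadence (rpm).
#' @param measured_rpm Measured cadence (rpm).
#' @param dt Time step (s), positive.
#' @return The updated `fes_pi` state; the output is in `$u`.
#' @export
pi_step <- function(state, reference_rpm, measured_rpm, dt) {
  stopifnot(dt > 0)
  e <- reference_rpm - measured_rpm
  int_new <- state$integral + e * dt
  u_raw <- state$kp * e + state$ki * int_new
  if (u_raw > state$u_max) {
    state$u <- state$u_max
    if (!state$anti_windup) state$integral <- int_new
  } else if (u_raw < 0) {
    state$u <- 0
    if (!state$anti_windup) state$integral <- int_new
  } else {
    state$u <- u_raw
    state$integral <- int_new
  }
  state
}
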