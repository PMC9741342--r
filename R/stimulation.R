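# Stimulation channels, the agent's action set, admissibility rules and
# injected-charge accounting.

# The delta multipliers the agent may apply to a pulse parameter.
.D3 <- c(-0.5, 0, 1)

#' Stimulation channel configuration
#'
#' One stimulation channel: a muscle group (VM, VL+RF or HAM on one side),
#' its baseline pulse parameters and the crank-angle window within which it
#' stimulates. Six channels (ids 0-5) cover both legs.
#'
#' @param channel_id Integer 0-5.
#' @param muscle_label Text label, e.g. `"R_VL+RF"`.
#' @param amplitude_mA Baseline pulse amplitude in mA, within `[0, 100]`.
#' @param width_us Baseline pulse width in microseconds.
#' @param frequency_hz Pulse frequency in Hz (constant during a session).
#' @param theta_start,theta_end Stimulation window in degrees, each in
#'   `[0, 360)`. Windows with `theta_start > theta_end` wrap through 0.
#' @param enabled Is the channel active?
#' @param limits A [parameter_limits()] object used for validation.
#' @return An object of class `fes_channel`.
#' @examples
#' channel_config(0, "R_VL+RF", 45, 500, 35, 330, 90)
#' @export
channel_config <- function(channel_id, muscle_label, amplitude_mA, width_us,
                           frequency_hz = 35, theta_start = 0, theta_end = 359.99,
                           enabled = TRUE, limits = parameter_limits()) {
  stopifnot(length(channel_id) == 1, channel_id >= 0, channel_id == as.integer(channel_id))
  if (amplitude_mA < 0 || amplitude_mA > limits$max_amplitude_mA)
    stop("amplitude_mA must lie in [0, ", limits$max_amplitude_mA, "] mA")
  if (width_us < limits$width_min_us || width_us > limits$width_max_us)
    stop("width_us must lie in [", limits$width_min_us, ", ", limits$width_max_us, "] us")
  if (frequency_hz <= 0) stop("frequency_hz must be positive")
  if (theta_start < 0 || theta_start >= 360 || theta_end < 0 || theta_end >= 360)
    stop("window angles must lie in [0, 360)")
  structure(list(
    channel_id = as.integer(channel_id), muscle_label = as.character(muscle_label),
    amplitude_mA = as.numeric(amplitude_mA), width_us = as.numeric(width_us),
    frequency_hz = as.numeric(frequency_hz),
    theta_start = as.numeric(theta_start), theta_end = as.numeric(theta_end),
    enabled = isTRUE(enabled)
  ), class = "fes_channel")
}

#' Pulse-parameter limits and agent step sizes
#'
#' Hard bounds for pulse amplitude and width, the allowed excursion of the
#' agent-controlled baseline around its initial setting, and the per-action
#' step sizes. Defaults follow the deployed protocol: 100 mA amplitude
#' ceiling, 450-600 us width, +/-10 mA baseline excursion, steps of 2 mA and
#' 20 us per action unit.
#'
#' @param max_amplitude_mA Amplitude ceiling Ma (mA).
#' @param width_min_us,width_max_us Hard pulse-width bounds (us).
#' @param delta_a_mA Allowed excursion of the agent-adjusted amplitude
#'   baseline around the session's initial baseline (mA). The PI contribution
#'   is not limited by this, only by `max_amplitude_mA`.
#' @param delta_w_us Informational width excursion (us); the hard bounds
#'   `width_min_us`/`width_max_us` govern.
#' @param step_a_mA,step_w_us Step sizes k_a (mA) and k_w (us) multiplying the
#'   action components.
#' @return An object of class `fes_limits`.
#' @export
parameter_limits <- function(max_amplitude_mA = 100, width_min_us = 450,
                             width_max_us = 600, delta_a_mA = 10,
                             delta_w_us = 100, step_a_mA = 2, step_w_us = 20) {
  stopifnot(width_min_us < width_max_us, step_a_mA > 0, step_w_us > 0,
            delta_a_mA >= 0, delta_w_us >= 0, max_amplitude_mA > 0)
  structure(list(
    max_amplitude_mA = max_amplitude_mA, width_min_us = width_min_us,
    width_max_us = width_max_us, delta_a_mA = delta_a_mA, delta_w_us = delta_w_us,
    step_a_mA = step_a_mA, step_w_us = step_w_us
  ), class = "fes_limits")
}

#' An agent action: a pair of delta multipliers
#'
#' An action is a pair `(alpha, omega)` of multipliers drawn from
#' `D3 = {-0.5, 0, 1}`; `alpha` scales the amplitude step and `omega` the
#' width step. `(0, 0)` is the no-op.
#'
#' @param alpha,omega Multipliers, each one of -0.5, 0, 1.
#' @return A named numeric vector of class `fes_action`.
#' @export
fes_action <- function(alpha, omega) {
  if (!(alpha %in% .D3) || !(omega %in% .D3))
    stop("action components must be drawn from {-0.5, 0, 1}")
  structure(c(alpha = alpha, omega = omega), class = "fes_action")
}

#' Enumerate the agent's action set
#'
#' Enumerates all `3^n_params` delta combinations over `D3 = {-0.5, 0, 1}` in
#' lexicographic order (first component varies slowest, components ordered
#' -0.5, 0, 1). Indices are 1-based and stable across runs; for the default
#' two parameters the set has 9 actions and the no-op `(0, 0)` sits at
#' index 5. With three parameters (amplitude, width, frequency) the set grows
#' to 27, though the default agent leaves frequency constant.
#'
#' @param n_params Number of pulse parameters the agent may change (>= 1).
#' @return A data frame with one row per action; columns `alpha`, `omega`
#'   (and `gamma` for a third parameter).
#' @examples
#' nrow(enumerate_actions(2))  # 9
#' @export
enumerate_actions <- function(n_params = 2) {
  if (length(n_params) != 1 || is.na(n_params) || n_params < 1 ||
      n_params != as.integer(n_params))
    stop("n_params must be a positive integer")
  n_params <- as.integer(n_params)
  nm <- if (n_params <= 3) c("alpha", "omega", "gamma")[seq_len(n_params)]
        else paste0("d", seq_len(n_params))
  g <- expand.grid(rev(rep(list(.D3), n_params)), KEEP.OUT.ATTRS = FALSE)
  g <- g[, rev(seq_len(n_params)), drop = FALSE]  # first column slowest
  names(g) <- nm
  rownames(g) <- NULL
  g
}

# 1-based index of the all-zero action in enumerate_actions(n)
.noop_index <- function(n_params = 2) (3L^as.integer(n_params) + 1L) %/% 2L

# Coerce an action given as fes_action / numeric pair / index into c(alpha, omega)
.as_action <- function(action, actions = NULL) {
  if (inherits(action, "fes_action")) return(unclass(action))
  if (is.numeric(action) && length(action) == 1 && !is.null(actions))
    return(c(alpha = actions$alpha[action], omega = actions$omega[action]))
  if (is.numeric(action) && length(action) >= 2)
    return(c(alpha = action[[1]], omega = action[[2]]))
  stop("cannot interpret action")
}

#' Is an action admissible for a channel?
#'
#' The agent must obey two selection rules: (1) the resulting parameters must
#' stay within range - amplitude within the excursion band
#' `[a0 - delta_a, a0 + delta_a]` intersected with `[0, Ma]`, width within the
#' hard bounds; and (2) when the delivered amplitude is saturated at the
#' ceiling (the PI controller has no headroom left), the pulse width must not
#' be reduced - increasing it remains allowed.
#'
#' @param channel A [channel_config()] holding the current baseline.
#' @param action An [fes_action()], numeric pair, or 1-based index into
#'   [enumerate_actions()].
#' @param limits A [parameter_limits()].
#' @param initial_amplitude_mA The session's initial baseline amplitude a0
#'   anchoring the excursion band (defaults to the channel's current value).
#' @param amplitude_saturated Is the delivered amplitude pinned at the ceiling?
#' @return `TRUE` or `FALSE`.
#' @export
is_admissible <- function(channel, action, limits = parameter_limits(),
                          initial_amplitude_mA = channel$amplitude_mA,
                          amplitude_saturated = FALSE) {
  act <- .as_action(action, enumerate_actions(2))
  a2 <- channel$amplitude_mA + act[["alpha"]] * limits$step_a_mA
  w2 <- channel$width_us + act[["omega"]] * limits$step_w_us
  lo_a <- max(0, initial_amplitude_mA - limits$delta_a_mA)
  hi_a <- min(limits$max_amplitude_mA, initial_amplitude_mA + limits$delta_a_mA)
  tol <- 1e-9
  ok <- a2 >= lo_a - tol && a2 <= hi_a + tol &&
    w2 >= limits$width_min_us - tol && w2 <= limits$width_max_us + tol
  if (amplitude_saturated && act[["omega"]] < 0) ok <- FALSE
  ok
}

#' Admissible subset of the action set for a channel
#'
#' Vectorized form of [is_admissible()] over a whole action table. The no-op
#' `(0, 0)` is always admissible, so the returned mask is never all-`FALSE`.
#'
#' @inheritParams is_admissible
#' @param actions The action table, as from [enumerate_actions()].
#' @return Logical vector, one entry per action.
#' @export
admissible_actions <- function(channel, limits = parameter_limits(),
                               initial_amplitude_mA = channel$amplitude_mA,
                               amplitude_saturated = FALSE,
                               actions = enumerate_actions(2)) {
  .admissible_mask(channel$amplitude_mA, channel$width_us, initial_amplitude_mA,
                   limits, amplitude_saturated, actions)
}

# Fast internal mask on raw numerics (used every interaction boundary).
.admissible_mask <- function(base_a, base_w, a0, limits, saturated, actions) {
  a2 <- base_a + actions$alpha * limits$step_a_mA
  w2 <- base_w + actions$omega * limits$step_w_us
  lo_a <- max(0, a0 - limits$delta_a_mA)
  hi_a <- min(limits$max_amplitude_mA, a0 + limits$delta_a_mA)
  tol <- 1e-9
  ok <- a2 >= lo_a - tol & a2 <= hi_a + tol &
    w2 >= limits$width_min_us - tol & w2 <= limits$width_max_us + tol
  if (saturated) ok <- ok & actions$omega >= 0
  ok
}

#' Apply an admissible action to a channel baseline
#'
#' Returns a copy of the channel with
#' `amplitude' = amplitude + alpha * k_a` and `width' = width + omega * k_w`;
#' frequency and angle window are untouched and the input channel is not
#' modified. An inadmissible action raises a condition of class
#' `fescycle_inadmissible` - the caller is expected to resample.
#'
#' @inheritParams is_admissible
#' @return A new `fes_channel`.
#' @examples
#' lim <- parameter_limits(step_a_mA = 1, step_w_us = 20)
#' ch <- channel_config(2, "R_HAM", 45, 500)
#' ch2 <- apply_action(ch, fes_action(1, -0.5), lim)
#' c(ch2$amplitude_mA, ch2$width_us)  # 46, 490
#' @export
apply_action <- function(channel, action, limits = parameter_limits(),
                         initial_amplitude_mA = channel$amplitude_mA,
                         amplitude_saturated = FALSE) {
  act <- .as_action(action, enumerate_actions(2))
  if (!is_admissible(channel, act, limits, initial_amplitude_mA, amplitude_saturated))
    stop(structure(class = c("fescycle_inadmissible", "error", "condition"),
                   list(message = sprintf(
                     "action (%g, %g) is inadmissible for channel %d",
                     act[["alpha"]], act[["omega"]], channel$channel_id),
                     call = sys.call(-1))))
  channel$amplitude_mA <- channel$amplitude_mA + act[["alpha"]] * limits$step_a_mA
  channel$width_us <- channel$width_us + act[["omega"]] * limits$step_w_us
  channel
}

#' Injected charge rate of a pulse train
#'
#' Charge per second delivered by a rectangular pulse train:
#' `amplitude x width` gives the single-phase charge per pulse (mA x us = nC),
#' multiplied by the frequency and expressed in uC/s. The stimulation pulses
#' are symmetric biphasic; by convention only the leading phase counts toward
#' "injected charge" (the second phase is charge-balanced). Set `phases = 2`
#' to count both.
#'
#' @param amplitude_mA Pulse amplitude (mA), vectorized.
#' @param width_us Pulse width (us), vectorized.
#' @param frequency_hz Pulse frequency (Hz), vectorized.
#' @param phases 1 (default) or 2 phases counted.
#' @return Charge rate in microcoulombs per second.
#' @examples
#' pulse_charge_rate(45, 500, 35)  # 787.5 uC/s
#' @export
pulse_charge_rate <- function(amplitude_mA, width_us, frequency_hz, phases = 1L) {
  if (any(amplitude_mA < 0) || any(width_us < 0) || any(frequency_hz < 0))
    stop("amplitude, width and frequency must be non-negative")
  amplitude_mA * width_us * frequency_hz * phases / 1000
}

#' Is a crank angle inside a stimulation window?
#'
#' Windows are closed at both ends; windows whose start exceeds their end wrap
#' through 0/360 degrees (common for muscle groups straddling top dead
#' center).
#'
#' @param theta Crank angle(s) in degrees, `[0, 360)`.
#' @param theta_start Window start in degrees, or an `fes_channel` (in which
#'   case its window is used and `theta_end` is ignored).
#' @param theta_end Window end in degrees.
#' @return Logical vector along `theta`.
#' @export
in_window <- function(theta, theta_start, theta_end = NULL) {
  if (inherits(theta_start, "fes_channel")) {
    theta_end <- theta_start$theta_end
    theta_start <- theta_start$theta_start
  }
  if (theta_start <= theta_end) theta >= theta_start & theta <= theta_end
  else theta >= theta_start | theta <= theta_end
}

#' Build the stimulation command delivered to one channel
#'
#' Combines the channel's working parameters (baseline plus any temporary
#' agent delta) with the shared PI amplitude contribution, clips to the
#' physical limits, and flags whether the crank currently sits inside the
#' channel's window.
#'
#' @param channel A [channel_config()] carrying the working parameters.
#' @param theta Current crank angle (degrees).
#' @param pi_u_mA PI amplitude contribution (mA), added before clipping.
#' @param limits A [parameter_limits()].
#' @return A list of class `fes_command` with fields `channel_id`,
#'   `amplitude_mA`, `width_us`, `frequency_hz`, `enabled`, `active`,
#'   `theta_start`, `theta_end`.
#' @export
stimulation_command <- function(channel, theta, pi_u_mA = 0,
                                limits = parameter_limits()) {
  amp <- min(max(channel$amplitude_mA + pi_u_mA, 0), limits$max_amplitude_mA)
  wid <- min(max(channel$width_us, limits$width_min_us), limits$width_max_us)
  structure(list(
    channel_id = channel$channel_id, amplitude_mA = amp, width_us = wid,
    frequency_hz = channel$frequency_hz, enabled = channel$enabled,
    active = channel$enabled && in_window(theta, channel),
    theta_start = channel$theta_start, theta_end = channel$theta_end
  ), class = "fes_command")
}
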