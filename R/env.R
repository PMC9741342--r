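# Synthetic cycling environment: angle-gated, charge-driven torque with
# progressive fatigue, first-order crank dynamics and an encoder model.

#' Synthetic cycling-environment configuration
#'
#' A deliberately simple stand-in for the rider + tricycle, built to exercise
#' the controller rather than to be a validated musculoskeletal model. Each
#' channel contributes torque through a raised-cosine angle profile scaled by
#' a piecewise-linear recruitment of its injected charge rate and by a scalar
#' fitness state that fatigues under activation and recovers at rest:
#' `dphi/dt = -lambda act (phi - phi_min) + rho (1 - phi) (1 - act)`.
#' The crank obeys `J dw/dt = sum(act_c g_c(theta)) - b w - tau_load`,
#' integrated semi-implicitly with sub-stepping, cadence floored at zero.
#'
#' Two gear-ratio presets are provided via [env_preset()]: `m1` and the
#' heavier `m2` (larger load torque), calibrated so that a PI-only session on
#' `m2` saturates the amplitude ceiling within a 20-40 simulated-minute ride.
#'
#' @param J Crank inertia (kg m^2).
#' @param b Viscous damping (N m s/rad).
#' @param tau_load Constant load torque opposing motion (N m).
#' @param center,half_width,peak Per-channel raised-cosine torque profiles:
#'   bump centers (deg), half-supports (deg) and peak torques at full
#'   activation (N m).
#' @param shape Per-channel profile shape, `"cosine"` (raised cosine) or
#'   `"flat"` (constant `peak` inside the support).
#' @param win_start,win_end Per-channel stimulation windows (deg); default to
#'   the bump supports.
#' @param q_threshold,q_saturation Recruitment thresholds (uC/s): activation
#'   is 0 below `q_threshold` and 1 at `q_saturation`, linear between.
#' @param lambda Fatigue rate per unit activation per second.
#' @param rho Recovery rate per second.
#' @param phi_min Residual fitness floor in `(0, 1]`.
#' @param dt_internal Integrator substep (s).
#' @param encoder_resolution Encoder counts per revolution (default 1440,
#'   a 360-PPR incremental encoder read in quadrature).
#' @param torque_noise_sd Relative SD of optional per-step multiplicative
#'   torque noise (0 disables; uses the session RNG when enabled).
#' @param preset Label carried through to logs ("m1", "m2" or "custom").
#' @return An object of class `fes_env_config`.
#' @export
env_config <- function(J = 1.2, b = 0.8, tau_load = 1.0,
                       center = c(30, 90, 150, 210, 270, 330),
                       half_width = rep(60, 6),
                       peak = c(10, 9, 9, 10, 9, 9),
                       shape = rep("cosine", 6),
                       win_start = NULL, win_end = NULL,
                       q_threshold = 200, q_saturation = 2500,
                       lambda = 8e-4, rho = 2e-5, phi_min = 0.3,
                       dt_internal = 0.01, encoder_resolution = 1440L,
                       torque_noise_sd = 0, preset = "custom") {
  stopifnot(J > 0, b > 0, tau_load >= 0, q_saturation > q_threshold,
            lambda >= 0, rho >= 0, phi_min > 0, phi_min <= 1,
            dt_internal > 0, encoder_resolution >= 1)
  n <- length(center)
  stopifnot(length(half_width) == n, length(peak) == n, length(shape) == n)
  if (is.null(win_start)) win_start <- (center - half_width) %% 360
  if (is.null(win_end)) win_end <- (center + half_width) %% 360
  structure(list(
    J = J, b = b, tau_load = tau_load, center = center,
    half_width = half_width, peak = peak, shape = shape,
    win_start = win_start, win_end = win_end,
    q_threshold = q_threshold, q_saturation = q_saturation,
    lambda = lambda, rho = rho, phi_min = phi_min,
    dt_internal = dt_internal,
    encoder_resolution = as.integer(encoder_resolution),
    torque_noise_sd = torque_noise_sd, n_channels = n, preset = preset
  ), class = "fes_env_config")
}

#' Gear-ratio presets for the synthetic environment
#'
#' `"m1"` is the lighter gear; `"m2"` the heavier one (higher load torque,
#' requiring a strictly higher steady-state charge rate to hold 35 rpm).
#'
#' @param name `"m1"` or `"m2"`.
#' @param fatigue Set `FALSE` to disable fatigue and recovery (fitness stays
#'   at its initial value).
#' @param ... Overrides passed to [env_config()].
#' @return An `fes_env_config`.
#' @export
env_preset <- function(name = c("m1", "m2"), fatigue = TRUE, ...) {
  name <- match.arg(name)
  args <- list(tau_load = if (name == "m1") 1.0 else 2.5, preset = name)
  if (!fatigue) args <- c(args, list(lambda = 0, rho = 0))
  do.call(env_config, modifyList(args, list(...)))
}

#' Environment state
#'
#' @param theta Crank angle (deg), wrapped to `[0, 360)`.
#' @param cadence_rpm Pedaling cadence (rpm), non-negative.
#' @param fitness Per-channel fitness in `[phi_min, 1]`.
#' @param elapsed_s Elapsed simulated time (s).
#' @param theta_total Unwrapped crank angle (deg) driving the encoder counts.
#' @return An object of class `fes_env_state`.
#' @export
env_state <- function(theta = 0, cadence_rpm = 0, fitness = rep(1, 6),
                      elapsed_s = 0, theta_total = theta) {
  stopifnot(cadence_rpm >= 0, all(fitness >= 0), all(fitness <= 1))
  structure(list(theta = theta %% 360, cadence_rpm = cadence_rpm,
                 fitness = fitness, elapsed_s = elapsed_s,
                 theta_total = theta_total), class = "fes_env_state")
}

# charge rate vector (uC/s) from a list of fes_command objects
.charge_from_commands <- function(commands, n_channels) {
  ch <- numeric(n_channels)
  for (cmd in commands) {
    i <- cmd$channel_id + 1L
    if (isTRUE(cmd$enabled))
      ch[i] <- pulse_charge_rate(cmd$amplitude_mA, cmd$width_us, cmd$frequency_hz)
  }
  ch
}

#' Advance the environment by one control period
#'
#' Holds the stimulation commands constant and integrates the crank and
#' fatigue dynamics over `dt`, sub-stepping internally when `dt` exceeds the
#' configured integrator step. Stimulation is gated per substep by each
#' channel's angular window, so a window entered mid-tick still contributes.
#'
#' @param state An [env_state()].
#' @param commands List of [stimulation_command()] objects (one per enabled
#'   channel), or a numeric vector of per-channel charge rates (uC/s).
#' @param config An [env_config()].
#' @param dt Control period (s), positive.
#' @return The new `fes_env_state`, with the mean mechanical power over the
#'   step attached as attribute `"power_w"`.
#' @export
env_step <- function(state, commands, config, dt = 0.1) {
  stopifnot(dt > 0)
  charge <- if (is.numeric(commands)) commands
            else .charge_from_commands(commands, config$n_channels)
  stopifnot(length(charge) == config$n_channels)
  gain <- 1
  if (config$torque_noise_sd > 0)
    gain <- max(0, 1 + rnorm(1, 0, config$torque_noise_sd))
  nsub <- max(1L, as.integer(ceiling(dt / config$dt_internal - 1e-9)))
  out <- crank_advance_cpp(state$theta, state$theta_total, state$cadence_rpm,
                           state$fitness, charge,
                           config$win_start, config$win_end,
                           config$center, config$half_width, config$peak,
                           config$shape == "flat",
                           config$q_threshold, config$q_saturation,
                           config$J, config$b, config$tau_load,
                           config$lambda, config$rho, config$phi_min,
                           gain, dt, nsub)
  new <- env_state(out$theta, out$cadence_rpm, out$fitness,
                   state$elapsed_s + dt, out$theta_total)
  attr(new, "power_w") <- out$power_w
  new
}

#' Encoder count at a state
#'
#' @param state An [env_state()].
#' @param resolution Counts per revolution.
#' @return Integer-valued count of the unwrapped crank angle.
#' @export
encoder_count <- function(state, resolution = 1440L) {
  floor(state$theta_total * resolution / 360)
}

#' Encoder-like measurement of angle and cadence
#'
#' The crank angle is floor-quantized to the encoder resolution; cadence is
#' derived from the count difference over the reporting window, which makes
#' it a discrete estimate within one quantization step of the true value
#' (the incremental encoder limits continuous cadence calculation).
#'
#' @param state An [env_state()].
#' @param resolution Counts per revolution.
#' @param prev_count Encoder count at the previous report; `NULL` yields a
#'   0 rpm first report by convention.
#' @param dt Reporting period (s).
#' @return List with `theta_deg` (quantized angle) and `cadence_rpm`.
#' @export
measure <- function(state, resolution = 1440L, prev_count = NULL, dt = 0.1) {
  step <- 360 / resolution
  theta_meas <- floor((state$theta %% 360) / step) * step
  cad <- if (is.null(prev_count)) 0
         else (encoder_count(state, resolution) - prev_count) / resolution / dt * 60
  list(theta_deg = theta_meas, cadence_rpm = max(cad, 0))
}
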