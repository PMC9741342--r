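# Session orchestration: the 10-Hz control loop, scenario presets, and
# log reading/writing.

#' Default six-channel stimulation pattern
#'
#' Builds the six channels (VL+RF, VM, HAM; right then left) with windows
#' taken from the environment's torque profiles and the protocol baselines:
#' 45 mA on the right leg, 50 mA on the left, 500 us width, 35 Hz.
#'
#' @param env An [env_config()] supplying the per-channel windows.
#' @param limits A [parameter_limits()].
#' @param right_amplitude_mA,left_amplitude_mA Baseline amplitudes (mA).
#' @param width_us Baseline pulse width (us).
#' @param frequency_hz Pulse frequency (Hz).
#' @return A list of six [channel_config()] objects.
#' @export
default_channels <- function(env = env_preset("m1"), limits = parameter_limits(),
                             right_amplitude_mA = 45, left_amplitude_mA = 50,
                             width_us = 500, frequency_hz = 35) {
  labels <- c("R_VL+RF", "R_VM", "R_HAM", "L_VL+RF", "L_VM", "L_HAM")
  lapply(seq_len(6), function(i) {
    channel_config(i - 1L, labels[i],
                   if (i <= 3) right_amplitude_mA else left_amplitude_mA,
                   width_us, frequency_hz,
                   env$win_start[i], env$win_end[i], TRUE, limits)
  })
}

#' Session configuration
#'
#' Everything needed to run one closed-loop session: the scenario (PI-only or
#' PI plus the RL agent), agent/PI/limit settings, the environment, the
#' channel baselines, reference cadence and duration.
#'
#' @param scenario `"pi_rl"` or `"pi_only"` (agent settings ignored for the
#'   latter).
#' @param env An [env_config()] / [env_preset()].
#' @param agent An [agent_config()].
#' @param pi A [pi_config()].
#' @param limits A [parameter_limits()].
#' @param channels List of [channel_config()]; defaults to
#'   [default_channels()] on the chosen environment.
#' @param reference_rpm Reference cadence (rpm), default 35.
#' @param duration_s Session duration (s), default 3600 (sessions were capped
#'   at sixty minutes).
#' @param control_rate_hz Control and logging rate (Hz), default 10.
#' @param initial_cadence_rpm Warm-start cadence (rpm) emulating the helper
#'   push that brings the pedal out of inertia.
#' @param initial_fitness Initial per-channel fitness (scalar or vector).
#' @param seed Default RNG seed for [run_session()].
#' @param label Optional preset label carried into logs.
#' @return An object of class `fes_session_config`.
#' @export
session_config <- function(scenario = c("pi_rl", "pi_only"),
                           env = env_preset("m1"), agent = agent_config(),
                           pi = pi_config(), limits = parameter_limits(),
                           channels = default_channels(env, limits),
                           reference_rpm = 35, duration_s = 3600,
                           control_rate_hz = 10, initial_cadence_rpm = 10,
                           initial_fitness = 1, seed = 1L, label = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(duration_s > 0, control_rate_hz > 0, reference_rpm > 0,
            initial_cadence_rpm >= 0)
  if (length(initial_fitness) == 1)
    initial_fitness <- rep(initial_fitness, length(channels))
  stopifnot(length(initial_fitness) == length(channels),
            all(initial_fitness > 0), all(initial_fitness <= 1))
  for (ch in channels) {
    if (ch$amplitude_mA < 0 || ch$amplitude_mA > limits$max_amplitude_mA ||
        ch$width_us < limits$width_min_us || ch$width_us > limits$width_max_us)
      stop("channel ", ch$channel_id, " baseline outside limits")
  }
  dt <- 1 / control_rate_hz
  tpi <- agent$interaction_period_s / dt
  tpe <- agent$episode_length_s / dt
  if (scenario == "pi_rl" &&
      (abs(tpi - round(tpi)) > 1e-9 || abs(tpe - round(tpe)) > 1e-9))
    stop("interaction and episode lengths must be whole numbers of control ticks")
  structure(list(
    scenario = scenario, env = env, agent = agent, pi = pi, limits = limits,
    channels = channels, reference_rpm = reference_rpm,
    duration_s = duration_s, control_rate_hz = control_rate_hz,
    initial_cadence_rpm = initial_cadence_rpm,
    initial_fitness = initial_fitness, seed = as.integer(seed),
    label = label %||% scenario
  ), class = "fes_session_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The six protocol scenario presets
#'
#' PI-only, PI+RL at a 60% initial exploration rate, and PI+RL at 40% - each
#' decaying epsilon by 0.99 per episode - crossed with the M1 and M2 gear
#' ratios. Agent timing: 5-s interactions, 45-s episodes; steps 2 mA / 20 us;
#' baselines 45 mA (right) / 50 mA (left), 500 us, 35 Hz; 35 rpm reference.
#'
#' @param duration_s Session duration (s) applied to every preset.
#' @param ... Further overrides passed to [session_config()].
#' @return Named list of six [session_config()] objects
#'   (`pi_only_m1`, `pi_rl_60_m1`, `pi_rl_40_m1`, and the `_m2` variants).
#' @export
scenario_presets <- function(duration_s = 3600, ...) {
  out <- list()
  for (gear in c("m1", "m2")) {
    env <- env_preset(gear)
    out[[paste0("pi_only_", gear)]] <- session_config(
      "pi_only", env = env, duration_s = duration_s,
      label = paste0("pi_only_", gear), ...)
    for (e0 in c(60, 40)) {
      nm <- paste0("pi_rl_", e0, "_", gear)
      out[[nm]] <- session_config(
        "pi_rl", env = env, agent = agent_config(epsilon = e0 / 100),
        duration_s = duration_s, label = nm, ...)
    }
  }
  out
}

#' Run a closed-loop session
#'
#' Executes the control loop at the configured rate: measure the crank
#' through the encoder model, update the moving-average cadence error
#' (window 10), run the PI step, do the agent bookkeeping (new action every
#' interaction, baseline promotion / epsilon decay / value reset at every
#' episode boundary), build the stimulation commands, advance the
#' environment, and log one record per tick. Fully reproducible: the same
#' configuration and seed give bitwise-identical logs.
#'
#' @param config A [session_config()].
#' @param seed RNG seed; defaults to the one recorded in the config.
#' @return An object of class `fescycle_log`: a list with `data` (one row
#'   per 10-Hz tick), `config` (the resolved configuration), `seed`, and
#'   `final` (final epsilon, episode count and fitness).
#' @export
run_session <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "fes_session_config"))
  set.seed(seed)
  env <- config$env
  limits <- config$limits
  agent <- config$agent
  rp <- agent$reward
  rl <- config$scenario == "pi_rl"
  dt <- 1 / config$control_rate_hz
  n_ticks <- as.integer(round(config$duration_s * config$control_rate_hz))
  ticks_int <- as.integer(round(agent$interaction_period_s * config$control_rate_hz))
  ticks_ep <- as.integer(round(agent$episode_length_s * config$control_rate_hz))

  channels <- config$channels
  nch <- length(channels)
  base_a <- vapply(channels, `[[`, 0, "amplitude_mA")
  base_w <- vapply(channels, `[[`, 0, "width_us")
  freq <- vapply(channels, `[[`, 0, "frequency_hz")
  ws <- vapply(channels, `[[`, 0, "theta_start")
  we <- vapply(channels, `[[`, 0, "theta_end")
  enabled <- vapply(channels, `[[`, TRUE, "enabled")
  a0 <- base_a

  actions <- enumerate_actions(2)
  n_act <- nrow(actions)
  table <- action_value_table(n_act, nch)
  eps <- agent$epsilon
  episode <- 1L
  cur_action <- rep(NA_integer_, nch)
  acc_sum <- numeric(nch)
  acc_n <- integer(nch)
  work_a <- base_a
  work_w <- base_w
  sat <- rep(FALSE, nch)

  pis <- config$pi
  state <- env_state(theta = 0, cadence_rpm = config$initial_cadence_rpm,
                     fitness = config$initial_fitness)
  res <- env$encoder_resolution
  # virtual previous count so the first report reflects the warm-start cadence
  prev_count <- floor((state$theta_total -
                         config$initial_cadence_rpm * 6 * dt) * res / 360)
  err_hist <- numeric(n_ticks)

  # preallocated log columns
  L <- list(t_s = numeric(n_ticks), episode = integer(n_ticks),
            epsilon = numeric(n_ticks), ref_rpm = numeric(n_ticks),
            cadence_rpm = numeric(n_ticks), cadence_true_rpm = numeric(n_ticks),
            theta_deg = numeric(n_ticks), theta_true_deg = numeric(n_ticks),
            err_bar_rpm = numeric(n_ticks), pi_u_mA = numeric(n_ticks),
            power_w = numeric(n_ticks))
  m_on <- matrix(FALSE, n_ticks, nch)
  m_amp <- matrix(0, n_ticks, nch)
  m_wid <- matrix(0, n_ticks, nch)
  m_act <- matrix(NA_integer_, n_ticks, nch)
  m_rew <- matrix(0, n_ticks, nch)
  m_fit <- matrix(0, n_ticks, nch)

  flat <- env$shape == "flat"

  close_interaction <- function() {
    r_int <- ifelse(acc_n > 0L, acc_sum / pmax(acc_n, 1L), 0)
    for (ch in seq_len(nch))
      table <<- update_estimate(table, ch, cur_action[ch], r_int[ch])
    acc_sum[] <<- 0
    acc_n[] <<- 0L
  }
  close_episode <- function() {
    ee <- end_episode(table, channels, limits, eps, agent$decay_rate,
                      a0, sat, agent$prefer_noop, agent$reset_each_episode,
                      actions)
    channels <<- ee$channels
    base_a <<- vapply(channels, `[[`, 0, "amplitude_mA")
    base_w <<- vapply(channels, `[[`, 0, "width_us")
    eps <<- ee$epsilon
    table <<- ee$table
    episode <<- episode + 1L
  }

  for (t in seq_len(n_ticks)) {
    mm <- measure(state, res, prev_count, dt)
    prev_count <- encoder_count(state, res)
    err <- config$reference_rpm - mm$cadence_rpm
    err_hist[t] <- err
    ebar <- mean(err_hist[max(1L, t - 9L):t])

    pis <- pi_step(pis, config$reference_rpm, mm$cadence_rpm, dt)
    u <- pis$u

    if (rl) {
      boundary <- (t - 1L) %% ticks_int == 0L
      if (boundary && t > 1L) {
        close_interaction()
        if ((t - 1L) %% ticks_ep == 0L) close_episode()
      }
      if (boundary) {
        for (ch in seq_len(nch)) {
          mask <- .admissible_mask(base_a[ch], base_w[ch], a0[ch], limits,
                                   sat[ch], actions)
          cur_action[ch] <- select_action(table$q[, ch], eps, mask,
                                          agent$prefer_noop)
        }
        work_a <- base_a + actions$alpha[cur_action] * limits$step_a_mA
        work_w <- base_w + actions$omega[cur_action] * limits$step_w_us
      }
    }

    eff_a <- pmin(pmax(work_a + u, 0), limits$max_amplitude_mA)
    eff_w <- pmin(pmax(work_w, limits$width_min_us), limits$width_max_us)
    inw <- ifelse(ws <= we, mm$theta_deg >= ws & mm$theta_deg <= we,
                  mm$theta_deg >= ws | mm$theta_deg <= we) & enabled
    sat <- eff_a >= limits$max_amplitude_mA - 1e-9

    r_inst <- .reward_kernel(eff_a, eff_w, ebar, rp) * inw
    if (rl) {
      acc_sum <- acc_sum + r_inst
      acc_n <- acc_n + inw
    }

    gain <- 1
    if (env$torque_noise_sd > 0)
      gain <- max(0, 1 + rnorm(1, 0, env$torque_noise_sd))
    charge <- eff_a * eff_w * freq / 1000 * enabled
    nsub <- max(1L, as.integer(ceiling(dt / env$dt_internal - 1e-9)))
    out <- crank_advance_cpp(state$theta, state$theta_total, state$cadence_rpm,
                             state$fitness, charge, ws, we,
                             env$center, env$half_width, env$peak, flat,
                             env$q_threshold, env$q_saturation,
                             env$J, env$b, env$tau_load,
                             env$lambda, env$rho, env$phi_min, gain, dt, nsub)

    L$t_s[t] <- t * dt
    L$episode[t] <- if (rl) episode else NA_integer_
    L$epsilon[t] <- if (rl) eps else NA_real_
    L$ref_rpm[t] <- config$reference_rpm
    L$cadence_rpm[t] <- mm$cadence_rpm
    L$cadence_true_rpm[t] <- state$cadence_rpm
    L$theta_deg[t] <- mm$theta_deg
    L$theta_true_deg[t] <- state$theta
    L$err_bar_rpm[t] <- ebar
    L$pi_u_mA[t] <- u
    L$power_w[t] <- out$power_w
    m_on[t, ] <- inw
    m_amp[t, ] <- eff_a
    m_wid[t, ] <- eff_w
    if (rl) m_act[t, ] <- cur_action
    m_rew[t, ] <- r_inst
    m_fit[t, ] <- state$fitness

    state <- env_state(out$theta, out$cadence_rpm, out$fitness,
                       state$elapsed_s + dt, out$theta_total)
  }

  if (rl && n_ticks >= 1L) {
    if (n_ticks %% ticks_int == 0L) close_interaction()
    if (n_ticks %% ticks_ep == 0L) close_episode()
  }

  df <- as.data.frame(L)
  for (ch in seq_len(nch)) {
    p <- paste0("ch", ch - 1L, "_")
    df[[paste0(p, "on")]] <- m_on[, ch]
    df[[paste0(p, "amp_mA")]] <- m_amp[, ch]
    df[[paste0(p, "width_us")]] <- m_wid[, ch]
    df[[paste0(p, "freq_hz")]] <- rep(freq[ch], n_ticks)
    df[[paste0(p, "action")]] <- m_act[, ch]
    df[[paste0(p, "reward")]] <- m_rew[, ch]
    df[[paste0(p, "fitness")]] <- m_fit[, ch]
  }

  structure(list(
    data = df,
    config = .config_as_list(config),
    seed = as.integer(seed),
    final = list(epsilon = if (rl) eps else NA_real_,
                 episodes = if (rl) episode - 1L else 0L,
                 fitness = state$fitness,
                 baseline_amplitude_mA = base_a,
                 baseline_width_us = base_w)
  ), class = "fescycle_log")
}

# strip classes so the config serializes cleanly to JSON and back
.config_as_list <- function(x) {
  if (is.list(x)) lapply(unclass(x), .config_as_list) else x
}

#' @export
print.fescycle_log <- function(x, ...) {
  cfg <- x$config
  cat("<fescycle_log> ", cfg$label, ": ", nrow(x$data), " ticks @ ",
      cfg$control_rate_hz, " Hz, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write a session log to disk
#'
#' CSV with a JSON header block (lines prefixed `#`) carrying the resolved
#' configuration, the seed and the final agent state, so a log is fully
#' self-describing and metrics can be recomputed offline.
#'
#' @param log A `fescycle_log` from [run_session()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(log, path) {
  hdr <- jsonlite::toJSON(list(config = log$config, seed = log$seed,
                               final = log$final),
                          auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, "w")
  writeLines(paste0("#fescycle ", hdr), con)
  close(con)
  data.table::fwrite(log$data, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a session log written by [write_session_log()]
#'
#' @param path File path.
#' @return A `fescycle_log`.
#' @export
read_session_log <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#fescycle "))
    stop("not a fescycle session log: ", path)
  meta <- jsonlite::fromJSON(sub("^#fescycle ", "", first),
                             simplifyDataFrame = FALSE)
  df <- as.data.frame(data.table::fread(path, skip = 1L, header = TRUE))
  structure(list(data = df, config = meta$config, seed = meta$seed,
                 final = meta$final), class = "fescycle_log")
}

#' Read a session configuration from a YAML or JSON file
#'
#' Top-level keys mirror the [session_config()] arguments; nested blocks
#' `agent`, `pi`, `limits`, `env` and `reward` override the corresponding
#' constructor defaults, and `env` may give `preset: m1|m2`. Per-channel
#' fields (`on`, start/end angle, frequency, pulse width, amplitude) can be
#' set under `channels:` as a list indexed by channel id.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A [session_config()].
#' @export
read_session_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  env_args <- raw$env %||% list()
  env <- if (!is.null(env_args$preset)) {
    preset <- env_args$preset
    env_args$preset <- NULL
    do.call(env_preset, c(list(name = preset), env_args))
  } else do.call(env_config, env_args)
  limits <- do.call(parameter_limits, raw$limits %||% list())
  agent_args <- raw$agent %||% list()
  if (!is.null(agent_args$reward))
    agent_args$reward <- do.call(reward_params, agent_args$reward)
  agent <- do.call(agent_config, agent_args)
  pi <- do.call(pi_config, raw$pi %||% list())
  channels <- default_channels(env, limits)
  for (spec in raw$channels %||% list()) {
    i <- spec$channel_id + 1L
    ch <- channels[[i]]
    channels[[i]] <- channel_config(
      ch$channel_id, spec$muscle_label %||% ch$muscle_label,
      spec$amplitude_mA %||% ch$amplitude_mA,
      spec$width_us %||% ch$width_us,
      spec$frequency_hz %||% ch$frequency_hz,
      spec$theta_start %||% ch$theta_start,
      spec$theta_end %||% ch$theta_end,
      spec$enabled %||% ch$enabled, limits)
  }
  keep <- intersect(names(raw), c("scenario", "reference_rpm", "duration_s",
                                  "control_rate_hz", "initial_cadence_rpm",
                                  "initial_fitness", "seed", "label"))
  do.call(session_config, c(list(env = env, agent = agent, pi = pi,
                                 limits = limits, channels = channels),
                            raw[keep]))
}
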