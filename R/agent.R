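# The decayed-epsilon-greedy agent: reward evaluation, sample-average value
# estimates, action selection and episodic baseline promotion.

#' Reward-function parameters
#'
#' Constants of the instantaneous reward. Pulse width and amplitude enter in
#' a scaled convention: `P = width * width_scale` (500 us -> 0.05) and
#' `A = amplitude * amplitude_scale` (45 mA -> 0.045, ceiling 100 mA -> 0.1).
#' The mirrored width `Pbar = (width_max + width_min - width - pk) * width_scale`
#' decreases as the width grows, which makes wide pulses rewarding at high
#' amplitudes (charge headroom to delay saturation) and narrow pulses
#' rewarding at low amplitudes (stimulation cost). The offset `pk` is in
#' width units (us) before scaling; with the defaults `pk = 100` keeps
#' `Pbar >= 0` over the whole admissible width range.
#'
#' @param max_amplitude_mA Amplitude ceiling Ma (mA).
#' @param pk Reward offset in width units (us).
#' @param width_max_us,width_min_us Width bounds entering `Pbar` (us).
#' @param amplitude_scale,width_scale Normalizers applied to mA and us.
#' @param error_floor_rpm Lower clamp on the moving-average cadence error
#'   magnitude (rpm), preventing division by zero at perfect tracking.
#' @return An object of class `fes_reward_params`.
#' @export
reward_params <- function(max_amplitude_mA = 100, pk = 100, width_max_us = 600,
                          width_min_us = 450, amplitude_scale = 1e-3,
                          width_scale = 1e-4, error_floor_rpm = 0.1) {
  stopifnot(error_floor_rpm > 0, amplitude_scale > 0, width_scale > 0)
  if (width_min_us < pk)
    stop("pk must not exceed width_min_us, otherwise Pbar goes negative in range")
  structure(list(
    max_amplitude_mA = max_amplitude_mA, pk = pk, width_max_us = width_max_us,
    width_min_us = width_min_us, amplitude_scale = amplitude_scale,
    width_scale = width_scale, error_floor_rpm = error_floor_rpm
  ), class = "fes_reward_params")
}

#' Agent configuration
#'
#' @param epsilon Initial exploration probability in `[0, 1]`.
#' @param decay_rate Multiplier applied to epsilon at each episode end.
#' @param interaction_period_s Seconds an action is held before its reward is
#'   evaluated (default 5).
#' @param episode_length_s Episode duration in seconds (default 45); must be
#'   an integer multiple of `interaction_period_s` (9 interactions per episode
#'   at the defaults).
#' @param reward A [reward_params()] object.
#' @param prefer_noop Resolve greedy ties that include the no-op in favour of
#'   the no-op (prevents random baseline drift while no rewards have been
#'   observed). Default `FALSE`: ties break by a seeded uniform draw.
#' @param reset_each_episode Reset the value table at episode boundaries so
#'   each episode is evaluated independently from the previous one (the
#'   deployed behaviour). Disable to carry estimates across episodes, e.g.
#'   for stationary-bandit convergence diagnostics.
#' @return An object of class `fes_agent_config`.
#' @export
agent_config <- function(epsilon = 0.6, decay_rate = 0.99,
                         interaction_period_s = 5, episode_length_s = 45,
                         reward = reward_params(), prefer_noop = FALSE,
                         reset_each_episode = TRUE) {
  stopifnot(epsilon >= 0, epsilon <= 1, decay_rate >= 0, decay_rate <= 1,
            interaction_period_s > 0, episode_length_s > 0)
  k <- episode_length_s / interaction_period_s
  if (abs(k - round(k)) > 1e-9)
    stop("episode_length_s must be an integer multiple of interaction_period_s")
  structure(list(
    epsilon = epsilon, decay_rate = decay_rate,
    interaction_period_s = interaction_period_s,
    episode_length_s = episode_length_s, reward = reward,
    prefer_noop = isTRUE(prefer_noop),
    reset_each_episode = isTRUE(reset_each_episode)
  ), class = "fes_agent_config")
}

#' Agent state vector
#'
#' What the agent observes at a time step: the crank angle and the
#' moving-average cadence error (window 10 at the 10-Hz control rate).
#'
#' @param theta_deg Crank angle in degrees, `[0, 360)`.
#' @param mean_cadence_error_rpm Moving-average cadence error (rpm); may be
#'   signed, only its magnitude enters the reward.
#' @return An object of class `fes_state`.
#' @export
state_vector <- function(theta_deg, mean_cadence_error_rpm) {
  stopifnot(theta_deg >= 0, theta_deg < 360)
  structure(list(theta_deg = theta_deg,
                 mean_cadence_error_rpm = mean_cadence_error_rpm),
            class = "fes_state")
}

# Ungated reward kernel, vectorized over channels:
# |P^2 A - Pbar^2 (Ma - A)| / max(|ebar|, floor)
.reward_kernel <- function(amp_eff_mA, width_us, err_rpm, p) {
  A <- amp_eff_mA * p$amplitude_scale
  P <- width_us * p$width_scale
  Pb <- (p$width_max_us + p$width_min_us - width_us - p$pk) * p$width_scale
  Ma <- p$max_amplitude_mA * p$amplitude_scale
  abs(P^2 * A - Pb^2 * (Ma - A)) / pmax(abs(err_rpm), p$error_floor_rpm)
}

#' Instantaneous reward of a channel at a state
#'
#' Evaluates the reward
#' `|P^2 A - Pbar^2 (Ma - A)| / ebar` when the crank angle lies inside the
#' channel's stimulation window, and exactly 0 otherwise. `A` is the
#' delivered amplitude - baseline plus agent delta plus PI contribution,
#' clipped at the ceiling - and `P` the working width, both in the scaled
#' convention of [reward_params()]. The error magnitude is clamped below at
#' `error_floor_rpm`, so rewards are finite, non-negative, and inversely
#' proportional to the cadence error.
#'
#' @param state A [state_vector()].
#' @param channel A [channel_config()] holding the working (baseline) values.
#' @param params A [reward_params()].
#' @param action Optional action (delta applied on top of the channel values
#'   via the step sizes in `limits`).
#' @param pi_u_mA PI amplitude contribution (mA).
#' @param limits A [parameter_limits()] supplying step sizes and the ceiling.
#' @return A single non-negative number.
#' @export
instantaneous_reward <- function(state, channel, params = reward_params(),
                                 action = NULL, pi_u_mA = 0,
                                 limits = parameter_limits()) {
  if (!channel$enabled) return(0)
  if (!in_window(state$theta_deg, channel)) return(0)
  a <- channel$amplitude_mA
  w <- channel$width_us
  if (!is.null(action)) {
    act <- .as_action(action, enumerate_actions(2))
    a <- a + act[["alpha"]] * limits$step_a_mA
    w <- w + act[["omega"]] * limits$step_w_us
  }
  a_eff <- min(a + pi_u_mA, limits$max_amplitude_mA)
  .reward_kernel(a_eff, w, state$mean_cadence_error_rpm, params)
}

#' Pooled reward of one interaction window
#'
#' The reward attributed to an action held over an interaction is the mean of
#' the instantaneous rewards at the samples where the crank was inside the
#' channel's window. If the crank never entered the window the interaction
#' reward is 0.
#'
#' @param rewards Numeric vector of instantaneous rewards over the window.
#' @param in_window Logical vector flagging the in-window samples; `NULL`
#'   treats every sample as in-window.
#' @return A single number.
#' @export
interaction_reward <- function(rewards, in_window = NULL) {
  if (is.null(in_window)) in_window <- rep(TRUE, length(rewards))
  stopifnot(length(in_window) == length(rewards))
  if (!any(in_window)) return(0)
  mean(rewards[in_window])
}

#' Per-channel action-value table
#'
#' Sample-average estimates `Q` and selection counts `n` for every action and
#' channel; both restart at zero (episode boundaries reset them by default).
#'
#' @param n_actions Number of actions (rows).
#' @param n_channels Number of channels (columns).
#' @return An object of class `fes_avtable` with matrices `q` and `n`.
#' @export
action_value_table <- function(n_actions = 9L, n_channels = 6L) {
  structure(list(q = matrix(0, n_actions, n_channels),
                 n = matrix(0L, n_actions, n_channels)),
            class = "fes_avtable")
}

#' Incremental sample-average update of an action value
#'
#' `NewEstimate <- OldEstimate + (Reward - OldEstimate) / n`, so that after
#' any number of updates `Q` equals the arithmetic mean of the rewards
#' received for that action.
#'
#' @param table An [action_value_table()].
#' @param channel Channel column (1-based).
#' @param action Action row (1-based).
#' @param reward Observed interaction reward.
#' @return The updated table.
#' @export
update_estimate <- function(table, channel, action, reward) {
  n <- table$n[action, channel] + 1L
  table$n[action, channel] <- n
  table$q[action, channel] <- table$q[action, channel] +
    (reward - table$q[action, channel]) / n
  table
}

# Greedy admissible action; ties broken uniformly (or toward the no-op).
.greedy <- function(q, admissible, prefer_noop = FALSE, noop = .noop_index(2)) {
  idx <- which(admissible)
  if (length(idx) == 0L) stop("internal error: empty admissible set")
  mx <- max(q[idx])
  cand <- idx[q[idx] == mx]
  if (prefer_noop && !is.na(noop) && noop %in% cand) return(noop)
  if (length(cand) == 1L) return(cand)
  cand[sample.int(length(cand), 1L)]
}

#' Epsilon-greedy action selection
#'
#' With probability `epsilon` a uniform draw over the admissible actions
#' (exploration); otherwise the admissible action with the greatest estimated
#' value (exploitation), ties broken by a uniform draw among the maxima. The
#' admissible set is never empty because the no-op is always admissible.
#'
#' @param q Numeric vector of action-value estimates for one channel.
#' @param epsilon Exploration probability in `[0, 1]`.
#' @param admissible Logical mask over actions (see [admissible_actions()]).
#' @param prefer_noop Resolve greedy ties containing the no-op to the no-op.
#' @param noop Index of the no-op action (for `prefer_noop`).
#' @return The selected action index (1-based).
#' @export
select_action <- function(q, epsilon, admissible = rep(TRUE, length(q)),
                          prefer_noop = FALSE, noop = .noop_index(2)) {
  stopifnot(length(admissible) == length(q))
  idx <- which(admissible)
  if (length(idx) == 0L) stop("internal error: empty admissible set")
  if (epsilon > 0 && runif(1) < epsilon) {
    if (length(idx) == 1L) return(idx)
    return(idx[sample.int(length(idx), 1L)])
  }
  .greedy(q, admissible, prefer_noop, noop)
}

#' Close an episode: promote greedy actions, decay epsilon, reset values
#'
#' At the end of an episode the greedy (highest-valued admissible) action of
#' every channel is applied once to that channel's baseline, epsilon is
#' multiplied by the decay rate, and - by default - the value table restarts
#' so the next episode is evaluated independently.
#'
#' @param table An [action_value_table()].
#' @param channels List of [channel_config()] baselines.
#' @param limits A [parameter_limits()].
#' @param epsilon Current exploration probability.
#' @param decay_rate Epsilon decay multiplier.
#' @param initial_amplitudes_mA Per-channel initial baseline amplitudes
#'   anchoring the excursion band; defaults to the current baselines.
#' @param amplitude_saturated Per-channel saturation flags (rule 2).
#' @param prefer_noop,reset See [agent_config()].
#' @param actions Action table (rows matching `table`).
#' @return A list with `channels` (promoted baselines), `epsilon`,
#'   `table` (reset or carried), and `promoted` (chosen index per channel).
#' @export
end_episode <- function(table, channels, limits = parameter_limits(),
                        epsilon = 0.6, decay_rate = 0.99,
                        initial_amplitudes_mA = vapply(channels, `[[`, 0, "amplitude_mA"),
                        amplitude_saturated = rep(FALSE, length(channels)),
                        prefer_noop = FALSE, reset = TRUE,
                        actions = enumerate_actions(2)) {
  noop <- which(actions$alpha == 0 & actions$omega == 0)
  promoted <- integer(length(channels))
  for (i in seq_along(channels)) {
    ch <- channels[[i]]
    mask <- .admissible_mask(ch$amplitude_mA, ch$width_us,
                             initial_amplitudes_mA[i], limits,
                             amplitude_saturated[i], actions)
    g <- .greedy(table$q[, i], mask, prefer_noop, noop)
    promoted[i] <- g
    channels[[i]] <- apply_action(ch, g, limits, initial_amplitudes_mA[i],
                                  amplitude_saturated[i])
  }
  if (reset) table <- action_value_table(nrow(table$q), ncol(table$q))
  list(channels = channels, epsilon = epsilon * decay_rate,
       table = table, promoted = promoted)
}

#' Stationary-bandit harness for the selection/update machinery
#'
#' Runs the epsilon-greedy loop against a user-supplied stationary reward
#' function of the action index alone - no environment, channels all
#' admissible - and records the greedy (promoted) action at each episode end.
#' Useful for convergence diagnostics of the sample-average estimator; with
#' `reset_each_episode = FALSE` estimates accumulate across episodes, the
#' standard bandit setting in which the promoted action converges to the
#' optimum as exploration decays.
#'
#' @param reward_fn Function mapping an action index to a reward.
#' @param n_episodes Number of episodes.
#' @param epsilon0 Initial exploration probability.
#' @param decay_rate Epsilon decay per episode.
#' @param interactions_per_episode Interactions per episode (default 9).
#' @param n_actions Size of the action set (default 9).
#' @param reset_each_episode Reset estimates at episode boundaries.
#' @param prefer_noop Tie-break preference for the no-op index.
#' @return A data frame with columns `episode`, `promoted`, `epsilon_after`.
#' @export
run_bandit <- function(reward_fn, n_episodes, epsilon0 = 0.4, decay_rate = 0.99,
                       interactions_per_episode = 9L, n_actions = 9L,
                       reset_each_episode = TRUE, prefer_noop = FALSE) {
  table <- action_value_table(n_actions, 1L)
  eps <- epsilon0
  all_ok <- rep(TRUE, n_actions)
  promoted <- integer(n_episodes)
  eps_after <- numeric(n_episodes)
  noop <- .noop_index(2)
  if (noop > n_actions) noop <- NA_integer_
  for (ep in seq_len(n_episodes)) {
    for (i in seq_len(interactions_per_episode)) {
      a <- select_action(table$q[, 1], eps, all_ok, prefer_noop, noop)
      table <- update_estimate(table, 1L, a, reward_fn(a))
    }
    promoted[ep] <- .greedy(table$q[, 1], all_ok, prefer_noop, noop)
    eps <- eps * decay_rate
    if (reset_each_episode) table <- action_value_table(n_actions, 1L)
    eps_after[ep] <- eps
  }
  data.frame(episode = seq_len(n_episodes), promoted = promoted,
             epsilon_after = eps_after)
}
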