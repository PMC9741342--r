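# Shared fixtures built in code.

# A minimal hand-built log data frame (2 channels) for metric unit tests.
make_fake_log <- function(n = 10, cadence = rep(35, n), reward1 = rep(0, n),
                          reward2 = rep(0, n), on1 = rep(TRUE, n),
                          on2 = rep(TRUE, n), amp = rep(45, n),
                          width = rep(500, n), freq = 35, ref = 35,
                          power = rep(10, n), dt = 0.1) {
  data.frame(
    t_s = seq_len(n) * dt, ref_rpm = ref, cadence_rpm = cadence,
    power_w = power,
    ch0_on = on1, ch0_amp_mA = amp, ch0_width_us = width, ch0_freq_hz = freq,
    ch0_action = NA_integer_, ch0_reward = reward1, ch0_fitness = 1,
    ch1_on = on2, ch1_amp_mA = amp, ch1_width_us = width, ch1_freq_hz = freq,
    ch1_action = NA_integer_, ch1_reward = reward2, ch1_fitness = 1
  )
}

# Short sessions used by several test files.
short_session <- function(scenario = "pi_rl", gear = "m1", duration_s = 120,
                          seed = 1, ...) {
  run_session(session_config(scenario, env = env_preset(gear),
                             duration_s = duration_s, seed = seed, ...))
}

# Decode an action index into its (alpha, omega) pair.
action_tuple <- function(idx, actions = enumerate_actions(2)) {
  c(alpha = actions$alpha[idx], omega = actions$omega[idx])
}
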