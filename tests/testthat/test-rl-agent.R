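test_that("instantaneous reward reproduces the hand arithmetic and the gating", {
  rp <- reward_params()
  ch <- channel_config(0, "x", 45, 500, theta_start = 0, theta_end = 120)
  s_in <- state_vector(60, 1)
  # |0.05^2 * 0.045 - 0.045^2 * (0.1 - 0.045)| / 1
  expect_equal(instantaneous_reward(s_in, ch, rp), 1.125e-6, tolerance = 1e-12)
  expect_identical(instantaneous_reward(state_vector(200, 1), ch, rp), 0)
  ch_off <- ch; ch_off$enabled <- FALSE
  expect_identical(instantaneous_reward(s_in, ch_off, rp), 0)
  # error magnitude is clamped below, keeping the reward finite
  r0 <- instantaneous_reward(state_vector(60, 0), ch, rp)
  expect_equal(r0, 1.125e-6 / rp$error_floor_rpm)
  # sign of the error does not matter
  expect_equal(instantaneous_reward(state_vector(60, -2), ch, rp),
               instantaneous_reward(state_vector(60, 2), ch, rp))
})

test_that("reward prefers wide pulses at high amplitude and narrow at low", {
  rp <- reward_params()
  widths <- seq(450, 600, by = 10)
  r_at <- function(amp) vapply(widths, function(w) {
    ch <- channel_config(0, "x", amp, w, theta_start = 0, theta_end = 359.99)
    instantaneous_reward(state_vector(10, 1), ch, rp)
  }, 0)
  expect_true(all(diff(r_at(75)) > 0))  # strictly increasing in width
  expect_true(all(diff(r_at(25)) < 0))  # strictly decreasing in width
})

test_that("interaction reward is the mean over in-window samples, zero if none", {
  expect_identical(interaction_reward(numeric(0)), 0)
  expect_identical(interaction_reward(rep(3, 10), rep(FALSE, 10)), 0)
  expect_equal(interaction_reward(rep(1.5, 20)), 1.5)
  r <- c(rep(2, 25), rep(99, 25))
  expect_equal(interaction_reward(r, c(rep(TRUE, 25), rep(FALSE, 25))), 2)
  set.seed(3)
  x <- runif(50); inw <- runif(50) > 0.5
  expect_equal(interaction_reward(x, inw), sum(x[inw]) / sum(inw))
})

test_that("incremental value updates equal the batch arithmetic mean", {
  expect_equal(update_estimate(action_value_table(9, 1), 1, 4, 2)$q[4, 1], 2)
  tb <- action_value_table(9, 1)
  for (r in c(1, 2, 3)) tb <- update_estimate(tb, 1, 2, r)
  expect_equal(tb$q[2, 1], 2)
  expect_equal(tb$n[2, 1], 3L)
  # zero innovation leaves the estimate unchanged
  tb2 <- update_estimate(tb, 1, 2, tb$q[2, 1])
  expect_equal(tb2$q[2, 1], tb$q[2, 1])
  # property: random sequences, incremental vs accumulator oracle
  set.seed(42)
  for (i in 1:50) {
    rs <- runif(sample(1:30, 1), -5, 5)
    tb <- action_value_table(9, 2)
    for (r in rs) tb <- update_estimate(tb, 2, 7, r)
    expect_equal(tb$q[7, 2], mean(rs), tolerance = 1e-12)
  }
})

test_that("epsilon-greedy selection is greedy at 0 and uniform at 1", {
  q <- c(0, 0, 0, 1, 0, 0, 0, 0, 0)
  for (i in 1:10) expect_equal(select_action(q, 0), 4)
  set.seed(5)
  draws <- replicate(1e4, select_action(q, 1))
  tab <- table(factor(draws, levels = 1:9))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.001)
})

test_that("selection respects the admissible mask, including saturation rule 2", {
  acts <- enumerate_actions(2)
  ch <- channel_config(0, "x", 50, 500)
  mask <- admissible_actions(ch, amplitude_saturated = TRUE)
  expect_true(all(acts$omega[mask] >= 0))
  q <- rep(0, 9); q[1] <- 10  # best action reduces the width
  set.seed(9)
  for (i in 1:50) {
    a <- select_action(q, runif(1), mask)
    expect_gte(acts$omega[a], 0)
  }
})

test_that("episode closure promotes the greedy action, decays epsilon and resets", {
  lim <- parameter_limits()
  chs <- list(channel_config(0, "x", 45, 500), channel_config(1, "y", 50, 500))
  tb <- action_value_table(9, 2)
  tb <- update_estimate(tb, 1, 9, 5)  # channel 1: (1, 1) best
  tb <- update_estimate(tb, 2, 1, 3)  # channel 2: (-0.5, -0.5) best
  ee <- end_episode(tb, chs, lim, epsilon = 0.6, decay_rate = 0.99)
  expect_equal(ee$epsilon, 0.6 * 0.99)
  expect_equal(ee$promoted, c(9, 1))
  expect_equal(ee$channels[[1]]$amplitude_mA, 47)
  expect_equal(ee$channels[[1]]$width_us, 520)
  expect_equal(ee$channels[[2]]$amplitude_mA, 49)
  expect_equal(ee$channels[[2]]$width_us, 490)
  expect_true(all(ee$table$q == 0) && all(ee$table$n == 0L))
  # identity decay
  expect_equal(end_episode(tb, chs, lim, epsilon = 0.4, decay_rate = 1)$epsilon, 0.4)
})

test_that("all-equal estimates promote within the admissible tie set; no-op bias holds", {
  lim <- parameter_limits()
  chs <- list(channel_config(0, "x", 45, 500))
  tb <- action_value_table(9, 1)
  set.seed(13)
  mask <- admissible_actions(chs[[1]], lim)
  for (i in 1:25) {
    ee <- end_episode(tb, chs, lim)
    expect_true(mask[ee$promoted])
  }
  for (i in 1:10) {
    ee <- end_episode(tb, chs, lim, prefer_noop = TRUE)
    expect_equal(ee$promoted, 5L)
    expect_equal(ee$channels[[1]]$amplitude_mA, 45)
    expect_equal(ee$channels[[1]]$width_us, 500)
  }
})

test_that("agent config enforces the interaction/episode nesting", {
  expect_error(agent_config(interaction_period_s = 5, episode_length_s = 44),
               "multiple")
  a <- agent_config()
  expect_equal(a$episode_length_s / a$interaction_period_s, 9)
})
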