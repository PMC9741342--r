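test_that("the six protocol presets carry the printed settings", {
  ps <- scenario_presets()
  expect_length(ps, 6)
  expect_named(ps, c("pi_only_m1", "pi_rl_60_m1", "pi_rl_40_m1",
                     "pi_only_m2", "pi_rl_60_m2", "pi_rl_40_m2"))
  expect_equal(ps$pi_rl_60_m1$agent$epsilon, 0.6)
  expect_equal(ps$pi_rl_40_m2$agent$epsilon, 0.4)
  expect_equal(ps$pi_rl_60_m1$agent$decay_rate, 0.99)
  expect_equal(ps$pi_only_m2$scenario, "pi_only")
  expect_equal(ps$pi_only_m2$env$preset, "m2")
  for (p in ps) {
    amps <- vapply(p$channels, `[[`, 0, "amplitude_mA")
    expect_equal(amps, c(45, 45, 45, 50, 50, 50))
    expect_equal(vapply(p$channels, `[[`, 0, "width_us"), rep(500, 6))
    expect_equal(vapply(p$channels, `[[`, 0, "frequency_hz"), rep(35, 6))
    expect_equal(p$reference_rpm, 35)
    expect_equal(p$agent$interaction_period_s, 5)
    expect_equal(p$agent$episode_length_s, 45)
    expect_equal(p$limits$step_a_mA, 2)
    expect_equal(p$limits$step_w_us, 20)
  }
})

test_that("a PI-only session never moves the width and logs no agent actions", {
  log <- short_session("pi_only", duration_s = 90)
  d <- log$data
  expect_true(all(is.na(d[, grep("_action$", names(d))])))
  expect_true(all(d[, grep("_width_us$", names(d))] == 500))
  expect_true(all(is.na(d$episode)))
})

test_that("a 45-s episode holds exactly 9 interactions per channel", {
  log <- short_session("pi_rl", duration_s = 90, seed = 4)
  d <- log$data
  for (ep in 1:2) {
    rows <- which(d$episode == ep)
    expect_length(rows, 450)
    # action changes only at interaction boundaries: 9 blocks of 50 ticks
    a <- d$ch0_action[rows]
    blocks <- rle(rep(seq_len(9), each = 50))
    expect_equal(length(a), sum(blocks$lengths))
    for (k in 1:9) {
      seg <- a[((k - 1) * 50 + 1):(k * 50)]
      expect_length(unique(seg), 1)
    }
  }
})

test_that("identical configuration and seed give bitwise-identical logs", {
  l1 <- short_session("pi_rl", duration_s = 60, seed = 99)
  l2 <- short_session("pi_rl", duration_s = 60, seed = 99)
  expect_identical(l1$data, l2$data)
  expect_identical(l1$final, l2$final)
  l3 <- short_session("pi_rl", duration_s = 60, seed = 100)
  expect_false(identical(l3$data, l1$data))
})

test_that("epsilon in the log is non-increasing and follows the decay law", {
  log <- short_session("pi_rl", duration_s = 300, seed = 2)
  d <- log$data
  expect_true(all(diff(d$epsilon) <= 0))
  eps_by_ep <- vapply(split(d$epsilon, d$episode), unique, 0)
  k <- seq_along(eps_by_ep) - 1
  expect_equal(unname(eps_by_ep), 0.6 * 0.99^k, tolerance = 1e-12)
  expect_equal(log$final$epsilon, 0.6 * 0.99^6, tolerance = 1e-12)
})

test_that("logged parameters respect the physical and protocol bounds", {
  for (seed in 1:3) {
    for (gear in c("m1", "m2")) {
      d <- short_session("pi_rl", gear, duration_s = 120, seed = seed)$data
      amp <- as.matrix(d[, grep("_amp_mA$", names(d))])
      wid <- as.matrix(d[, grep("_width_us$", names(d))])
      expect_true(all(amp >= 0 & amp <= 100))
      expect_true(all(wid >= 450 & wid <= 600))
    }
  }
})

test_that("logs round-trip through disk and metrics replay to within 1e-9", {
  log <- short_session("pi_rl", duration_s = 120, seed = 8)
  path <- tempfile(fileext = ".csv")
  write_session_log(log, path)
  back <- read_session_log(path)
  expect_equal(back$seed, log$seed)
  expect_equal(back$config$label, log$config$label)
  expect_equal(nrow(back$data), nrow(log$data))
  expect_equal(stimulation_cost(back), stimulation_cost(log), tolerance = 1e-9)
  for (f in c("reward", "abs_error"))
    expect_equal(accumulated_series(back, f), accumulated_series(log, f),
                 tolerance = 1e-9)
  # the logged moving-average error replays from the raw series
  replayed <- moving_average(back$data$ref_rpm - back$data$cadence_rpm, 10)
  expect_equal(replayed, back$data$err_bar_rpm, tolerance = 1e-9)
  unlink(path)
})

test_that("session configs load from YAML with nested overrides", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "scenario: pi_rl",
    "duration_s: 90",
    "seed: 7",
    "agent:",
    "  epsilon: 0.4",
    "  decay_rate: 0.95",
    "env:",
    "  preset: m2",
    "pi:",
    "  kp: 1.5",
    "channels:",
    "  - channel_id: 2",
    "    enabled: false",
    "    amplitude_mA: 48"
  ), path)
  cfg <- read_session_config(path)
  expect_equal(cfg$scenario, "pi_rl")
  expect_equal(cfg$agent$epsilon, 0.4)
  expect_equal(cfg$agent$decay_rate, 0.95)
  expect_equal(cfg$env$preset, "m2")
  expect_equal(cfg$pi$kp, 1.5)
  expect_false(cfg$channels[[3]]$enabled)
  expect_equal(cfg$channels[[3]]$amplitude_mA, 48)
  expect_equal(cfg$channels[[1]]$amplitude_mA, 45)
  log <- run_session(cfg)
  expect_true(all(!log$data$ch2_on))
  unlink(path)
})

test_that("invalid configurations fail before any stepping", {
  expect_error(session_config("pi_only", duration_s = -1))
  expect_error(session_config("pi_rl", agent = agent_config(epsilon = 1.2)))
  bad <- default_channels()
  bad[[1]]$amplitude_mA <- 150
  expect_error(session_config("pi_only", channels = bad), "outside limits")
})
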