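test_that("action set enumeration has the right size, order and distinctness", {
  a2 <- enumerate_actions(2)
  expect_equal(nrow(a2), 9)
  expect_equal(nrow(enumerate_actions(3)), 27)
  expect_equal(nrow(enumerate_actions(1)), 3)
  expect_equal(nrow(unique(a2)), 9)
  # lexicographic with D3 ordered (-0.5, 0, 1): first row, no-op, last row
  expect_equal(unlist(a2[1, ]), c(alpha = -0.5, omega = -0.5))
  expect_equal(unlist(a2[5, ]), c(alpha = 0, omega = 0))
  expect_equal(unlist(a2[9, ]), c(alpha = 1, omega = 1))
  # stable across calls
  expect_identical(a2, enumerate_actions(2))
  expect_error(enumerate_actions(0), "positive")
  expect_error(fes_action(0.5, 0), "-0.5")
})

test_that("applying an action scales deltas by the step sizes and copies the channel", {
  lim <- parameter_limits(step_a_mA = 1, step_w_us = 20)
  ch <- channel_config(2, "R_HAM", 45, 500)
  ch2 <- apply_action(ch, fes_action(1, -0.5), lim)
  expect_equal(ch2$amplitude_mA, 46)
  expect_equal(ch2$width_us, 490)
  expect_equal(ch$amplitude_mA, 45)  # original untouched
  expect_equal(ch2$frequency_hz, ch$frequency_hz)
  expect_equal(ch2$theta_start, ch$theta_start)
  # identity action
  ch3 <- apply_action(ch, fes_action(0, 0), lim)
  expect_equal(ch3$amplitude_mA, 45)
  expect_equal(ch3$width_us, 500)
})

test_that("at the width ceiling exactly the width-increasing actions are rejected", {
  lim <- parameter_limits()
  ch <- channel_config(0, "R_VM", 45, 600)
  acts <- enumerate_actions(2)
  rejected <- !admissible_actions(ch, lim)
  expect_equal(rejected, acts$omega == 1)
  expect_error(apply_action(ch, fes_action(0, 1), lim),
               class = "fescycle_inadmissible")
})

test_that("rule 2 blocks width decrease, but not increase, under amplitude saturation", {
  lim <- parameter_limits()
  ch <- channel_config(0, "R_VM", 45, 500)
  expect_false(is_admissible(ch, fes_action(0, -0.5), lim, amplitude_saturated = TRUE))
  expect_true(is_admissible(ch, fes_action(0, 1), lim, amplitude_saturated = TRUE))
  expect_true(is_admissible(ch, fes_action(0, 0), lim, amplitude_saturated = TRUE))
  expect_true(is_admissible(ch, fes_action(0, -0.5), lim, amplitude_saturated = FALSE))
})

test_that("the no-op is admissible in every reachable state", {
  lim <- parameter_limits()
  set.seed(11)
  for (i in 1:50) {
    a0 <- runif(1, 40, 50)
    a <- runif(1, a0 - lim$delta_a_mA, a0 + lim$delta_a_mA)  # reachable band
    w <- runif(1, 450, 600)
    ch <- channel_config(0, "x", a, w)
    mask <- admissible_actions(ch, lim, initial_amplitude_mA = a0,
                               amplitude_saturated = sample(c(TRUE, FALSE), 1))
    expect_true(mask[5])
  }
})

test_that("amplitude excursion stays anchored to the initial baseline", {
  lim <- parameter_limits(step_a_mA = 2, delta_a_mA = 10)
  ch <- channel_config(0, "x", 54, 500)  # drifted +9 from a0 = 45
  expect_false(is_admissible(ch, fes_action(1, 0), lim, initial_amplitude_mA = 45))
  expect_true(is_admissible(ch, fes_action(-0.5, 0), lim, initial_amplitude_mA = 45))
  # repeated admissible increments never exceed a0 + delta_a
  ch <- channel_config(0, "x", 45, 500)
  for (i in 1:20) {
    if (is_admissible(ch, fes_action(1, 0), lim, 45))
      ch <- apply_action(ch, fes_action(1, 0), lim, 45)
  }
  expect_lte(ch$amplitude_mA, 55)
})

test_that("charge rate does the unit arithmetic and is monotone", {
  expect_equal(pulse_charge_rate(45, 500, 35), 787.5)  # uC/s
  expect_equal(pulse_charge_rate(0, 500, 35), 0)
  expect_equal(pulse_charge_rate(45, 0, 35), 0)
  expect_equal(pulse_charge_rate(45, 500, 35, phases = 2), 1575)
  g <- expand.grid(a = c(0, 45, 100), w = c(450, 600), f = c(20, 35))
  q <- pulse_charge_rate(g$a, g$w, g$f)
  for (v in c("a", "w", "f")) {
    for (i in seq_len(nrow(g))) for (j in seq_len(nrow(g))) {
      others <- setdiff(c("a", "w", "f"), v)
      if (g[[v]][i] <= g[[v]][j] &&
          all(g[others][i, ] == g[others][j, ]))
        expect_lte(q[i], q[j])
    }
  }
  expect_error(pulse_charge_rate(-1, 500, 35), "non-negative")
})

test_that("window membership handles wrap-around and closed boundaries", {
  # brute force oracle over integer degrees: shift so the window starts at 0
  oracle <- function(th, s, e) ((th - s) %% 360) <= ((e - s) %% 360)
  cases <- list(c(300, 60), c(0, 120), c(350, 10), c(120, 240))
  for (cs in cases) {
    th <- 0:359
    expect_equal(in_window(th, cs[1], cs[2]), oracle(th, cs[1], cs[2]),
                 info = paste(cs, collapse = "-"))
  }
  ch <- channel_config(0, "x", 45, 500, theta_start = 300, theta_end = 60)
  expect_true(in_window(350, ch))
  expect_false(in_window(180, ch))
  expect_true(in_window(300, ch))  # closed at start
  expect_true(in_window(60, ch))   # closed at end
  # full-circle window
  expect_true(all(in_window(0:359, 0, 359.99)))
})

test_that("stimulation commands clip at the physical limits", {
  lim <- parameter_limits()
  ch <- channel_config(0, "x", 50, 500, theta_start = 0, theta_end = 120)
  cmd <- stimulation_command(ch, theta = 60, pi_u_mA = 70, limits = lim)
  expect_equal(cmd$amplitude_mA, 100)
  expect_true(cmd$active)
  cmd2 <- stimulation_command(ch, theta = 200, pi_u_mA = 10, limits = lim)
  expect_false(cmd2$active)
  expect_equal(cmd2$amplitude_mA, 60)
})
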