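---
title: "Methods: a learning stimulation pattern for FES-cycling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a learning stimulation pattern for FES-cycling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fescycle)
```

## The control problem

In FES-cycling, surface electrodes stimulate leg muscle groups — vastus
medialis (VM), vastus lateralis + rectus femoris (VL+RF) and hamstrings
(HAM) on each side, six channels in all — within angular windows of the
crank cycle, so that the evoked contractions drive the pedals. The charge a
pulse train injects is the product of pulse amplitude (mA), width (µs) and
frequency (Hz). Two coupled questions arise at every session: how to track a
reference cadence in closed loop, and how to choose the *baseline* pulse
parameters, which interact with muscle fatigue and ultimately decide how
long the rider can pedal.

`fescycle` implements a two-layer answer. A shared proportional–integral
(PI) controller modulates pulse amplitude at 10 Hz to track the reference
cadence (35 rpm by default). In parallel, a decayed-epsilon-greedy agent
adapts each channel's baseline amplitude and width in discrete steps,
learning — per channel and online — which adjustment earns the most reward
under a configurable charge-versus-error policy.

## The agent

Each channel has the 9-element action set `{(α, ω) : α, ω ∈ {−0.5, 0, 1}}`;
an action changes the working amplitude by `α·k_a` and width by `ω·k_w`
(defaults `k_a = 2` mA, `k_w = 20` µs). Actions are admissible only if
(1) the resulting parameters stay in range — amplitude within ±10 mA of the
session's initial baseline and inside `[0, 100]` mA, width inside
`[450, 600]` µs — and (2) the width is not reduced while the delivered
amplitude is saturated at the 100 mA ceiling (widening is allowed there:
it is the only remaining way to add charge).

A selected action is held for a 5-s interaction; its reward is the mean of
the in-window instantaneous rewards over that interaction (an interaction
whose window the crank never entered scores 0). The instantaneous reward of
channel `c` is

```
R = | P² · A  −  P̄² · (Ma − A) |  /  ē        inside the channel's window
R = 0                                          otherwise
```

with `P` the working width and `A` the delivered amplitude (baseline + agent
delta + PI output, clipped at the ceiling `Ma`) in a scaled convention
(width × 10⁻⁴, amplitude × 10⁻³, so 500 µs → 0.05 and 100 mA → 0.1), the
mirrored width `P̄ = (w_max + w_min − w − PK) × 10⁻⁴` with `PK = 100` µs, and
`ē` the magnitude of the moving-average cadence error (window 10). Above a
crossing amplitude (half the ceiling at the defaults) the first term
dominates and wider pulses earn more — the policy banks charge headroom to
delay amplitude saturation; below it, narrower pulses win and stimulation
cost is prioritized. Dividing by `ē` makes every reward larger when tracking
is good, so the agent prefers actions compatible with low cadence error.

Value estimates use the sample average, updated incrementally
(`Q ← Q + (R − Q)/n`), and selection is epsilon-greedy: explore uniformly
over the admissible set with probability ε, otherwise take the admissible
argmax. After each 45-s episode (9 interactions) the greedy action of every
channel is promoted into its baseline, ε is multiplied by the decay rate
(0.99), and the value table resets so the next episode starts from the new
baseline independently of the previous one.

### Numerical choices

* **Scaling exponents.** The reward's width/amplitude normalizers are read
  as 10⁻⁴ and 10⁻³. Positive exponents would scale every reward by the same
  astronomically large constant without changing any argmax, so the choice
  is immaterial to behaviour; both are exposed in `reward_params()`.
* **Error clamp.** `ē` is clamped below at 0.1 rpm (`error_floor_rpm`) so
  perfect tracking does not divide by zero. The error enters as `|ē|`; a
  signed error would flip reward signs meaninglessly.
* **Tie-breaks.** Greedy ties resolve by a seeded uniform draw among the
  maxima. An optional `prefer_noop` mode resolves ties that include the
  no-op `(0, 0)` to the no-op, preventing random baseline drift during
  unrewarded startup; it is off by default so the base behaviour is the
  unbiased draw.
* **Q initialization.** Zeros. Rewards are non-negative, so zero is
  optimistic-neutral: any observed reward immediately beats the untried.
* **Interaction pooling.** Mean (not sum) of in-window samples, which keeps
  Q magnitudes comparable across cadences and window sizes.
* **Action indices.** 1-based, lexicographic over `(α, ω)` with the set
  ordered `(−0.5, 0, 1)`; the no-op is index 5. Only the ordering's
  stability matters; it is fixed and documented.
* **Episode reset versus carry-over.** The session default resets estimates
  each episode (each episode judged from its own baseline). For stationary
  bandit diagnostics `run_bandit(reset_each_episode = FALSE)` carries
  estimates across episodes; with per-episode reset a 9-interaction episode
  simply cannot identify the optimum reliably (a fresh episode finds a
  uniquely better arm with probability ≈ 0.38 at ε = 0.4), which is a
  property of the episodic design, not of the estimator.

## The PI layer

One shared PI output `u` (mA) is added to every enabled channel's working
amplitude before clipping at the ceiling: `u = clip(kp·e + ki·∫e dt, 0,
u_max)` with forward-Euler integration at 10 Hz and conditional-integration
anti-windup (the integrator freezes while the output is clipped). Defaults
`kp = 2` mA/rpm, `ki = 0.6` mA/(rpm·s), `u_max = 55` mA were tuned once
against the default light-gear plant so that closed-loop cadence settles
within ±1 rpm of 35 rpm inside 30 s and holds it; they live in
`pi_config()`. A per-channel error option is not provided — the deployed
controller modulates all channels simultaneously — but gains are plain
config values.

## The synthetic environment

The environment exists to exercise the controller at desk scale, not to be
a validated musculoskeletal model. Its parts:

* **Torque generation.** Each channel has a raised-cosine torque profile
  (default: centers every 60°, half-support 60°, peaks 10/9/9 N·m for
  VL+RF/VM/HAM, left side phased 180°), scaled by a piecewise-linear
  recruitment of its charge rate (threshold 200 µC/s, saturation 2500 µC/s)
  and by a per-channel fitness state. Stimulation windows default to the
  profile supports, so several straddle 0°/360° and exercise wrap-around.
  Overlapping equal-height cosine bumps at half-support spacing sum to a
  nearly flat profile, which keeps intra-revolution torque ripple — and
  hence cadence ripple — small.
* **Crank.** `J·dω/dt = Σ act_c·g_c(θ) − b·ω − τ_load`, integrated
  semi-implicitly at 10-ms substeps; cadence floored at zero (the rider
  cannot be driven backwards). `J = 1.2` kg·m² (effective inertia of crank,
  legs and drivetrain), `b = 0.8` N·m·s/rad; load torque 1.0 N·m for the M1
  gear preset and 2.5 N·m for the heavier M2.
* **Fatigue.** `dφ/dt = −λ·act·(φ − φ_min) + ρ·(1 − φ)·(1 − act)` per
  channel, `λ = 8×10⁻⁴`, `ρ = 2×10⁻⁵`, `φ_min = 0.3`. The rates were
  calibrated once so that a PI-only session on the M2 preset saturates the
  amplitude ceiling after roughly 24 simulated minutes — inside the 20–40
  minute band the presets are specified to — while the M1 preset tracks for
  a full hour. Against this plant, the agent's width increases demonstrably
  delay saturation on M2, reproducing the qualitative signature the design
  targets.
* **Encoder.** Angle floor-quantized at 1440 counts/rev (a 360-PPR
  incremental encoder in quadrature); cadence is the count difference over
  each 100-ms reporting window, so the measurement is discrete to about
  0.42 rpm and continuous cadence is deliberately unavailable to the
  controller.
* **Noise.** Optional seeded multiplicative torque noise
  (`torque_noise_sd`), off by default so tests are deterministic.

What the environment does *not* emulate: calcium/Hill-type contraction
dynamics, spasticity, day-to-day variability, 3-D biomechanics, electrode
placement effects, or measurement dropout. Tests passing against this plant
show the controller's logic is correct and its qualitative interplay with
fatigue is as designed; they do not certify performance on a human rider.

## Sessions, logging and metrics

`run_session()` runs measure → PI → agent bookkeeping → command →
environment at 10 Hz, with tick-based clocks (50 ticks per interaction, 450
per episode), and logs one row per tick: reference and measured cadence,
crank angle, PI output, ε, episode, and per channel the delivered amplitude
and width, gating flag, action index, instantaneous reward and fitness. The
first action of an episode is selected immediately after promotion at the
episode boundary. Logs are CSV with a JSON header holding the resolved
config and seed; identical config + seed gives bitwise-identical logs.
`scenario_presets()` returns the six protocol presets (PI-only, 60%@.99,
40%@.99 × M1/M2; baselines 45/50 mA right/left, 500 µs, 35 Hz).

Metrics recompute everything from the log alone: `stimulation_cost()` (sum
of in-window charge rates; a window-100 moving average is the conventional
presentation), `accumulated_series()` for reward and |cadence error|,
`time_to_saturation()` (first sustained hold of the smoothed minimum
delivered amplitude at the ceiling), and `summarize_session()` (distance,
speed, and a mean ± SD mechanical-power proxy of the simulated crank —
explicitly not comparable watt-for-watt with a rider). A true cumulative
sum of non-negative rewards cannot decrease, so where a declining
"accumulated reward" is of interest after saturation, the windowed reward
*rate* (`moving_average()` of the per-tick reward) is the quantity to plot;
both are available and neither is conflated with the other.

## Problem sizes used in the test suite

Unit and property tests run on seconds-to-minutes of simulated time; the
heavier properties use 20 seeds × two gears of 5-minute partially-fatigued
sessions (admissibility safety), 20 paired seeds of 30-minute M2 sessions
(saturation delay, censoring non-saturating runs at the session end — a
conservative choice that can only shorten the measured delay), a simulated
hour for the ε-decay law, and 200 episodes for bandit convergence. These
sizes were chosen so the full suite runs in a few minutes while each
property retains a comfortable margin.

## Known limitations

* The fatigue and recruitment constants are calibrated to the stated study
  conditions, not fitted to data; absolute distances and powers are
  synthetic-plant artifacts even though they land in a plausible range.
* The agent is a per-channel bandit: value estimates are tabulated per
  action only, mirroring the stateless sample-average formulation; the
  crank angle and cadence error shape the reward but do not index Q.
* Frequency and window-angle actions are enumerable
  (`enumerate_actions(3)`) but not wired into the default agent, which
  holds them constant.
* With per-episode resets the promoted action is noisy early on; the decay
  schedule, not the within-episode estimator, is what shifts the balance
  from exploration to exploitation over a session.
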