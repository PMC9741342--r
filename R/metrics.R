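# Session-log metrics: moving averages, injected-charge accounting,
# accumulated reward/error, saturation timing and session summaries.

# accept a fescycle_log or a bare data.frame of ticks
.log_data <- function(log) {
  if (inherits(log, "fescycle_log")) log$data
  else if (is.data.frame(log)) log
  else stop("expected a fescycle_log or a data frame")
}

.log_channels <- function(df) {
  ids <- sub("_on$", "", grep("^ch[0-9]+_on$", names(df), value = TRUE))
  if (length(ids) == 0L) stop("log has no channel columns")
  ids
}

#' Trailing moving average
#'
#' Simple (trailing) moving average. For the first `k < window` samples the
#' mean of the available prefix is used, so derived series start at t = 0
#' instead of carrying missing values.
#'
#' @param x Numeric series.
#' @param window Window size (>= 1).
#' @return A series of the same length as `x`.
#' @examples
#' moving_average(1:20, 10)[20]  # mean(11:20) = 15.5
#' @export
moving_average <- function(x, window) {
  if (length(window) != 1 || is.na(window) || window < 1)
    stop("window must be a positive integer")
  n <- length(x)
  if (n == 0L) return(numeric(0))
  window <- as.integer(window)
  cs <- cumsum(x)
  lag <- c(rep(0, min(window, n)), cs[seq_len(max(0L, n - window))])
  (cs - lag) / pmin(seq_len(n), window)
}

#' Summed injected-charge time series
#'
#' Per tick, the sum over channels of the injected charge rate
#' (amplitude x width x frequency), counting a channel only while the crank
#' is inside its stimulation window - the stimulation cost of the session.
#'
#' @param log A `fescycle_log` or its data frame.
#' @param smooth_window Optional moving-average window for presentation
#'   (the conventional choice is 100 samples, i.e. 10 s at 10 Hz); `NULL`
#'   returns the raw series.
#' @return Numeric series of total charge rate (uC/s), one value per tick.
#' @export
stimulation_cost <- function(log, smooth_window = NULL) {
  df <- .log_data(log)
  total <- 0
  for (id in .log_channels(df)) {
    total <- total + df[[paste0(id, "_on")]] *
      pulse_charge_rate(df[[paste0(id, "_amp_mA")]],
                        df[[paste0(id, "_width_us")]],
                        df[[paste0(id, "_freq_hz")]])
  }
  if (!is.null(smooth_window)) total <- moving_average(total, smooth_window)
  total
}

#' Accumulated reward or absolute cadence error
#'
#' Running sum of a per-tick quantity: `"reward"` sums the instantaneous
#' rewards across channels; `"abs_error"` uses `|reference - measured|`.
#' Sampled at the log's 10-Hz rate.
#'
#' @param log A `fescycle_log` or its data frame.
#' @param field `"reward"` or `"abs_error"`.
#' @return Cumulative numeric series, one value per tick.
#' @export
accumulated_series <- function(log, field = c("reward", "abs_error")) {
  field <- match.arg(field)
  df <- .log_data(log)
  per_tick <- if (field == "reward") {
    cols <- paste0(.log_channels(df), "_reward")
    rowSums(df[, cols, drop = FALSE])
  } else {
    abs(df$ref_rpm - df$cadence_rpm)
  }
  cumsum(per_tick)
}

#' Time at which the delivered amplitude saturates
#'
#' First time (s) at which the smoothed per-tick minimum of the enabled
#' channels' delivered amplitudes reaches the ceiling and holds it - the
#' point after which the PI loop has no headroom and cadence tracking
#' degrades. `NA` if the session never saturates.
#'
#' @param log A `fescycle_log` or its data frame.
#' @param threshold_mA Amplitude threshold (mA); default 99.5.
#' @param hold_s Required hold duration (s).
#' @param smooth_window Moving-average window applied before thresholding.
#' @return Time in seconds, or `NA_real_`.
#' @export
time_to_saturation <- function(log, threshold_mA = 99.5, hold_s = 10,
                               smooth_window = 100) {
  df <- .log_data(log)
  ids <- .log_channels(df)
  amp <- do.call(pmin, lapply(ids, function(id) df[[paste0(id, "_amp_mA")]]))
  sm <- moving_average(amp, smooth_window)
  dt <- if (nrow(df) > 1) df$t_s[2] - df$t_s[1] else 0.1
  need <- max(1L, as.integer(round(hold_s / dt)))
  r <- rle(sm >= threshold_mA)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= need)
  if (length(hit) == 0L) return(NA_real_)
  df$t_s[starts[hit[1]]]
}

#' Session summary
#'
#' Distance, duration, average speed and an average-power proxy in the style
#' of a session report. Distance integrates the measured cadence times a
#' gear-dependent distance per crank revolution; "power" is the mean
#' mechanical power of the simulated crank (an explicit proxy - watt-level
#' comparability with a real rider is not claimed).
#'
#' @param log A `fescycle_log`.
#' @param meters_per_rev Distance per crank revolution (m). Defaults by gear
#'   preset: 2.05 (m1), 2.2 (m2).
#' @return A list of class `fescycle_summary` with `label`, `distance_m`,
#'   `duration_s`, `avg_speed_kmh`, `avg_power_w`, `sd_power_w`.
#' @export
summarize_session <- function(log, meters_per_rev = NULL) {
  df <- .log_data(log)
  cfg <- if (inherits(log, "fescycle_log")) log$config else NULL
  if (is.null(meters_per_rev)) {
    preset <- cfg$env$preset %||% "custom"
    meters_per_rev <- switch(preset, m1 = 2.05, m2 = 2.2,
                             stop("meters_per_rev required for custom environments"))
  }
  dt <- if (nrow(df) > 1) df$t_s[2] - df$t_s[1] else 0.1
  dist <- sum(df$cadence_rpm) / 60 * dt * meters_per_rev
  dur <- nrow(df) * dt
  structure(list(
    label = cfg$label %||% "session",
    distance_m = dist, duration_s = dur,
    avg_speed_kmh = dist / dur * 3.6,
    avg_power_w = mean(df$power_w), sd_power_w = stats::sd(df$power_w)
  ), class = "fescycle_summary")
}

#' @export
print.fescycle_summary <- function(x, ...) {
  cat(sprintf("<fescycle_summary> %s\n", x$label))
  cat(sprintf("  distance   %8.1f m\n", x$distance_m))
  cat(sprintf("  duration   %8.1f s\n", x$duration_s))
  cat(sprintf("  avg speed  %8.2f km/h\n", x$avg_speed_kmh))
  cat(sprintf("  avg power  %8.2f +/- %.2f W (simulated-crank proxy)\n",
              x$avg_power_w, x$sd_power_w))
  invisible(x)
}
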