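#' Construct a light/TTL pulse train
#'
#' @param onsets Pulse onset times, s (sorted; pulses must not overlap).
#' @param duration Pulse length, s (scalar).
#' @param mode `"direct"` (pulse coincides with detection) or `"delayed"`
#'   (control mode: pulse shifted by `delay`).
#' @param intensity `"full"` or `"half"` (half-intensity pulses are used for
#'   the per-cell inhibition control sleep).
#' @param delay Detector-to-laser delay, s (0 for direct mode; must be > 0
#'   for delayed mode).
#' @return A `pulse_train`: data frame with `onset` and `offset` columns and
#'   the remaining fields as attributes.
#' @export
pulse_train <- function(onsets, duration, mode = c("direct", "delayed"),
                        intensity = c("full", "half"), delay = 0) {
  mode <- match.arg(mode)
  intensity <- match.arg(intensity)
  assert_scalar_pos(duration, "duration")
  if (mode == "delayed" && delay <= 0)
    stopf("delayed mode requires `delay` > 0")
  onsets <- sort(as.numeric(onsets))
  if (length(onsets) > 1 && any(diff(onsets) < duration))
    stopf("pulses must not overlap")
  structure(data.frame(onset = onsets, offset = onsets + duration),
            class = c("pulse_train", "data.frame"),
            duration = duration, mode = mode, intensity = intensity,
            delay = delay)
}

#' Regularly timed pulses (inhibition-control protocol)
#'
#' The per-cell inhibition check uses regularly timed half-intensity pulses
#' (500 ms every 3 s by default) during a rest session.
#'
#' @param t_start,t_end Session bounds, s.
#' @param period Pulse period, s.
#' @param duration Pulse length, s.
#' @param intensity `"full"` or `"half"`.
#' @return A `pulse_train`.
#' @export
regular_pulse_train <- function(t_start, t_end, period = 3, duration = 0.5,
                                intensity = "half") {
  if (period <= duration) stopf("`period` must exceed `duration`")
  onsets <- seq(t_start + period, t_end - duration, by = period)
  pulse_train(onsets, duration, mode = "direct", intensity = intensity)
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("<pulse_train> %d pulses x %.0f ms, mode=%s, intensity=%s%s\n",
              nrow(x), attr(x, "duration") * 1000, attr(x, "mode"),
              attr(x, "intensity"),
              if (attr(x, "mode") == "delayed")
                sprintf(", delay=%.2f s", attr(x, "delay")) else ""))
  invisible(x)
}

#' Apply optogenetic light suppression to spike trains
#'
#' Emulates archaerhodopsin-mediated inhibition of pyramidal cells: each
#' spike falling inside a light pulse is deleted independently with
#' probability `suppression`; spikes outside pulses are untouched. An
#' optional rebound adds Poisson spikes in a short window after each pulse
#' offset, mimicking the rebound activity seen after release from
#' inhibition.
#'
#' @param spikes A `spike_train_set`.
#' @param pulses A [pulse_train()].
#' @param suppression Per-spike deletion probability inside pulses, in
#'   `[0, 1]`.
#' @param rebound_params `NULL` (default, no rebound) or a list with
#'   `window` (s after pulse offset) and `rate` (Hz of added spikes per
#'   unit).
#' @param seed Optional integer seed.
#' @return A `spike_train_set` with the same units.
#' @export
apply_light_suppression <- function(spikes, pulses, suppression,
                                    rebound_params = NULL, seed = NULL) {
  if (!is.numeric(suppression) || length(suppression) != 1L ||
      suppression < 0 || suppression > 1)
    stopf("`suppression` must be a single value in [0, 1]")
  with_seed(seed, {
    inside <- in_intervals(spikes$time, pulses$onset, pulses$offset)
    drop <- inside & stats::runif(nrow(spikes)) < suppression
    out <- spikes[!drop, , drop = FALSE]
    if (!is.null(rebound_params) && nrow(pulses)) {
      w <- rebound_params$window %||% 0.05
      r <- rebound_params$rate %||% 0
      units <- attr(spikes, "units")$unit
      extra <- lapply(units, function(u) {
        n <- stats::rpois(nrow(pulses), r * w)
        idx <- rep.int(seq_len(nrow(pulses)), n)
        if (!length(idx)) return(NULL)
        data.frame(time = pulses$offset[idx] + stats::runif(length(idx)) * w,
                   unit = u)
      })
      out <- rbind(as.data.frame(out), do.call(rbind, extra))
    }
    new_spike_train_set(out, units = attr(spikes, "units"),
                        t_start = attr(spikes, "t_start"),
                        t_stop = attr(spikes, "t_stop"))
  })
}

# TRUE for each x falling inside any [lo_i, hi_i) interval (intervals sorted,
# non-overlapping).
in_intervals <- function(x, lo, hi) {
  if (!length(lo)) return(rep(FALSE, length(x)))
  i <- findInterval(x, lo)
  i > 0 & x < hi[pmax(i, 1)]
}
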