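#' Closed-loop ripple detector configuration
#'
#' Digital counterpart of the analog ripple-detector device: a causal 4-pole
#' band-pass filter centred on the ripple band, a fixed gain, a comparator
#' threshold, and a non-retriggerable TTL pulse. In the delayed (control)
#' mode the laser pulse is shifted by `control_delay` after the TTL so it
#' misses the triggering event while delivering identical light energy.
#'
#' @param center_freq Filter centre frequency, Hz.
#' @param band Pass band edges, Hz; defaults to 100-200 Hz around the
#'   centre.
#' @param filter_order Total number of poles (must be even; realized as a
#'   Butterworth band-pass of order `filter_order / 2`).
#' @param gain Post-filter amplification.
#' @param threshold_sd Comparator threshold in multiples of the filtered
#'   signal's session s.d.
#' @param pulse_length TTL/laser pulse length, s.
#' @param control_delay Detector-to-laser delay in delayed mode, s.
#' @return A `detector_config`.
#' @export
detector_config <- function(center_freq = 150, band = c(100, 200),
                            filter_order = 4, gain = 10, threshold_sd = 4,
                            pulse_length = 0.2, control_delay = 1.32) {
  if (filter_order %% 2 != 0 || filter_order < 2)
    stopf("`filter_order` (poles) must be a positive even number")
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1])
    stopf("`band` must be increasing positive edges")
  assert_scalar_pos(pulse_length, "pulse_length")
  if (control_delay < 0) stopf("`control_delay` must be >= 0")
  structure(list(center_freq = center_freq, band = band,
                 filter_order = filter_order, gain = gain,
                 threshold_sd = threshold_sd, pulse_length = pulse_length,
                 control_delay = control_delay),
            class = "detector_config")
}

#' Differential ripple channel
#'
#' Subtracts the stratum radiatum channel from the stratum pyramidale
#' channel to isolate ripple oscillations (the sharp wave is common-mode
#' rejected in sign: the radiatum trough adds to the pyramidale ripple).
#'
#' @param lfp An `lfp_recording` with exactly one channel tagged
#'   `pyramidale` and one tagged `radiatum`.
#' @return Numeric vector, same length and sampling rate as the input.
#' @export
differential_signal <- function(lfp) {
  ip <- which(lfp$roles == "pyramidale")
  ir <- which(lfp$roles == "radiatum")
  if (length(ip) != 1L || length(ir) != 1L)
    stopf("recording must have exactly one pyramidale and one radiatum channel")
  lfp$samples[, ip] - lfp$samples[, ir]
}

#' Causal ripple-band filter
#'
#' Applies the detector's band-pass (discretized Butterworth, `filter_order`
#' poles total) causally — a one-pass recursive filter, as the analog device
#' is causal — followed by the gain.
#'
#' @param x Numeric signal.
#' @param sampling_rate Hz.
#' @param config A [detector_config()].
#' @return Filtered, amplified signal of the same length.
#' @export
ripple_bandpass <- function(x, sampling_rate, config = detector_config()) {
  ny <- sampling_rate / 2
  if (config$band[2] >= ny)
    stopf("band edge %.0f Hz is at or above Nyquist (%.0f Hz)",
          config$band[2], ny)
  bf <- signal::butter(config$filter_order / 2, config$band / ny, type = "pass")
  as.numeric(signal::filter(bf, x)) * config$gain
}

#' Emulate the online closed-loop detector
#'
#' Scans the filtered signal causally: at every upward crossing of the
#' comparator threshold occurring outside an active TTL, a fixed-length TTL
#' pulse is emitted; no new TTL can begin while one is active (and the
#' detector may re-fire immediately after a pulse ends). In `direct` mode
#' the laser pulses coincide with the TTLs; in `delayed` mode every laser
#' onset is the TTL onset plus `control_delay`, so pulse count and total
#' light energy are identical across modes.
#'
#' @param filtered Band-passed, amplified signal (see [ripple_bandpass()]).
#' @param sampling_rate Hz.
#' @param config A [detector_config()].
#' @param mode `"direct"` (blockade) or `"delayed"` (control).
#' @param threshold Absolute comparator level; default
#'   `config$threshold_sd * sd(filtered)`.
#' @return List with `ttl` and `laser`, both [pulse_train()]s.
#' @export
online_closed_loop <- function(filtered, sampling_rate,
                               config = detector_config(),
                               mode = c("direct", "delayed"),
                               threshold = NULL) {
  mode <- match.arg(mode)
  threshold <- threshold %||% (config$threshold_sd * stats::sd(filtered))
  if (!is.finite(threshold) || threshold <= 0)
    stopf("`threshold` must be a positive number")
  above <- filtered >= threshold
  crossings <- which(above & !c(FALSE, above[-length(above)]))
  pulse_n <- round(config$pulse_length * sampling_rate)
  onsets_idx <- integer(0)
  guard_until <- -1L
  for (i in crossings) {
    if (i > guard_until) {
      onsets_idx <- c(onsets_idx, i)
      guard_until <- i + pulse_n - 1L
    }
  }
  onsets <- (onsets_idx - 1L) / sampling_rate
  ttl <- pulse_train(onsets, config$pulse_length, mode = "direct")
  laser <- if (mode == "direct") ttl else
    pulse_train(onsets + config$control_delay, config$pulse_length,
                mode = "delayed", delay = config$control_delay)
  list(ttl = ttl, laser = laser)
}

#' Non-stringent offline SWR detector
#'
#' Offline envelope detector run at low stringency so that truncated,
#' low-amplitude remnants of blocked events are still identified: band-pass
#' (zero-phase) -> rectify -> moving-average smooth -> z-score against the
#' whole-session statistics -> contiguous suprathreshold runs meeting the
#' duration bounds become events, with nearby events merged.
#'
#' @param lfp An `lfp_recording` (the differential channel is formed
#'   internally), or a plain numeric vector with `sampling_rate` supplied.
#' @param band Detection band, Hz.
#' @param threshold_sd Envelope z-score threshold (default 2: non-stringent).
#' @param min_duration,max_duration Event duration bounds, s.
#' @param merge_gap Events closer than this are merged, s.
#' @param smooth Envelope moving-average length, s (default 15 ms, about two
#'   ripple cycles, so truncated event stubs integrate above threshold).
#' @param sampling_rate Required when `lfp` is a plain vector.
#' @return A `ripple_event_table` with provenance `"offline"` (columns
#'   `onset`, `offset`, `peak_time`, `peak_frequency` (NA), `amplitude` =
#'   peak envelope z-score).
#' @export
offline_detect <- function(lfp, band = c(100, 250), threshold_sd = 2,
                           min_duration = 0.015, max_duration = 0.5,
                           merge_gap = 0.010, smooth = 0.015,
                           sampling_rate = NULL) {
  if (inherits(lfp, "lfp_recording")) {
    x <- differential_signal(lfp)
    fs <- lfp$sampling_rate
  } else {
    x <- as.numeric(lfp)
    fs <- sampling_rate %||% stopf("`sampling_rate` required for a plain signal")
  }
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      peak_time = numeric(0), peak_frequency = numeric(0),
                      amplitude = numeric(0))
  if (!length(x)) return(new_ripple_event_table(empty, "offline"))
  if (band[2] >= fs / 2) stopf("band must lie below Nyquist")

  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, x)
  k <- max(1L, round(smooth * fs))
  env <- as.numeric(stats::filter(abs(filt), rep(1 / k, k), sides = 2))
  env[is.na(env)] <- 0
  z <- (env - mean(env)) / stats::sd(env)

  above <- z >= threshold_sd
  if (!any(above)) return(new_ripple_event_table(empty, "offline"))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])

  # merge runs separated by less than merge_gap
  if (nrow(runs) > 1) {
    gap_n <- merge_gap * fs
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      if (runs[i, 1] - merged[nrow(merged), 2] <= gap_n)
        merged[nrow(merged), 2] <- runs[i, 2]
      else merged <- rbind(merged, runs[i, ])
    }
    runs <- merged
  }

  dur <- (runs[, 2] - runs[, 1] + 1) / fs
  runs <- runs[dur >= min_duration & dur <= max_duration, , drop = FALSE]
  if (!nrow(runs)) return(new_ripple_event_table(empty, "offline"))
  ev <- do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
    idx <- runs[i, 1]:runs[i, 2]
    pk <- idx[which.max(z[idx])]
    data.frame(onset = (runs[i, 1] - 1) / fs, offset = (runs[i, 2] - 1) / fs,
               peak_time = (pk - 1) / fs, peak_frequency = NA_real_,
               amplitude = max(z[idx]))
  }))
  new_ripple_event_table(ev, "offline")
}

#' Score detected events against ground truth
#'
#' Greedy one-to-one matching of detected events to ground-truth events: a
#' detection matches a truth event if their intervals overlap or their
#' onsets are within `tolerance`. Latency is the detection onset minus the
#' truth onset, also expressed in ripple cycles.
#'
#' @param detected,truth `ripple_event_table`s (or pulse trains, for TTL
#'   latency), sorted by onset.
#' @param tolerance Onset matching tolerance, s.
#' @param ripple_freq Hz, used to convert latencies to cycles.
#' @return A `detection_evaluation` list: `precision`, `recall`,
#'   `n_detected`, `n_truth`, `n_matched`, `latency` (s, per matched event)
#'   and `latency_cycles`.
#' @export
evaluate_detection <- function(detected, truth, tolerance = 0.05,
                               ripple_freq = 160) {
  d_on <- detected$onset; d_off <- detected$offset
  t_on <- truth$onset; t_off <- truth$offset
  used <- rep(FALSE, length(d_on))
  match_idx <- rep(NA_integer_, length(t_on))
  for (i in seq_along(t_on)) {
    cand <- which(!used &
                    (pmin(d_off, t_off[i]) > pmax(d_on, t_on[i]) |
                       abs(d_on - t_on[i]) <= tolerance))
    if (length(cand)) {
      j <- cand[which.min(abs(d_on[cand] - t_on[i]))]
      used[j] <- TRUE
      match_idx[i] <- j
    }
  }
  n_matched <- sum(!is.na(match_idx))
  lat <- d_on[match_idx[!is.na(match_idx)]] - t_on[!is.na(match_idx)]
  structure(list(
    precision = if (length(d_on)) n_matched / length(d_on) else NaN,
    recall = if (length(t_on)) n_matched / length(t_on) else NaN,
    n_detected = length(d_on), n_truth = length(t_on), n_matched = n_matched,
    latency = lat, latency_cycles = lat * ripple_freq),
    class = "detection_evaluation")
}

#' @export
print.detection_evaluation <- function(x, ...) {
  cat(sprintf("<detection_evaluation> precision %.3f, recall %.3f (%d/%d/%d det/truth/matched)\n",
              x$precision, x$recall, x$n_detected, x$n_truth, x$n_matched))
  if (length(x$latency))
    cat(sprintf("  latency: mean %.1f ms (%.2f cycles)\n",
                mean(x$latency) * 1000, mean(x$latency_cycles)))
  invisible(x)
}
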