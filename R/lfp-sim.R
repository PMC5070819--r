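#' Synthesize a sleep LFP with ground-truth sharp wave/ripple events
#'
#' Produces a two-channel local field potential emulating a CA1 recording
#' during slow-wave sleep: the stratum pyramidale channel carries 1/f-like
#' background noise plus discrete ripple bursts (Gaussian-enveloped
#' sinusoids, 160 Hz by default), and the stratum radiatum channel carries
#' independent background plus a concurrent negative sharp-wave deflection.
#' The injected events are returned as an exact ground-truth table.
#'
#' Ripple amplitude is specified in multiples of the standard deviation of
#' the band-passed (100-250 Hz) background, so default detection thresholds
#' are meaningful regardless of the background level. Setting
#' `truncate_after_cycles` cuts every ripple's envelope that many cycles
#' after its onset, emulating a successful closed-loop blockade in which the
#' oscillation is destroyed within about two cycles.
#'
#' @param duration Recording length, s.
#' @param ripple_rate Mean event rate, Hz (default 0.3, typical of
#'   slow-wave sleep).
#' @param ripple_freq Ripple oscillation frequency, Hz (default 160, the
#'   predominant frequency of intact events).
#' @param ripple_cycles Nominal number of cycles per event (default 7); sets
#'   the envelope width.
#' @param ripple_amp Burst peak amplitude in multiples of the background's
#'   100-250 Hz band s.d. (default 5).
#' @param sharp_wave_amp Sharp-wave trough amplitude on the radiatum channel
#'   in multiples of that channel's background s.d. (default 5, negative
#'   deflection).
#' @param noise_params List with `sd` (background s.d. in raw units, default
#'   40) and `slope` (spectral exponent of the 1/f-like component, default 1).
#' @param sampling_rate Hz (default 2000; must exceed `2 * ripple_freq`).
#' @param truncate_after_cycles If non-`NULL`, the ripple envelope is cut
#'   this many cycles after the oscillation becomes apparent (the envelope's
#'   half-maximum rise), emulating a blockade that destroys the event within
#'   about two cycles of its detection.
#' @param min_gap Minimum spacing between event peaks, s.
#' @param seed Optional integer seed.
#' @return A list with `lfp` (an `lfp_recording`) and `events` (a ground
#'   truth `ripple_event_table` with columns `onset`, `offset`, `peak_time`,
#'   `peak_frequency`, `amplitude`).
#' @examples
#' sim <- simulate_sleep_lfp(10, ripple_rate = 0.5, seed = 1)
#' nrow(sim$events)
#' @export
simulate_sleep_lfp <- function(duration, ripple_rate = 0.3, ripple_freq = 160,
                               ripple_cycles = 7, ripple_amp = 5,
                               sharp_wave_amp = 5,
                               noise_params = list(sd = 40, slope = 1),
                               sampling_rate = 2000,
                               truncate_after_cycles = NULL,
                               min_gap = 0.25, seed = NULL) {
  assert_scalar_pos(duration, "duration")
  assert_scalar_pos(sampling_rate, "sampling_rate")
  if (ripple_freq >= sampling_rate / 2)
    stopf("`ripple_freq` (%.0f Hz) must be below the Nyquist frequency (%.0f Hz)",
          ripple_freq, sampling_rate / 2)
  if (ripple_rate < 0) stopf("`ripple_rate` must be >= 0")

  fs <- sampling_rate
  n <- round(duration * fs)
  noise_sd <- noise_params$sd %||% 40
  slope <- noise_params$slope %||% 1

  with_seed(seed, {
    pyr <- pink_noise(n, fs, sd = noise_sd, slope = slope)
    rad <- pink_noise(n, fs, sd = noise_sd, slope = slope)

    # reference band s.d. of the background for amplitude calibration
    band_sd <- if (noise_sd > 0) {
      bf <- signal::butter(2, c(100, 250) / (fs / 2), type = "pass")
      stats::sd(signal::filtfilt(bf, pyr))
    } else 1

    ev_dur <- ripple_cycles / ripple_freq          # nominal event length, s
    env_sigma <- ev_dur / 4                        # +/- 2 sigma spans it
    times <- draw_event_times(duration, ripple_rate, min_gap + ev_dur,
                              edge = ev_dur)
    amp <- ripple_amp * band_sd
    sw_amp <- sharp_wave_amp * noise_sd

    t <- seq_len(n) / fs
    events <- data.frame(onset = numeric(0), offset = numeric(0),
                         peak_time = numeric(0), peak_frequency = numeric(0),
                         amplitude = numeric(0))
    for (tp in times) {
      i0 <- max(1L, floor((tp - 4 * env_sigma) * fs))
      i1 <- min(n, ceiling((tp + 4 * env_sigma) * fs))
      idx <- i0:i1
      tt <- t[idx] - tp
      env <- exp(-tt^2 / (2 * env_sigma^2))
      if (!is.null(truncate_after_cycles)) {
        # blockade emulation: the oscillation is destroyed within
        # `truncate_after_cycles` of becoming apparent (envelope half-max)
        rise_t <- -env_sigma * sqrt(2 * log(2))
        env[tt > rise_t + truncate_after_cycles / ripple_freq] <- 0
      }
      phase <- stats::runif(1, 0, 2 * pi)
      pyr[idx] <- pyr[idx] + amp * env * sin(2 * pi * ripple_freq * tt + phase)
      sw_env <- exp(-tt^2 / (2 * (ev_dur / 2)^2))
      rad[idx] <- rad[idx] - sw_amp * sw_env
      events <- rbind(events, data.frame(
        onset = tp - ev_dur / 2, offset = tp + ev_dur / 2, peak_time = tp,
        peak_frequency = ripple_freq, amplitude = amp))
    }
    events <- events[order(events$onset), , drop = FALSE]
    rownames(events) <- NULL
    lfp <- lfp_recording(cbind(pyramidale = pyr, radiatum = rad), fs,
                         roles = c("pyramidale", "radiatum"))
    list(lfp = lfp,
         events = new_ripple_event_table(events, provenance = "ground_truth"))
  })
}

# 1/f^slope-shaped Gaussian noise plus a white floor, scaled to sd.
pink_noise <- function(n, fs, sd = 1, slope = 1, white_frac = 0.2) {
  if (sd == 0) return(numeric(n))
  nf <- floor(n / 2)
  f <- seq_len(nf) * fs / n
  shape <- f^(-slope / 2)
  re <- stats::rnorm(nf) * shape
  im <- stats::rnorm(nf) * shape
  spec <- complex(real = c(0, re), imaginary = c(0, im))
  full <- c(spec, Conj(rev(spec[2:(n - nf)])))
  x <- Re(stats::fft(full, inverse = TRUE))[seq_len(n)]
  x <- x / stats::sd(x)
  w <- stats::rnorm(n)
  y <- sqrt(1 - white_frac) * x + sqrt(white_frac) * w
  y / stats::sd(y) * sd
}

# Poisson event times thinned to a minimum spacing, away from the edges.
draw_event_times <- function(duration, rate, min_gap, edge = 0) {
  if (rate <= 0 || duration <= 2 * edge) return(numeric(0))
  n <- stats::rpois(1, rate * duration)
  if (n == 0) return(numeric(0))
  tp <- sort(stats::runif(n, edge, duration - edge))
  keep <- c(TRUE, diff(tp) >= min_gap)
  while (!all(keep)) {
    tp <- tp[keep]
    keep <- c(TRUE, diff(tp) >= min_gap)
  }
  tp
}

#' Construct an LFP recording container
#'
#' @param samples Numeric matrix, one column per channel.
#' @param sampling_rate Hz.
#' @param roles Character vector of per-channel anatomical roles
#'   (`"pyramidale"`, `"radiatum"`, or `"other"`).
#' @param scale Volts per raw unit (kept as metadata; samples stay in raw
#'   units).
#' @return An `lfp_recording`.
#' @export
lfp_recording <- function(samples, sampling_rate, roles, scale = 1e-6) {
  samples <- as.matrix(samples)
  if (length(roles) != ncol(samples))
    stopf("`roles` must name every channel")
  roles <- match.arg(roles, c("pyramidale", "radiatum", "other"),
                     several.ok = TRUE)
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 roles = roles, scale = scale),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channels x %d samples @ %.0f Hz (%s)\n",
              ncol(x$samples), nrow(x$samples), x$sampling_rate,
              paste(x$roles, collapse = ", ")))
  invisible(x)
}

new_ripple_event_table <- function(df, provenance) {
  if (nrow(df)) {
    if (any(df$onset >= df$offset)) stopf("event onsets must precede offsets")
    if (is.unsorted(df$onset)) df <- df[order(df$onset), , drop = FALSE]
    if (nrow(df) > 1 && any(df$onset[-1] < df$offset[-nrow(df)]))
      stopf("events in a ripple event table must not overlap")
  }
  rownames(df) <- NULL
  structure(df, class = c("ripple_event_table", "data.frame"),
            provenance = provenance)
}
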