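#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, via the standard symmetric tridiagonal eigenproblem. Tapers
#' are unit-energy and ordered by decreasing in-band energy concentration.
#'
#' @param n Taper length, samples.
#' @param nw Time-bandwidth product (typically 2-4).
#' @param k Number of tapers; at most `2 * nw - 1` for well-concentrated
#'   tapers.
#' @return An `n` x `k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 3, k = 5) {
  if (k > 2 * nw - 1 + 1e-9)
    stopf("`k` must not exceed 2*nw - 1 (= %g)", 2 * nw - 1)
  if (n < k) stopf("`n` must be at least `k`")
  w <- nw / n
  i <- 0:(n - 1)
  diagonal <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- (1:(n - 1)) * ((n - 1):1) / 2
  A <- matrix(0, n, n)
  A[cbind(i + 1, i + 1)] <- diagonal
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(A, symmetric = TRUE)
  tapers <- e$vectors[, seq_len(k), drop = FALSE]
  # normalize: unit energy; symmetric tapers positive-summed, antisymmetric
  # tapers positive initial slope (standard sign convention)
  for (j in seq_len(k)) {
    v <- tapers[, j] / sqrt(sum(tapers[, j]^2))
    if (j %% 2 == 1) { if (sum(v) < 0) v <- -v }
    else if (v[2] - v[1] < 0) v <- -v
    tapers[, j] <- v
  }
  tapers
}

#' Multi-taper power spectrum of a signal segment
#'
#' Averages periodograms computed with orthogonal Slepian tapers, reducing
#' variance and spectral leakage relative to a single-window periodogram.
#' The segment mean is removed first.
#'
#' @param segment Numeric signal segment.
#' @param sampling_rate Hz.
#' @param nw Time-bandwidth product (default 3).
#' @param k Number of tapers (default 5).
#' @return A data frame with columns `freq` (Hz, 0 to Nyquist) and `power`
#'   (a.u., non-negative).
#' @export
multitaper_spectrum <- function(segment, sampling_rate, nw = 3, k = 5) {
  n <- length(segment)
  if (n < 8) stopf("segment too short for spectral estimation")
  x <- segment - mean(segment)
  tapers <- dpss_tapers(n, nw, k)
  nf <- floor(n / 2) + 1
  p <- matrix(0, nf, k)
  for (j in seq_len(k)) {
    ft <- stats::fft(x * tapers[, j])[seq_len(nf)]
    p[, j] <- Mod(ft)^2 / sampling_rate
  }
  data.frame(freq = (seq_len(nf) - 1) * sampling_rate / n,
             power = rowMeans(p))
}

#' Event-triggered time-frequency map
#'
#' Tiles short analysis windows (150 ms by default, 75% overlap) across a
#' span around each event time, computes a multi-taper power spectrum per
#' window, and averages over events. `align_shift` is subtracted from every
#' event time before alignment, so that a map computed from laser onsets in
#' the delayed-control mode (`align_shift = control delay`) puts the SWR
#' event that actually triggered the light at time 0.
#'
#' @param x Numeric signal.
#' @param sampling_rate Hz.
#' @param event_times Event (trigger) times, s.
#' @param window Analysis window length, s (default 0.150).
#' @param span Half-width of the map around each event, s.
#' @param step Window centre spacing, s (default `window / 4`, i.e. 75%
#'   overlap).
#' @param align_shift Seconds subtracted from each event time before
#'   alignment (default 0).
#' @param nw,k Multi-taper parameters.
#' @return A `time_frequency_map`: list with `time` (window-centre offsets,
#'   s), `freq` (Hz), `power` (freq x time matrix averaged over events),
#'   `window`, `n_events`.
#' @export
triggered_spectrogram <- function(x, sampling_rate, event_times,
                                  window = 0.150, span = 1,
                                  step = window / 4, align_shift = 0,
                                  nw = 3, k = 5) {
  centres <- seq(-span, span, by = step)
  half_n <- round(window * sampling_rate / 2)
  ev <- event_times - align_shift
  n <- length(x)
  usable <- ev[(ev - span - window) * sampling_rate >= 1 &
                 (ev + span + window) * sampling_rate <= n]
  if (!length(usable)) stopf("no usable events within the signal bounds")
  win_n <- 2 * half_n
  tapers <- dpss_tapers(win_n, nw, k)
  nf <- floor(win_n / 2) + 1
  pow <- matrix(0, nf, length(centres))
  for (tev in usable) {
    for (ci in seq_along(centres)) {
      c0 <- round((tev + centres[ci]) * sampling_rate)
      seg <- x[(c0 - half_n + 1):(c0 + half_n)]
      seg <- seg - mean(seg)
      for (j in seq_len(k)) {
        ft <- stats::fft(seg * tapers[, j])[seq_len(nf)]
        pow[, ci] <- pow[, ci] + Mod(ft)^2 / sampling_rate
      }
    }
  }
  pow <- pow / (length(usable) * k)
  structure(list(time = centres,
                 freq = (seq_len(nf) - 1) * sampling_rate / win_n,
                 power = pow, window = window, n_events = length(usable)),
            class = "time_frequency_map")
}

#' @export
print.time_frequency_map <- function(x, ...) {
  cat(sprintf("<time_frequency_map> %d freq x %d time bins, %d events, %.0f ms windows\n",
              length(x$freq), length(x$time), x$n_events, x$window * 1000))
  invisible(x)
}

#' Baseline-normalized event spectrum
#'
#' Multi-taper spectra are averaged over windows centred on the events and
#' over windows shifted by `shift` (400 ms by default), and the shifted
#' baseline is subtracted from the event spectrum. On stationary data the
#' difference fluctuates around zero; intact ripples produce a positive peak
#' in the ripple band that shrinks when events are truncated.
#'
#' @param x Numeric signal.
#' @param sampling_rate Hz.
#' @param event_times Event times, s.
#' @param shift Baseline shift, s (default 0.400).
#' @param window Analysis window length, s (default 0.150).
#' @param nw,k Multi-taper parameters.
#' @return A `normalized_spectrum`: data frame with `freq` and `power`
#'   (event minus baseline; may be negative), with `n_events` and `shift`
#'   attributes.
#' @export
normalized_event_spectrum <- function(x, sampling_rate, event_times,
                                      shift = 0.400, window = 0.150,
                                      nw = 3, k = 5) {
  half_n <- round(window * sampling_rate / 2)
  n <- length(x)
  ok <- (event_times - window) * sampling_rate >= 1 &
    (event_times + shift + window) * sampling_rate <= n
  ev <- event_times[ok]
  if (!length(ev)) stopf("no usable events within the signal bounds")
  avg_spec <- function(times) {
    acc <- NULL
    for (tt in times) {
      c0 <- round(tt * sampling_rate)
      s <- multitaper_spectrum(x[(c0 - half_n + 1):(c0 + half_n)],
                               sampling_rate, nw, k)
      acc <- if (is.null(acc)) s$power else acc + s$power
    }
    list(freq = s$freq, power = acc / length(times))
  }
  at_ev <- avg_spec(ev)
  at_base <- avg_spec(ev + shift)
  structure(data.frame(freq = at_ev$freq,
                       power = at_ev$power - at_base$power),
            class = c("normalized_spectrum", "data.frame"),
            n_events = length(ev), shift = shift)
}

#' Peak frequency within a band
#'
#' @param spectrum A data frame with `freq` and `power` columns (e.g. from
#'   [multitaper_spectrum()]), or a `time_frequency_map` time slice.
#' @param band Frequency range `c(lo, hi)`, Hz.
#' @return The frequency (Hz) of maximal power within the band.
#' @export
peak_frequency <- function(spectrum, band = c(100, 250)) {
  sel <- spectrum$freq >= band[1] & spectrum$freq <= band[2]
  if (!any(sel)) stopf("band [%g, %g] contains no frequency bins", band[1], band[2])
  f <- spectrum$freq[sel]
  f[which.max(spectrum$power[sel])]
}

#' Extract one time slice of a time-frequency map as a spectrum
#'
#' @param map A [triggered_spectrogram()] result.
#' @param at Time offset, s; the nearest window centre is used.
#' @return Data frame with `freq` and `power`.
#' @export
tf_slice <- function(map, at = 0) {
  i <- which.min(abs(map$time - at))
  data.frame(freq = map$freq, power = map$power[, i])
}
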