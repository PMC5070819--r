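test_that("differential channel is pyramidale minus radiatum", {
  x <- matrix(rnorm(2000), ncol = 2)
  rec <- lfp_recording(x, 2000, roles = c("pyramidale", "radiatum"))
  expect_equal(differential_signal(rec), x[, 1] - x[, 2])
  same <- lfp_recording(cbind(x[, 1], x[, 1]), 2000,
                        roles = c("pyramidale", "radiatum"))
  expect_equal(differential_signal(same), rep(0, 1000))
  zero_rad <- lfp_recording(cbind(x[, 1], 0), 2000,
                            roles = c("pyramidale", "radiatum"))
  expect_equal(differential_signal(zero_rad), x[, 1])
  bad <- lfp_recording(x, 2000, roles = c("pyramidale", "other"))
  expect_error(differential_signal(bad), "radiatum")
})

test_that("the differential channel boosts the event-band envelope", {
  env_peaks <- function(sim) {
    cfg <- detector_config(gain = 1)
    fs <- sim$lfp$sampling_rate
    one <- function(x) {
      f <- abs(ripple_bandpass(x, fs, cfg))
      vapply(seq_len(nrow(sim$events)), function(i)
        max(f[round(sim$events$onset[i] * fs):round((sim$events$offset[i] + 0.01) * fs)]),
        numeric(1))
    }
    list(diff = one(differential_signal(sim$lfp)),
         pyr = one(sim$lfp$samples[, 1]),
         rad = one(sim$lfp$samples[, 2]))
  }
  # noise-free event: differential envelope >= either channel alone
  clean <- env_peaks(simulate_sleep_lfp(4, ripple_rate = 0.25,
                                        noise_params = list(sd = 0),
                                        seed = 4))
  expect_gte(clean$diff, max(clean$pyr, clean$rad) * (1 - 1e-9))
  # with background noise the differential stays close to the better channel
  noisy <- env_peaks(simulate_sleep_lfp(30, ripple_rate = 0.4, seed = 1))
  expect_true(all(noisy$diff >= pmax(noisy$pyr, noisy$rad) * 0.7))
})

test_that("the causal band-pass has the expected frequency response", {
  fs <- 2000
  t <- seq(0, 2, by = 1 / fs)
  cfg <- detector_config()
  in_band <- ripple_bandpass(sin(2 * pi * 150 * t), fs, cfg)
  out_band <- ripple_bandpass(sin(2 * pi * 50 * t), fs, cfg)
  tail_idx <- seq(length(t) / 2, length(t))  # past the transient
  expect_gt(max(abs(in_band[tail_idx])), 5 * max(abs(out_band[tail_idx])))
  # analytic check: |H| from the digital filter coefficients
  bf <- signal::butter(cfg$filter_order / 2, cfg$band / (fs / 2), "pass")
  H <- function(f) {
    z <- exp(-1i * 2 * pi * f / fs)
    abs(sum(bf$b * z^(seq_along(bf$b) - 1)) /
          sum(bf$a * z^(seq_along(bf$a) - 1)))
  }
  expect_equal(max(abs(in_band[tail_idx])), cfg$gain * H(150), tolerance = 0.01)
  # DC dies after the transient
  dc <- ripple_bandpass(rep(1, fs), fs, cfg)
  expect_lt(max(abs(dc[(fs / 2):fs])), 1e-6)
  # white noise: variance concentrates in the pass band (Parseval)
  set.seed(1)
  wn <- ripple_bandpass(rnorm(fs * 4), fs, detector_config(gain = 1))
  sp <- Mod(stats::fft(wn))^2
  f <- (seq_along(sp) - 1) * fs / length(sp)
  half <- f <= fs / 2
  in_frac <- sum(sp[half & f >= 90 & f <= 220]) / sum(sp[half])
  # theoretical fraction from the filter's squared magnitude response
  bf2 <- signal::butter(2, c(100, 200) / 1000, "pass")
  Hf <- function(f) {
    z <- exp(-1i * 2 * pi * f / fs)
    abs(sum(bf2$b * z^(seq_along(bf2$b) - 1)) /
          sum(bf2$a * z^(seq_along(bf2$a) - 1)))^2
  }
  fg <- seq(0.5, 999.5, by = 1)
  frac_theory <- sum(vapply(fg[fg >= 90 & fg <= 220], Hf, numeric(1))) /
    sum(vapply(fg, Hf, numeric(1)))
  expect_equal(in_frac, frac_theory, tolerance = 0.05)
  expect_gt(in_frac, 0.8)
  expect_error(ripple_bandpass(wn, fs, detector_config(band = c(100, 1100))),
               "Nyquist")
})

test_that("the closed-loop scan is causal, non-retriggerable and exact", {
  fs <- 2000
  cfg <- detector_config(pulse_length = 0.2)
  # all-subthreshold signal -> no pulses
  quiet <- online_closed_loop(rep(0.1, fs), fs, cfg, "direct", threshold = 1)
  expect_equal(nrow(quiet$ttl), 0L)
  # two crossings 50 ms apart -> one TTL (second falls inside the pulse)
  x <- rep(0, fs)
  x[c(200, 300)] <- 2                      # 50 ms apart at 2 kHz
  one <- online_closed_loop(x, fs, cfg, "direct", threshold = 1)
  expect_equal(nrow(one$ttl), 1L)
  expect_equal(one$ttl$onset, 199 / fs)
  # crossings beyond the pulse re-trigger
  x2 <- rep(0, fs)
  x2[c(200, 700)] <- 2                     # 250 ms apart
  two <- online_closed_loop(x2, fs, cfg, "direct", threshold = 1)
  expect_equal(nrow(two$ttl), 2L)
  # causality: every TTL starts exactly at a crossing sample
  expect_true(all((round(two$ttl$onset * fs) + 1) %in% c(200, 700)))
})

test_that("delayed mode shifts laser onsets by exactly the control delay", {
  sim <- simulate_sleep_lfp(60, ripple_rate = 0.4, seed = 2)
  cfg <- detector_config()
  filt <- ripple_bandpass(differential_signal(sim$lfp),
                          sim$lfp$sampling_rate, cfg)
  direct <- online_closed_loop(filt, 2000, cfg, "direct")
  delayed <- online_closed_loop(filt, 2000, cfg, "delayed")
  expect_gt(nrow(direct$ttl), 0)
  expect_identical(as.data.frame(direct$ttl), as.data.frame(delayed$ttl))
  expect_equal(delayed$laser$onset, delayed$ttl$onset + 1.32)
  # energy parity: same pulse count and total light duration in both modes
  expect_equal(nrow(direct$laser), nrow(delayed$laser))
  expect_equal(sum(direct$laser$offset - direct$laser$onset),
               sum(delayed$laser$offset - delayed$laser$onset))
})

test_that("TTLs fire within two ripple cycles of the first suprathreshold sample", {
  sim <- simulate_sleep_lfp(120, ripple_rate = 0.4, seed = 3)
  cfg <- detector_config()
  fs <- sim$lfp$sampling_rate
  filt <- ripple_bandpass(differential_signal(sim$lfp), fs, cfg)
  thr <- cfg$threshold_sd * sd(filt)
  loop <- online_closed_loop(filt, fs, cfg, "direct", threshold = thr)
  expect_gt(nrow(loop$ttl), 3)
  above <- which(filt >= thr)
  for (on in loop$ttl$onset) {
    first_cross <- above[above >= on * fs + 1 - 2 * fs / 160]
    expect_lte(on - (first_cross[1] - 1) / fs, 2 / 160)
  }
})

test_that("offline detector finds intact and truncated events, rarely noise", {
  # pure background at 6 SD -> (near-)empty table
  noise <- simulate_sleep_lfp(120, ripple_rate = 0, seed = 4)
  fp <- offline_detect(noise$lfp, threshold_sd = 6)
  expect_lte(nrow(fp), 1)
  # single strong ripple -> exactly one overlapping event
  one <- simulate_sleep_lfp(20, ripple_rate = 0.1, seed = 22)
  expect_equal(nrow(one$events), 1L)
  det <- offline_detect(one$lfp)
  ev <- evaluate_detection(det, one$events)
  expect_equal(ev$n_matched, 1L)
  # truncated events still found at the non-stringent threshold
  cut <- simulate_sleep_lfp(120, ripple_rate = 0.4, seed = 5,
                            truncate_after_cycles = 2)
  det2 <- offline_detect(cut$lfp, threshold_sd = 2)
  ev2 <- evaluate_detection(det2, cut$events)
  expect_gt(ev2$recall, 0.5)
  # empty signal -> empty table
  expect_equal(nrow(offline_detect(numeric(0), sampling_rate = 2000)), 0L)
})

test_that("offline events cover nearly all online-triggering events", {
  sim <- simulate_sleep_lfp(180, ripple_rate = 0.4, seed = 6)
  cfg <- detector_config()
  filt <- ripple_bandpass(differential_signal(sim$lfp), 2000, cfg)
  loop <- online_closed_loop(filt, 2000, cfg, "direct")
  off <- offline_detect(sim$lfp)
  # TTLs that were triggered by a real event (matched to ground truth)
  ev <- evaluate_detection(loop$ttl, sim$events)
  expect_gt(ev$n_matched, 5)
  trig <- loop$ttl$onset[vapply(loop$ttl$onset, function(on)
    any(sim$events$onset - 0.05 <= on & sim$events$offset + 0.05 >= on),
    logical(1))]
  covered <- vapply(trig, function(on)
    any(off$onset - 0.02 <= on & off$offset + 0.02 >= on), logical(1))
  expect_gte(mean(covered), 0.95)
})

test_that("detection scoring matches its closed-form cases", {
  tbl <- function(onset, offset)
    swrpipe:::new_ripple_event_table(
      data.frame(onset = onset, offset = offset,
                 peak_time = (onset + offset) / 2,
                 peak_frequency = rep(NA_real_, length(onset)),
                 amplitude = rep(1, length(onset))), "offline")
  truth <- tbl(seq(0, 99) + 0.1, seq(0, 99) + 0.15)
  perfect <- evaluate_detection(truth, truth)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(max(abs(perfect$latency)), 0)
  none <- evaluate_detection(tbl(numeric(0), numeric(0)), truth)
  expect_equal(none$recall, 0)
  expect_true(is.nan(none$precision))
  shifted <- tbl(truth$onset + 0.005, truth$offset + 0.005)
  ev <- evaluate_detection(shifted, truth)
  expect_equal(ev$recall, 1)
  expect_equal(mean(ev$latency), 0.005, tolerance = 1e-12)
  expect_equal(mean(ev$latency_cycles), 0.005 * 160, tolerance = 1e-9)
})
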