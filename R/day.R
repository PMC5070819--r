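#' Configuration for a simulated recording day
#'
#' Bundles every generator and analysis parameter for one experimental day.
#' Defaults reproduce the study timeline: 20 min pre-sleep, 24 min
#' exploration of a novel arena, a 3 h sleep/rest with closed-loop
#' stimulation of which the first 20 min of each hour are recorded (three
#' 20-min blocks), a second 24 min exploration, 20 min post-sleep, and a
#' final 30 min rest with regular half-intensity 500 ms pulses every 3 s to
#' quantify per-cell inhibition. Durations are configurable so analyses can
#' be exercised at reduced scale.
#'
#' @param condition `"blockade"` (direct mode, ripples truncated after ~2
#'   cycles) or `"control"` (delayed mode, ripples intact).
#' @param presleep,exploration,sleep_block,postsleep,control_sleep Session
#'   durations, s.
#' @param n_sleep_blocks Number of recorded sleep blocks.
#' @param n_cells Ensemble size.
#' @param arena_obj The exploration [arena()].
#' @param stability_params Passed to [make_ensemble()].
#' @param ripple List of sleep-LFP parameters: `rate`, `freq`, `cycles`,
#'   `amp`, `sw_amp`, `noise_sd`, `sampling_rate`.
#' @param detector A [detector_config()].
#' @param suppression In-pulse spike deletion probability (light efficacy).
#' @param sleep_rate_range Per-cell homogeneous sleep firing rates are drawn
#'   uniformly from this range, Hz.
#' @param pulse_period,pulse_duration Inhibition-control pulse timing, s.
#' @param bin_size,smoothing_sigma,min_occupancy,speed_threshold Rate-map
#'   parameters.
#' @param cofiring_bin Temporal bin for cofiring coefficients, s.
#' @param alpha Per-cell significance level for the inhibition test.
#' @return A `day_config` list.
#' @export
day_config <- function(condition = c("blockade", "control"),
                       presleep = 1200, exploration = 1440,
                       sleep_block = 1200, n_sleep_blocks = 3,
                       postsleep = 1200, control_sleep = 1800,
                       n_cells = 30,
                       arena_obj = arena("rectangle", 60, 60),
                       stability_params = list(drift_mean = 0, drift_sd = 2,
                                               rate_sdlog = 0.1),
                       ripple = list(rate = 0.3, freq = 160, cycles = 7,
                                     amp = 5, sw_amp = 5, noise_sd = 40,
                                     sampling_rate = 2000),
                       detector = detector_config(),
                       suppression = 0.9,
                       sleep_rate_range = c(0.5, 3),
                       pulse_period = 3, pulse_duration = 0.5,
                       bin_size = 2, smoothing_sigma = 1,
                       min_occupancy = 0.1, speed_threshold = 2.5,
                       cofiring_bin = 0.25, alpha = 0.05) {
  condition <- match.arg(condition)
  structure(as.list(environment()), class = "day_config")
}

#' Simulate one full experimental day
#'
#' Generates every input the analysis pipeline consumes for one day, on a
#' single clock starting at t = 0: the session manifest, the two-session
#' place-field ensemble, exploration trajectories and spike trains, sleep
#' LFP blocks with ground-truth ripple events and emulated closed-loop
#' stimulation (direct mode truncating ripples in the blockade condition,
#' delayed mode leaving them intact in the control condition), and the final
#' half-intensity pulse session with light-suppressed sleep spiking.
#'
#' @param config A [day_config()].
#' @param seed Integer seed; every random stream is derived from it, so the
#'   whole day is reproducible.
#' @return A `sim_day` list: `manifest`, `condition`, `ensemble`,
#'   `trajectories` (expl1/expl2), `spikes` (expl1/expl2/control_sleep),
#'   `sleep` (per block: `lfp`, `truth`, `ttl`, `laser`),
#'   `control_pulses`, `sleep_rates`, `config`, `seed`.
#' @export
simulate_day <- function(config = day_config(), seed = 1L) {
  cfg <- config
  sessions <- data.frame(
    name = c("presleep", "exploration1",
             paste0("sleep_block", seq_len(cfg$n_sleep_blocks)),
             "exploration2", "postsleep", "laser_control_sleep"),
    kind = c("presleep", "exploration1",
             rep("sleep_block", cfg$n_sleep_blocks),
             "exploration2", "postsleep", "laser_control_sleep"),
    duration = c(cfg$presleep, cfg$exploration,
                 rep(cfg$sleep_block, cfg$n_sleep_blocks),
                 cfg$exploration, cfg$postsleep, cfg$control_sleep))
  sessions$end <- cumsum(sessions$duration)
  sessions$start <- sessions$end - sessions$duration
  sessions$condition <- cfg$condition
  manifest <- sessions[, c("name", "kind", "start", "end", "condition")]

  ens <- make_ensemble(cfg$n_cells, cfg$arena_obj,
                       stability_params = cfg$stability_params,
                       seed = derive_seed(seed, "ensemble"))

  tr1 <- simulate_trajectory(cfg$arena_obj, cfg$exploration,
                             seed = derive_seed(seed, "traj1"))
  tr2 <- simulate_trajectory(cfg$arena_obj, cfg$exploration,
                             seed = derive_seed(seed, "traj2"))
  sp1 <- generate_spikes(ens, tr1, session = 1,
                         t_offset = session_start(manifest, "exploration1"),
                         seed = derive_seed(seed, "spikes1"))
  sp2 <- generate_spikes(ens, tr2, session = 2,
                         t_offset = session_start(manifest, "exploration2"),
                         seed = derive_seed(seed, "spikes2"))

  mode <- if (cfg$condition == "blockade") "direct" else "delayed"
  trunc <- if (cfg$condition == "blockade") 2 else NULL
  sleep <- lapply(seq_len(cfg$n_sleep_blocks), function(b) {
    sim <- simulate_sleep_lfp(cfg$sleep_block,
                              ripple_rate = cfg$ripple$rate,
                              ripple_freq = cfg$ripple$freq,
                              ripple_cycles = cfg$ripple$cycles,
                              ripple_amp = cfg$ripple$amp,
                              sharp_wave_amp = cfg$ripple$sw_amp,
                              noise_params = list(sd = cfg$ripple$noise_sd),
                              sampling_rate = cfg$ripple$sampling_rate,
                              truncate_after_cycles = trunc,
                              seed = derive_seed(seed, paste0("sleep", b)))
    filt <- ripple_bandpass(differential_signal(sim$lfp),
                            sim$lfp$sampling_rate, cfg$detector)
    loop <- online_closed_loop(filt, sim$lfp$sampling_rate, cfg$detector,
                               mode = mode)
    list(lfp = sim$lfp, truth = sim$events, ttl = loop$ttl,
         laser = loop$laser,
         start = session_start(manifest, paste0("sleep_block", b)))
  })

  ctrl_start <- session_start(manifest, "laser_control_sleep")
  pulses <- regular_pulse_train(ctrl_start, ctrl_start + cfg$control_sleep,
                                period = cfg$pulse_period,
                                duration = cfg$pulse_duration,
                                intensity = "half")
  sleep_rates <- with_seed(derive_seed(seed, "sleeprates"),
                           stats::runif(cfg$n_cells, cfg$sleep_rate_range[1],
                                        cfg$sleep_rate_range[2]))
  names(sleep_rates) <- seq_len(cfg$n_cells)
  ctrl_raw <- generate_poisson_spikes(sleep_rates, cfg$control_sleep,
                                      t_offset = ctrl_start,
                                      seed = derive_seed(seed, "ctrlspk"))
  ctrl <- apply_light_suppression(ctrl_raw, pulses, cfg$suppression,
                                  seed = derive_seed(seed, "suppress"))

  structure(list(manifest = manifest, condition = cfg$condition,
                 ensemble = ens,
                 trajectories = list(expl1 = tr1, expl2 = tr2),
                 spikes = list(expl1 = sp1, expl2 = sp2,
                               control_sleep = ctrl),
                 sleep = sleep, control_pulses = pulses,
                 sleep_rates = sleep_rates, config = cfg, seed = seed),
            class = "sim_day")
}

session_start <- function(manifest, name) {
  manifest$start[manifest$name == name]
}

#' Validate a session manifest
#'
#' Checks the day structure: sessions ordered and non-overlapping, a single
#' condition throughout, and both exploration sessions present.
#'
#' @param manifest Data frame with `name`, `kind`, `start`, `end`,
#'   `condition`.
#' @return The manifest, invisibly; errors on violation.
#' @export
validate_manifest <- function(manifest) {
  need <- c("name", "kind", "start", "end", "condition")
  if (!all(need %in% names(manifest)))
    stopf("manifest must have columns %s", paste(need, collapse = ", "))
  if (any(manifest$start >= manifest$end))
    stopf("sessions must have start < end")
  if (is.unsorted(manifest$start) ||
      any(manifest$start[-1] < manifest$end[-nrow(manifest)]))
    stopf("sessions must be ordered and non-overlapping")
  if (length(unique(manifest$condition)) != 1)
    stopf("a day must have a single condition")
  for (k in c("exploration1", "exploration2"))
    if (!k %in% manifest$kind) stopf("manifest is missing a %s session", k)
  invisible(manifest)
}
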