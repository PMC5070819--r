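# Shared settings for the analysis scripts. The two simulated days (one
# SWR-blockade, one delayed control) use reduced session durations so the
# whole workflow re-runs in about a minute; the generator's event and
# firing-rate parameters are the study defaults.

library(swrpipe)

DAY_SEEDS <- c(blockade = 101L, control = 202L)

example_config <- function(condition) {
  day_config(condition = condition,
             presleep = 30, exploration = 600,
             sleep_block = 120, n_sleep_blocks = 2,
             postsleep = 30, control_sleep = 600,
             n_cells = 25,
             stability_params = list(drift_mean = 0, drift_sd = 3,
                                     rate_sdlog = 0.15))
}

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

get_day <- function(condition) {
  simulate_day(example_config(condition), seed = DAY_SEEDS[[condition]])
}
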