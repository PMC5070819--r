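# Shared fixtures: everything is generated in code at test time.

box60 <- function() arena("rectangle", width = 60, height = 60)

# A reduced-scale day configuration that exercises every pipeline stage in
# a few seconds.
mini_config <- function(condition = "control", ...) {
  day_config(condition = condition,
             presleep = 10, exploration = 300,
             sleep_block = 60, n_sleep_blocks = 1,
             postsleep = 10, control_sleep = 300,
             n_cells = 10, ...)
}

# One stationary ensemble row (for direct construction of models in tests).
model_row <- function(cx, cy, sigma = 6, peak = 10, baseline = 0,
                      session = 1L, cell = 1L) {
  data.frame(cell = cell, session = session, cx = cx, cy = cy,
             sigma = sigma, peak = peak, baseline = baseline,
             drift = 0, rate_scale = 1)
}

# Build a rate_map directly from a rate matrix (uniform occupancy mask).
matrix_rate_map <- function(m, bin_size = 2) {
  mask <- matrix(TRUE, nrow(m), ncol(m))
  swrpipe:::new_rate_map(rate = m, rate_unsmoothed = m, mask = mask,
                         xedges = seq(0, nrow(m) * bin_size, by = bin_size),
                         yedges = seq(0, ncol(m) * bin_size, by = bin_size),
                         smoothing_sigma = 0)
}

# Matching uniform occupancy map.
uniform_occupancy <- function(nx, ny, dwell = 1, bin_size = 2) {
  d <- matrix(dwell, nx, ny)
  structure(list(dwell = d, mask = d > 0,
                 xedges = seq(0, nx * bin_size, by = bin_size),
                 yedges = seq(0, ny * bin_size, by = bin_size),
                 bin_size = bin_size, duration = sum(d),
                 speed_threshold = NULL),
            class = "occupancy_map")
}

# Wrap bare spike times in a spike_train_set.
spike_set <- function(times, unit = 1L, t_start = 0,
                      t_stop = max(unlist(times), 1)) {
  df <- do.call(rbind, lapply(seq_along(times), function(i)
    data.frame(time = times[[i]],
               unit = rep(unit[[i]], length(times[[i]])))))
  swrpipe:::new_spike_train_set(df,
    units = data.frame(unit = unlist(unit), class = "pyramidal"),
    t_start = t_start, t_stop = t_stop)
}
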