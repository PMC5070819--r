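# Plain-text / flat-binary readers and writers. Formats are deliberately
# minimal dialects (documented here bit-exactly) rather than NWB/NEO
# containers, keeping the pipeline dependency-light; converters are an
# extension point.

#' Read / write spike-time files
#'
#' Two-column whitespace-separated plain text (`time_s`, `unit_id`) with a
#' header line. Times are sorted within unit on read; a file with unsorted
#' rows is accepted with a warning.
#'
#' @param path File path.
#' @param spikes A `spike_train_set`.
#' @return `read_spike_file()` returns a `spike_train_set`.
#' @export
read_spike_file <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  if (!nrow(df)) {
    df <- data.frame(time = numeric(0), unit = integer(0))
  } else {
    names(df)[1:2] <- c("time", "unit")
    if (any(!is.finite(df$time)) || any(!is.finite(df$unit)))
      stopf("non-numeric rows in %s", path)
    if (is.unsorted(df$time)) warning("spike times were not sorted; sorting on read")
  }
  units <- sort(unique(df$unit))
  new_spike_train_set(df,
                      units = data.frame(unit = units,
                                         class = rep("pyramidal", length(units))),
                      t_start = if (nrow(df)) min(df$time) else 0,
                      t_stop = if (nrow(df)) max(df$time) else 0)
}

#' @rdname read_spike_file
#' @export
write_spike_file <- function(spikes, path) {
  df <- as.data.frame(spikes)[order(spikes$time), c("time", "unit")]
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write flat-binary LFP recordings
#'
#' Interleaved little-endian signed 16-bit samples (channel-major within
#' each frame), with a YAML sidecar declaring `n_channels`,
#' `sampling_rate`, `channel_roles` and `scale` (volts per unit). Sample
#' values are rounded and clamped to the int16 range on write.
#'
#' @param path Binary file path.
#' @param sidecar Sidecar path (default `paste0(path, ".yaml")`).
#' @param rec An `lfp_recording`.
#' @return `read_lfp()` returns an `lfp_recording`.
#' @export
read_lfp <- function(path, sidecar = paste0(path, ".yaml")) {
  meta <- yaml::read_yaml(sidecar)
  nch <- meta$n_channels
  bytes <- file.size(path)
  if (bytes %% (2 * nch) != 0)
    stopf("%s: %d bytes is not a whole number of %d-channel int16 frames (expected a multiple of %d)",
          path, bytes, nch, 2 * nch)
  n <- bytes / (2 * nch)
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "integer", n = n * nch, size = 2, signed = TRUE,
                 endian = "little")
  m <- matrix(as.numeric(raw), ncol = nch, byrow = TRUE)
  colnames(m) <- unlist(meta$channel_roles)
  lfp_recording(m, meta$sampling_rate, roles = unlist(meta$channel_roles),
                scale = meta$scale %||% 1e-6)
}

#' @rdname read_lfp
#' @export
write_lfp <- function(rec, path, sidecar = paste0(path, ".yaml")) {
  m <- round(rec$samples)
  m[m > 32767] <- 32767
  m[m < -32768] <- -32768
  con <- file(path, "wb")
  writeBin(as.integer(t(m)), con, size = 2, endian = "little")
  close(con)
  yaml::write_yaml(list(n_channels = ncol(m),
                        sampling_rate = rec$sampling_rate,
                        channel_roles = as.list(rec$roles),
                        scale = rec$scale),
                   sidecar)
  invisible(path)
}

#' Read / write event and pulse tables
#'
#' CSV with header `onset,offset,...`; extra columns are preserved. Rows
#' are sorted by onset on read; for `kind = "ripple"` overlapping rows are a
#' validation error, and any row with `onset >= offset` is rejected.
#'
#' @param path CSV path.
#' @param kind `"ripple"` for a ripple event table, `"pulse"` for a pulse
#'   train.
#' @param provenance Provenance tag for ripple tables.
#' @param table A `ripple_event_table` or `pulse_train`.
#' @return `read_events()` returns a `ripple_event_table` or `pulse_train`.
#' @export
read_events <- function(path, kind = c("ripple", "pulse"),
                        provenance = "offline") {
  kind <- match.arg(kind)
  df <- utils::read.csv(path)
  if (nrow(df) && any(df$onset >= df$offset))
    stopf("%s: rows with onset >= offset", path)
  df <- df[order(df$onset), , drop = FALSE]
  if (kind == "ripple") {
    for (col in c("peak_time", "peak_frequency", "amplitude"))
      if (is.null(df[[col]])) df[[col]] <- rep(NA_real_, nrow(df))
    new_ripple_event_table(df, provenance = provenance)
  } else {
    dur <- if (nrow(df)) stats::median(df$offset - df$onset) else 0.2
    pulse_train(df$onset, duration = dur,
                mode = if (!is.null(df$mode) && nrow(df)) df$mode[1] else "direct",
                delay = if (!is.null(df$delay) && nrow(df)) df$delay[1] else 0)
  }
}

#' @rdname read_events
#' @export
write_events <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a position-tracking CSV
#'
#' Header `t,x,y`; one row per tracker sample.
#'
#' @param path CSV path.
#' @param arena The [arena()] the positions belong to.
#' @param trajectory A `trajectory`.
#' @return `read_positions()` returns a `trajectory`.
#' @export
read_positions <- function(path, arena) {
  df <- utils::read.csv(path)
  as_trajectory(df$t, df$x, df$y, arena)
}

#' @rdname read_positions
#' @export
write_positions <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory)[, c("t", "x", "y")], path,
                   row.names = FALSE)
  invisible(path)
}
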