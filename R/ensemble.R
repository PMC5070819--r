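#' Build a two-session place-field ensemble with controllable drift
#'
#' Each cell is modelled as a single 2-D Gaussian place field (centre, width
#' sigma, peak rate above a low baseline). The session-2 model is the
#' session-1 model with its centre displaced by a per-cell drift distance (in
#' a uniformly random direction) and its peak rate multiplied by a per-cell
#' log-normal factor. Zero drift and unit rate scaling reproduce session 1
#' exactly, emulating a perfectly stable ensemble; large drift emulates
#' global remapping.
#'
#' @param n_cells Number of place cells (>= 1).
#' @param arena An [arena()]; field centres are drawn uniformly inside it
#'   (inset by one field width so fields fit).
#' @param stability_params List controlling session-1 -> session-2 change:
#'   `drift_mean`, `drift_sd` (cm; per-cell drift distance is
#'   `|N(drift_mean, drift_sd)|`; both may be length-`n_cells` vectors to mix
#'   stable and remapping subpopulations) and `rate_sdlog` (s.d. of the log
#'   peak-rate scaling; 0 keeps rates fixed).
#' @param field_params List with `sigma` (field width, cm), `peak_range`
#'   (Hz, uniform draw) and `baseline` (Hz).
#' @param seed Optional integer seed.
#' @return A `place_field_ensemble`: data frame with one row per cell and
#'   session (`cell`, `session`, `cx`, `cy`, `sigma`, `peak`, `baseline`,
#'   `drift`, `rate_scale`), with the arena attached.
#' @examples
#' ens <- make_ensemble(5, arena("rectangle", 60, 60),
#'                      stability_params = list(drift_mean = 0, drift_sd = 0),
#'                      seed = 1)
#' subset(ens, session == 2)
#' @export
make_ensemble <- function(n_cells, arena,
                          stability_params = list(drift_mean = 0, drift_sd = 2,
                                                  rate_sdlog = 0.1),
                          field_params = list(sigma = 6, peak_range = c(4, 15),
                                              baseline = 0.1),
                          seed = NULL) {
  if (!is.numeric(n_cells) || n_cells < 1) stopf("`n_cells` must be >= 1")
  n_cells <- as.integer(n_cells)
  if (!inherits(arena, "arena")) stopf("`arena` must be an arena object")
  drift_mean <- rep_len(stability_params$drift_mean %||% 0, n_cells)
  drift_sd <- rep_len(stability_params$drift_sd %||% 0, n_cells)
  rate_sdlog <- stability_params$rate_sdlog %||% 0
  ext <- max(arena_extent(arena))
  if (any(drift_mean > ext))
    stopf("drift (%.1f cm) exceeds the arena extent (%.1f cm)",
          max(drift_mean), ext)
  sigma <- field_params$sigma %||% 6
  peak_range <- field_params$peak_range %||% c(4, 15)
  baseline <- field_params$baseline %||% 0.1

  with_seed(seed, {
    cen <- draw_points_in_arena(n_cells, arena, inset = sigma)
    peak <- stats::runif(n_cells, peak_range[1], peak_range[2])
    drift <- abs(stats::rnorm(n_cells, drift_mean, drift_sd))
    theta <- stats::runif(n_cells, 0, 2 * pi)
    rate_scale <- exp(stats::rnorm(n_cells, 0, rate_sdlog))

    cx2 <- cen[, 1] + drift * cos(theta)
    cy2 <- cen[, 2] + drift * sin(theta)
    # keep drifted centres inside the arena without shrinking the distance
    # more than necessary: fold back towards the centre
    bad <- !arena_contains(arena, cx2, cy2)
    if (any(bad)) {
      mid <- arena_centre(arena)
      cx2[bad] <- cen[bad, 1] - drift[bad] * cos(theta[bad])
      cy2[bad] <- cen[bad, 2] - drift[bad] * sin(theta[bad])
      still <- !arena_contains(arena, cx2, cy2)
      cx2[still] <- pmin(pmax(cx2[still], 0), arena_extent(arena)[1])
      cy2[still] <- pmin(pmax(cy2[still], 0), arena_extent(arena)[2])
    }

    ens <- rbind(
      data.frame(cell = seq_len(n_cells), session = 1L,
                 cx = cen[, 1], cy = cen[, 2], sigma = sigma,
                 peak = peak, baseline = baseline,
                 drift = 0, rate_scale = 1),
      data.frame(cell = seq_len(n_cells), session = 2L,
                 cx = cx2, cy = cy2, sigma = sigma,
                 peak = peak * rate_scale, baseline = baseline,
                 drift = drift, rate_scale = rate_scale))
    structure(ens, class = c("place_field_ensemble", "data.frame"),
              arena = arena)
  })
}

draw_points_in_arena <- function(n, arena, inset = 0) {
  ext <- arena_extent(arena)
  if (arena$shape == "rectangle") {
    cbind(stats::runif(n, inset, ext[1] - inset),
          stats::runif(n, inset, ext[2] - inset))
  } else {
    r <- arena$diameter / 2 - inset
    rr <- r * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    cbind(arena$diameter / 2 + rr * cos(th), arena$diameter / 2 + rr * sin(th))
  }
}

# Instantaneous model firing rate (Hz) of one ensemble row at positions x, y.
field_rate <- function(model_row, x, y) {
  d2 <- (x - model_row$cx)^2 + (y - model_row$cy)^2
  model_row$baseline + model_row$peak * exp(-d2 / (2 * model_row$sigma^2))
}

#' Evaluate a place-field model as a rate map on a grid
#'
#' Direct (noise-free) evaluation of a cell's model firing rate at bin
#' centres, useful as ground truth against which estimated rate maps are
#' compared.
#'
#' @param model One row of a [make_ensemble()] data frame.
#' @param arena The [arena()].
#' @param bin_size Spatial bin size, cm.
#' @return A `rate_map` (all bins valid, no smoothing metadata).
#' @export
model_rate_map <- function(model, arena, bin_size = 2) {
  ext <- arena_extent(arena)
  xe <- seq(0, ext[1], by = bin_size)
  ye <- seq(0, ext[2], by = bin_size)
  xc <- xe[-length(xe)] + bin_size / 2
  yc <- ye[-length(ye)] + bin_size / 2
  g <- expand.grid(x = xc, y = yc)
  rate <- matrix(field_rate(model, g$x, g$y), nrow = length(xc))
  mask <- matrix(arena_contains(arena, g$x, g$y), nrow = length(xc))
  rate[!mask] <- NA_real_
  new_rate_map(rate = rate, rate_unsmoothed = rate, mask = mask,
               xedges = xe, yedges = ye, smoothing_sigma = 0)
}

#' Generate place-cell spike trains along a trajectory
#'
#' Draws spikes from an inhomogeneous Poisson process whose rate is the
#' cell's place-field model evaluated at the animal's position:
#' `lambda(t) = baseline + peak * exp(-||x(t) - c||^2 / (2 sigma^2))`. The
#' rate is treated as piecewise constant over tracker steps (25 ms by
#' default), which is exact for an inhomogeneous Poisson process with that
#' rate profile.
#'
#' @param ensemble A [make_ensemble()] result (or any data frame of model
#'   rows).
#' @param trajectory A [simulate_trajectory()] result sharing the ensemble's
#'   arena.
#' @param session Which session's models to use (1 or 2).
#' @param t_offset Added to all spike times, to place the session on the
#'   day's clock.
#' @param seed Optional integer seed.
#' @return A `spike_train_set`: data frame with columns `time` (s, sorted
#'   within unit) and `unit` (integer), with unit classes and session bounds
#'   as attributes.
#' @export
generate_spikes <- function(ensemble, trajectory, session = 1L, t_offset = 0,
                            seed = NULL) {
  if (!identical(attr(ensemble, "arena"), attr(trajectory, "arena")))
    stopf("ensemble and trajectory must share the same arena")
  rows <- ensemble[ensemble$session == session, , drop = FALSE]
  if (nrow(rows) == 0L) stopf("no models for session %s", session)
  step <- attr(trajectory, "step")
  with_seed(seed, {
    out <- vector("list", nrow(rows))
    for (i in seq_len(nrow(rows))) {
      m <- rows[i, ]
      lam <- field_rate(m, trajectory$x, trajectory$y)
      counts <- stats::rpois(length(lam), lam * step)
      idx <- rep.int(seq_along(counts), counts)
      times <- trajectory$t[idx] + stats::runif(length(idx)) * step
      out[[i]] <- data.frame(time = sort(times) + t_offset,
                             unit = rep(m$cell, length(times)))
    }
    spikes <- do.call(rbind, out)
    new_spike_train_set(spikes,
                        units = data.frame(unit = rows$cell,
                                           class = "pyramidal"),
                        t_start = t_offset,
                        t_stop = t_offset + trajectory_duration(trajectory))
  })
}

new_spike_train_set <- function(spikes, units, t_start, t_stop) {
  spikes <- spikes[order(spikes$unit, spikes$time), , drop = FALSE]
  rownames(spikes) <- NULL
  structure(spikes, class = c("spike_train_set", "data.frame"),
            units = units, t_start = t_start, t_stop = t_stop)
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("<spike_train_set> %d spikes, %d units, t in [%.1f, %.1f] s\n",
              nrow(x), length(unique(x$unit)),
              attr(x, "t_start"), attr(x, "t_stop")))
  invisible(x)
}

#' Spike times of one unit
#'
#' @param set A `spike_train_set`.
#' @param unit Unit id.
#' @return Sorted numeric vector of that unit's spike times, s.
#' @export
unit_spikes <- function(set, unit) set$time[set$unit == unit]

#' Generate homogeneous Poisson spike trains (sleep firing)
#'
#' Sleep/rest activity is modelled as homogeneous Poisson firing at per-cell
#' rates: adequate for testing pulse-triggered inhibition statistics, which
#' only assume exchangeable baseline counts.
#'
#' @param rates Named or plain numeric vector of per-unit rates (Hz); names
#'   or indices become unit ids.
#' @param duration Session length (s).
#' @param t_offset Added to all spike times.
#' @param seed Optional integer seed.
#' @return A `spike_train_set`.
#' @export
generate_poisson_spikes <- function(rates, duration, t_offset = 0, seed = NULL) {
  assert_scalar_pos(duration, "duration")
  ids <- if (!is.null(names(rates))) as.integer(names(rates)) else seq_along(rates)
  with_seed(seed, {
    out <- lapply(seq_along(rates), function(i) {
      n <- stats::rpois(1, rates[i] * duration)
      data.frame(time = sort(stats::runif(n, 0, duration)) + t_offset,
                 unit = ids[i])
    })
    new_spike_train_set(do.call(rbind, out),
                        units = data.frame(unit = ids, class = "pyramidal"),
                        t_start = t_offset, t_stop = t_offset + duration)
  })
}
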