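#' Occupancy (dwell-time) map
#'
#' Accumulates tracker dwell time in square spatial bins, optionally after a
#' running-speed filter (immobility periods excluded, the convention for
#' exploration sessions). Bins are half-open `[edge, edge + size)`; the grid
#' spans the arena's bounding extent.
#'
#' @param trajectory A [simulate_trajectory()] / [as_trajectory()] result.
#' @param bin_size Bin side, cm (default 2).
#' @param min_occupancy Bins with less dwell than this (s) are excluded from
#'   the valid mask (default 0.1 s).
#' @param speed_threshold If non-`NULL`, samples slower than this (cm/s) are
#'   discarded before accumulating.
#' @return An `occupancy_map`: list with `dwell` (matrix, s), `mask`
#'   (logical matrix), `xedges`, `yedges`, `bin_size`, `duration` (total
#'   dwell retained, s), `speed_threshold`.
#' @export
occupancy_map <- function(trajectory, bin_size = 2, min_occupancy = 0.1,
                          speed_threshold = NULL) {
  assert_scalar_pos(bin_size, "bin_size")
  a <- attr(trajectory, "arena")
  step <- attr(trajectory, "step")
  ext <- arena_extent(a)
  xe <- seq(0, ext[1] + bin_size * 0.999, by = bin_size)
  ye <- seq(0, ext[2] + bin_size * 0.999, by = bin_size)
  nx <- length(xe) - 1L; ny <- length(ye) - 1L
  keep <- if (is.null(speed_threshold)) rep(TRUE, nrow(trajectory))
          else trajectory$speed >= speed_threshold
  tr <- trajectory[keep, , drop = FALSE]
  dwell <- matrix(0, nx, ny)
  if (nrow(tr)) {
    ix <- pmin(pmax(findInterval(tr$x, xe, rightmost.closed = FALSE), 1L), nx)
    iy <- pmin(pmax(findInterval(tr$y, ye, rightmost.closed = FALSE), 1L), ny)
    tab <- table(factor(ix, levels = seq_len(nx)),
                 factor(iy, levels = seq_len(ny)))
    dwell <- matrix(as.numeric(tab), nx, ny) * step
  }
  structure(list(dwell = dwell, mask = dwell >= min_occupancy,
                 xedges = xe[seq_len(nx + 1)], yedges = ye[seq_len(ny + 1)],
                 bin_size = bin_size, duration = sum(dwell),
                 speed_threshold = speed_threshold),
            class = "occupancy_map")
}

#' @export
print.occupancy_map <- function(x, ...) {
  cat(sprintf("<occupancy_map> %d x %d bins (%.0f cm), %.1f s dwell, %d valid bins\n",
              nrow(x$dwell), ncol(x$dwell), x$bin_size, x$duration,
              sum(x$mask)))
  invisible(x)
}

new_rate_map <- function(rate, rate_unsmoothed, mask, xedges, yedges,
                         smoothing_sigma, counts = NULL) {
  structure(list(rate = rate, rate_unsmoothed = rate_unsmoothed,
                 counts = counts, mask = mask, xedges = xedges,
                 yedges = yedges, smoothing_sigma = smoothing_sigma,
                 peak_rate = suppressWarnings(max(rate[mask], na.rm = TRUE))),
            class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("<rate_map> %d x %d bins, peak %.2f Hz, smoothing sigma %.1f bins\n",
              nrow(x$rate), ncol(x$rate), x$peak_rate, x$smoothing_sigma))
  invisible(x)
}

#' Occupancy-normalized firing-rate map
#'
#' Positions each spike by linear interpolation of the tracker at the spike
#' time, applies the same speed filter as the occupancy map, accumulates
#' spike counts per bin, and divides by dwell time. When smoothing is
#' requested, the Gaussian kernel is applied to the count and dwell grids
#' separately before division (the standard adaptive-edge convention). The
#' unsmoothed rate is always retained for metrics that require it.
#'
#' @param spike_times Numeric vector of one unit's spike times, s (on the
#'   trajectory's clock).
#' @param trajectory The session trajectory.
#' @param occupancy The matching [occupancy_map()].
#' @param smoothing_sigma Gaussian kernel s.d. in bins (default 1; 0
#'   disables smoothing).
#' @return A `rate_map`: `rate` (Hz; `NA` outside the valid mask),
#'   `rate_unsmoothed`, `counts`, `mask`, bin edges, `smoothing_sigma`,
#'   `peak_rate`.
#' @export
rate_map <- function(spike_times, trajectory, occupancy, smoothing_sigma = 1) {
  if (!inherits(occupancy, "occupancy_map"))
    stopf("`occupancy` must be an occupancy_map")
  nx <- nrow(occupancy$dwell); ny <- ncol(occupancy$dwell)
  counts <- matrix(0, nx, ny)
  st <- spike_times[spike_times >= min(trajectory$t) &
                      spike_times <= max(trajectory$t) + attr(trajectory, "step")]
  if (length(st) && nrow(trajectory) > 1) {
    sx <- stats::approx(trajectory$t, trajectory$x, st, rule = 2)$y
    sy <- stats::approx(trajectory$t, trajectory$y, st, rule = 2)$y
    if (!is.null(occupancy$speed_threshold)) {
      sv <- stats::approx(trajectory$t, trajectory$speed, st, rule = 2)$y
      ok <- sv >= occupancy$speed_threshold
      sx <- sx[ok]; sy <- sy[ok]
    }
    if (length(sx)) {
      ix <- pmin(pmax(findInterval(sx, occupancy$xedges), 1L), nx)
      iy <- pmin(pmax(findInterval(sy, occupancy$yedges), 1L), ny)
      tab <- table(factor(ix, levels = seq_len(nx)),
                   factor(iy, levels = seq_len(ny)))
      counts <- matrix(as.numeric(tab), nx, ny)
    }
  }
  raw <- counts / occupancy$dwell
  raw[!occupancy$mask] <- NA_real_
  if (smoothing_sigma > 0) {
    kc <- gauss_smooth2d(counts, smoothing_sigma)
    kd <- gauss_smooth2d(occupancy$dwell, smoothing_sigma)
    sm <- kc / kd
    sm[!occupancy$mask] <- NA_real_
  } else sm <- raw
  new_rate_map(rate = sm, rate_unsmoothed = raw, mask = occupancy$mask,
               xedges = occupancy$xedges, yedges = occupancy$yedges,
               smoothing_sigma = smoothing_sigma, counts = counts)
}

# 2-D Gaussian smoothing, kernel truncated at 3 sigma; edge effects cancel
# in rate maps because counts and dwell are smoothed with the same kernel.
gauss_smooth2d <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k1 <- stats::dnorm(-r:r, sd = sigma)
  k1 <- k1 / sum(k1)
  pad <- function(mm, n, dim) {
    if (dim == 1) rbind(matrix(0, n, ncol(mm)), mm, matrix(0, n, ncol(mm)))
    else cbind(matrix(0, nrow(mm), n), mm, matrix(0, nrow(mm), n))
  }
  conv1 <- function(mm, along) {
    mp <- pad(mm, r, along)
    out <- matrix(0, nrow(mm), ncol(mm))
    for (s in -r:r) {
      w <- k1[s + r + 1]
      if (along == 1) out <- out + w * mp[(r + 1 + s):(r + s + nrow(mm)), , drop = FALSE]
      else out <- out + w * mp[, (r + 1 + s):(r + s + ncol(mm)), drop = FALSE]
    }
    out
  }
  conv1(conv1(m, 1), 2)
}

#' Skaggs sparsity of a rate map
#'
#' `sparsity = (sum_i p_i lambda_i)^2 / sum_i p_i lambda_i^2`, with `p_i`
#' the dwell fraction and `lambda_i` the firing rate of bin `i`, over valid
#' bins. 1 for spatially uniform firing; `1/N` when all firing is confined
#' to one of `N` equally occupied bins — lower values mean more spatially
#' restricted firing.
#'
#' @param map A [rate_map()].
#' @param occupancy The matching [occupancy_map()].
#' @param use_smoothed Use the smoothed rate (default) or the raw rate.
#' @return Sparsity in `(0, 1]`, or `NaN` for an all-zero map.
#' @export
sparsity <- function(map, occupancy, use_smoothed = TRUE) {
  v <- occupancy$mask & map$mask
  lam <- (if (use_smoothed) map$rate else map$rate_unsmoothed)[v]
  p <- occupancy$dwell[v] / sum(occupancy$dwell[v])
  num <- sum(p * lam)^2
  den <- sum(p * lam^2)
  if (den == 0) return(NaN)
  num / den
}

#' Spatial coherence of a rate map
#'
#' First-order spatial autocorrelation: the Pearson correlation, across
#' valid bins, between each bin's rate and the mean rate of its available
#' 8-neighbourhood. Computed on the unsmoothed map (the metric's usual
#' convention). Measures how smooth/contiguous the place field is.
#'
#' @param map A [rate_map()].
#' @param fisher_z If `TRUE`, return `atanh(r)`.
#' @return Coherence (correlation-like scalar), or `NaN` for a
#'   zero-variance map.
#' @export
map_coherence <- function(map, fisher_z = FALSE) {
  rate <- map$rate_unsmoothed
  mask <- map$mask & is.finite(rate)
  nx <- nrow(rate); ny <- ncol(rate)
  if (sum(mask) < 8) return(NaN)
  centre <- c(); neigh <- c()
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (!mask[i, j]) next
    ii <- max(1, i - 1):min(nx, i + 1)
    jj <- max(1, j - 1):min(ny, j + 1)
    vals <- rate[ii, jj]
    ok <- mask[ii, jj]
    ok[which(ii == i) , which(jj == j)] <- FALSE
    if (!any(ok)) next
    centre <- c(centre, rate[i, j])
    neigh <- c(neigh, mean(vals[ok]))
  }
  if (length(centre) < 8) return(NaN)
  if (stats::sd(centre) == 0 || stats::sd(neigh) == 0) return(NaN)
  r <- stats::cor(centre, neigh)
  if (fisher_z) atanh(r) else r
}
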