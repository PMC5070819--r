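#' Firing-rate change between two sessions
#'
#' `RC = |f1 - f2| / (f1 + f2)`: 0 for identical mean rates, 1 when a cell
#' is silent in one session. Covers both rate remapping and the rate
#' signature of global remapping. Vectorized over cells.
#'
#' @param f1,f2 Mean firing rates (Hz) in exploration 1 and 2; must be
#'   non-negative.
#' @return RC in `[0, 1]`; `NaN` (cell excluded) where `f1 + f2 == 0`.
#' @examples
#' rate_change(3, 1)  # 0.5
#' @export
rate_change <- function(f1, f2) {
  if (any(f1 < 0 | f2 < 0, na.rm = TRUE)) stopf("rates must be non-negative")
  ifelse(f1 + f2 > 0, abs(f1 - f2) / (f1 + f2), NaN)
}

#' Pearson correlation between two rate maps
#'
#' Correlates bin rates of the first-exposure map with the congruent bins of
#' the second-exposure map, over bins valid in both maps. Identical maps
#' give 1; unrelated maps give values around 0.
#'
#' @param map1,map2 [rate_map()]s on identical grids.
#' @param min_bins Minimum jointly valid bins (default 20).
#' @param use_smoothed Correlate smoothed (default) or raw rates.
#' @return Pearson r in `[-1, 1]`; `NaN` (cell excluded) when either map has
#'   zero variance over the joint bins or too few bins are jointly valid.
#' @export
map_correlation <- function(map1, map2, min_bins = 20, use_smoothed = TRUE) {
  if (!identical(dim(map1$rate), dim(map2$rate)))
    stopf("rate maps must share the same grid")
  r1 <- if (use_smoothed) map1$rate else map1$rate_unsmoothed
  r2 <- if (use_smoothed) map2$rate else map2$rate_unsmoothed
  v <- map1$mask & map2$mask & is.finite(r1) & is.finite(r2)
  if (sum(v) < min_bins) return(NaN)
  if (stats::sd(r1[v]) == 0 || stats::sd(r2[v]) == 0) return(NaN)
  stats::cor(r1[v], r2[v])
}

#' Pairwise cofiring coefficients of an ensemble
#'
#' Splits a session into temporal bins (250 ms by default), counts each
#' unit's spikes per bin, and computes for every unordered cell pair the
#' Pearson correlation of the two count vectors — the pair's cofiring
#' coefficient for that session. Pairs involving a unit with fewer than
#' `min_spikes` spikes, or with zero count variance, are dropped (logged in
#' the result's `excluded` attribute).
#'
#' @param spikes A `spike_train_set`.
#' @param t_start,t_end Session bounds, s (default: the set's bounds).
#' @param bin Temporal bin size, s (default 0.250).
#' @param min_spikes Per-unit inclusion threshold (default 10).
#' @return A `cofiring_set`: data frame with `unit_a`, `unit_b`, `r`;
#'   attributes `bin`, `n_bins`, `excluded` (unit ids).
#' @export
pairwise_cofiring <- function(spikes, t_start = NULL, t_end = NULL,
                              bin = 0.250, min_spikes = 10) {
  assert_scalar_pos(bin, "bin")
  t_start <- t_start %||% attr(spikes, "t_start")
  t_end <- t_end %||% attr(spikes, "t_stop")
  edges <- seq(t_start, t_end, by = bin)
  n_bins <- length(edges) - 1L
  units <- sort(unique(attr(spikes, "units")$unit))
  if (length(units) < 2) stopf("need at least 2 units")
  counts <- sapply(units, function(u) {
    st <- spikes$time[spikes$unit == u]
    st <- st[st >= t_start & st < edges[n_bins + 1]]
    tabulate(findInterval(st, edges), nbins = n_bins)
  })
  tot <- colSums(counts)
  vars <- apply(counts, 2, stats::var)
  ok <- tot >= min_spikes & vars > 0
  excluded <- units[!ok]
  units <- units[ok]
  counts <- counts[, ok, drop = FALSE]
  if (length(units) < 2)
    return(structure(data.frame(unit_a = integer(0), unit_b = integer(0),
                                r = numeric(0)),
                     class = c("cofiring_set", "data.frame"),
                     bin = bin, n_bins = n_bins, excluded = excluded))
  cm <- stats::cor(counts)
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  structure(data.frame(unit_a = units[idx[, 1]], unit_b = units[idx[, 2]],
                       r = cm[idx]),
            class = c("cofiring_set", "data.frame"),
            bin = bin, n_bins = n_bins, excluded = excluded)
}

#' Cofiring similarity between two sessions
#'
#' The population-level stability measure: the Pearson correlation, across
#' cell pairs retained in both sessions, between the session-1 and
#' session-2 cofiring coefficients. High similarity means pairs that
#' co-fired in the first exploration co-fire again in the second.
#'
#' @param set1,set2 [pairwise_cofiring()] results for the two sessions.
#' @return List with `r` (Pearson across pairs) and `n_pairs`.
#' @export
cofiring_similarity <- function(set1, set2) {
  m <- merge(as.data.frame(set1), as.data.frame(set2),
             by = c("unit_a", "unit_b"), suffixes = c("_1", "_2"))
  if (nrow(m) < 3) stopf("fewer than 3 cell pairs valid in both sessions")
  list(r = stats::cor(m$r_1, m$r_2), n_pairs = nrow(m))
}

#' Fisher's Z comparison of two correlations
#'
#' Tests whether two independent Pearson correlations differ, via the
#' variance-stabilizing transform:
#' `Z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided p-value from the standard normal.
#'
#' @param r1,r2 The two correlations (`|r| < 1`).
#' @param n1,n2 The sample sizes behind them (`> 3`).
#' @return List with `Z` and `p`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stopf("correlations must satisfy |r| < 1")
  if (n1 <= 3 || n2 <= 3) stopf("sample sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(Z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Whole-session mean firing rates
#'
#' @param spikes A `spike_train_set`.
#' @param t_start,t_end Session bounds, s (default: the set's bounds).
#' @return Data frame with `unit` and `rate` (Hz) for every unit in the
#'   set's registry (zero-spike units included at rate 0).
#' @export
mean_rates <- function(spikes, t_start = NULL, t_end = NULL) {
  t_start <- t_start %||% attr(spikes, "t_start")
  t_end <- t_end %||% attr(spikes, "t_stop")
  dur <- t_end - t_start
  units <- attr(spikes, "units")$unit
  n <- vapply(units, function(u)
    sum(spikes$unit == u & spikes$time >= t_start & spikes$time < t_end),
    integer(1))
  data.frame(unit = units, rate = n / dur)
}
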