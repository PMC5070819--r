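#' Peri-pulse spike-time histogram (PSTH)
#'
#' Spike counts in fixed-width bins (10 ms by default) aligned to pulse
#' onsets and summed over pulses. Offsets extending into a neighbouring
#' pulse's window are still counted (the caller chooses a window consistent
#' with the pulse period).
#'
#' @param spike_times One unit's spike times, s.
#' @param pulses A [pulse_train()].
#' @param bin Bin width, s (default 0.010).
#' @param window Peri-pulse window `c(before, after)` relative to pulse
#'   onset, s.
#' @param normalize If `TRUE`, return rates (counts / (n_pulses * bin), Hz)
#'   instead of counts.
#' @return Data frame with `t` (bin centre offset, s) and `count` (or
#'   `rate`).
#' @export
pulse_psth <- function(spike_times, pulses, bin = 0.010,
                       window = c(-0.5, 1.0), normalize = FALSE) {
  if (!nrow(pulses)) stopf("need at least one pulse")
  edges <- seq(window[1], window[2], by = bin)
  nb <- length(edges) - 1L
  counts <- integer(nb)
  for (on in pulses$onset) {
    rel <- spike_times - on
    rel <- rel[rel >= window[1] & rel < edges[nb + 1]]
    counts <- counts + tabulate(findInterval(rel, edges), nbins = nb)
  }
  out <- data.frame(t = edges[-(nb + 1)] + bin / 2, count = counts)
  if (normalize) {
    out$rate <- out$count / (nrow(pulses) * bin)
    out$count <- NULL
  }
  out
}

#' Per-cell optogenetic inhibition test
#'
#' For each pulse, the unit's spikes are counted inside the pulse and in an
#' equal-length baseline window immediately preceding the pulse onset. The
#' paired counts are compared with a two-sided Wilcoxon signed-rank test
#' (zero-difference pairs dropped, the standard convention; exact null for
#' few untied pairs, normal approximation otherwise, as implemented by
#' [stats::wilcox.test()]). The cell is classified `inhibited` if the test
#' is significant and firing is lower inside the pulses, `disinhibited` if
#' significant and higher, and `unchanged` otherwise (including the
#' degenerate all-tied case, where p is undefined).
#'
#' @param spike_times One unit's spike times, s.
#' @param pulses A [pulse_train()] with at least 10 pulses whose baseline
#'   windows do not precede the recording.
#' @param alpha Significance level (default 0.05, per-cell, uncorrected).
#' @return A `pulse_response` list: `p`, `direction`, `n_pulses`,
#'   `baseline_rate`, `inpulse_rate` (Hz), `baseline_counts`,
#'   `inpulse_counts`, `note` (reason when p is undefined).
#' @export
inhibition_test <- function(spike_times, pulses, alpha = 0.05) {
  if (nrow(pulses) < 10) stopf("need >= 10 pulses for the per-cell test")
  dur <- attr(pulses, "duration")
  inp <- count_in_windows(spike_times, pulses$onset, pulses$offset)
  base <- count_in_windows(spike_times, pulses$onset - dur, pulses$onset)
  d <- base - inp
  note <- NA_character_
  if (all(d == 0)) {
    p <- NA_real_
    direction <- "unchanged"
    note <- "all baseline/in-pulse pairs tied; p undefined"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(base, inp, paired = TRUE, exact = FALSE)$p.value)
    nz <- d[d != 0]
    med <- stats::median(nz)
    if (med == 0) med <- mean(nz)
    direction <- if (p < alpha && med > 0) "inhibited"
                 else if (p < alpha && med < 0) "disinhibited"
                 else "unchanged"
  }
  structure(list(p = p, direction = direction, n_pulses = nrow(pulses),
                 baseline_rate = sum(base) / (nrow(pulses) * dur),
                 inpulse_rate = sum(inp) / (nrow(pulses) * dur),
                 baseline_counts = base, inpulse_counts = inp, note = note),
            class = "pulse_response")
}

# spikes in [lo_i, hi_i) per window; O((n + m) log n) via findInterval
count_in_windows <- function(x, lo, hi) {
  x <- sort(x)
  findInterval(hi, x, left.open = TRUE) - findInterval(lo, x, left.open = TRUE)
}

#' @export
print.pulse_response <- function(x, ...) {
  cat(sprintf("<pulse_response> %s (p = %.3g), baseline %.2f Hz -> in-pulse %.2f Hz over %d pulses\n",
              x$direction, x$p, x$baseline_rate, x$inpulse_rate, x$n_pulses))
  invisible(x)
}

#' Population summary of inhibition responses
#'
#' @param responses List of [inhibition_test()] results.
#' @param alpha Significance level used (metadata).
#' @return List with `n`, `fraction_inhibited`, `fraction_disinhibited`,
#'   `fraction_unchanged`, `alpha`.
#' @export
population_summary <- function(responses, alpha = 0.05) {
  if (!length(responses)) stopf("need at least one response")
  dirs <- vapply(responses, function(r) r$direction, character(1))
  n <- length(dirs)
  list(n = n,
       fraction_inhibited = mean(dirs == "inhibited"),
       fraction_disinhibited = mean(dirs == "disinhibited"),
       fraction_unchanged = mean(dirs == "unchanged"),
       alpha = alpha)
}

#' Classical one-way ANOVA
#'
#' Fixed-effects one-way analysis of variance across two or more groups
#' (equal-variance F test), as used for group comparisons of sparsity,
#' coherence and rate-change values.
#'
#' @param groups List of numeric vectors, each with `n >= 2` finite values.
#' @return List with `F`, `p`, `df` (between, within).
#' @export
oneway_anova <- function(groups) {
  if (length(groups) < 2) stopf("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stopf("every group needs n >= 2")
  values <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(values))) stopf("values must be finite")
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  f <- unname(fit$statistic)
  if (is.nan(f)) f <- 0  # zero between- and within-group variance
  list(F = f, p = unname(fit$p.value), df = unname(fit$parameter))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF1 - ECDF2|` with the asymptotic p-value, as used to compare
#' the distributions of rate-change and map-correlation values across
#' conditions.
#'
#' @param sample1,sample2 Non-empty numeric vectors.
#' @return List with `D` and `p`.
#' @export
ks_test <- function(sample1, sample2) {
  if (!length(sample1) || !length(sample2)) stopf("samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(sample1, sample2, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}
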