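#' Run the full analysis over one (simulated or assembled) day
#'
#' Chains every stage of the pipeline: detection evaluation on each sleep
#' block (online TTLs and the offline non-stringent detector against ground
#' truth where available), event-triggered spectra on the first sleep block,
#' occupancy-normalized rate maps and per-cell sparsity/coherence for both
#' explorations, per-cell rate change and rate-map correlation, pairwise
#' cofiring and its between-session similarity, and the per-cell inhibition
#' test on the final half-intensity pulse session. The manifest is
#' validated before any computation; identical input and seed give an
#' identical report.
#'
#' @param day A [simulate_day()] result (or a compatible assembled day).
#' @return A `day_report` list: `condition`, `cells` (per-cell table with
#'   `unit`, `rate1`, `rate2`, `rc`, `map_r`, `sparsity1`, `sparsity2`,
#'   `coherence1`, `coherence2`), `cofiring` (`r`, `n_pairs`), `detection`
#'   (per sleep block), `spectra` (`spectrogram`, `normalized`,
#'   `peak_freq`), `inhibition` (per-cell responses and population
#'   summary), `n_cells`, `seed`.
#' @export
run_day <- function(day) {
  validate_manifest(day$manifest)
  cfg <- day$config

  # --- detection ----------------------------------------------------------
  detection <- lapply(day$sleep, function(bl) {
    offline <- offline_detect(bl$lfp)
    list(online = evaluate_detection(bl$ttl, bl$truth,
                                     ripple_freq = cfg$ripple$freq),
         offline = evaluate_detection(offline, bl$truth,
                                      ripple_freq = cfg$ripple$freq),
         n_offline = nrow(offline))
  })

  # --- spectra (first sleep block) ---------------------------------------
  bl <- day$sleep[[1]]
  x <- differential_signal(bl$lfp)
  fs <- bl$lfp$sampling_rate
  shift <- if (attr(bl$laser, "mode") == "delayed") attr(bl$laser, "delay") else 0
  spectra <- if (nrow(bl$laser)) {
    sg <- triggered_spectrogram(x, fs, bl$laser$onset, align_shift = shift,
                                span = 0.5)
    offline <- offline_detect(bl$lfp)
    norm <- if (nrow(offline) >= 2)
      normalized_event_spectrum(x, fs, offline$peak_time) else NULL
    list(spectrogram = sg, normalized = norm,
         peak_freq = peak_frequency(tf_slice(sg, 0), c(100, 250)))
  } else NULL

  # --- place maps and single-cell stability ------------------------------
  occ1 <- occupancy_map(day$trajectories$expl1, cfg$bin_size,
                        cfg$min_occupancy, cfg$speed_threshold)
  occ2 <- occupancy_map(day$trajectories$expl2, cfg$bin_size,
                        cfg$min_occupancy, cfg$speed_threshold)
  e1_start <- session_start(day$manifest, "exploration1")
  e2_start <- session_start(day$manifest, "exploration2")
  units <- attr(day$spikes$expl1, "units")$unit
  f1 <- mean_rates(day$spikes$expl1)
  f2 <- mean_rates(day$spikes$expl2)
  cells <- do.call(rbind, lapply(units, function(u) {
    m1 <- rate_map(unit_spikes(day$spikes$expl1, u) - e1_start,
                   day$trajectories$expl1, occ1, cfg$smoothing_sigma)
    m2 <- rate_map(unit_spikes(day$spikes$expl2, u) - e2_start,
                   day$trajectories$expl2, occ2, cfg$smoothing_sigma)
    data.frame(unit = u,
               rate1 = f1$rate[f1$unit == u], rate2 = f2$rate[f2$unit == u],
               rc = rate_change(f1$rate[f1$unit == u], f2$rate[f2$unit == u]),
               map_r = map_correlation(m1, m2),
               sparsity1 = sparsity(m1, occ1), sparsity2 = sparsity(m2, occ2),
               coherence1 = map_coherence(m1), coherence2 = map_coherence(m2))
  }))

  # --- cofiring ----------------------------------------------------------
  cf1 <- pairwise_cofiring(day$spikes$expl1, bin = cfg$cofiring_bin)
  cf2 <- pairwise_cofiring(day$spikes$expl2, bin = cfg$cofiring_bin)
  cof <- tryCatch(cofiring_similarity(cf1, cf2),
                  error = function(e) list(r = NA_real_, n_pairs = 0L))

  # --- inhibition --------------------------------------------------------
  responses <- lapply(units, function(u)
    inhibition_test(unit_spikes(day$spikes$control_sleep, u),
                    day$control_pulses, alpha = cfg$alpha))
  names(responses) <- units

  structure(list(condition = day$condition, cells = cells, cofiring = cof,
                 detection = detection, spectra = spectra,
                 inhibition = list(responses = responses,
                                   summary = population_summary(responses,
                                                                cfg$alpha)),
                 n_cells = length(units), seed = day$seed),
            class = "day_report")
}

#' @export
print.day_report <- function(x, ...) {
  cat(sprintf("<day_report> condition=%s, %d cells\n", x$condition, x$n_cells))
  cat(sprintf("  mean RC %.3f, mean map r %.3f, cofiring similarity r=%.3f (%d pairs)\n",
              mean(x$cells$rc, na.rm = TRUE),
              mean(x$cells$map_r, na.rm = TRUE),
              x$cofiring$r, x$cofiring$n_pairs))
  cat(sprintf("  inhibited: %.0f%% of cells (alpha %.2f)\n",
              100 * x$inhibition$summary$fraction_inhibited,
              x$inhibition$summary$alpha))
  invisible(x)
}

#' Compare two conditions (blockade vs control)
#'
#' Applies the group statistics used for the headline comparisons: one-way
#' ANOVA on per-cell sparsity, coherence and rate change; Kolmogorov-
#' Smirnov tests on the distributions of rate change and map correlation;
#' and Fisher's Z test on the two cofiring-similarity correlations.
#'
#' @param report_a,report_b [run_day()] reports for the two conditions.
#' @return A `condition_comparison` list of test results, each `(stat, p)`.
#' @export
compare_days <- function(report_a, report_b) {
  ca <- report_a$cells; cb <- report_b$cells
  cc <- function(x) x[is.finite(x)]
  out <- list(
    conditions = c(report_a$condition, report_b$condition),
    sparsity1_anova = oneway_anova(list(cc(ca$sparsity1), cc(cb$sparsity1))),
    sparsity2_anova = oneway_anova(list(cc(ca$sparsity2), cc(cb$sparsity2))),
    coherence1_anova = oneway_anova(list(cc(ca$coherence1), cc(cb$coherence1))),
    coherence2_anova = oneway_anova(list(cc(ca$coherence2), cc(cb$coherence2))),
    rc_anova = oneway_anova(list(cc(ca$rc), cc(cb$rc))),
    rc_ks = ks_test(cc(ca$rc), cc(cb$rc)),
    map_r_anova = oneway_anova(list(cc(ca$map_r), cc(cb$map_r))),
    map_r_ks = ks_test(cc(ca$map_r), cc(cb$map_r)),
    cofiring_fisher = fisher_z_compare(report_a$cofiring$r,
                                       report_a$cofiring$n_pairs,
                                       report_b$cofiring$r,
                                       report_b$cofiring$n_pairs))
  structure(out, class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<condition_comparison> %s vs %s\n",
              x$conditions[1], x$conditions[2]))
  cat(sprintf("  RC: F=%.2f p=%.3f | map r KS: D=%.3f p=%.3f | cofiring: Z=%.3f p=%.3f\n",
              x$rc_anova$F, x$rc_anova$p, x$map_r_ks$D, x$map_r_ks$p,
              x$cofiring_fisher$Z, x$cofiring_fisher$p))
  invisible(x)
}
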