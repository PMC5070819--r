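#!/usr/bin/env Rscript
# Between-session stability of the spatial code: per-cell rate change
# RC = |f1 - f2| / (f1 + f2) and rate-map Pearson correlation, plus the
# population-level cofiring similarity, compared across conditions with
# ANOVA, Kolmogorov-Smirnov and Fisher's Z — the full set of headline
# stability statistics.

source(file.path("analysis", "00_config.R"))

reports <- lapply(names(DAY_SEEDS), function(cond) run_day(get_day(cond)))
names(reports) <- names(DAY_SEEDS)
cmp <- compare_days(reports$blockade, reports$control)

summ <- data.frame(
  condition = names(reports),
  mean_rc = vapply(reports, function(r) mean(r$cells$rc, na.rm = TRUE),
                   numeric(1)),
  mean_map_r = vapply(reports, function(r) mean(r$cells$map_r, na.rm = TRUE),
                      numeric(1)),
  cofiring_r = vapply(reports, function(r) r$cofiring$r, numeric(1)),
  n_pairs = vapply(reports, function(r) r$cofiring$n_pairs, numeric(1)))
write.csv(summ, file.path(results_dir(), "stability_summary.csv"),
          row.names = FALSE)

stats <- data.frame(
  test = c("RC ANOVA", "RC KS", "map-r ANOVA", "map-r KS", "cofiring Fisher Z"),
  stat = c(cmp$rc_anova$F, cmp$rc_ks$D, cmp$map_r_anova$F, cmp$map_r_ks$D,
           cmp$cofiring_fisher$Z),
  p = c(cmp$rc_anova$p, cmp$rc_ks$p, cmp$map_r_anova$p, cmp$map_r_ks$p,
        cmp$cofiring_fisher$p))
write.csv(stats, file.path(results_dir(), "stability_comparison.csv"),
          row.names = FALSE)

print(summ, digits = 3)
cat("\n")
print(stats, digits = 3)
cat("\nBoth days use the same drift settings, so the population-level map",
    "correlation and cofiring comparisons come out non-significant; note that",
    "each simulated day draws its own per-cell drifts and rate scalings, so",
    "single-cell metrics (like RC) can differ incidentally between two",
    "single days, much as day-specific environments do in real recordings.",
    "Re-running with a larger drift on one day makes RC rise and map-r /",
    "cofiring fall on that day.\n")
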