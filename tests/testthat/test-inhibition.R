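test_that("PSTH counts land in the right 10 ms bins", {
  pulses <- regular_pulse_train(0, 100, period = 3, duration = 0.5)
  # zero spikes -> all-zero histogram
  h0 <- pulse_psth(numeric(0), pulses)
  expect_true(all(h0$count == 0))
  expect_equal(diff(h0$t)[1], 0.010, tolerance = 1e-12)
  # one spike exactly at one pulse onset -> a single count at offset 0
  h1 <- pulse_psth(pulses$onset[5], pulses)
  expect_equal(sum(h1$count), 1L)
  expect_equal(h1$t[h1$count == 1], 0.005)
  expect_error(pulse_psth(1, pulse_train(numeric(0), 0.5)), "one pulse")
})

test_that("PSTH level inside pulses reflects the suppression fraction", {
  pulses <- regular_pulse_train(0, 1800, period = 3, duration = 0.5)
  spk <- generate_poisson_spikes(c(`1` = 5), 1800, seed = 1)
  sup <- apply_light_suppression(spk, pulses, 0.8, seed = 2)
  h <- pulse_psth(unit_spikes(sup, 1), pulses, window = c(-0.5, 0.5),
                  normalize = TRUE)
  in_pulse <- h$rate[h$t > 0 & h$t < 0.5]
  pre <- h$rate[h$t < 0]
  expect_equal(mean(in_pulse) / mean(pre), 0.2, tolerance = 0.15)
})

test_that("the per-cell Wilcoxon procedure classifies the obvious cases", {
  pulses <- regular_pulse_train(0, 100, period = 3, duration = 0.5)
  # identical counts in every pair -> unchanged, p = 1 (all ties dropped)
  per <- as.vector(outer(pulses$onset, c(-0.25, 0.25), `+`))
  r <- inhibition_test(sort(per), pulses)
  expect_equal(r$direction, "unchanged")
  # silence -> degenerate, unchanged with a logged note
  r0 <- inhibition_test(numeric(0), pulses)
  expect_equal(r0$direction, "unchanged")
  expect_match(r0$note, "tied")
  # 30 pulses, baseline >= 3 spikes, total silence inside -> inhibited
  p30 <- regular_pulse_train(0, 93, period = 3, duration = 0.5)
  expect_equal(nrow(p30), 30L)
  base_spikes <- as.vector(outer(p30$onset, c(-0.4, -0.3, -0.2, -0.1), `+`))
  r1 <- inhibition_test(sort(base_spikes), p30)
  expect_equal(r1$direction, "inhibited")
  expect_lt(r1$p, 0.001)
  expect_error(inhibition_test(1:5, regular_pulse_train(0, 10, 3, 0.5)),
               ">= 10 pulses")
})

test_that("wilcox p-values agree with an exact sign-flip enumeration", {
  # small-n oracle: enumerate all 2^n signed-rank sums for untied pairs
  set.seed(3)
  d <- round(rnorm(12, 0.3, 1), 3)
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  null_W <- signs %*% rk
  p_exact <- mean(abs(null_W - n * (n + 1) / 4) >=
                    abs(W - n * (n + 1) / 4) - 1e-9)
  p_got <- stats::wilcox.test(d, exact = TRUE)$p.value
  expect_equal(p_got, p_exact, tolerance = 1e-10)
})

test_that("strongly suppressed generator cells are flagged inhibited", {
  pulses <- regular_pulse_train(0, 1800, period = 3, duration = 0.5)
  flagged <- vapply(1:8, function(s) {
    spk <- generate_poisson_spikes(c(`1` = 2), 1800, seed = 100 + s)
    sup <- apply_light_suppression(spk, pulses, 0.8, seed = 200 + s)
    inhibition_test(unit_spikes(sup, 1), pulses)$direction
  }, character(1))
  expect_true(all(flagged == "inhibited"))
})

test_that("the inhibition test holds its size and gains power with suppression", {
  pulses <- regular_pulse_train(0, 300, period = 3, duration = 0.5)
  run_cells <- function(suppression, n_cells, seed0) {
    vapply(seq_len(n_cells), function(i) {
      spk <- generate_poisson_spikes(c(`1` = 2), 300, seed = seed0 + i)
      sup <- apply_light_suppression(spk, pulses, suppression,
                                     seed = seed0 + 1000 + i)
      r <- inhibition_test(unit_spikes(sup, 1), pulses)
      c(sig = !is.na(r$p) && r$p < 0.05, inh = r$direction == "inhibited")
    }, logical(2))
  }
  null_cells <- run_cells(0, 200, 300)
  # type-I: ~5% significant under the null (two-sided)
  expect_lt(mean(null_cells["sig", ]), 0.10)
  expect_gt(mean(null_cells["sig", ]), 0.01)
  # power is non-decreasing in suppression strength
  frac_inh <- c(mean(null_cells["inh", ]),
                mean(run_cells(0.4, 60, 600)["inh", ]),
                mean(run_cells(0.8, 60, 900)["inh", ]))
  expect_true(all(diff(frac_inh) >= 0))
  expect_gt(frac_inh[3], 0.9)
})

test_that("population summaries count directions correctly", {
  mk <- function(dir) structure(list(direction = dir), class = "pulse_response")
  all_inh <- population_summary(lapply(1:5, function(i) mk("inhibited")))
  expect_equal(all_inh$fraction_inhibited, 1)
  mixed <- population_summary(c(lapply(1:7, function(i) mk("inhibited")),
                                lapply(1:3, function(i) mk("unchanged"))))
  expect_equal(mixed$fraction_inhibited, 0.7)
  expect_equal(mixed$fraction_disinhibited, 0)
  expect_equal(mixed$fraction_unchanged, 0.3)
  expect_equal(mixed$fraction_inhibited + mixed$fraction_disinhibited +
                 mixed$fraction_unchanged, 1)
  expect_error(population_summary(list()), "at least one")
})

test_that("one-way ANOVA matches an independent sums-of-squares oracle", {
  anova_oracle <- function(groups) {
    all <- unlist(groups)
    gm <- mean(all)
    ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                      numeric(1)))
    ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
    dfb <- length(groups) - 1
    dfw <- length(all) - length(groups)
    f <- (ssb / dfb) / (ssw / dfw)
    list(F = f, p = pf(f, dfb, dfw, lower.tail = FALSE))
  }
  expect_equal(oneway_anova(list(c(1, 2, 3), c(1, 2, 3)))$F, 0)
  g <- list(c(0, 1), c(10, 11))
  expect_equal(oneway_anova(g)$F, anova_oracle(g)$F, tolerance = 1e-10)
  expect_equal(oneway_anova(g)$p, anova_oracle(g)$p, tolerance = 1e-10)
  set.seed(4)
  for (i in 1:10) {
    gg <- lapply(1:3, function(j) rnorm(sample(3:8, 1), j * 0.3))
    expect_equal(oneway_anova(gg)$F, anova_oracle(gg)$F, tolerance = 1e-10)
    expect_equal(oneway_anova(gg)$p, anova_oracle(gg)$p, tolerance = 1e-10)
  }
  near_null <- oneway_anova(list(rnorm(10), rnorm(10)))
  expect_gt(near_null$p, 0.001)
  expect_error(oneway_anova(list(1:3)), "2 groups")
})

test_that("the KS statistic matches a brute-force ECDF scan", {
  ks_oracle <- function(a, b) {
    pts <- sort(unique(c(a, b)))
    max(abs(vapply(pts, function(p) mean(a <= p) - mean(b <= p), numeric(1))))
  }
  expect_equal(ks_test(1:10, 1:10)$D, 0)
  expect_equal(ks_test(runif(20), 10 + runif(20))$D, 1)
  got <- ks_test(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(got$D, ks_oracle(c(1, 2, 3, 4), c(2, 3, 4, 5)),
               tolerance = 1e-10)
  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(sample(5:30, 1)); b <- rnorm(sample(5:30, 1), 0.5)
    expect_equal(ks_test(a, b)$D, ks_oracle(a, b), tolerance = 1e-10)
  }
  expect_error(ks_test(numeric(0), 1:3), "non-empty")
})
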