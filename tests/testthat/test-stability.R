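test_that("rate change follows RC = |f1 - f2| / (f1 + f2)", {
  expect_equal(rate_change(2, 2), 0)
  expect_equal(rate_change(3, 1), 0.5)
  expect_equal(rate_change(2, 0), 1)
  expect_true(is.nan(rate_change(0, 0)))
  expect_equal(rate_change(c(2, 3), c(2, 1)), c(0, 0.5))
  expect_error(rate_change(-1, 2), "non-negative")
})

test_that("map correlation hits its identity, reflection and null cases", {
  set.seed(1)
  m1 <- matrix_rate_map(matrix(rexp(900), 30, 30))
  expect_equal(map_correlation(m1, m1), 1)
  refl <- matrix_rate_map(max(m1$rate) - m1$rate)
  expect_equal(map_correlation(m1, refl), -1)
  # unrelated random maps: r ~ 0 over repeated draws
  rs <- replicate(50, {
    a <- matrix_rate_map(matrix(rexp(900), 30, 30))
    b <- matrix_rate_map(matrix(rexp(900), 30, 30))
    map_correlation(a, b)
  })
  expect_lt(abs(mean(rs)), 0.1)
  # zero variance -> NaN
  expect_true(is.nan(map_correlation(m1, matrix_rate_map(matrix(1, 30, 30)))))
  expect_error(map_correlation(m1, matrix_rate_map(matrix(1, 5, 5))), "grid")
})

test_that("cofiring coefficients match direct count-vector construction", {
  # identical trains -> coefficient 1
  tt <- sort(runif(200, 0, 60))
  s <- spike_set(list(tt, tt), list(1L, 2L), t_start = 0, t_stop = 60)
  cf <- pairwise_cofiring(s, bin = 0.25)
  expect_equal(cf$r, 1)
  # independent Poisson units -> |r| < 3/sqrt(n_bins)
  set.seed(2)
  n_bins <- 1440 / 0.25
  s2 <- generate_poisson_spikes(c(`1` = 3, `2` = 3), 1440, seed = 3)
  cf2 <- pairwise_cofiring(s2, bin = 0.25)
  expect_lt(abs(cf2$r), 3 / sqrt(n_bins))
  # anti-phase bursting -> negative coefficient, equal to the brute-force
  # correlation of the binned counts
  a_times <- as.vector(outer(seq(0, 59.5, by = 0.5), c(0.05, 0.1, 0.15), `+`))
  b_times <- a_times + 0.25
  s3 <- spike_set(list(sort(a_times), sort(b_times)),
                  list(1L, 2L), t_start = 0, t_stop = 60)
  cf3 <- pairwise_cofiring(s3, bin = 0.25)
  edges <- seq(0, 60, by = 0.25)
  ca <- tabulate(findInterval(sort(a_times), edges), nbins = 240)
  cb <- tabulate(findInterval(sort(b_times), edges), nbins = 240)
  expect_equal(cf3$r, cor(ca, cb), tolerance = 1e-12)
  expect_lt(cf3$r, 0)
})

test_that("cofiring exclusions drop sparse and zero-variance units", {
  s <- spike_set(list(sort(runif(100, 0, 60)), c(1, 2, 3)),
                 list(1L, 2L), t_start = 0, t_stop = 60)
  cf <- pairwise_cofiring(s, bin = 0.25, min_spikes = 10)
  expect_equal(nrow(cf), 0L)
  expect_true(2L %in% attr(cf, "excluded"))
  expect_error(pairwise_cofiring(spike_set(list(1:3), list(1L)), bin = 1),
               "2 units")
})

test_that("cofiring similarity is 1 on identity and ~0 under permutation", {
  set.seed(4)
  s1 <- generate_poisson_spikes(rep(4, 10), 600, seed = 5)
  cf <- pairwise_cofiring(s1, bin = 0.25)
  expect_equal(cofiring_similarity(cf, cf)$r, 1)
  perm_rs <- replicate(30, {
    shuf <- cf
    shuf$r <- sample(shuf$r)
    cofiring_similarity(cf, shuf)$r
  })
  expect_lt(abs(mean(perm_rs)), 3 / sqrt(30 * nrow(cf)))
  tiny <- cf[1:2, ]
  class(tiny) <- class(cf)
  expect_error(cofiring_similarity(tiny, tiny), "fewer than 3")
})

test_that("map correlation and cofiring similarity fall with drift", {
  a <- box60()
  tr1 <- simulate_trajectory(a, 1440, seed = 6)
  tr2 <- simulate_trajectory(a, 1440, seed = 7)
  occ1 <- occupancy_map(tr1)
  occ2 <- occupancy_map(tr2)
  res <- lapply(c(0, 8, 25), function(drift) {
    ens <- make_ensemble(50, a,
                         stability_params = list(drift_mean = drift,
                                                 drift_sd = drift / 10,
                                                 rate_sdlog = 0),
                         seed = 8)
    sp1 <- generate_spikes(ens, tr1, session = 1, seed = 9)
    sp2 <- generate_spikes(ens, tr2, session = 2, seed = 10)
    map_r <- vapply(1:50, function(u) map_correlation(
      rate_map(unit_spikes(sp1, u), tr1, occ1),
      rate_map(unit_spikes(sp2, u), tr2, occ2)), numeric(1))
    cof <- cofiring_similarity(pairwise_cofiring(sp1),
                               pairwise_cofiring(sp2))
    list(map_r = mean(map_r, na.rm = TRUE), cof = cof$r)
  })
  map_rs <- vapply(res, `[[`, numeric(1), "map_r")
  cofs <- vapply(res, `[[`, numeric(1), "cof")
  expect_true(all(diff(map_rs) < 0))
  expect_true(all(diff(cofs) < 0))
  # zero-drift recovery: stable code reproduces itself
  expect_gt(map_rs[1], 0.9)
})

test_that("zero-drift RC sits at its Poisson noise floor", {
  # with f1 = f2 = f and independent Poisson counts over duration T,
  # E[RC] ~ E|N1 - N2| / (N1 + N2); oracle: direct Monte Carlo over the
  # observed per-cell counts
  a <- box60()
  tr1 <- simulate_trajectory(a, 1440, seed = 11)
  tr2 <- simulate_trajectory(a, 1440, seed = 12)
  ens <- make_ensemble(40, a,
                       stability_params = list(drift_mean = 0, drift_sd = 0,
                                               rate_sdlog = 0),
                       seed = 13)
  sp1 <- generate_spikes(ens, tr1, session = 1, seed = 14)
  sp2 <- generate_spikes(ens, tr2, session = 2, seed = 15)
  f1 <- mean_rates(sp1); f2 <- mean_rates(sp2)
  rc <- mean(rate_change(f1$rate, f2$rate))
  lam <- (f1$rate + f2$rate) / 2 * 1440
  set.seed(16)
  floor_mc <- mean(vapply(lam, function(l) {
    n1 <- rpois(500, l); n2 <- rpois(500, l)
    mean(abs(n1 - n2) / (n1 + n2), na.rm = TRUE)
  }, numeric(1)))
  # trajectory sampling differences add on top of pure count noise, but the
  # ensemble mean should stay within a small factor of the Poisson floor
  expect_lt(rc, 3 * floor_mc + 0.05)
})

test_that("Fisher's Z comparison matches its closed form and is antisymmetric", {
  expect_equal(fisher_z_compare(0.4, 50, 0.4, 80)$Z, 0)
  expect_equal(fisher_z_compare(0.4, 50, 0.4, 80)$p, 1)
  got <- fisher_z_compare(0.5, 100, 0.3, 100)
  z_oracle <- (atanh(0.5) - atanh(0.3)) / sqrt(1 / 97 + 1 / 97)
  expect_equal(got$Z, z_oracle, tolerance = 1e-12)
  expect_equal(got$p, 2 * (1 - pnorm(abs(z_oracle))), tolerance = 1e-12)
  swapped <- fisher_z_compare(0.3, 100, 0.5, 100)
  expect_equal(swapped$Z, -got$Z)
  expect_equal(swapped$p, got$p)
  expect_error(fisher_z_compare(1, 10, 0.5, 10), "\\|r\\| < 1")
  expect_error(fisher_z_compare(0.2, 3, 0.5, 10), "exceed 3")
})

test_that("stability statistics are invariant under unit relabelling", {
  s1 <- generate_poisson_spikes(rep(4, 6), 300, seed = 17)
  cf <- pairwise_cofiring(s1, bin = 0.25)
  relabel <- s1
  relabel$unit <- 7L - relabel$unit  # reverse ids
  attr(relabel, "units")$unit <- sort(7L - attr(relabel, "units")$unit)
  cf_rel <- pairwise_cofiring(relabel, bin = 0.25)
  expect_equal(sort(cf$r), sort(cf_rel$r), tolerance = 1e-12)
  expect_equal(cofiring_similarity(cf, cf)$r,
               cofiring_similarity(cf_rel, cf_rel)$r)
})
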