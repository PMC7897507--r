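test_that("noise is seed-deterministic and vanishes at zero amplitude", {
  tr <- trace01()
  clean <- noise_model(sigma = 0, drift_rate = 0, seed = 3)
  expect_equal(add_noise(tr, clean)$compaction_nm_per_nt,
               tr$compaction_nm_per_nt)
  nm <- noise_model(seed = 11)
  a <- add_noise(tr, nm)
  b <- add_noise(tr, nm)
  expect_identical(a$compaction_nm_per_nt, b$compaction_nm_per_nt)
  expect_false(identical(add_noise(tr, nm, seed = 12)$compaction_nm_per_nt,
                         a$compaction_nm_per_nt))
  expect_error(add_noise(a, nm), "ideal")
})

test_that("the mean of many noisy realizations converges to the ideal trace", {
  p <- tbl1()
  tr <- simulate_protocol(incubation_protocol(5, t_incubate = 20,
                                              t_rinse = 10), p)
  nm <- noise_model(sigma = 0.005, drift_rate = 0.002)
  n_real <- 1000
  acc <- matrix(0, n_real, nrow(tr))
  for (i in seq_len(n_real)) {
    acc[i, ] <- add_noise(tr, nm, seed = i)$compaction_nm_per_nt
  }
  mu <- colMeans(acc)
  sem <- apply(acc, 2, stats::sd) / sqrt(n_real)
  expect_true(all(abs(mu - tr$compaction_nm_per_nt) < 3.6 * sem))
})

test_that("the concentration series has the advertised structure", {
  p <- tbl1()
  ser <- cached("series_small", {
    generate_concentration_series(
      p, concentrations = c(0.1, 0.5, 1, 5, 10, 50),
      noise = noise_model(seed = 77), n_rep = 3,
      t_incubate = 120, t_rinse = 120, t_reincubate = 60)
  })
  expect_length(ser$traces, 18)
  expect_equal(nrow(ser$index), 18)
  expect_length(unique(ser$index$seed), 18)
  # ideal incubation amplitudes decrease with concentration
  amps <- vapply(ser$ideal, function(tr) {
    max(tr$compaction_nm_per_nt[tr$time_s <= 120])
  }, numeric(1))
  expect_true(all(diff(amps) < 0))
  # rinse plateaus agree across c >= 1 nM
  plats <- vapply(ser$ideal[c("1", "5", "10", "50")], function(tr) {
    tail(tr$compaction_nm_per_nt[tr$time_s <= 240], 1)
  }, numeric(1))
  expect_lt((max(plats) - min(plats)) / mean(plats), 0.02)
})

test_that("per-trace seeds derive from the master seed by a stable counter", {
  p <- tbl1()
  s1 <- generate_concentration_series(p, concentrations = c(1, 5),
                                      noise = noise_model(seed = 5),
                                      n_rep = 2, t_incubate = 10,
                                      t_rinse = 10, t_reincubate = 0)
  s2 <- generate_concentration_series(p, concentrations = c(1, 5),
                                      noise = noise_model(seed = 5),
                                      n_rep = 3, t_incubate = 10,
                                      t_rinse = 10, t_reincubate = 0)
  # replicates 1-2 of concentration 1 are unchanged when replicates grow
  expect_identical(s1$traces[[1]]$compaction_nm_per_nt,
                   s2$traces[[1]]$compaction_nm_per_nt)
  expect_identical(s1$traces[[2]]$compaction_nm_per_nt,
                   s2$traces[[2]]$compaction_nm_per_nt)
})

test_that("RecA saturation curves follow the exponential identity and round-trip", {
  nf <- generate_reca_curve(0.003, duration = 1 / 0.003)
  # the last sample sits on the 10 Hz grid, a hair before t = 1/rate
  expect_equal(tail(nf$saturation, 1),
               1 - exp(-0.003 * tail(nf$time_s, 1)), tolerance = 1e-12)
  expect_equal(tail(nf$saturation, 1), 1 - exp(-1), tolerance = 1e-3)
  n1 <- generate_reca_curve(0.01, noise = noise_model(seed = 4),
                            duration = 300)
  n2 <- generate_reca_curve(0.01, noise = noise_model(seed = 4),
                            duration = 300)
  expect_identical(n1$saturation, n2$saturation)
  fit <- fit_filamentation_rate(generate_reca_curve(0.003, duration = 1500))
  expect_equal(fit$rate, 0.003, tolerance = 1e-6)
})
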