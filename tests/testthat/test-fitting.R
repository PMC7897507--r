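test_that("exponential fits are exact on noiseless exponentials", {
  for (k in c(0.01, 0.1, 1, 5)) {
    for (B in c(0, 0.05)) {
      tt <- seq(0, 8 / k, by = min(0.1, 0.4 / k))
      tr <- structure(data.frame(time_s = tt,
                                 compaction_nm_per_nt = 0.06 * exp(-k * tt) + B),
                      class = c("ssb_trace", "data.frame"))
      f <- fit_exponential(tr, c(0, max(tt)))
      expect_equal(f$rate, k, tolerance = 1e-6)
      expect_equal(f$offset, B, tolerance = 1e-6)
    }
  }
  # exactness holds regardless of window phase (start inside the decay)
  tt <- seq(0, 100, by = 0.1)
  tr <- structure(data.frame(time_s = tt,
                             compaction_nm_per_nt = 0.05 * exp(-0.1 * tt) + 0.02),
                  class = c("ssb_trace", "data.frame"))
  f <- fit_exponential(tr, c(17.3, 90))
  expect_equal(f$rate, 0.1, tolerance = 1e-6)
})

test_that("exponential fit input contracts hold", {
  tt <- seq(0, 1, by = 0.5)
  tr <- structure(data.frame(time_s = tt, compaction_nm_per_nt = tt),
                  class = c("ssb_trace", "data.frame"))
  expect_error(fit_exponential(tr, c(0, 1)), "10 samples")
})

test_that("the serial two-step relation has the stated limits", {
  k_b <- 0.18; k_w <- 1.8
  cs <- c(1e-4, 1e-3)
  expect_equal(apparent_bind_rate(cs, k_b, k_w) / cs, rep(k_b, 2),
               tolerance = 1e-3)
  expect_equal(apparent_bind_rate(1e6, k_b, k_w), k_w, tolerance = 1e-4)
  expect_equal(apparent_bind_rate(k_w / k_b, k_b, k_w), k_w / 2)
  expect_error(apparent_bind_rate(1, -1, 1), "> 0")
})

test_that("phase segmentation reflects the protocol structure", {
  tr <- trace50()
  ph <- segment_phases(tr)
  # saturating incubation -> rinse -> re-incubation: compaction rises to
  # the oversaturated equilibrium, rises further on rinse, falls on
  # re-incubation
  expect_equal(ph$label, c("bind-wrap", "unbind-wrap", "rebind-unwrap"))
  expect_equal(sign(ph$amplitude), c(1, 1, -1))
  # flat trace: no phases
  flat <- structure(data.frame(time_s = seq(0, 99.9, by = 0.1),
                               compaction_nm_per_nt = rep(0.01, 1000)),
                    class = c("ssb_trace", "data.frame"))
  fp <- protocol(c(50, 50), c(1, 0))
  expect_equal(nrow(segment_phases(flat, fp)), 0)
  expect_error(segment_phases(flat, protocol(1000, 5)), "do not match")
})

test_that("rinse-phase and dissociation-phase rates recover the fitted constants", {
  p <- tbl1()
  tr <- trace50()
  ph <- segment_phases(tr)
  f <- fit_exponential(tr, ph[ph$label == "unbind-wrap", ])
  expect_equal(f$rate, 0.11, tolerance = 0.02)
  tr20 <- simulate_protocol(protocol(c(60, 600), c(50, 0), 20), p)
  ph20 <- segment_phases(tr20)
  f20 <- fit_exponential(tr20, ph20[ph20$label == "direct-dissociation", ])
  expect_equal(f20$rate, p$k_off, tolerance = 1e-4)
})

test_that("isotherm fits are exact on exact isotherms and robust to noise", {
  cs <- c(0.5, 1, 2, 4, 8, 16, 32)
  expect_equal(fit_isotherm(cs, cs / (cs + 5))$c_crit, 5, tolerance = 1e-6)
  expect_error(fit_isotherm(c(1, 2), c(0.2, 0.4)), "at least 5")
  # median over noisy replicates stays within 10% of truth
  set.seed(9)
  est <- replicate(100, {
    fb <- cs / (cs + 5) * (1 + rnorm(length(cs), 0, 0.05))
    fit_isotherm(cs, pmin(pmax(fb, 0), 1))$c_crit
  })
  expect_lt(abs(stats::median(est) - 5) / 5, 0.10)
})

test_that("equilibrium occupancies follow a binding isotherm with the calibrated midpoint", {
  p <- tbl1()
  cs <- c(0.2, 0.5, 1, 2, 3, 5, 8, 12, 20, 50)
  fb <- vapply(cs, function(cc) {
    th <- occupancies(steady_state(cc, p))
    th[["theta_b"]] / (th[["theta_b"]] + th[["theta_w"]])
  }, numeric(1))
  iso <- fit_isotherm(cs, fb)
  expect_equal(iso$c_crit, 3.4, tolerance = 0.5)
})

test_that("step detection recovers staircase step sizes and ignores flat noise", {
  s2 <- staircase(2)
  st2 <- detect_steps(s2$time, s2$value)
  expect_gt(nrow(st2), 5)
  expect_equal(step_size_mode(st2$size), 2, tolerance = 0.15)
  s5 <- staircase(5)
  st5 <- detect_steps(s5$time, s5$value)
  expect_equal(step_size_mode(st5$size), 5, tolerance = 0.3)
  set.seed(1)
  flat <- data.frame(time = seq(0.1, 80, by = 0.1),
                     value = rnorm(800, 0, 0.4))
  expect_equal(nrow(detect_steps(flat$time, flat$value)), 0)
  expect_true(is.na(step_size_mode(numeric(0))))
})

test_that("rate-curve fitting recovers the bimolecular on-rate from a noisy series", {
  pp <- prose()
  ser <- cached("series_prose", {
    generate_concentration_series(pp, noise = noise_model(seed = 101))
  })
  rc <- fit_rate_curve(ser)
  # footprint-normalised bimolecular estimate (one arrival converts an
  # n_w-nt footprint, so the extension-rate slope is n_w * k_b)
  expect_equal(rc$k_b, pp$k_b, tolerance = 0.15)
  # rinse-phase rate is the stimulated-dissociation-limited constant
  expect_equal(rc$unbind_wrap_rate, 0.11, tolerance = 0.10)
  # bind-wrap rates rise with concentration
  agg <- stats::aggregate(rate ~ conc_nM,
                          rc$rates[rc$rates$label == "bind-wrap" &
                                     rc$rates$segment == 1, ],
                          stats::median)
  expect_true(all(diff(agg$rate[order(agg$conc_nM)]) > 0))
})
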