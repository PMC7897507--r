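test_that("effective rates reduce to intrinsic values without neighbours and grow linearly", {
  p <- tbl1()
  expect_equal(unname(effective_rates(p, 0)), c(0.0171, 0))
  expect_equal(unname(effective_rates(p, 1)), c(0.0171 + 0.113, 0.095))
  # any set: theta_b = 0 leaves intrinsic rates unchanged
  p2 <- parameter_set(k_b = 1, k_off = 0.3, k_w = 2, k_unw = 0.05,
                      k_off_stim = 1, k_unw_stim = 1)
  expect_equal(unname(effective_rates(p2, 0)), c(0.3, 0.05))
  # monotone non-decreasing in theta_b
  th <- seq(0, 1, by = 0.1)
  eff <- t(vapply(th, function(x) effective_rates(p, x), numeric(2)))
  expect_true(all(diff(eff[, 1]) >= 0))
  expect_true(all(diff(eff[, 2]) >= 0))
  expect_error(effective_rates(p, -0.1), "0, 1")
  expect_error(effective_rates(p, 1.5), "0, 1")
})

test_that("stimulation requires an accessible wrapped state", {
  p20 <- at_force(tbl1(), 20)
  expect_false(wrapping_active(p20))
  expect_equal(unname(effective_rates(p20, 0.9)), c(0.0171, 0))
  expect_equal(unname(effective_rates(h55y_params(), 0.9))[1], 0.0171)
})

test_that("rhs reproduces the bimolecular binding flux on bare ssDNA", {
  p <- tbl1()
  d <- rhs(state_vector(0, 0, p), 1, p)
  expect_equal(unname(d), c(0.150, 0))
  expect_equal(unname(rhs(state_vector(0, 0, p), 0, p)), c(0, 0))
  # steady state returned by equilibrate has vanishing derivatives
  st <- equilibrate(3.4, p)
  expect_lt(max(abs(rhs(st, 3.4, p))), 1e-8)
  expect_error(rhs(state_vector(0, 0, p), -1, p), ">= 0")
})

test_that("equilibrium occupancies behave across the concentration range", {
  p <- tbl1()
  # bound and wrapped states nearly equal at the critical concentration
  th <- occupancies(equilibrate(3.4, p))
  expect_lt(abs(th[["theta_b"]] - th[["theta_w"]]) /
              mean(c(th[["theta_b"]], th[["theta_w"]])), 0.05)
  # low concentration: wrapped dominates, compaction approaches x_w
  st <- equilibrate(0.05, p)
  th_lo <- occupancies(st)
  expect_gt(th_lo[["theta_w"]], 10 * th_lo[["theta_b"]])
  expect_equal(extension_change(st, p), p$x_w, tolerance = 0.02)
  # conservation is exact by construction
  for (cc in c(0.05, 3.4, 50)) {
    th_c <- occupancies(equilibrate(cc, p))
    expect_equal(sum(th_c), 1, tolerance = 1e-12)
  }
})

test_that("equilibrate is independent of the starting state", {
  p <- tbl1()
  for (cc in c(1, 3.4, 10)) {
    a <- equilibrate(cc, p)
    b <- equilibrate(cc, p, init = state_vector(0.005, 0.9 / p$n_w, p))
    expect_equal(occupancies(a), occupancies(b), tolerance = 1e-6)
  }
})

test_that("algebraic steady state agrees with ODE integration", {
  p <- tbl1()
  for (cc in c(0.5, 2, 3.4, 10, 50)) {
    expect_equal(occupancies(steady_state(cc, p)),
                 occupancies(equilibrate(cc, p)), tolerance = 1e-4)
  }
})

test_that("equilibrium theta_b rises and theta_w falls with concentration", {
  p <- tbl1()
  cs <- c(0.05, 0.2, 0.5, 1, 2, 5, 10, 20, 50, 100)
  th <- t(vapply(cs, function(cc) occupancies(steady_state(cc, p)),
                 numeric(3)))
  expect_true(all(diff(th[, "theta_b"]) > -1e-9))
  expect_true(all(diff(th[, "theta_w"]) < 1e-9))
})

test_that("critical concentration matches the calibrated simulation value and shifts correctly", {
  p <- tbl1()
  cc <- critical_concentration(p)
  expect_equal(cc, 3.4, tolerance = 0.3)
  # doubling the on-rate makes saturation (and the crossing) earlier
  expect_lt(critical_concentration(modify_params(p, k_b = 0.3)), cc)
  # ablating stimulation stabilises wrapping: crossing moves up
  # (a non-zero intrinsic unwrapping rate is needed for any crossing)
  p_ref <- modify_params(p, k_unw = 0.01)
  p_abl <- modify_params(p_ref, k_off_stim = 0, k_unw_stim = 0)
  expect_gt(critical_concentration(p_abl), critical_concentration(p_ref))
  # error contracts
  expect_error(critical_concentration(h55y_params()), "wrapping")
  expect_error(critical_concentration(p, interval = c(100, 1000)),
               class = "ssb_root_error")
})

test_that("extension change sums per-state compactions", {
  p <- tbl1()
  expect_equal(extension_change(state_vector(0, 1 / p$n_w, p), p), 0.083)
  expect_equal(extension_change(state_vector(1 / p$n_b, 0, p), p), 0.0159)
  expect_equal(extension_change(state_vector(0, 0, p), p), 0)
})

test_that("analytic helpers reproduce their closed forms", {
  expect_equal(per_nt_compaction(2, 17), 2 / 17)
  expect_equal(round(per_nt_compaction(2, 17), 1), 0.1)
  expect_equal(round(per_nt_compaction(5, 35), 2), 0.14)
  expect_equal(per_nt_compaction(0, 33), 0)
  expect_error(per_nt_compaction(2, 0), "> 0")

  expect_equal(round(dissociation_Kd(0.017, 0.18), 1), 0.1)
  expect_equal(dissociation_Kd(0, 5), 0)
  expect_equal(dissociation_Kd(0.3, 2), dissociation_Kd(3, 20))

  expect_equal(diffusion_length(300, 10), sqrt(3000))
  expect_equal(round(diffusion_length(300, 10)), 55)
  expect_equal(diffusion_length(0, 7), 0)
  expect_equal(diffusion_length(300, 40), 2 * diffusion_length(300, 10))
})

test_that("occupancies stay within [0,1] and conserved along trajectories", {
  p <- tbl1()
  for (cc in c(0.1, 3.4, 50)) {
    tr <- simulate_protocol(incubation_protocol(cc, t_rinse = 100), p)
    expect_true(all(tr$theta_b >= -1e-9 & tr$theta_b <= 1 + 1e-9))
    expect_true(all(tr$theta_w >= -1e-9 & tr$theta_w <= 1 + 1e-9))
    expect_true(all(tr$theta_b + tr$theta_w <= 1 + 1e-9))
  }
})

test_that("parameter and state validation rejects invalid inputs", {
  expect_error(parameter_set(k_b = 0, k_off = 1, k_w = 1), "k_b")
  expect_error(parameter_set(k_b = 1, k_off = -1, k_w = 1), "rates")
  expect_error(parameter_set(k_b = 1, k_off = 1, k_w = 1, n_b = 20, n_w = 17),
               "footprints")
  expect_error(parameter_set(k_b = 1, k_off = 1, k_w = 1, x_b = 0.1,
                             x_w = 0.05), "compactions")
  p <- tbl1()
  expect_error(state_vector(-0.1, 0, p), ">= 0")
  expect_error(state_vector(0.2, 0, p), "\\[0, 1\\]")
})
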