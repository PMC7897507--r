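test_that("protocol construction validates segments and forces", {
  expect_error(protocol(c(10, -5), c(1, 0)), "durations")
  expect_error(protocol(10, -1), "concentrations")
  expect_error(protocol(10, 1, forces = 9.5), "force regime")
  pr <- incubation_protocol(50, t_reincubate = 200)
  expect_s3_class(pr, "ssb_protocol")
  expect_equal(nrow(pr), 3)
  expect_equal(pr$conc_nM, c(50, 0, 50))
})

test_that("incubation at saturating concentration equilibrates at reduced compaction", {
  tr <- trace50()
  p <- tbl1()
  inc <- tr[tr$time_s <= 300, ]
  # monotone compaction rise to the oversaturated equilibrium (~0.02 nm/nt),
  # far below the fully wrapped value x_w
  expect_equal(tail(inc$compaction_nm_per_nt, 1), 0.0197, tolerance = 0.01)
  expect_lt(tail(inc$compaction_nm_per_nt, 1), 0.3 * p$x_w)
  expect_gt(tail(inc$theta_b, 1), 0.9)
})

test_that("rinse drives the complex to the maximally wrapped plateau", {
  tr <- trace50()
  p <- tbl1()
  plateau <- tail(tr$compaction_nm_per_nt[tr$time_s <= 600], 1)
  expect_equal(plateau, p$x_w, tolerance = 0.005)
  # plateau is independent of the incubation concentration for c >= 1 nM
  plats <- vapply(c(1, 5, 10), function(cc) {
    tail(simulate_protocol(incubation_protocol(cc), p)$compaction_nm_per_nt, 1)
  }, numeric(1))
  expect_lt((max(plats) - min(plats)) / mean(plats), 0.02)
  expect_lt(abs(mean(plats) - plateau) / plateau, 0.02)
})

test_that("low-concentration binding is single phase and insensitive to rinsing", {
  tr <- trace01()
  inc_end <- tail(tr$compaction_nm_per_nt[tr$time_s <= 300], 1)
  rinse_end <- tail(tr$compaction_nm_per_nt[tr$time_s <= 600], 1)
  expect_lt(abs(rinse_end - inc_end), 0.005)
  ph <- segment_phases(tr)
  expect_equal(ph$label[1], "bind-wrap")
  expect_false("bind-unwrap" %in% ph$label)
  expect_false("unbind-wrap" %in% ph$label)
})

test_that("re-incubation restores the previous equilibrium", {
  tr <- trace50()
  eq1 <- tail(tr$compaction_nm_per_nt[tr$time_s <= 300], 1)
  eq2 <- tail(tr$compaction_nm_per_nt, 1)
  expect_lt(abs(eq2 - eq1) / eq1, 0.01)
})

test_that("concentration cycling returns to identical equilibria each cycle", {
  p <- tbl1()
  prot <- protocol(rep(c(300, 300), 3), rep(c(5, 0), 3), 12)
  tr <- simulate_protocol(prot, p)
  ends <- vapply(1:3, function(k) {
    tr$compaction_nm_per_nt[which.min(abs(tr$time_s - (600 * k - 300)))]
  }, numeric(1))
  expect_lt(diff(range(ends)) / mean(ends), 0.001)
  plateaus <- vapply(1:3, function(k) {
    tr$compaction_nm_per_nt[which.min(abs(tr$time_s - 600 * k))]
  }, numeric(1))
  expect_lt(diff(range(plateaus)) / mean(plateaus), 0.001)
})

test_that("wrap-disabled regimes give single-exponential binding and slow release", {
  p <- tbl1()
  # H55Y at the tetramer-equivalent of 5 nM monomer
  trh <- simulate_protocol(
    incubation_protocol(monomer_equivalent_concentration(5),
                        t_incubate = 200, t_rinse = 400), h55y_params())
  ph <- segment_phases(trh)
  expect_setequal(ph$label, c("bind-wrap", "direct-dissociation"))
  rise <- fit_exponential(trh, ph[ph$label == "bind-wrap", ])
  decay <- fit_exponential(trh, ph[ph$label == "direct-dissociation", ])
  # rise at the bimolecular filling rate, plateau near x_b, decay at k_off
  expect_equal(rise$rate, p$n_b * p$k_b * 1.25 + p$k_off, tolerance = 1e-3)
  # plateau is x_b * Theta_b,eq with Theta_b,eq = 0.989 at this concentration
  expect_equal(max(trh$compaction_nm_per_nt), p$x_b, tolerance = 0.02)
  expect_equal(decay$rate, p$k_off, tolerance = 1e-3)
  # same shape for wild type at 20 pN
  tr20 <- simulate_protocol(protocol(c(60, 400), c(50, 0), 20), p)
  ph20 <- segment_phases(tr20)
  expect_setequal(ph20$label, c("bind-wrap", "direct-dissociation"))
  d20 <- fit_exponential(tr20, ph20[ph20$label == "direct-dissociation", ])
  expect_equal(d20$rate, p$k_off, tolerance = 1e-3)
})

test_that("force-jump survival follows the slow intrinsic dissociation", {
  p <- tbl1()
  expect_equal(force_jump_survival(p, 60, 10), exp(-0.171))
  expect_equal(round(force_jump_survival(p, 60, 10), 3), 0.843)
  expect_equal(force_jump_survival(p, 60, 0), 1)
  tt <- c(1, 5, 10, 50)
  expect_true(all(diff(force_jump_survival(p, 60, tt)) < 0))
  expect_error(force_jump_survival(p, 7, 10), "wrapping-enabled")
})

test_that("a force jump and return lets survivors rewrap", {
  p <- tbl1()
  prot <- protocol(c(300, 120, 10, 200), c(50, 0, 0, 0), c(12, 12, 60, 12))
  tr <- simulate_protocol(prot, p)
  before <- tr$compaction_nm_per_nt[which.min(abs(tr$time_s - 420))]
  after <- tail(tr$compaction_nm_per_nt, 1)
  # slightly below the pure-survival bound: stimulated dissociation removes
  # a little more protein while the survivors rewrap after the return
  expect_equal(after / before, force_jump_survival(p, 60, 10),
               tolerance = 0.04)
  # during the hold, only the small bound-state compaction remains
  hold <- tr$compaction_nm_per_nt[tr$time_s > 421 & tr$time_s < 429]
  expect_lt(max(hold), 0.02)
})

test_that("monomer-tetramer conversion is linear", {
  expect_equal(monomer_equivalent_concentration(5), 1.25)
  expect_equal(monomer_equivalent_concentration(0), 0)
  expect_equal(monomer_equivalent_concentration(c(2, 4, 8)),
               c(0.5, 1, 2))
  expect_error(monomer_equivalent_concentration(-1), ">= 0")
})
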