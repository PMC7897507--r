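# Shared fixtures, computed lazily and cached for the whole run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

tbl1 <- function() table1_params()
prose <- function() prose_params()

# ideal 50 nM incubate/rinse/re-incubate trace at 12 pN, Table 1 kinetics
trace50 <- function() cached("trace50", {
  simulate_protocol(incubation_protocol(50, t_reincubate = 200), tbl1())
})

# ideal 0.1 nM incubate/rinse trace
trace01 <- function() cached("trace01", {
  simulate_protocol(incubation_protocol(0.1, t_reincubate = 200), tbl1())
})

# deterministic ODE reference trajectory on the lattice sampling grid
ode_occupancy <- function(conc, times, params = tbl1()) {
  f <- function(t, y, par) list(ssbkinetics:::rhs_raw(y[1], y[2], conc, params))
  out <- deSolve::ode(c(0, 0), times, f, NULL, rtol = 1e-8, atol = 1e-10)
  data.frame(time = out[, 1],
             theta_b = params$n_b * out[, 2],
             theta_w = params$n_w * out[, 3])
}

# synthetic noisy staircase in total nm, for the step detector
staircase <- function(step_nm, n_steps = 12, dwell = 80, sigma = 0.4,
                      seed = 42) {
  set.seed(seed)
  lv <- rep(seq(0, by = step_nm, length.out = n_steps), each = dwell)
  data.frame(time = seq_along(lv) / 10, value = lv + rnorm(length(lv), 0, sigma))
}
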