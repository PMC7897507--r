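#' Effective dissociation and unwrapping rates under neighbour stimulation
#'
#' In an oversaturated complex, ssDNA released by one protein is immediately
#' claimed by the OB-fold domain of a neighbouring tetramer as it wraps,
#' lowering the free-energy barrier for both dissociation and unwrapping.
#' The effective rates therefore grow with the bound-unwrapped occupancy:
#' k_off_eff = k_off + k_off_stim * Theta_b and
#' k_unw_eff = k_unw + k_unw_stim * Theta_b.
#' Because the enhancement is mediated by a wrapping-capable neighbour, it
#' is only active when the wrapped state is accessible
#' ([wrapping_active()]); otherwise the intrinsic rates are returned.
#'
#' @param params an `ssb_params` object.
#' @param theta_b bound-unwrapped occupancy fraction, in \[0, 1\].
#' @return Named numeric vector `c(k_off_eff =, k_unw_eff =)` in s^-1; both
#'   monotone non-decreasing in `theta_b`.
#' @export
effective_rates <- function(params, theta_b) {
  if (!is.numeric(theta_b) || any(!is.finite(theta_b)) ||
      any(theta_b < 0 | theta_b > 1))
    stop("theta_b must lie in [0, 1]", call. = FALSE)
  if (wrapping_active(params)) {
    c(k_off_eff = params$k_off + params$k_off_stim * theta_b,
      k_unw_eff = params$k_unw + params$k_unw_stim * theta_b)
  } else {
    c(k_off_eff = params$k_off + 0 * theta_b,
      k_unw_eff = params$k_unw + 0 * theta_b)
  }
}

## Internal right-hand side on raw (beta, omega) vectors. Tolerates the tiny
## negative excursions an adaptive integrator may probe (clamped at 0), which
## the exported rhs() rejects as a domain error.
rhs_raw <- function(beta, omega, conc, params) {
  beta <- max(beta, 0); omega <- max(omega, 0)
  theta_b <- params$n_b * beta
  theta_w <- params$n_w * omega
  theta_0 <- max(1 - theta_b - theta_w, 0)
  eff <- effective_rates(params, min(theta_b, 1))
  wrap_on <- wrapping_active(params)
  phi <- if (!wrap_on) 0
  else if (params$availability == "linear") theta_0
  else if (beta <= 0) 1
  else min(1, theta_0 / ((params$n_w - params$n_b) * beta))
  wrap <- if (wrap_on) params$k_w * phi * beta else 0
  unwrap <- eff[["k_unw_eff"]] * omega
  dbeta <- params$k_b * conc * theta_0 - eff[["k_off_eff"]] * beta -
    wrap + unwrap
  domega <- wrap - unwrap
  c(dbeta, domega)
}

#' Time derivatives of the mean-field two-step model
#'
#' The model tracks protein densities per nucleotide. Free protein binds any
#' free nucleotide as a nucleation point (flux k_b * c * Theta_0 in
#' proteins nt^-1 s^-1); bound protein dissociates at the effective
#' (possibly stimulated) rate; wrapping one protein consumes the additional
#' n_w - n_b nucleotides, so the wrapping rate carries an availability
#' factor phi = min(1, Theta_0 / ((n_w - n_b) beta)) rationing free ssDNA
#' among wrap candidates (phi = 1 when beta = 0; `availability = "linear"`
#' substitutes phi = Theta_0); wrapped protein unwraps at the effective
#' stimulated rate. With wrapping disabled the wrap and unwrap terms vanish
#' and the scheme reduces to bind/unbind.
#'
#' @param state an `ssb_state` object.
#' @param conc free protein concentration (nM).
#' @param params an `ssb_params` object.
#' @return Named numeric vector `c(dbeta_dt =, domega_dt =)` in
#'   proteins nt^-1 s^-1.
#' @export
rhs <- function(state, conc, params) {
  if (!inherits(state, "ssb_state"))
    stop("state must be an ssb_state", call. = FALSE)
  if (state$beta < 0 || state$omega < 0)
    stop("negative densities are outside the model domain", call. = FALSE)
  if (!is.finite(conc) || conc < 0)
    stop("concentration must be >= 0", call. = FALSE)
  d <- rhs_raw(state$beta, state$omega, conc, params)
  c(dbeta_dt = d[1], domega_dt = d[2])
}

ode_func <- function(t, y, parms) {
  list(rhs_raw(y[1], y[2], parms$conc, parms$params))
}

integrate_model <- function(beta0, omega0, conc, params, times,
                            rtol = 1e-8, atol = 1e-10) {
  out <- deSolve::ode(c(beta = beta0, omega = omega0), times, ode_func,
                      list(conc = conc, params = params),
                      rtol = rtol, atol = atol, method = "lsoda")
  out
}

#' Equilibrium state at fixed free protein concentration
#'
#' Integrates the model to steady state. Convergence is declared when both
#' derivatives fall below `tol` (in proteins nt^-1 s^-1, relative to the
#' density scale); a convergence error carrying the residual is raised if
#' the iteration budget `t_max` is exhausted first. The fixed point is
#' independent of the starting state; at c = 0 with wrapping enabled the
#' wrapped fraction rises to its packing-limited maximum while beta drains
#' to zero.
#'
#' @param conc free protein concentration (nM).
#' @param params an `ssb_params` object.
#' @param init optional `ssb_state` starting point (default empty lattice).
#' @param t_max integration budget (s).
#' @param tol steady-state residual tolerance (proteins nt^-1 s^-1).
#' @return An `ssb_state` with attributes `residual` and `time`.
#' @export
equilibrate <- function(conc, params, init = NULL, t_max = 2e4, tol = 1e-9) {
  if (!is.finite(conc) || conc < 0)
    stop("concentration must be >= 0", call. = FALSE)
  y <- if (is.null(init)) c(0, 0) else c(init$beta, init$omega)
  t_done <- 0
  chunk <- 200
  repeat {
    out <- integrate_model(y[1], y[2], conc, params,
                           times = c(0, chunk / 2, chunk),
                           rtol = 1e-10, atol = 1e-12)
    y <- pmax(as.numeric(out[nrow(out), 2:3]), 0)
    t_done <- t_done + chunk
    res <- max(abs(rhs_raw(y[1], y[2], conc, params)))
    if (res < tol) break
    if (t_done >= t_max) {
      cond <- structure(class = c("ssb_convergence_error", "error", "condition"),
                        list(message = sprintf(
                          "equilibrate(c = %g) did not reach steady state within %g s (residual %.3g)",
                          conc, t_max, res), call = sys.call(-1),
                          residual = res))
      stop(cond)
    }
    chunk <- min(chunk * 2, t_max - t_done + chunk)
  }
  ## guard against sub-tolerance overshoot of the packing boundary
  if (params$n_b * y[1] + params$n_w * y[2] > 1)
    y[2] <- (1 - params$n_b * y[1]) / params$n_w
  st <- state_vector(y[1], y[2], params)
  attr(st, "residual") <- max(abs(rhs_raw(y[1], y[2], conc, params)))
  attr(st, "time") <- t_done
  st
}

#' Algebraic steady state from the nullclines
#'
#' Solves the steady-state conditions by one-dimensional root finding in
#' beta (the bind/unbind balance expresses Theta_0 through beta; the
#' wrap/unwrap balance residual is then bracketed and solved). When no
#' interior balance exists (low concentration, wrapping enabled) the
#' packing-limited boundary state is returned. Used by
#' [critical_concentration()] for speed; cross-checked against
#' [equilibrate()] in the test suite.
#'
#' @inheritParams equilibrate
#' @return An `ssb_state`.
#' @export
steady_state <- function(conc, params) {
  if (!is.finite(conc) || conc < 0)
    stop("concentration must be >= 0", call. = FALSE)
  if (!wrapping_active(params)) {
    ## bind/unbind only: k_b c (1 - n_b beta) = k_off beta
    beta <- params$k_b * conc /
      (params$k_b * conc * params$n_b + params$k_off)
    return(state_vector(beta, 0, params))
  }
  if (conc == 0) return(state_vector(0, 1 / params$n_w, params))
  ## residual of d(omega)/dt with omega eliminated via the beta-balance
  resid <- function(beta) {
    theta_b <- params$n_b * beta
    eff <- effective_rates(params, min(theta_b, 1))
    theta_0 <- eff[["k_off_eff"]] * beta / (params$k_b * conc)
    theta_w <- 1 - theta_b - theta_0
    if (theta_w < 0) return(NA_real_)
    omega <- theta_w / params$n_w
    phi <- if (params$availability == "linear") theta_0
    else if (beta <= 0) 1
    else min(1, theta_0 / ((params$n_w - params$n_b) * beta))
    params$k_w * phi * beta - eff[["k_unw_eff"]] * omega
  }
  beta_hi <- uniroot(function(b) {
    eff <- effective_rates(params, min(params$n_b * b, 1))
    1 - params$n_b * b - eff[["k_off_eff"]] * b / (params$k_b * conc)
  }, c(0, 1 / params$n_b), tol = 1e-14)$root
  grid <- beta_hi * seq(1e-8, 1 - 1e-8, length.out = 400)
  vals <- vapply(grid, resid, numeric(1))
  ok <- which(is.finite(vals))
  sgn <- sign(vals[ok])
  flip <- which(diff(sgn) != 0)
  if (length(flip) == 0) {
    ## no interior balance: wrap flux exceeds unwrap flux throughout, the
    ## system runs to the packing boundary (theta_w -> 1, beta -> 0)
    if (all(sgn > 0)) return(state_vector(0, 1 / params$n_w, params))
    return(state_vector(beta_hi, 0, params))
  }
  i <- ok[flip[length(flip)]]
  beta <- uniroot(resid, c(grid[i], grid[i + 1]), tol = 1e-14)$root
  eff <- effective_rates(params, min(params$n_b * beta, 1))
  theta_0 <- eff[["k_off_eff"]] * beta / (params$k_b * conc)
  omega <- (1 - params$n_b * beta - theta_0) / params$n_w
  state_vector(beta, max(omega, 0), params)
}

#' Critical concentration at which bound and wrapped states are equal
#'
#' Finds the free protein concentration where the equilibrium
#' bound-unwrapped and wrapped occupancies cross (Theta_b = Theta_w).
#' Theta_b(c) increases and Theta_w(c) decreases across the root, so the
#' root is unique on the bracket.
#'
#' @param params an `ssb_params` object with wrapping enabled.
#' @param interval concentration bracket (nM).
#' @param tol root tolerance (nM).
#' @param method `"algebraic"` (default, uses [steady_state()]) or `"ode"`
#'   (uses [equilibrate()]).
#' @return Critical concentration in nM.
#' @export
critical_concentration <- function(params, interval = c(0.01, 1000),
                                   tol = 1e-3, method = c("algebraic", "ode")) {
  method <- match.arg(method)
  if (!wrapping_active(params))
    stop("critical concentration requires wrapping to be enabled",
         call. = FALSE)
  gap <- function(conc) {
    st <- if (method == "algebraic") steady_state(conc, params)
    else equilibrate(conc, params)
    th <- occupancies(st)
    th[["theta_b"]] - th[["theta_w"]]
  }
  g_lo <- gap(interval[1]); g_hi <- gap(interval[2])
  if (is.na(g_lo) || is.na(g_hi) || g_lo * g_hi > 0) {
    cond <- structure(class = c("ssb_root_error", "error", "condition"),
                      list(message = sprintf(
                        "Theta_b - Theta_w does not change sign on [%g, %g] nM",
                        interval[1], interval[2]), call = sys.call(-1)))
    stop(cond)
  }
  uniroot(gap, interval, tol = tol)$root
}

#' Net compaction of a state
#'
#' Summing all bound protein over the substrate gives the normalised
#' extension change in nm per nucleotide (positive = shortening):
#' Delta X = x_b * Theta_b + x_w * Theta_w.
#'
#' @param state an `ssb_state` object.
#' @param params an `ssb_params` object.
#' @return Compaction in nm/nt.
#' @export
extension_change <- function(state, params) {
  th <- occupancies(state)
  params$x_b * th[["theta_b"]] + params$x_w * th[["theta_w"]]
}

#' Per-nucleotide compaction of one wrapped protein
#'
#' @param dx_per_protein compaction caused by one protein (nm).
#' @param footprint nucleotides occluded by that protein (nt).
#' @return nm/nt.
#' @export
per_nt_compaction <- function(dx_per_protein, footprint) {
  if (any(footprint <= 0)) stop("footprint must be > 0", call. = FALSE)
  dx_per_protein / footprint
}

#' Equilibrium dissociation constant from rates
#'
#' @param k_off dissociation rate (s^-1).
#' @param k_on bimolecular on-rate (nM^-1 s^-1).
#' @return K_d in nM.
#' @export
dissociation_Kd <- function(k_off, k_on) {
  if (any(k_on <= 0)) stop("k_on must be > 0", call. = FALSE)
  k_off / k_on
}

#' One-dimensional diffusion length
#'
#' Distance a protein diffusing along ssDNA covers in time t,
#' L = sqrt(D * t); with D = 300 nt^2/s and t = 10 s this is about 55 nt,
#' the neighbourhood within which bound tetramers can interact during one
#' stimulated-dissociation lifetime.
#'
#' @param D diffusion coefficient (nt^2/s).
#' @param t time (s).
#' @return Length in nt.
#' @export
diffusion_length <- function(D, t) {
  if (any(D < 0) || any(t < 0)) stop("D and t must be >= 0", call. = FALSE)
  sqrt(D * t)
}
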