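#' Piecewise-constant experiment protocol
#'
#' Describes a constant-force flow experiment as an ordered list of segments,
#' each holding a fixed free protein concentration and template tension for a
#' fixed duration. Solution exchange at segment boundaries is treated as
#' instantaneous (complete exchange in the flow cell takes about 1 s, far
#' below the phase timescales); a linear mixing ramp of `mixing_s` seconds
#' can be enabled for sensitivity checks.
#'
#' @param durations segment durations (s), all > 0.
#' @param concentrations free SSB concentrations per segment (nM), >= 0.
#' @param forces template tension per segment (pN); must appear in the
#'   force-regime table. Scalar forces are recycled.
#' @param sampling_rate trace sampling rate (Hz).
#' @param mixing_s duration of the optional linear concentration ramp at
#'   each boundary (0 = instantaneous exchange).
#' @param label free-text label.
#' @return An object of class `ssb_protocol` (a data.frame of segments with
#'   attributes `sampling_rate`, `mixing_s`, `label`).
#' @export
protocol <- function(durations, concentrations, forces = 12,
                     sampling_rate = 10, mixing_s = 0, label = "protocol") {
  n <- length(durations)
  forces <- rep_len(forces, n)
  if (length(concentrations) != n)
    stop("durations and concentrations must have equal length", call. = FALSE)
  if (any(durations <= 0)) stop("durations must be > 0", call. = FALSE)
  if (any(concentrations < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  if (sampling_rate <= 0) stop("sampling_rate must be > 0", call. = FALSE)
  for (f in unique(forces)) force_regime(f)  # errors on unknown force
  structure(
    data.frame(duration_s = durations, conc_nM = concentrations,
               force_pN = forces),
    sampling_rate = sampling_rate, mixing_s = mixing_s, label = label,
    class = c("ssb_protocol", "data.frame"))
}

#' Standard incubate / rinse / re-incubate protocol
#'
#' The workhorse design: expose bare ssDNA to a fixed SSB concentration,
#' rinse with protein-free buffer, then re-introduce the same concentration.
#'
#' @param conc incubation concentration (nM).
#' @param force tension (pN).
#' @param t_incubate,t_rinse,t_reincubate segment durations (s);
#'   `t_reincubate = 0` drops the third segment.
#' @param sampling_rate Hz.
#' @return An `ssb_protocol`.
#' @export
incubation_protocol <- function(conc, force = 12, t_incubate = 300,
                                t_rinse = 300, t_reincubate = 0,
                                sampling_rate = 10) {
  durs <- c(t_incubate, t_rinse)
  concs <- c(conc, 0)
  if (t_reincubate > 0) {
    durs <- c(durs, t_reincubate)
    concs <- c(concs, conc)
  }
  protocol(durs, concs, force, sampling_rate,
           label = sprintf("incubate_%gnM_%gpN", conc, force))
}

segment_bounds <- function(prot) {
  ends <- cumsum(prot$duration_s)
  cbind(start = c(0, ends[-length(ends)]), end = ends)
}

make_trace <- function(time, compaction, theta_b, theta_w, protocol, params,
                       noise = NULL, seed = NULL) {
  structure(
    data.frame(time_s = time, compaction_nm_per_nt = compaction,
               theta_b = theta_b, theta_w = theta_w),
    protocol = protocol, params = params, noise = noise, seed = seed,
    ideal = is.null(noise),
    class = c("ssb_trace", "data.frame"))
}

#' @export
print.ssb_trace <- function(x, ...) {
  cat(sprintf("<ssb_trace> %d samples over %.1f s (%s)\n", nrow(x),
              max(x$time_s), if (isTRUE(attr(x, "ideal"))) "ideal" else "noisy"))
  invisible(x)
}

## Map the carried state across a segment boundary when the force regime
## changes. Protein densities are preserved; wrapped protein entering a
## wrap-disabled regime unwraps instantly (high tension destabilises the
## wrap, the tetramer stays attached through one OB fold); excess wrapped
## density that cannot be accommodated by a larger footprint is released to
## the bound pool.
carry_state <- function(beta, omega, params_old, params_new) {
  if (!wrapping_active(params_new) && omega > 0) {
    beta <- beta + omega
    omega <- 0
  }
  if (wrapping_active(params_new) && omega > 0) {
    omega_max <- (1 - params_new$n_b * beta) / params_new$n_w
    if (omega > omega_max) {
      beta <- beta + (omega - omega_max)
      omega <- omega_max
    }
  }
  c(beta, omega)
}

#' Simulate an ideal compaction trace for a protocol
#'
#' Integrates the mean-field model through each segment, carrying the
#' protein densities across boundaries (only the concentration and the
#' force regime change there, never beta or omega) and mapping the state
#' through force-regime changes. Returns the noise-free compaction trace
#' sampled on a uniform grid.
#'
#' @param prot an `ssb_protocol`.
#' @param params an `ssb_params` object (its force field is overridden per
#'   segment through [at_force()]).
#' @param init optional starting `ssb_state` (default empty ssDNA).
#' @return An `ssb_trace` data.frame with columns `time_s`,
#'   `compaction_nm_per_nt`, `theta_b`, `theta_w`; attribute `final_state`
#'   holds the end state.
#' @export
simulate_protocol <- function(prot, params, init = NULL) {
  stopifnot(inherits(prot, "ssb_protocol"))
  rate <- attr(prot, "sampling_rate")
  mixing <- attr(prot, "mixing_s")
  bounds <- segment_bounds(prot)
  y <- if (is.null(init)) c(0, 0) else c(init$beta, init$omega)
  p_prev <- NULL
  times_all <- comp_all <- tb_all <- tw_all <- vector("list", nrow(prot))
  for (i in seq_len(nrow(prot))) {
    p_seg <- at_force(params, prot$force_pN[i])
    if (!is.null(p_prev)) y <- carry_state(y[1], y[2], p_prev, p_seg)
    dur <- prot$duration_s[i]
    t_local <- seq(0, dur, by = 1 / rate)
    if (t_local[length(t_local)] < dur) t_local <- c(t_local, dur)
    if (mixing > 0 && i > 1 && prot$conc_nM[i] != prot$conc_nM[i - 1]) {
      c_from <- prot$conc_nM[i - 1]; c_to <- prot$conc_nM[i]
      ramp <- function(t, y_, parms) {
        cc <- if (t >= mixing) c_to else c_from + (c_to - c_from) * t / mixing
        list(rhs_raw(y_[1], y_[2], cc, parms$params))
      }
      out <- deSolve::ode(c(beta = y[1], omega = y[2]), t_local, ramp,
                          list(params = p_seg), rtol = 1e-8, atol = 1e-10)
    } else {
      out <- integrate_model(y[1], y[2], prot$conc_nM[i], p_seg, t_local)
    }
    beta_t <- pmax(out[, 2], 0); omega_t <- pmax(out[, 3], 0)
    keep <- seq_len(length(t_local))
    ## drop the duplicated boundary sample (keep segment start only at t=0)
    if (i > 1) keep <- keep[-1]
    tb <- p_seg$n_b * beta_t; tw <- p_seg$n_w * omega_t
    times_all[[i]] <- bounds[i, "start"] + t_local[keep]
    comp_all[[i]] <- p_seg$x_b * tb[keep] + p_seg$x_w * tw[keep]
    tb_all[[i]] <- tb[keep]; tw_all[[i]] <- tw[keep]
    y <- c(beta_t[length(beta_t)], omega_t[length(omega_t)])
    p_prev <- p_seg
  }
  tr <- make_trace(unlist(times_all), unlist(comp_all), unlist(tb_all),
                   unlist(tw_all), prot, params)
  attr(tr, "final_state") <- state_vector(y[1], y[2], p_prev)
  tr
}

#' Surviving bound fraction after a high-force hold
#'
#' During an abrupt jump to a wrapping-disabled tension, wrapped protein
#' unwraps and the bound tetramers dissociate at the slow intrinsic rate
#' (no wrapping-capable neighbours exist to stimulate release), so the
#' fraction of the pre-jump proteins still bound after `hold_time` is
#' exp(-k_off * hold_time). On return to a low force the survivors resume
#' wrapping.
#'
#' @param params an `ssb_params` object (supplies k_off).
#' @param hold_force hold tension (pN); must be in a wrapping-disabled
#'   regime.
#' @param hold_time hold duration (s).
#' @return Surviving bound fraction in \[0, 1\].
#' @export
force_jump_survival <- function(params, hold_force, hold_time) {
  reg <- force_regime(hold_force)
  if (isTRUE(reg$wrapping_enabled))
    stop(sprintf("hold force %g pN is in a wrapping-enabled regime",
                 hold_force), call. = FALSE)
  if (any(hold_time < 0)) stop("hold_time must be >= 0", call. = FALSE)
  exp(-params$k_off * hold_time)
}

#' Convert a monomer concentration to the equivalent tetramer concentration
#'
#' Four monomers make one tetramer, so a monomer preparation at c nM
#' corresponds to c/4 nM of tetramer binding units.
#'
#' @param c_monomer monomer concentration (nM).
#' @return Tetramer-equivalent concentration (nM).
#' @export
monomer_equivalent_concentration <- function(c_monomer) {
  if (any(c_monomer < 0)) stop("concentration must be >= 0", call. = FALSE)
  c_monomer / 4
}
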