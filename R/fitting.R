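#' Segment a protocol trace into kinetic phases
#'
#' Mirrors the analysis of constant-force traces: within an incubation
#' segment the bind-wrap / bind-unwrap split is placed at the global
#' compaction maximum (robust to noise via a running-mean smoother);
#' monotone (monophasic) segments yield a single bind-wrap window and no
#' bind-unwrap window. A protein-free (rinse) segment becomes an
#' unbind-wrap phase when compaction rises (dissociation frees ssDNA that
#' remaining protein wraps) or a direct-dissociation phase when compaction
#' decays (wrapping unavailable, protein simply leaves). A re-incubation
#' segment in which compaction falls is a rebind-unwrap phase. Phases whose
#' amplitude does not exceed `min_amplitude` are dropped, so a flat trace
#' yields no phases.
#'
#' @param trace an `ssb_trace`.
#' @param prot the generating `ssb_protocol` (defaults to the trace
#'   attribute).
#' @param min_amplitude smallest |compaction change| (nm/nt) that counts as
#'   a phase. On noisy traces the effective threshold is raised to five
#'   standard errors of the smoothed level (noise estimated from first
#'   differences) so noise wiggles never register as phases.
#' @param smooth_n running-mean window (samples) used only to locate the
#'   extremum and measure amplitudes; fits always use raw data.
#' @return A data.frame with columns `segment`, `label`
#'   (bind-wrap, bind-unwrap, unbind-wrap, rebind-unwrap,
#'   direct-dissociation), `t_start`, `t_end` (s) and `amplitude` (signed
#'   compaction change, nm/nt).
#' @export
segment_phases <- function(trace, prot = attr(trace, "protocol"),
                           min_amplitude = 0.005, smooth_n = 5) {
  stopifnot(inherits(trace, "ssb_trace"))
  if (is.null(prot))
    stop("trace carries no protocol; supply one", call. = FALSE)
  if (max(trace$time_s) < sum(prot$duration_s) - 1)
    stop("trace and protocol do not match", call. = FALSE)
  bounds <- segment_bounds(prot)
  y <- trace$compaction_nm_per_nt
  sm <- if (smooth_n > 1) {
    as.numeric(stats::filter(y, rep(1 / smooth_n, smooth_n), sides = 2))
  } else y
  sm[is.na(sm)] <- y[is.na(sm)]
  sigma <- stats::sd(diff(y)) / sqrt(2)
  thr <- max(min_amplitude, 5 * sigma / sqrt(max(smooth_n, 1)))
  out <- list()
  add <- function(segment, label, i0, i1) {
    amp_sm <- sm[i1] - sm[i0]
    if (abs(amp_sm) >= thr) {
      out[[length(out) + 1L]] <<- data.frame(
        segment = segment, label = label,
        t_start = trace$time_s[i0], t_end = trace$time_s[i1],
        amplitude = amp_sm)
    }
  }
  for (i in seq_len(nrow(prot))) {
    in_seg <- which(trace$time_s >= bounds[i, "start"] &
                      trace$time_s <= bounds[i, "end"])
    if (length(in_seg) < 3) next
    i0 <- in_seg[1]; i1 <- in_seg[length(in_seg)]
    conc <- prot$conc_nM[i]
    start_level <- sm[i0]; end_level <- sm[i1]
    if (conc > 0 && end_level >= start_level - thr / 2) {
      ## incubation from a less-compacted state: bind-wrap, possibly
      ## followed by bind-unwrap after the global maximum
      imax <- in_seg[which.max(sm[in_seg])]
      add(i, "bind-wrap", i0, imax)
      if (imax < i1) add(i, "bind-unwrap", imax, i1)
    } else if (conc > 0) {
      ## re-incubation of a wrapped complex: compaction falls
      add(i, "rebind-unwrap", i0, i1)
    } else {
      if (end_level > start_level) add(i, "unbind-wrap", i0, i1)
      else add(i, "direct-dissociation", i0, i1)
    }
  }
  if (length(out) == 0) {
    return(data.frame(segment = integer(0), label = character(0),
                      t_start = numeric(0), t_end = numeric(0),
                      amplitude = numeric(0)))
  }
  do.call(rbind, out)
}

#' Fit a single-rate exponential to a trace window
#'
#' Least-squares fit of y(t) = A exp(-k (t - t0)) + B (optionally plus a
#' linear drift term m (t - t0), mirroring the instrumental drift
#' correction applied before rate analysis). Initialisation: k0 from the
#' time to reach 63 per cent of the window amplitude, A and B from the
#' window endpoints; k is bounded to \[1e-4, 100\] s^-1. Exact (to 1e-6
#' relative) on noiseless exponentials.
#'
#' @param trace an `ssb_trace` (or any data.frame with `time_s` and a value
#'   column).
#' @param window numeric length-2 `c(t_start, t_end)` in seconds, or a
#'   one-row slice of [segment_phases()] output.
#' @param value name of the fitted column.
#' @param drift include a linear drift term.
#' @param label optional phase label stored on the result.
#' @return An object of class `ssb_phase_fit`: list with `rate` (s^-1),
#'   `amplitude` (signed compaction change over the window, nm/nt),
#'   `offset`, `drift`, `window`, `label`, `residual_rms`, `n`.
#' @export
fit_exponential <- function(trace, window, value = "compaction_nm_per_nt",
                            drift = FALSE, label = NA_character_) {
  if (is.data.frame(window)) {
    if (!is.na(window$label[1]) && is.na(label)) label <- window$label[1]
    window <- c(window$t_start[1], window$t_end[1])
  }
  sel <- trace$time_s >= window[1] & trace$time_s <= window[2]
  tt <- trace$time_s[sel]; yy <- trace[[value]][sel]
  if (length(tt) < 10)
    stop("fit window must contain at least 10 samples", call. = FALSE)
  t0 <- tt[1]
  B0 <- mean(yy[max(1, length(yy) - 4):length(yy)])
  A0 <- mean(yy[1:min(5, length(yy))]) - B0
  amp <- abs(A0)
  i63 <- which(abs(yy - yy[1]) >= 0.63 * amp)[1]
  k0 <- if (is.na(i63) || tt[i63] <= t0) 1 else 1 / (tt[i63] - t0)
  k0 <- min(max(k0, 1e-4), 100)
  fit <- tryCatch({
    if (drift) {
      minpack.lm::nlsLM(yy ~ A * exp(-k * (tt - t0)) + B + m * (tt - t0),
                        start = list(A = A0, k = k0, B = B0, m = 0),
                        lower = c(-Inf, 1e-4, -Inf, -Inf),
                        upper = c(Inf, 100, Inf, Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(yy ~ A * exp(-k * (tt - t0)) + B,
                        start = list(A = A0, k = k0, B = B0),
                        lower = c(-Inf, 1e-4, -Inf),
                        upper = c(Inf, 100, Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e) {
    cond <- structure(class = c("ssb_fit_error", "error", "condition"),
                      list(message = paste0("exponential fit failed: ",
                                            conditionMessage(e)),
                           call = sys.call(-1), window = window))
    stop(cond)
  })
  cf <- coef(fit)
  structure(list(rate = unname(cf["k"]),
                 amplitude = yy[length(yy)] - yy[1],
                 offset = unname(cf["B"]),
                 drift = if (drift) unname(cf["m"]) else 0,
                 A = unname(cf["A"]),
                 window = window, label = label,
                 residual_rms = sqrt(mean(residuals(fit)^2)),
                 n = length(tt)),
            class = "ssb_phase_fit")
}

#' @export
print.ssb_phase_fit <- function(x, ...) {
  cat(sprintf("<ssb_phase_fit%s> rate %.4g /s, amplitude %+.4g nm/nt, window [%.1f, %.1f] s\n",
              if (is.na(x$label)) "" else paste0(" ", x$label),
              x$rate, x$amplitude, x$window[1], x$window[2]))
  invisible(x)
}

#' Serial two-step apparent binding rate
#'
#' When binding (rate c k_b) and wrapping (rate k_w) act in series, the
#' apparent single-exponential rate of the combined step is
#' k_app = c k_b k_w / (c k_b + k_w): linear with slope k_b at low
#' concentration, saturating at k_w at high concentration.
#'
#' @param conc free protein concentration (nM); vectorised.
#' @param k_b bimolecular on-rate (nM^-1 s^-1).
#' @param k_w wrapping rate (s^-1).
#' @return Apparent rate (s^-1).
#' @export
apparent_bind_rate <- function(conc, k_b, k_w) {
  if (k_b <= 0 || k_w <= 0) stop("k_b and k_w must be > 0", call. = FALSE)
  conc * k_b * k_w / (conc * k_b + k_w)
}

#' Fit phase rates across a concentration series
#'
#' For every trace in the series the incubation and rinse phases are
#' segmented and fitted with single exponentials; the bind-wrap rates are
#' then fitted with the serial two-step relation [apparent_bind_rate()]
#' (weighted by inverse replicate variance) and, nonparametrically, a
#' low-concentration slope and a high-concentration plateau are computed.
#'
#' Note on scales: in this model one nucleation event converts an n_w-nt
#' footprint, so the low-concentration slope of the *extension* apparent
#' rate is n_w * k_b exactly (see the package vignette for the derivation).
#' The returned `k_b` is therefore the model-consistent bimolecular
#' estimate slope / n_w; the raw serial-fit parameters are reported
#' alongside as `k_b_apparent` and `k_w_apparent`.
#'
#' @param series an `ssb_series` from [generate_concentration_series()].
#' @param drift include a drift term in the per-phase exponential fits.
#' @param min_amplitude passed to [segment_phases()].
#' @return An object of class `ssb_rate_curve`: list with `rates`
#'   (data.frame conc/rep/label/rate/amplitude), `k_b` (nM^-1 s^-1, the
#'   footprint-normalised bimolecular estimate), `k_b_apparent`,
#'   `k_w_apparent` (serial-fit parameters on the extension-rate scale),
#'   `k_b_slope` (nonparametric low-c slope / n_w), `unwrap_plateau`
#'   (mean bind-unwrap rate at the highest concentrations, NA when that
#'   phase is absent), `unbind_wrap_rate` (mean rinse-phase rate).
#' @export
fit_rate_curve <- function(series, drift = TRUE, min_amplitude = 0.005) {
  stopifnot(inherits(series, "ssb_series"))
  rows <- list()
  for (j in seq_along(series$traces)) {
    tr <- series$traces[[j]]
    info <- series$index[j, ]
    ph <- segment_phases(tr, min_amplitude = min_amplitude)
    for (i in seq_len(nrow(ph))) {
      f <- tryCatch(fit_exponential(tr, ph[i, ], drift = drift),
                    error = function(e) NULL)
      if (is.null(f)) next
      rows[[length(rows) + 1L]] <- data.frame(
        conc_nM = info$conc_nM, rep = info$rep, segment = ph$segment[i],
        label = ph$label[i], rate = f$rate, amplitude = f$amplitude)
    }
  }
  rates <- do.call(rbind, rows)
  n_w <- series$params$n_w
  ## the serial relation describes the first incubation of bare ssDNA
  bw <- rates[rates$label == "bind-wrap" & rates$segment == 1, ]
  agg <- stats::aggregate(rate ~ conc_nM, bw, stats::median)
  vagg <- stats::aggregate(rate ~ conc_nM, bw, stats::var)
  w <- 1 / pmax(vagg$rate, 1e-8)
  w[!is.finite(w)] <- max(w[is.finite(w)], 1)
  k_b0 <- agg$rate[1] / agg$conc_nM[1]
  k_w0 <- max(agg$rate)
  serial <- tryCatch(
    minpack.lm::nlsLM(rate ~ apparent_bind_rate(conc_nM, kb, kw),
                      data = agg,
                      start = list(kb = k_b0, kw = k_w0),
                      weights = w,
                      lower = c(1e-6, 1e-4),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  kb_app <- if (!is.null(serial)) coef(serial)[["kb"]] else NA_real_
  kw_app <- if (!is.null(serial)) coef(serial)[["kw"]] else NA_real_
  ## nonparametric: slope from the 3 lowest concentrations
  low <- utils::head(agg[order(agg$conc_nM), ], 3)
  slope <- stats::coef(stats::lm(rate ~ 0 + conc_nM, low))[[1]]
  bu <- rates[rates$label == "bind-unwrap", ]
  plateau <- if (nrow(bu) > 0) {
    hi <- bu$conc_nM >= stats::median(unique(bu$conc_nM))
    mean(bu$rate[hi])
  } else NA_real_
  ## the rinse rate is concentration independent but only well resolved
  ## for well-saturated complexes: summarise at the top concentration
  uw <- rates[rates$label == "unbind-wrap" &
                rates$conc_nM == max(rates$conc_nM), ]
  structure(list(rates = rates,
                 k_b = kb_app / n_w,
                 k_b_apparent = kb_app,
                 k_w_apparent = kw_app,
                 k_b_slope = slope / n_w,
                 unwrap_plateau = plateau,
                 unbind_wrap_rate = if (nrow(uw)) mean(uw$rate) else NA_real_,
                 n_w = n_w),
            class = "ssb_rate_curve")
}

#' @export
print.ssb_rate_curve <- function(x, ...) {
  cat(sprintf("<ssb_rate_curve> k_b %.4g /nM/s (apparent %.4g), k_w_apparent %.4g /s\n",
              x$k_b, x$k_b_apparent, x$k_w_apparent))
  cat(sprintf("  unbind-wrap rate %.4g /s, bind-unwrap plateau %s\n",
              x$unbind_wrap_rate,
              ifelse(is.na(x$unwrap_plateau), "absent",
                     sprintf("%.4g /s", x$unwrap_plateau))))
  invisible(x)
}

#' Fit a binding isotherm to equilibrium occupancy fractions
#'
#' The fraction of bound protein in the unwrapped state follows a standard
#' binding isotherm f(c) = c / (c + c_crit); the midpoint c_crit is the
#' critical concentration at which bound and wrapped states are equally
#' occupied.
#'
#' @param conc concentrations (nM), at least 5 points spanning the
#'   midpoint.
#' @param frac_bound Theta_b / (Theta_b + Theta_w) at each concentration.
#' @return List with `c_crit` (nM), `se` (standard error) and the `fit`
#'   object.
#' @export
fit_isotherm <- function(conc, frac_bound) {
  if (length(conc) < 5)
    stop("need at least 5 points spanning the midpoint", call. = FALSE)
  mid0 <- stats::approx(frac_bound, conc, xout = 0.5, ties = "ordered")$y
  if (is.na(mid0)) mid0 <- stats::median(conc)
  fit <- minpack.lm::nlsLM(frac_bound ~ conc / (conc + cc),
                           start = list(cc = mid0), lower = 1e-6,
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  list(c_crit = coef(fit)[["cc"]],
       se = summary(fit)$coefficients["cc", "Std. Error"],
       fit = fit)
}

#' Detect discrete steps in a total-extension trace
#'
#' Sliding-window change-point detector for piecewise-constant signals:
#' at each sample the means of the `window` points before and after are
#' compared with a two-sample t statistic; local maxima of |t| above the
#' Bonferroni-corrected threshold are step candidates, and the step size is
#' the difference of the flanking medians. Intended for sparse single-event
#' traces in total nm (compaction times substrate length).
#'
#' @param time sample times (s).
#' @param value signal (nm).
#' @param min_step smallest |step| reported (nm).
#' @param window half-window length (samples).
#' @param alpha familywise error rate for the threshold.
#' @return data.frame with columns `time` and `size` (signed, nm).
#' @export
detect_steps <- function(time, value, min_step = 1, window = 15,
                         alpha = 0.01) {
  n <- length(value)
  if (n < 2 * window + 1)
    return(data.frame(time = numeric(0), size = numeric(0)))
  tstat <- rep(NA_real_, n)
  for (i in (window + 1):(n - window)) {
    a <- value[(i - window):(i - 1)]
    b <- value[i:(i + window - 1)]
    sp <- sqrt((stats::var(a) + stats::var(b)) / 2)
    if (sp <= 0) sp <- 1e-12
    tstat[i] <- (mean(b) - mean(a)) / (sp * sqrt(2 / window))
  }
  thr <- stats::qt(1 - alpha / (2 * n), df = 2 * window - 2)
  cand <- which(abs(tstat) > thr)
  if (length(cand) == 0)
    return(data.frame(time = numeric(0), size = numeric(0)))
  ## keep the |t| maximum of each run of consecutive candidates
  runs <- split(cand, cumsum(c(1, diff(cand) > window)))
  steps <- lapply(runs, function(idx) {
    i <- idx[which.max(abs(tstat[idx]))]
    lo <- value[max(1, i - window):(i - 1)]
    hi <- value[i:min(n, i + window - 1)]
    data.frame(time = time[i], size = stats::median(hi) - stats::median(lo))
  })
  res <- do.call(rbind, steps)
  res <- res[abs(res$size) >= min_step, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Mode of a step-size distribution
#'
#' Kernel-density mode estimator for histograms of single-event compaction
#' sizes.
#'
#' @param sizes step sizes (nm); signs are dropped.
#' @return Mode location (nm), or NA for empty input.
#' @export
step_size_mode <- function(sizes) {
  sizes <- abs(sizes)
  if (length(sizes) == 0) return(NA_real_)
  if (length(sizes) == 1 || stats::sd(sizes) < 1e-9)
    return(stats::median(sizes))
  d <- tryCatch(stats::density(sizes, bw = "SJ", n = 512),
                error = function(e) stats::density(sizes, n = 512))
  d$x[which.max(d$y)]
}
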