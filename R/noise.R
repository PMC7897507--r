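#' Measurement noise model for synthetic traces
#'
#' Additive white Gaussian noise plus a slow linear drift, mimicking bead
#' tracking noise and residual thermal drift of the flow cell at a 10 Hz
#' force clamp. The instrument's true noise figures are unpublished; the
#' defaults (sigma 0.005 nm/nt, drift 0.002 nm/nt per 100 s) keep single
#' phases fittable at the shortest phase timescales.
#'
#' @param sigma additive white noise standard deviation (nm/nt).
#' @param drift_rate scale of the slow linear drift (nm/nt per 100 s): each
#'   realization draws its drift slope from N(0, drift_rate^2).
#' @param seed integer RNG seed; identical seeds reproduce identical traces.
#' @return An object of class `ssb_noise`.
#' @export
noise_model <- function(sigma = 0.005, drift_rate = 0.002, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(sigma = sigma, drift_rate = drift_rate,
                 seed = as.integer(seed)),
            class = "ssb_noise")
}

## Deterministic per-artifact seed stream: a Lehmer step keeps derived seeds
## in (0, 2^31) and adding replicates never perturbs existing ones.
derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 48271 + counter) %% 2147483647)
}

#' Add measurement noise to an ideal trace
#'
#' @param trace an ideal `ssb_trace`.
#' @param noise an `ssb_noise` model.
#' @param seed optional seed override (defaults to the model's seed).
#' @return A noisy `ssb_trace`. The drift slope is drawn once per
#'   realization from N(0, drift_rate^2) -- drift direction and magnitude
#'   vary between experiments -- so the pointwise mean over many
#'   realizations converges to the ideal trace.
#' @export
add_noise <- function(trace, noise, seed = noise$seed) {
  stopifnot(inherits(trace, "ssb_trace"), inherits(noise, "ssb_noise"))
  if (!isTRUE(attr(trace, "ideal")))
    stop("add_noise expects an ideal trace", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  slope <- rnorm(1, 0, noise$drift_rate)
  eps <- rnorm(nrow(trace), 0, noise$sigma)
  drift <- slope * trace$time_s / 100
  out <- trace
  out$compaction_nm_per_nt <- trace$compaction_nm_per_nt + eps + drift
  attr(out, "ideal") <- FALSE
  attr(out, "noise") <- noise
  attr(out, "seed") <- as.integer(seed)
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a replicated concentration series of noisy traces
#'
#' For each concentration, simulates the incubate -> rinse -> re-incubate
#' protocol once (ideal trace) and adds `n_rep` independent noise
#' realizations with seeds derived from the master seed by a counter, so the
#' dataset is exactly regenerable and extending it never changes existing
#' traces. Experimental series used three or more replicates per condition;
#' `n_rep` defaults to 3.
#'
#' @param params generating `ssb_params`.
#' @param concentrations concentration grid (nM).
#' @param noise an `ssb_noise` model; its seed is the master seed.
#' @param n_rep replicates per concentration (>= 3 to mirror the
#'   experimental design).
#' @param t_incubate,t_rinse,t_reincubate protocol durations (s).
#' @param force tension (pN).
#' @param sampling_rate Hz.
#' @return An object of class `ssb_series`: list with `traces` (list of
#'   noisy `ssb_trace`), `ideal` (list of ideal traces, one per
#'   concentration), `index` (data.frame conc/rep/seed), `params`, `noise`.
#' @export
generate_concentration_series <- function(params,
                                          concentrations = c(0.1, 0.5, 1, 5, 10, 50),
                                          noise = noise_model(),
                                          n_rep = 3,
                                          t_incubate = 300, t_rinse = 300,
                                          t_reincubate = 200, force = 12,
                                          sampling_rate = 10) {
  if (n_rep < 1) stop("n_rep must be >= 1", call. = FALSE)
  ideal <- lapply(concentrations, function(cc) {
    simulate_protocol(
      incubation_protocol(cc, force, t_incubate, t_rinse, t_reincubate,
                          sampling_rate), params)
  })
  names(ideal) <- as.character(concentrations)
  traces <- list()
  idx <- data.frame(conc_nM = numeric(0), rep = integer(0), seed = integer(0))
  counter <- 0L
  for (i in seq_along(concentrations)) {
    for (r in seq_len(n_rep)) {
      counter <- counter + 1L
      sd_i <- derive_seed(noise$seed, counter)
      traces[[length(traces) + 1L]] <- add_noise(ideal[[i]], noise, sd_i)
      idx <- rbind(idx, data.frame(conc_nM = concentrations[i], rep = r,
                                   seed = sd_i))
    }
  }
  structure(list(traces = traces, ideal = ideal, index = idx,
                 params = params, noise = noise),
            class = "ssb_series")
}

#' @export
print.ssb_series <- function(x, ...) {
  cat(sprintf("<ssb_series> %d traces (%d concentrations x %d replicates)\n",
              length(x$traces), length(x$ideal),
              max(x$index$rep)))
  invisible(x)
}

#' Generate a RecA filamentation saturation curve
#'
#' An idealised array of binding sites filling at a set rate gives
#' S(t) = 1 - exp(-rate * t); optional measurement noise is added on the
#' normalised extension scale.
#'
#' @param rate filamentation rate (s^-1), > 0.
#' @param noise optional `ssb_noise` model (sigma interpreted on the 0..1
#'   saturation scale); `NULL` for a noise-free curve.
#' @param duration trace length (s).
#' @param sampling_rate Hz.
#' @return A data.frame of class `ssb_saturation` with columns `time_s`,
#'   `saturation`.
#' @export
generate_reca_curve <- function(rate, noise = NULL, duration = 1500,
                                sampling_rate = 10) {
  if (rate <= 0) stop("rate must be > 0", call. = FALSE)
  tt <- seq(0, duration, by = 1 / sampling_rate)
  s <- 1 - exp(-rate * tt)
  if (!is.null(noise)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(noise$seed)
    slope <- rnorm(1, 0, noise$drift_rate)
    s <- s + rnorm(length(s), 0, noise$sigma) + slope * tt / 100
  }
  structure(data.frame(time_s = tt, saturation = s),
            rate = rate, noise = noise,
            class = c("ssb_saturation", "data.frame"))
}
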