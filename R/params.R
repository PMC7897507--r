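#' Kinetic parameter set for the two-step SSB binding model
#'
#' Bundles every rate, footprint and per-state compaction needed to simulate
#' SSB binding and wrapping on long ssDNA at one condition (tension, buffer).
#' The two-step scheme distinguishes a bound-but-unwrapped state, in which a
#' single OB-fold domain holds `n_b` nucleotides, from a wrapped state
#' occluding `n_w` nucleotides. Dissociation and unwrapping are *stimulated*
#' by neighbouring bound-unwrapped protein: their effective rates grow
#' linearly with the bound-unwrapped occupancy (see [effective_rates()]).
#'
#' @param k_b bimolecular on-rate constant (nM^-1 s^-1).
#' @param k_off intrinsic dissociation rate of the bound state (s^-1).
#' @param k_w intrinsic wrapping rate (s^-1); 0 for species that cannot wrap.
#' @param k_unw intrinsic unwrapping rate (s^-1). The measured bound is
#'   "<0.01"; the default fixtures pin it to 0.
#' @param k_off_stim stimulated dissociation rate scale (s^-1).
#' @param k_unw_stim stimulated unwrapping rate scale (s^-1).
#' @param n_b bound-state footprint (nt).
#' @param n_w wrapped-state footprint (nt).
#' @param x_b per-nucleotide compaction of the bound state (nm/nt, positive
#'   shortening magnitude).
#' @param x_w per-nucleotide compaction of the wrapped state (nm/nt).
#' @param force applied template tension (pN).
#' @param wrapping logical; whether the wrapped state is accessible in this
#'   regime. Wrapping is treated as active only when `wrapping` is `TRUE`
#'   *and* `k_w > 0`.
#' @param availability wrapping availability law: `"rationed"` (default)
#'   shares free ssDNA among wrap candidates,
#'   phi = min(1, Theta_0 / ((n_w - n_b) beta)); `"linear"` uses the literal
#'   phi = Theta_0 variant for sensitivity analysis.
#' @param label free-text label carried through simulations and files.
#'
#' @return An object of class `ssb_params` (a named list).
#' @seealso [table1_params()], [prose_params()], [h55y_params()],
#'   [at_force()], [read_parameter_set()]
#' @export
parameter_set <- function(k_b, k_off, k_w, k_unw = 0, k_off_stim = 0,
                          k_unw_stim = 0, n_b = 8L, n_w = 17L,
                          x_b = 0.0159, x_w = 0.083, force = 12,
                          wrapping = TRUE, availability = c("rationed", "linear"),
                          label = "custom") {
  availability <- match.arg(availability)
  rates <- c(k_b = k_b, k_off = k_off, k_w = k_w, k_unw = k_unw,
             k_off_stim = k_off_stim, k_unw_stim = k_unw_stim)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and >= 0", call. = FALSE)
  if (k_b <= 0)
    stop("k_b must be > 0 for any binding to occur", call. = FALSE)
  if (!(n_b > 0 && n_w > n_b))
    stop("footprints must satisfy 0 < n_b < n_w", call. = FALSE)
  if (!(x_b >= 0 && x_w > x_b))
    stop("compactions must satisfy 0 <= x_b < x_w", call. = FALSE)
  structure(list(
    k_b = k_b, k_off = k_off, k_w = k_w, k_unw = k_unw,
    k_off_stim = k_off_stim, k_unw_stim = k_unw_stim,
    n_b = as.numeric(n_b), n_w = as.numeric(n_w),
    x_b = x_b, x_w = x_w, force = force,
    wrapping = isTRUE(wrapping), availability = availability,
    label = label
  ), class = "ssb_params")
}

#' @export
print.ssb_params <- function(x, ...) {
  cat(sprintf("<ssb_params '%s'>  force %g pN, wrapping %s (%s availability)\n",
              x$label, x$force, if (wrapping_active(x)) "on" else "off",
              x$availability))
  cat(sprintf("  k_b %.4g /nM/s  k_off %.4g /s  k_w %.4g /s  k_unw %.4g /s\n",
              x$k_b, x$k_off, x$k_w, x$k_unw))
  cat(sprintf("  stimulated: k_off_stim %.4g /s  k_unw_stim %.4g /s\n",
              x$k_off_stim, x$k_unw_stim))
  cat(sprintf("  footprints %g/%g nt, compaction %.4g/%.4g nm/nt\n",
              x$n_b, x$n_w, x$x_b, x$x_w))
  invisible(x)
}

#' Is the wrapped state kinetically accessible?
#'
#' Wrapping (and with it the neighbour-stimulated rate enhancement, which is
#' mediated by neighbours claiming released ssDNA as they wrap) requires both
#' a wrapping-permissive force regime and a non-zero wrapping rate.
#'
#' @param params an `ssb_params` object.
#' @return logical scalar.
#' @export
wrapping_active <- function(params) {
  isTRUE(params$wrapping) && params$k_w > 0
}

fixture_path <- function(name) {
  path <- system.file("extdata", name, package = "ssbkinetics")
  if (!nzchar(path)) {
    ## during in-source development (pkgload), fall back to inst/
    path <- file.path("inst", "extdata", name)
  }
  path
}

#' Shipped parameter fixtures
#'
#' `table1_params()` returns the calibrated 12 pN wild-type parameter set
#' (k_b 0.150 nM^-1 s^-1, k_off 0.0171 s^-1, k_w 1.40 s^-1, stimulated scales
#' 0.113 and 0.095 s^-1, compactions 0.0159 / 0.083 nm/nt).
#' `prose_params()` returns a companion calibration with slightly faster
#' binding and wrapping (k_b 0.18 nM^-1 s^-1, k_w 1.8 s^-1, stimulated
#' scales 0.10/0.10 s^-1, slow k_off 0.017 s^-1). Both are read from the
#' JSON fixtures shipped under `inst/extdata`.
#'
#' @param ... overrides passed to [parameter_set()] fields after loading.
#' @return An `ssb_params` object.
#' @export
table1_params <- function(...) {
  modify_params(read_parameter_set(fixture_path("table1_12pN.json")), ...)
}

#' @rdname table1_params
#' @export
prose_params <- function(...) {
  modify_params(read_parameter_set(fixture_path("prose_12pN.json")), ...)
}

#' Non-tetramerising (H55Y-like) parameter mode
#'
#' The H55Y substitution prevents tetramer formation at low concentration;
#' monomers bind through a single OB fold with wild-type on/off kinetics but
#' cannot wrap. Modelled as the wild-type set with `k_w = 0` (wrapping, and
#' hence stimulation, inactive). Concentrations for monomer preparations can
#' be converted with [monomer_equivalent_concentration()].
#'
#' @param base parameter set to start from, default [table1_params()].
#' @return An `ssb_params` object with wrapping disabled.
#' @export
h55y_params <- function(base = table1_params()) {
  modify_params(base, k_w = 0, wrapping = FALSE, label = "h55y_monomer")
}

#' Modify fields of a parameter set
#'
#' @param params an `ssb_params` object.
#' @param ... named fields to replace (same names as [parameter_set()]).
#' @return A new validated `ssb_params` object.
#' @export
modify_params <- function(params, ...) {
  dots <- list(...)
  if (length(dots) == 0) return(params)
  fields <- unclass(params)
  for (nm in names(dots)) {
    if (!nm %in% names(fields))
      stop("unknown parameter field: ", nm, call. = FALSE)
    fields[[nm]] <- dots[[nm]]
  }
  do.call(parameter_set, fields[setdiff(names(fields), character())])
}

#' Force-regime table for SSB wrapping modes
#'
#' Template tension selects which wrapped mode is accessible: at 7 pN the
#' 35-nt mode dominates (about 5 nm compaction per tetramer), at 12 pN only
#' the 17-nt mode survives (about 2 nm per tetramer; the calibrated
#' per-nucleotide value 0.083 nm/nt is used at 12 pN), and at 15 pN and above
#' wrapping is unstable so only single-domain binding remains.
#'
#' @return A data.frame with columns `force_pN`, `n_w`, `dx_per_protein_nm`,
#'   `wrapping_enabled`, sorted by force.
#' @export
force_regimes <- function() {
  data.frame(
    force_pN = c(7, 12, 20, 60),
    n_w = c(35, 17, NA, NA),
    dx_per_protein_nm = c(5, 2, NA, NA),
    wrapping_enabled = c(TRUE, TRUE, FALSE, FALSE)
  )
}

#' Look up the regime for one force
#'
#' @param force tension in pN.
#' @return One row of [force_regimes()] as a list.
#' @export
force_regime <- function(force) {
  reg <- force_regimes()
  i <- match(force, reg$force_pN)
  if (is.na(i)) {
    if (force >= 15) {
      return(list(force_pN = force, n_w = NA_real_,
                  dx_per_protein_nm = NA_real_, wrapping_enabled = FALSE))
    }
    stop(sprintf("no force regime tabulated for %g pN", force), call. = FALSE)
  }
  as.list(reg[i, ])
}

#' Re-express a parameter set at a different template tension
#'
#' Kinetic rates are kept (direct dissociation is only weakly force
#' dependent); the wrapped footprint, per-protein compaction and the
#' wrapping flag follow the force-regime table. At 12 pN the calibrated
#' x_w of the input set is retained; at 7 pN the geometric value
#' dx/footprint = 5/35 nm/nt is used.
#'
#' @param params an `ssb_params` object.
#' @param force target tension (pN).
#' @return An `ssb_params` object for that force.
#' @export
at_force <- function(params, force) {
  reg <- force_regime(force)
  if (!reg$wrapping_enabled) {
    return(modify_params(params, force = force, wrapping = FALSE))
  }
  x_w <- if (force == 12) params$x_w else
    per_nt_compaction(reg$dx_per_protein_nm, reg$n_w)
  modify_params(params, force = force, wrapping = TRUE,
                n_w = reg$n_w, x_w = x_w)
}
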