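#' Protein density state on the ssDNA lattice
#'
#' The mean-field state tracks two protein densities (proteins per
#' nucleotide): `beta` for bound-but-unwrapped tetramers and `omega` for
#' wrapped tetramers. The occupancy fractions follow from the footprints:
#' Theta_b = n_b * beta, Theta_w = n_w * omega, and the free fraction is
#' Theta_0 = 1 - Theta_b - Theta_w by construction, so the three fractions
#' always sum to one exactly.
#'
#' @param beta bound-unwrapped density (proteins/nt).
#' @param omega wrapped density (proteins/nt).
#' @param params an `ssb_params` object supplying the footprints.
#' @return An object of class `ssb_state`.
#' @export
state_vector <- function(beta, omega, params) {
  if (!is.finite(beta) || !is.finite(omega) || beta < 0 || omega < 0)
    stop("densities beta and omega must be finite and >= 0", call. = FALSE)
  th <- occupancies_raw(beta, omega, params)
  if (th[["theta_b"]] > 1 + 1e-12 || th[["theta_w"]] > 1 + 1e-12 ||
      th[["theta_0"]] < -1e-12)
    stop("occupancy fractions must lie in [0, 1]", call. = FALSE)
  structure(list(beta = beta, omega = omega,
                 n_b = params$n_b, n_w = params$n_w),
            class = "ssb_state")
}

occupancies_raw <- function(beta, omega, params) {
  theta_b <- params$n_b * beta
  theta_w <- params$n_w * omega
  c(theta_0 = 1 - theta_b - theta_w, theta_b = theta_b, theta_w = theta_w)
}

#' Occupancy fractions of a state
#'
#' @param state an `ssb_state` object.
#' @return Named numeric vector `theta_0`, `theta_b`, `theta_w` (free,
#'   bound-unwrapped, wrapped fractions of the ssDNA; sums to 1 exactly).
#' @export
occupancies <- function(state) {
  theta_b <- state$n_b * state$beta
  theta_w <- state$n_w * state$omega
  c(theta_0 = 1 - theta_b - theta_w, theta_b = theta_b, theta_w = theta_w)
}

#' @export
print.ssb_state <- function(x, ...) {
  th <- occupancies(x)
  cat(sprintf(
    "<ssb_state> beta %.5g, omega %.5g proteins/nt | Theta_0 %.4f Theta_b %.4f Theta_w %.4f\n",
    x$beta, x$omega, th["theta_0"], th["theta_b"], th["theta_w"]))
  invisible(x)
}

empty_state <- function(params) state_vector(0, 0, params)
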