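#' Conversion factor from e/(Angstrom * relative permittivity) to kcal/(mol e)
#'
#' Multiply by this `unit_factor` in [alpb_params()] to obtain potentials in
#' kcal/(mol e) instead of the natural charge/length units used by default.
#' @export
unit_factor_kcal <- 332.0636

#' Parameters of the ALPB electrostatic model
#'
#' The analytic linearized Poisson-Boltzmann (ALPB) model approximates the
#' potential outside a low-dielectric solute immersed in a high-dielectric
#' solvent. Its parameters are the two relative permittivities, the
#' dimensionless ALPB constant \eqn{\alpha}, and an output unit conversion.
#'
#' @param eps_in relative permittivity of the solute interior (> 0).
#' @param eps_out relative permittivity of the solvent (> 0).
#' @param alpha dimensionless ALPB constant (>= 0). The default 0.580127 is
#'   the standard value derived from the exact solution for a sphere.
#' @param unit_factor multiplier applied to every potential (> 0). The default
#'   1 keeps natural units of e/Angstrom; [unit_factor_kcal] gives
#'   kcal/(mol e).
#'
#' @return An object of class `alpb_params`.
#' @examples
#' alpb_params(eps_in = 1, eps_out = 80)
#' @export
alpb_params <- function(eps_in = 1, eps_out = 80, alpha = 0.580127,
                        unit_factor = 1) {
  stopifnot(is.numeric(eps_in), length(eps_in) == 1, is.finite(eps_in), eps_in > 0,
            is.numeric(eps_out), length(eps_out) == 1, is.finite(eps_out), eps_out > 0,
            is.numeric(alpha), length(alpha) == 1, is.finite(alpha), alpha >= 0,
            is.numeric(unit_factor), length(unit_factor) == 1,
            is.finite(unit_factor), unit_factor > 0)
  structure(list(eps_in = eps_in, eps_out = eps_out, alpha = alpha,
                 unit_factor = unit_factor),
            class = "alpb_params")
}

#' @export
print.alpb_params <- function(x, ...) {
  cat(sprintf("ALPB parameters: eps_in = %g, eps_out = %g, alpha = %g, unit_factor = %g\n",
              x$eps_in, x$eps_out, x$alpha, x$unit_factor))
  invisible(x)
}

#' ALPB potential of a point charge at an observation point
#'
#' Computes the screened electrostatic potential outside the solute due to a
#' single point charge:
#' \deqn{\phi = u \, \frac{q}{\epsilon_{in}} \frac{1}{1+\alpha\beta}
#'   \left[ \frac{1+\alpha}{d} - \frac{\alpha(1-\beta)}{r} \right],
#'   \qquad \beta = \epsilon_{in}/\epsilon_{out},}
#' where `d` is the charge-to-vertex distance, `r` the structure-center-to-
#' vertex distance, and `u` the unit conversion factor. When
#' \eqn{\epsilon_{in} = \epsilon_{out}} this collapses exactly to the Coulomb
#' potential \eqn{u q/(\epsilon d)}.
#'
#' All arguments are vectorized with the usual recycling rules.
#'
#' @param q charge(s), elementary charge units.
#' @param d distance(s) from the charge to the vertex, Angstrom (> 0).
#' @param r distance(s) from the reference (structure) center to the vertex,
#'   Angstrom (> 0).
#' @param params an [alpb_params()] object.
#' @return Potential(s) in output units (`unit_factor` applied).
#' @examples
#' # Coulomb limit: eps_in == eps_out
#' alpb_potential(1, d = 2, r = 7, alpb_params(eps_in = 80, eps_out = 80))
#' @export
alpb_potential <- function(q, d, r, params = alpb_params()) {
  stopifnot(inherits(params, "alpb_params"), is.numeric(q), is.numeric(d),
            is.numeric(r))
  if (any(!is.finite(d)) || any(d <= 0))
    stop("d must be finite and > 0 (vertex coincides with a charge?)")
  if (any(!is.finite(r)) || any(r <= 0))
    stop("r must be finite and > 0 (vertex coincides with the center?)")
  beta <- params$eps_in / params$eps_out
  params$unit_factor * (q / params$eps_in) * (1 / (1 + params$alpha * beta)) *
    ((1 + params$alpha) / d - params$alpha * (1 - beta) / r)
}

#' Summed ALPB potential over a batch of charge/query pairs
#'
#' Equivalent to `sum(alpb_potential(q, d, r, params))`; the potential at a
#' vertex is the sum of single-charge potentials over all charges in the
#' system.
#'
#' @inheritParams alpb_potential
#' @return A single number, the summed potential.
#' @export
alpb_potential_batch <- function(q, d, r, params = alpb_params()) {
  n <- length(q)
  if (length(d) != n || length(r) != n)
    stop("q, d and r must have equal lengths")
  sum(alpb_potential(q, d, r, params))
}
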