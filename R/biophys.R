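# Closed-form biophysical relations used in the mechanistic interpretation of
# proteinoid-actin bioelectricity. Each returns a `biophys_quantity` (value +
# unit tag) so downstream code can assert dimensional consistency.

bq <- function(value, units) {
  structure(list(value = value, units = units), class = "biophys_quantity")
}

#' @export
print.biophys_quantity <- function(x, ...) {
  cat(format(x$value), x$units, "\n")
  invisible(x)
}

#' Electric dipole moment of a charge separation
#'
#' \eqn{p = q d} per component.
#'
#' @param q Separated charge in coulomb.
#' @param d_vec Separation vector in metres (any length).
#' @return `biophys_quantity` in C m (vector value).
#' @export
dipole_moment <- function(q, d_vec) {
  stopifnot(is.finite(q), all(is.finite(d_vec)))
  bq(q * d_vec, "C.m")
}

#' Parallel-plate membrane capacitance
#'
#' \eqn{C = \varepsilon A / d} for a membrane-like dielectric layer.
#'
#' @param epsilon Permittivity in F/m.
#' @param area Area in m^2.
#' @param thickness Layer thickness in m (positive).
#' @return `biophys_quantity` in farad.
#' @export
membrane_capacitance <- function(epsilon, area, thickness) {
  check_positive(thickness, "thickness")
  bq(epsilon * area / thickness, "F")
}

#' Periodic potential along an actin filament
#'
#' The double-helical filament presents a periodic landscape to mobile
#' charges: 13 G-actin monomers per helical turn over a ~36 nm pitch give a
#' spatial frequency \eqn{f = 13/36 \approx 0.361} nm^-1. The potential is
#' taken as a cosine well, \eqn{U(x) = -V_0 \cos(2 \pi f x)}, so x = 0 sits
#' at a well of depth \eqn{V_0}.
#'
#' @param v0 Well depth (J or eV; units of the return follow the input).
#' @param x Position(s) along the filament in nm.
#' @param monomers_per_turn,pitch_nm Helix geometry.
#' @return List with `spatial_frequency` (`biophys_quantity`, nm^-1) and
#'   `potential` (`biophys_quantity`, same energy units as `v0`).
#' @export
actin_periodic_potential <- function(v0, x, monomers_per_turn = 13, pitch_nm = 36) {
  check_positive(pitch_nm, "pitch_nm")
  f <- monomers_per_turn / pitch_nm
  list(spatial_frequency = bq(f, "nm^-1"),
       potential = bq(-v0 * cos(2 * pi * f * x), "energy"))
}

#' Conductivity enhancement factor
#'
#' \eqn{\sigma / \sigma_{actin}}, the dimensionless gain of a preparation
#' over the pure-actin reference.
#'
#' @param sigma,sigma_actin Conductivities in a common unit;
#'   `sigma_actin` must be positive.
#' @return `biophys_quantity`, dimensionless.
#' @export
conductivity_enhancement <- function(sigma, sigma_actin) {
  check_positive(sigma_actin, "sigma_actin")
  bq(sigma / sigma_actin, "dimensionless")
}

#' Threshold-gated membrane potential update rate
#'
#' \eqn{dV/dt = \alpha\,\Theta(V - V_{th})} with Heaviside gate
#' \eqn{\Theta} (convention \eqn{\Theta(0) = 1}): the potential climbs at
#' rate \eqn{\alpha} once threshold is reached, and is static below it.
#'
#' @param v Membrane potential (mV).
#' @param alpha Rate constant (mV/s).
#' @param v_th Threshold (mV).
#' @return `biophys_quantity` in mV/s.
#' @export
threshold_update <- function(v, alpha, v_th) {
  bq(alpha * as.numeric(v >= v_th), "mV/s")
}

#' Ohmic channel current
#'
#' \eqn{I = g (V - E_{rev})}.
#'
#' @param g Conductance in siemens.
#' @param v Membrane potential in volt.
#' @param e_rev Reversal potential in volt.
#' @return `biophys_quantity` in ampere.
#' @export
channel_current <- function(g, v, e_rev) {
  bq(g * (v - e_rev), "A")
}

#' Diffusive RC time constant
#'
#' \eqn{\tau = R C}: the slow relaxation set by the access resistance and the
#' diffusion-associated capacitance.
#'
#' @param r Resistance in ohm (positive).
#' @param c_diffusion Capacitance in farad (positive).
#' @return `biophys_quantity` in seconds.
#' @export
diffusive_tau <- function(r, c_diffusion) {
  check_positive(r, "r")
  check_positive(c_diffusion, "c_diffusion")
  bq(r * c_diffusion, "s")
}
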