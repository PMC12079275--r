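#' Bulk conductivity from impedance magnitude and cell geometry
#'
#' For a cylindrical two-terminal measurement cell of length \eqn{L} and
#' radius \eqn{r},
#' \deqn{\sigma = \frac{L}{|Z| \, \pi r^2}}
#' converting the measured impedance magnitude into a bulk conductivity in
#' S/cm. The default geometry (L = 10 cm, r = 1 cm) is the documented
#' measurement-cell geometry for the reference LCR characterisation and is
#' overridable.
#'
#' @param z_mag_ohm Impedance magnitude in ohm (vectorised).
#' @param geometry A [cell_geometry()].
#' @return Conductivity in S/cm, same length as `z_mag_ohm`.
#' @examples
#' conductivity(6797)   # proteinoid-actin mixture at 300 kHz
#' conductivity(26630)  # pure actin
#' @export
conductivity <- function(z_mag_ohm, geometry = cell_geometry()) {
  if (any(!is.finite(z_mag_ohm)) || any(z_mag_ohm <= 0)) {
    abort("`z_mag_ohm` must be positive and finite.",
          class = "protoelec_domain_error")
  }
  geometry$length_cm / (z_mag_ohm * pi * geometry$radius_cm^2)
}

#' Measurement-cell geometry
#'
#' @param length_cm Electrode separation (cell length) in cm.
#' @param radius_cm Radius of the cylindrical cell in cm.
#' @return A list with `length_cm`, `radius_cm`, `area_cm2`.
#' @export
cell_geometry <- function(length_cm = 10, radius_cm = 1) {
  check_positive(length_cm, "length_cm")
  check_positive(radius_cm, "radius_cm")
  list(length_cm = length_cm, radius_cm = radius_cm,
       area_cm2 = pi * radius_cm^2)
}

#' Conductivity ratios against a reference preparation
#'
#' With a shared cell geometry the ratio of conductivities equals the inverse
#' ratio of impedance magnitudes, so enhancement factors are
#' geometry-independent.
#'
#' @param sigmas Named numeric vector of conductivities (any common unit).
#' @param reference Name of the reference entry.
#' @return Tibble with `sample` and `ratio` (sigma / sigma_reference).
#' @examples
#' s <- conductivity(c(mixture = 6797, actin = 26630, proteinoid = 177000))
#' conductivity_ratios(s, reference = "proteinoid")
#' @export
conductivity_ratios <- function(sigmas, reference) {
  if (is.null(names(sigmas)) || !reference %in% names(sigmas)) {
    abort("`reference` must name an entry of `sigmas`.",
          class = "protoelec_invalid_spec")
  }
  ref <- sigmas[[reference]]
  if (!is.finite(ref) || ref <= 0) {
    abort("reference conductivity must be positive.",
          class = "protoelec_domain_error")
  }
  tibble(sample = names(sigmas), ratio = unname(sigmas) / ref)
}

#' Derived quantities from an LCR resistance/reactance pair
#'
#' Closed forms relating the series resistance R and reactance X reported by
#' an LCR meter to the impedance magnitude, phase angle and dissipation
#' factor:
#' \deqn{|Z| = \sqrt{R^2 + X^2},\qquad
#'       \theta = \arctan(|X|/R)\ \mathrm{(degrees)},\qquad
#'       D = R/|X|.}
#' The phase angle is reported as a magnitude in degrees; the sign of X is
#' preserved in `x_sign`. `D` is infinite when X = 0.
#'
#' @param r_kohm Series resistance in kilo-ohm (positive; vectorised).
#' @param x_kohm Series reactance in kilo-ohm (sign retained).
#' @return Tibble with `z_mag_kohm`, `theta_deg`, `dissipation`, `x_sign`.
#' @examples
#' lcr_derive(26.71, -1.631) # theta = 3.494 degrees
#' @export
lcr_derive <- function(r_kohm, x_kohm) {
  if (any(!is.finite(r_kohm)) || any(r_kohm <= 0)) {
    abort("`r_kohm` must be positive.", class = "protoelec_domain_error")
  }
  tibble(
    z_mag_kohm = sqrt(r_kohm^2 + x_kohm^2),
    theta_deg = atan2(abs(x_kohm), r_kohm) * 180 / pi,
    dissipation = ifelse(x_kohm == 0, Inf, r_kohm / abs(x_kohm)),
    x_sign = sign(x_kohm)
  )
}

#' Reference single-frequency LCR characterisation table
#'
#' The published 300 kHz LCR characterisation of actin, Glu:Phe proteinoid
#' and their mixture (series capacitance, dissipation factors, series
#' inductance, impedance magnitude, phase angle, resistance/reactance, DC
#' resistance), shipped as a plain CSV.
#'
#' @param path Optional path to a CSV with the same columns.
#' @return Tibble with one row per preparation.
#' @export
lcr_reference <- function(path = system.file("extdata", "lcr_300khz.csv",
                                             package = "protoelec")) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_tibble(out)
}
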