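#' Radiative heat loss of the bee body
#'
#' Stefan-Boltzmann emission from the whole body surface,
#' \deqn{R_{loss} = \epsilon_b\,\sigma\,T_b^4\,A_b,}
#' with the body surface temperature `T_b` (mean of head, thorax and
#' abdomen) converted internally to Kelvin.  Body temperatures of foragers
#' lie in the 0-50 degC range, so emission peaks in the medium-to-long
#' infrared (see [wien_peak_wavelength()]).
#'
#' @param T_b Body surface temperature, degC (vectorised).
#' @param A_b Emitting surface area, m^2.
#' @param constants A [thermal_constants()] object.
#' @return Radiative heat loss, W.
#' @examples
#' radiative_loss(35, 163.7e-6)
#' @export
radiative_loss <- function(T_b, A_b, constants = thermal_constants()) {
  stopifnot(is.numeric(A_b), all(A_b > 0))
  T_K <- celsius_to_kelvin(T_b)
  constants$epsilon_b * constants$sigma * T_K^4 * A_b
}

#' Solar radiative heat gain
#'
#' Short-wave (visible + near-infrared) gain from global radiation `G`,
#' assumed to act on half the body surface:
#' \deqn{R_{gSOL} = \alpha_{bSOL}\, G\, (A_b/2) +
#'       \alpha_{bSOL}\, R_{rSOL}\, (A_b/2).}
#' The reflected component defaults to zero because only global radiation
#' was measured in the field; `reflected = TRUE` adds a ground-reflected
#' term \eqn{(1-\alpha_{paint}) G} for sensitivity analysis.
#'
#' @param G Global radiation, W m^-2 (vectorised, must be >= 0).
#' @param A_b Body surface area, m^2.
#' @param constants A [thermal_constants()] object.
#' @param reflected Include the ground-reflected solar term? Default `FALSE`.
#' @return Solar heat gain, W.
#' @examples
#' solar_gain(921, 163.7e-6)
#' @export
solar_gain <- function(G, A_b, constants = thermal_constants(),
                       reflected = FALSE) {
  if (!is.numeric(G) || any(G < 0)) {
    stop("global radiation G must be non-negative", call. = FALSE)
  }
  stopifnot(is.numeric(A_b), all(A_b > 0))
  R_rSOL <- if (reflected) (1 - constants$alpha_paint) * G else 0
  constants$alpha_bSOL * G * (A_b / 2) +
    constants$alpha_bSOL * R_rSOL * (A_b / 2)
}

#' Infrared radiative heat gain
#'
#' Long-wave gain from the surroundings.  Direct and ground-emitted
#' components each act on half the body surface; the reflected component is
#' zero because the black chamber paint (absorptivity 0.95) reabsorbs
#' essentially all reflected IR.  Under the default closure the
#' surroundings radiate as a blackbody at `T_surround`, so
#' \deqn{R_{gIR} = \alpha_{bIR}\,\sigma\,T_{surround}^4\,A_b.}
#' `T_surround` is an explicit argument (typically ambient air temperature)
#' so other closures, e.g. measured radiant temperatures, can be plugged in.
#'
#' @param T_surround Radiant temperature of the surroundings, degC
#'   (vectorised).
#' @param A_b Body surface area, m^2.
#' @param constants A [thermal_constants()] object.
#' @return Infrared heat gain, W.
#' @examples
#' ir_gain(25, 163.7e-6)
#' @export
ir_gain <- function(T_surround, A_b, constants = thermal_constants()) {
  stopifnot(is.numeric(A_b), all(A_b > 0))
  T_K <- celsius_to_kelvin(T_surround)
  # direct + ground-emitted on A_b/2 each, reflected = 0
  constants$alpha_bIR * constants$sigma * T_K^4 * (A_b / 2) +
    constants$alpha_bIR * constants$sigma * T_K^4 * (A_b / 2)
}

#' Full radiation budget of a visit
#'
#' Evaluates radiative loss and both gain components for given body and
#' surround temperatures and global radiation, and returns them with the
#' additive total \eqn{R_{gain} = R_{gIR} + R_{gSOL}}.
#'
#' @param T_b Mean body surface temperature, degC.
#' @param T_surround Radiant surround temperature, degC (usually air
#'   temperature).
#' @param G Global radiation, W m^-2.
#' @param A_b Body surface area, m^2.
#' @param constants A [thermal_constants()] object.
#' @param reflected_solar Passed to [solar_gain()].
#' @return A data.frame with columns `R_loss`, `R_gIR`, `R_gSOL`, `R_gain`
#'   (all W).
#' @examples
#' radiation_budget(T_b = 36, T_surround = 25, G = 500, A_b = 163.7e-6)
#' @export
radiation_budget <- function(T_b, T_surround, G, A_b,
                             constants = thermal_constants(),
                             reflected_solar = FALSE) {
  R_loss <- radiative_loss(T_b, A_b, constants)
  R_gIR <- ir_gain(T_surround, A_b, constants)
  R_gSOL <- solar_gain(G, A_b, constants, reflected = reflected_solar)
  data.frame(
    R_loss = R_loss, R_gIR = R_gIR, R_gSOL = R_gSOL,
    R_gain = R_gIR + R_gSOL
  )
}

#' Wien-law peak emission wavelength
#'
#' Wavelength of maximum blackbody emission at temperature `T`,
#' \eqn{\lambda_{max} = b/T_K} with the Wien displacement constant
#' b = 2897.77 um K.  At body temperatures of 0-50 degC the peak lies at
#' 10.61-8.97 um, i.e. in the medium-to-long infrared.
#'
#' @param T Temperature, degC (vectorised).
#' @return Peak wavelength, um.
#' @examples
#' wien_peak_wavelength(c(0, 50))
#' @export
wien_peak_wavelength <- function(T) {
  if (any(T <= -ZERO_C_IN_K)) {
    stop("temperature at or below absolute zero (-273.15 °C)", call. = FALSE)
  }
  b_wien <- 2897.77 # um K
  b_wien / celsius_to_kelvin(T)
}
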