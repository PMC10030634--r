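#' Physical and thermal constants of the heat-budget model
#'
#' Bundles the radiative and evaporative constants used throughout the model:
#' cuticle infrared emissivity and absorptivity, solar absorptivity (already
#' corrected for reduced absorption towards the curved body edges by a cosine
#' law), the infrared absorptivity of the measurement-chamber paint, the
#' Stefan-Boltzmann constant, and the fixed evaporative heat loss.
#'
#' Evaporative loss `E_ev` is held constant across air temperatures because
#' the foragers' mouthparts are wet from drinking under all conditions.
#'
#' @param epsilon_b Infrared emissivity of the bee cuticle (dimensionless).
#' @param alpha_bIR Infrared absorptivity; equals `epsilon_b` by Kirchhoff's
#'   law.
#' @param alpha_bSOL Solar (visible + near-IR) absorptivity.
#' @param alpha_paint Infrared absorptivity of the chamber paint; reflected
#'   IR is neglected because this is close to 1.
#' @param sigma Stefan-Boltzmann constant, W m^-2 K^-4.
#' @param E_ev Evaporative heat loss, W (default 0.004 W = 4 mW).
#'
#' @return An object of class `"thermal_constants"` (a named list).
#' @examples
#' thermal_constants()
#' thermal_constants(E_ev = 0.006)
#' @export
thermal_constants <- function(epsilon_b = 0.97,
                              alpha_bIR = 0.97,
                              alpha_bSOL = 0.825,
                              alpha_paint = 0.95,
                              sigma = 5.669e-8,
                              E_ev = 0.004) {
  stopifnot(
    epsilon_b > 0, epsilon_b <= 1,
    alpha_bIR > 0, alpha_bIR <= 1,
    alpha_bSOL > 0, alpha_bSOL <= 1,
    alpha_paint > 0, alpha_paint <= 1,
    sigma > 0, E_ev >= 0
  )
  structure(
    list(
      epsilon_b = epsilon_b, alpha_bIR = alpha_bIR,
      alpha_bSOL = alpha_bSOL, alpha_paint = alpha_paint,
      sigma = sigma, E_ev = E_ev
    ),
    class = "thermal_constants"
  )
}

#' @export
print.thermal_constants <- function(x, ...) {
  cat("Thermal constants:\n")
  cat(sprintf("  epsilon_b (IR emissivity)     %.3f\n", x$epsilon_b))
  cat(sprintf("  alpha_bIR (IR absorptivity)   %.3f\n", x$alpha_bIR))
  cat(sprintf("  alpha_bSOL (solar absorpt.)   %.3f\n", x$alpha_bSOL))
  cat(sprintf("  alpha_paint                   %.3f\n", x$alpha_paint))
  cat(sprintf("  sigma (W m-2 K-4)             %.3e\n", x$sigma))
  cat(sprintf("  E_ev (W)                      %.4f\n", x$E_ev))
  invisible(x)
}

# Absolute zero in degrees Celsius; the single Celsius->Kelvin boundary.
ZERO_C_IN_K <- 273.15

# absolute zero itself is admitted as a limiting value (T^4 = 0)
celsius_to_kelvin <- function(T_C) {
  if (any(T_C < -ZERO_C_IN_K)) {
    stop("temperature below absolute zero (-273.15 °C)", call. = FALSE)
  }
  T_C + ZERO_C_IN_K
}

#' Shade/sunshine classification threshold
#'
#' Visits are classified as sunshine when global radiation strictly exceeds
#' 100 W m^-2, otherwise as shade.  The threshold is centralised here and
#' used identically by the file reader, the synthetic generator and reports.
#'
#' @param G Global radiation, W m^-2 (vectorised).
#' @return `is_sunshine()`: logical vector, `TRUE` for sunshine.
#'   `sun_threshold()`: the threshold itself, W m^-2.
#' @examples
#' is_sunshine(c(3.4, 100, 100.1, 921))
#' @export
is_sunshine <- function(G) {
  stopifnot(is.numeric(G), all(G >= 0, na.rm = TRUE))
  G > sun_threshold()
}

#' @rdname is_sunshine
#' @export
sun_threshold <- function() 100
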