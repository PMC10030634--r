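#' Mean body surface temperature
#'
#' Unweighted mean of head, thorax and abdomen surface temperatures; this is
#' the `T_b` entering radiative loss and the whole-body convection term.
#'
#' @param visits A visit table (see [as_visits()]).
#' @return Numeric vector, degC.
#' @examples
#' v <- simulate_visits(synthetic_config(n_visits = 5), seed = 1)
#' mean_body_temperature(v)
#' @export
mean_body_temperature <- function(visits) {
  visits <- as_visits(visits)
  (visits$T_hd_C + visits$T_th_C + visits$T_ab_C) / 3
}

#' Whole-body convective heat loss
#'
#' Single-coefficient convection of the simple model:
#' \deqn{E_{cv} = h_b\,A_b\,(T_b - T_a)}
#' with `T_b` the mean of the three body-part surface temperatures.
#'
#' @param visits A visit table.
#' @param h_b Whole-body convection coefficient, W m^-2 degC^-1.
#' @param A_b Body surface area, m^2.
#' @return Convective heat loss per visit, W.
#' @examples
#' v <- simulate_visits(synthetic_config(n_visits = 3), seed = 1)
#' convection_simple(v, h_b = 12.14393, A_b = 163.7e-6)
#' @export
convection_simple <- function(visits, h_b, A_b) {
  visits <- as_visits(visits)
  T_b <- mean_body_temperature(visits)
  h_b * A_b * (T_b - visits$T_a_C)
}

#' Per-segment convective heat loss
#'
#' Convection summed over head, thorax and abdomen, each with its own
#' coefficient:
#' \deqn{E_{cv} = h_{hd} A_{hd}(T_{hd}-T_a) + h_{th} A_{th}(T_{th}-T_a)
#'   + h_{ab} A_{ab}(T_{ab}-T_a),}
#' where each segment coefficient is a linear function of air temperature,
#' `h = a + b * T_a` (variant `advanced_eq13`), or constant for the abdomen
#' (variant `advanced_eq14`).  The air-temperature dependence encodes the
#' finding that respiratory ventilation frequency — the main driver of
#' internal convective loss in stationary foragers — varies with air
#' temperature rather than with oxygen turnover.
#'
#' @param visits A visit table.
#' @param coeffs A [coefficient_set()] with variant `advanced_eq13` or
#'   `advanced_eq14`.
#' @param areas A [body_surface()] object.
#' @return Convective heat loss per visit, W.
#' @examples
#' v <- simulate_visits(synthetic_config(n_visits = 3), seed = 1)
#' convection_per_part(v, coef_preset("table2a"), body_surface())
#' @export
convection_per_part <- function(visits, coeffs, areas = body_surface()) {
  visits <- as_visits(visits)
  stopifnot(inherits(coeffs, "coefficient_set"), inherits(areas, "body_surface"))
  if (!coeffs$variant %in% c("advanced_eq13", "advanced_eq14")) {
    stop("convection_per_part() needs variant advanced_eq13 or advanced_eq14, got ",
      coeffs$variant,
      call. = FALSE
    )
  }
  k <- coeffs$values
  T_a <- visits$T_a_C
  h_hd <- k[["a_hhd"]] + k[["b_hhd"]] * T_a
  h_th <- k[["a_hth"]] + k[["b_hth"]] * T_a
  h_ab <- if (coeffs$variant == "advanced_eq13") {
    k[["a_hab"]] + k[["b_hab"]] * T_a
  } else {
    k[["h_ab"]]
  }
  h_hd * areas$A_hd * (visits$T_hd_C - T_a) +
    h_th * areas$A_th * (visits$T_th_C - T_a) +
    h_ab * areas$A_ab * (visits$T_ab_C - T_a)
}

#' Three-compartment convective heat loss
#'
#' Convection parameterised by internal temperature differences: head and
#' abdomen exchange heat with the thorax (the heat source, via haemolymph
#' circulation and ventilation) rather than directly with the air:
#' \deqn{E_{cv} = h_{thhd}(T_{th}-T_{hd}) + h_{th} A_{th}(T_{th}-T_a)
#'   + h_{thab}(T_{th}-T_{ab}).}
#' Only the thorax term carries an area factor; the head and abdomen
#' coefficients are absolute (W degC^-1).  Coefficients are linear in air
#' temperature (variant `three_comp_eq15`) or constant for the
#' thorax-abdomen exchange (variant `three_comp_eq16`).
#'
#' @inheritParams convection_per_part
#' @param coeffs A [coefficient_set()] with variant `three_comp_eq15` or
#'   `three_comp_eq16`.
#' @return Convective heat loss per visit, W.
#' @examples
#' v <- simulate_visits(synthetic_config(n_visits = 3), seed = 1)
#' convection_three_compartment(v, coef_preset("table3a"), body_surface())
#' @export
convection_three_compartment <- function(visits, coeffs,
                                         areas = body_surface()) {
  visits <- as_visits(visits)
  stopifnot(inherits(coeffs, "coefficient_set"), inherits(areas, "body_surface"))
  if (!coeffs$variant %in% c("three_comp_eq15", "three_comp_eq16")) {
    stop(
      "convection_three_compartment() needs variant three_comp_eq15 or three_comp_eq16, got ",
      coeffs$variant,
      call. = FALSE
    )
  }
  k <- coeffs$values
  T_a <- visits$T_a_C
  h_thhd <- k[["a_hthhd"]] + k[["b_hthhd"]] * T_a
  h_th <- k[["a_hth"]] + k[["b_hth"]] * T_a
  h_thab <- if (coeffs$variant == "three_comp_eq15") {
    k[["a_hthab"]] + k[["b_hthab"]] * T_a
  } else {
    k[["h_thab"]]
  }
  h_thhd * (visits$T_th_C - visits$T_hd_C) +
    h_th * areas$A_th * (visits$T_th_C - T_a) +
    h_thab * (visits$T_th_C - visits$T_ab_C)
}

#' Convective heat loss of any model variant
#'
#' Dispatches on the coefficient set's variant tag to the matching
#' convection term, so per-area (eq13/eq14) and absolute (eq15/eq16)
#' coefficient units can never be mixed.
#'
#' @inheritParams convection_per_part
#' @return Convective heat loss per visit, W.
#' @export
convective_loss <- function(visits, coeffs, areas = body_surface()) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  switch(coeffs$variant,
    simple_eq7 = convection_simple(visits, coeffs$values[["h_b"]], areas$A_b),
    advanced_eq13 = ,
    advanced_eq14 = convection_per_part(visits, coeffs, areas),
    three_comp_eq15 = ,
    three_comp_eq16 = convection_three_compartment(visits, coeffs, areas)
  )
}

#' Predict metabolic energy turnover from surface temperatures
#'
#' Evaluates the steady-state heat budget
#' \deqn{M = r_l R_{loss} - r_g R_{gain} + E_{cv} + e_{lev} E_{ev}}
#' for every visit: radiative loss from the mean body surface temperature,
#' radiative gain from the surroundings (infrared, blackbody closure at
#' `T_surround`) and from global radiation (solar), the variant's convective
#' term, and the weighted constant evaporative loss.  Conduction is
#' neglected (it occurs only through the leg tips and is very small).
#'
#' @param visits A visit table (see [as_visits()]).
#' @param coeffs A [coefficient_set()], e.g. from [coef_preset()].
#' @param areas A [body_surface()] object.
#' @param constants A [thermal_constants()] object.
#' @param T_surround Radiant surround temperature per visit, degC; defaults
#'   to ambient air temperature (blackbody-surroundings closure).
#' @param reflected_solar Include a ground-reflected solar term? See
#'   [solar_gain()].
#' @return A data.frame, one row per visit, with the prediction `M_W` and
#'   `M_mW` and its four components (`term_rloss_W = r_l R_loss`,
#'   `term_rgain_W = -r_g R_gain`, `term_ecv_W = E_cv`,
#'   `term_eev_W = e_lev E_ev`); the components sum exactly to `M_W`.
#' @examples
#' v <- simulate_visits(synthetic_config(n_visits = 5), seed = 1)
#' predict_metabolism(v, coef_preset("table2b"))
#' @export
predict_metabolism <- function(visits, coeffs, areas = body_surface(),
                               constants = thermal_constants(),
                               T_surround = NULL, reflected_solar = FALSE) {
  visits <- as_visits(visits)
  stopifnot(inherits(coeffs, "coefficient_set"))
  if (is.null(T_surround)) T_surround <- visits$T_a_C
  T_b <- mean_body_temperature(visits)
  rad <- radiation_budget(
    T_b = T_b, T_surround = T_surround, G = visits$G_Wm2,
    A_b = areas$A_b, constants = constants,
    reflected_solar = reflected_solar
  )
  k <- coeffs$values
  term_rloss <- k[["r_l"]] * rad$R_loss
  term_rgain <- -k[["r_g"]] * rad$R_gain
  term_ecv <- convective_loss(visits, coeffs, areas)
  term_eev <- k[["e_lev"]] * constants$E_ev
  M <- term_rloss + term_rgain + term_ecv + term_eev
  data.frame(
    M_W = M, M_mW = M * 1000,
    term_rloss_W = term_rloss, term_rgain_W = term_rgain,
    term_ecv_W = term_ecv, term_eev_W = term_eev
  )
}

#' Heat-conductance estimate
#'
#' Simple conductance estimate used as an exploratory statistic: energy
#' turnover divided by the body temperature excess over air,
#' `M / (T_b - T_a)`, in mW degC^-1.  Undefined (returned as `NA`) where
#' the body is at air temperature.
#'
#' @param M_mW Energy turnover, mW.
#' @param T_b Mean body surface temperature, degC.
#' @param T_a Ambient air temperature, degC.
#' @return Conductance estimate, mW degC^-1; `NA` where `T_b == T_a`.
#' @examples
#' conductance_estimate(50, 35, 25) # 5 mW/degC
#' @export
conductance_estimate <- function(M_mW, T_b, T_a) {
  dT <- T_b - T_a
  out <- ifelse(dT == 0, NA_real_, M_mW / dT)
  if (any(dT == 0)) {
    warning("conductance undefined where T_b == T_a; returned NA",
      call. = FALSE
    )
  }
  out
}
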