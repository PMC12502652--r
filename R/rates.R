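#' Temperature-dependent physiological rates
#'
#' The three rate laws that drive the steady-state allocation model:
#' a saturating-exponential light response of chlorophyll-specific carbon
#' fixation, a Q10 law for maintenance carbohydrate consumption, and an
#' Arrhenius law for biosynthetic capacity.
#'
#' @name rates
NULL

R_GAS <- 8.314  # J mol-1 K-1

#' Light-limited photosynthesis rate
#'
#' Chlorophyll-carbon-specific carbon fixation rate under irradiance `I`:
#' `Pmax_ref * (1 - exp(-a_I * I))`.  Monotone non-decreasing in `I` and
#' bounded above by `Pmax_ref`.
#'
#' @param I Irradiance (umol photons m^-2 s^-1), >= 0.  Vectorised.
#' @param params A [cell_parameters()] object.
#' @return Fixation rate (d^-1).
#' @export
#' @examples
#' light_limited_photosynthesis(100, cell_parameters(Pmax_ref = 6))
light_limited_photosynthesis <- function(I, params) {
  if (any(!is.finite(I)) || any(I < 0))
    stop("irradiance must be finite and >= 0")
  params$Pmax_ref * (1 - exp(-params$a_I * I))
}

#' Maintenance respiration rate
#'
#' Maintenance carbohydrate consumption at temperature `T_K`, following a Q10
#' law: `Rm_ref * Q10_R^((T_K - T_ref)/10)`.
#'
#' @param T_K Temperature in Kelvin, > 0.  Vectorised.
#' @inheritParams light_limited_photosynthesis
#' @return Respiration rate (d^-1).
#' @export
maintenance_respiration <- function(T_K, params) {
  if (any(!is.finite(T_K)) || any(T_K <= 0))
    stop("temperature must be finite and > 0 K")
  params$Rm_ref * params$Q10_R^((T_K - params$T_ref) / 10)
}

#' Biosynthetic capacity
#'
#' Growth rate deliverable per unit biosynthetic-pool carbon fraction at
#' temperature `T_K`, following an Arrhenius law:
#' `k_bio_ref * exp((Ea_bio / R) * (1/T_ref - 1/T_K))` with
#' R = 8.314 J mol^-1 K^-1.
#'
#' @param T_K Temperature in Kelvin, > 0.  Vectorised.
#' @inheritParams light_limited_photosynthesis
#' @return Biosynthetic capacity (d^-1).
#' @export
biosynthetic_capacity <- function(T_K, params) {
  if (any(!is.finite(T_K)) || any(T_K <= 0))
    stop("temperature must be finite and > 0 K")
  params$k_bio_ref * exp((params$Ea_bio / R_GAS) * (1 / params$T_ref - 1 / T_K))
}

#' Convert Celsius to Kelvin
#' @param T_C Temperature in degrees Celsius.
#' @return Temperature in Kelvin.
#' @export
celsius_to_kelvin <- function(T_C) T_C + 273.15
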