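#' Vehicle film thickness over time
#'
#' The film thins at the constant (zeroth-order) rate `kevap_veh` until
#' dry: `hv(t) = max(0, hv0 - kevap_veh * t)`.
#'
#' @param t Time in minutes (vectorised).
#' @param hv0 Initial thickness (cm, >= 0).
#' @param kevap_veh Thinning rate (cm/min, >= 0).
#' @return Thickness in cm.
#' @export
vehicle_thickness <- function(t, hv0, kevap_veh) {
  check_scalar(hv0, "hv0", nonneg = TRUE)
  check_scalar(kevap_veh, "kevap_veh", nonneg = TRUE)
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  pmax(0, hv0 - kevap_veh * t)
}

#' Time for the vehicle film to dry out
#'
#' `t_dry = hv0 / kevap_veh`. A non-evaporating vehicle
#' (`kevap_veh = 0`) never dries; `Inf` is returned.
#'
#' @param hv0 Initial film thickness (cm, >= 0).
#' @param kevap_veh Thinning rate (cm/min, >= 0).
#' @return Drying time in minutes (`Inf` when `kevap_veh = 0`).
#' @export
#' @examples
#' drying_time(0.01, 0.014) * 60  # ~43 s (ethanol)
#' drying_time(0.01, 0.0055) * 60 # ~109 s (aqueous)
drying_time <- function(hv0, kevap_veh) {
  check_scalar(hv0, "hv0", nonneg = TRUE)
  check_scalar(kevap_veh, "kevap_veh", nonneg = TRUE)
  if (kevap_veh == 0) {
    if (hv0 == 0) return(0)
    return(Inf)
  }
  hv0 / kevap_veh
}

#' Power-law evaporation correlation plug-in
#'
#' Builds a correlation object mapping wind velocity to the permeant
#' evaporative flux, `kevap_per = coefficient * u^exponent`. This is a
#' generic stand-in for boundary-layer mass-transfer correlations in
#' which the transfer coefficient grows as a fractional power of the
#' air velocity; any object with class `evaporation_correlation` that
#' is callable as `f(u, permeant)` and is monotone non-decreasing in
#' `u` may be supplied wherever a correlation is accepted.
#'
#' @param coefficient Flux at unit wind velocity
#'   (µg/cm²/min per (cm/min)^exponent, >= 0).
#' @param exponent Power on the wind velocity (>= 0, default 0.78).
#' @return A function of class `evaporation_correlation`.
#' @export
#' @examples
#' corr <- evaporation_correlation(0.05)
#' corr(43, NULL)
evaporation_correlation <- function(coefficient, exponent = 0.78) {
  check_scalar(coefficient, "coefficient", nonneg = TRUE)
  check_scalar(exponent, "exponent", nonneg = TRUE)
  f <- function(u, permeant = NULL) coefficient * u^exponent
  structure(f, class = c("evaporation_correlation", "function"),
            coefficient = coefficient, exponent = exponent)
}

#' Permeant evaporation rate
#'
#' Resolves the permeant's evaporative flux. With no correlation
#' configured the permeant's direct `kevap_per` value is passed
#' through; otherwise the correlation is evaluated at the given wind
#' velocity. A correlation returning a negative flux is rejected.
#'
#' @param u Wind velocity (cm/min, >= 0).
#' @param permeant A [permeant()].
#' @param correlation Optional [evaporation_correlation()] (or any
#'   callable accepting `(u, permeant)`).
#' @return kevap_per in µg/cm²/min.
#' @export
permeant_evaporation_rate <- function(u, permeant, correlation = NULL) {
  check_scalar(u, "u", nonneg = TRUE)
  if (is.null(correlation)) {
    return(permeant$kevap_per)
  }
  if (!is.function(correlation)) {
    stop("`correlation` must be a function of (u, permeant)", call. = FALSE)
  }
  k <- correlation(u, permeant)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0) {
    stop("evaporation correlation returned an invalid rate (", k,
         ") at u = ", u, call. = FALSE)
  }
  k
}
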