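#' Describe a diffusing permeant
#'
#' Collects the physicochemical and transport parameters of the chemical
#' being applied to the skin. All quantities use the package-wide unit
#' system of micrograms, centimetres and minutes.
#'
#' @param name Compound name.
#' @param mw Molecular weight (g/mol).
#' @param sw Water solubility (µg/cm³). Must be > 0.
#' @param sv Solubility in the applied vehicle (µg/cm³). Must be >= 0.
#' @param ksc_w Stratum corneum / water partition coefficient
#'   (dimensionless, > 0).
#' @param dsc Stratum corneum diffusivity (cm²/min, > 0).
#' @param kevap_per Permeant evaporative flux from the skin surface
#'   (µg/cm²/min, >= 0). May be superseded at simulation time by an
#'   evaporation correlation plug-in (see
#'   [permeant_evaporation_rate()]).
#'
#' @return An object of class `permeant`.
#' @seealso [vehicle_spec()], [exposure_scenario()], [derived_properties()]
#' @export
#' @examples
#' permeant("testosterone", mw = 288.4, sw = 23, sv = 4e5,
#'          ksc_w = 65, dsc = 6e-8)
permeant <- function(name, mw, sw, sv, ksc_w, dsc, kevap_per = 0) {
  check_scalar(mw, "mw", positive = TRUE)
  check_scalar(sw, "sw", positive = TRUE)
  check_scalar(sv, "sv", nonneg = TRUE)
  check_scalar(ksc_w, "ksc_w", positive = TRUE)
  check_scalar(dsc, "dsc", positive = TRUE)
  check_scalar(kevap_per, "kevap_per", nonneg = TRUE)
  structure(
    list(name = as.character(name), mw = mw, sw = sw, sv = sv,
         ksc_w = ksc_w, dsc = dsc, kevap_per = kevap_per),
    class = "permeant"
  )
}

#' Describe a vehicle (solvent)
#'
#' @param name Vehicle name, e.g. `"pbs"` or `"ethanol"`.
#' @param kevap_veh Zeroth-order thinning rate of the vehicle film
#'   (cm/min, >= 0).
#' @param eta_dep Deposition-layer proportion of the stratum corneum,
#'   in (0, 1]. The fraction of SC depth loaded by convection
#'   immediately upon application.
#' @param occluded If `TRUE`, the site is covered: all evaporation
#'   (vehicle and permeant) is disabled during simulation.
#'
#' @return An object of class `vehicle_spec`.
#' @export
#' @examples
#' vehicle_spec("ethanol", kevap_veh = 0.014, eta_dep = 0.05)
vehicle_spec <- function(name, kevap_veh, eta_dep, occluded = FALSE) {
  check_scalar(kevap_veh, "kevap_veh", nonneg = TRUE)
  check_scalar(eta_dep, "eta_dep", positive = TRUE)
  if (eta_dep > 1) {
    stop("`eta_dep` must lie in (0, 1]; got ", eta_dep, call. = FALSE)
  }
  structure(
    list(name = as.character(name), kevap_veh = kevap_veh,
         eta_dep = eta_dep, occluded = isTRUE(occluded)),
    class = "vehicle_spec"
  )
}

#' Describe the stratum corneum slab and its spatial resolution
#'
#' @param hsc Stratum corneum thickness in cm. The default 1.3e-3 cm
#'   (13 µm) corresponds to a partially hydrated SC.
#' @param n_nodes Number of finite-volume cells across the slab
#'   (integer >= 10; default 100).
#'
#' @return An object of class `skin_geometry`.
#' @export
skin_geometry <- function(hsc = 1.3e-3, n_nodes = 100) {
  check_scalar(hsc, "hsc", positive = TRUE)
  check_scalar(n_nodes, "n_nodes", positive = TRUE)
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 10L) {
    stop("`n_nodes` must be at least 10; got ", n_nodes, call. = FALSE)
  }
  structure(list(hsc = hsc, n_nodes = n_nodes), class = "skin_geometry")
}

#' Describe an exposure scenario
#'
#' @param m0 Applied dose per unit area (µg/cm², > 0).
#' @param hv0 Initial vehicle film thickness (cm, >= 0). A 10 µL dose
#'   spread over 1 cm² gives 0.01 cm.
#' @param u Ambient wind velocity (cm/min, >= 0); drives the permeant
#'   evaporation rate when a correlation plug-in is used.
#' @param t_end Exposure duration in minutes (default 1440, i.e. 24 h).
#'
#' @return An object of class `exposure_scenario`.
#' @export
exposure_scenario <- function(m0, hv0 = 0.01, u = 0, t_end = 1440) {
  check_scalar(m0, "m0", positive = TRUE)
  check_scalar(hv0, "hv0", nonneg = TRUE)
  check_scalar(u, "u", nonneg = TRUE)
  check_scalar(t_end, "t_end", positive = TRUE)
  structure(list(m0 = m0, hv0 = hv0, u = u, t_end = t_end),
            class = "exposure_scenario")
}

#' Derived partitioning quantities for a permeant/vehicle pair
#'
#' Computes the saturating SC concentration, the deposition-layer
#' capacity, and the vehicle/water and vehicle/SC partition
#' coefficients implied by the primary parameters.
#'
#' @param permeant A [permeant()].
#' @param vehicle A [vehicle_spec()].
#' @param geometry A [skin_geometry()].
#'
#' @return A one-row tibble with columns `csat` (µg/cm³), `msat`
#'   (µg/cm²), `kv_w` and `kv_sc` (dimensionless).
#' @export
derived_properties <- function(permeant, vehicle, geometry = skin_geometry()) {
  stopifnot(inherits(permeant, "permeant"), inherits(vehicle, "vehicle_spec"),
            inherits(geometry, "skin_geometry"))
  csat <- saturation_concentration(permeant$ksc_w, permeant$sw)
  kv_w <- vehicle_water_partition(permeant$sv, permeant$sw)
  tibble::tibble(
    csat = csat,
    msat = deposition_capacity(vehicle$eta_dep, geometry$hsc, csat),
    kv_w = kv_w,
    kv_sc = vehicle_sc_partition(kv_w, permeant$ksc_w)
  )
}

#' @export
print.permeant <- function(x, ...) {
  cat("<permeant> ", x$name, "\n", sep = "")
  cat(sprintf("  mw %.6g g/mol | Sw %.6g | Sv %.6g ug/cm3\n", x$mw, x$sw, x$sv))
  cat(sprintf("  Ksc/w %.6g | Dsc %.3g cm2/min | kevap_per %.3g ug/cm2/min\n",
              x$ksc_w, x$dsc, x$kevap_per))
  invisible(x)
}

#' @export
print.vehicle_spec <- function(x, ...) {
  cat("<vehicle_spec> ", x$name,
      sprintf(": kevap_veh %.4g cm/min, eta_dep %.4g", x$kevap_veh, x$eta_dep),
      if (x$occluded) " (occluded)" else "", "\n", sep = "")
  invisible(x)
}

# scalar validation shared by the constructors
check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number", call. = FALSE)
  }
  if (positive && x <= 0) {
    stop("`", name, "` must be > 0; got ", x, call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop("`", name, "` must be >= 0; got ", x, call. = FALSE)
  }
  invisible(x)
}
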