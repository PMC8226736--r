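#' Saturating stratum corneum concentration
#'
#' The highest permeant concentration the SC can hold, `Csat = Ksc/w * Sw`.
#'
#' @param ksc_w SC/water partition coefficient (> 0).
#' @param sw Water solubility (µg/cm³, > 0).
#' @return Csat in µg/cm³.
#' @export
#' @examples
#' saturation_concentration(50, 2000) # 1e5
saturation_concentration <- function(ksc_w, sw) {
  check_scalar(ksc_w, "ksc_w", positive = TRUE)
  check_scalar(sw, "sw", positive = TRUE)
  ksc_w * sw
}

#' Deposition-layer capacity
#'
#' Mass per area the deposition layer can absorb upon application:
#' `Msat = eta_dep * hsc * Csat`.
#'
#' @param eta_dep Deposition-layer proportion of the SC, in (0, 1].
#' @param hsc SC thickness (cm, > 0).
#' @param csat Saturating SC concentration (µg/cm³, >= 0).
#' @return Msat in µg/cm².
#' @export
#' @examples
#' deposition_capacity(0.03, 1.3e-3, 1e6) # 39
deposition_capacity <- function(eta_dep, hsc, csat) {
  check_scalar(eta_dep, "eta_dep", positive = TRUE)
  if (eta_dep > 1) {
    stop("`eta_dep` must lie in (0, 1]; got ", eta_dep, call. = FALSE)
  }
  check_scalar(hsc, "hsc", positive = TRUE)
  check_scalar(csat, "csat", nonneg = TRUE)
  eta_dep * hsc * csat
}

#' Initial mass remaining on the skin surface
#'
#' The part of the dose not taken up by the deposition layer:
#' `Msurf(0) = max(0, M0 - Msat)`.
#'
#' @param m0 Applied dose per area (µg/cm², > 0).
#' @param msat Deposition-layer capacity (µg/cm², >= 0).
#' @return Msurf(0) in µg/cm²; never negative.
#' @export
initial_surface_mass <- function(m0, msat) {
  check_scalar(m0, "m0", positive = TRUE)
  check_scalar(msat, "msat", nonneg = TRUE)
  max(0, m0 - msat)
}

#' Initial SC concentration profile
#'
#' Loads the deposition layer uniformly at `min(M0 / (eta_dep * hsc), Csat)`
#' and leaves the deeper SC empty. The profile integrates to
#' `min(M0, Msat)` so that, together with [initial_surface_mass()], the
#' applied dose is conserved exactly.
#'
#' @param m0 Applied dose per area (µg/cm²).
#' @param grid A grid from [build_grid()]; its interface must sit on a
#'   cell boundary (build_grid guarantees this).
#' @param csat Saturating SC concentration (µg/cm³).
#' @return Numeric vector of cell concentrations (µg/cm³), one per grid cell.
#' @export
initial_sc_profile <- function(m0, grid, csat) {
  check_scalar(m0, "m0", positive = TRUE)
  check_scalar(csat, "csat", nonneg = TRUE)
  stopifnot(inherits(grid, "sc_grid"))
  a <- grid$a
  c_dep <- min(m0 / a, csat)
  ifelse(grid$z_centers < a, c_dep, 0)
}

#' Vehicle/water partition coefficient
#'
#' `Kv/w = Sv / Sw`.
#'
#' @param sv Vehicle solubility (µg/cm³, >= 0).
#' @param sw Water solubility (µg/cm³, > 0).
#' @return Dimensionless ratio.
#' @export
vehicle_water_partition <- function(sv, sw) {
  check_scalar(sv, "sv", nonneg = TRUE)
  check_scalar(sw, "sw", positive = TRUE)
  sv / sw
}

#' Vehicle/stratum corneum partition coefficient
#'
#' `Kv/sc = Kv/w / Ksc/w`. For a saturated vehicle (`cv = Sv`) the
#' equilibrated SC surface concentration `Sv / Kv/sc` equals `Csat`
#' identically.
#'
#' @param kv_w Vehicle/water partition coefficient (>= 0).
#' @param ksc_w SC/water partition coefficient (> 0).
#' @return Dimensionless ratio.
#' @export
vehicle_sc_partition <- function(kv_w, ksc_w) {
  check_scalar(kv_w, "kv_w", nonneg = TRUE)
  check_scalar(ksc_w, "ksc_w", positive = TRUE)
  kv_w / ksc_w
}

#' Dissolved permeant concentration in the vehicle film
#'
#' `cv = min(Sv, Msurf / hv)`. Surface permeant in excess of solubility
#' is treated as precipitated solid (tracked implicitly as
#' `Msurf - cv * hv`) and does not drive diffusion.
#'
#' @param msurf Surface mass per area (µg/cm², >= 0).
#' @param hv Current vehicle film thickness (cm, > 0). Callers must
#'   branch on the dried-out state (`hv = 0`) before calling.
#' @param sv Vehicle solubility (µg/cm³, >= 0).
#' @return cv in µg/cm³.
#' @export
dissolved_vehicle_concentration <- function(msurf, hv, sv) {
  check_scalar(msurf, "msurf", nonneg = TRUE)
  check_scalar(sv, "sv", nonneg = TRUE)
  if (!is.numeric(hv) || length(hv) != 1L || !is.finite(hv) || hv <= 0) {
    stop("`hv` must be > 0; the dried-out state (hv = 0) must be handled ",
         "by the caller", call. = FALSE)
  }
  min(sv, msurf / hv)
}
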