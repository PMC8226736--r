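# Shared fixtures and independent oracles.

# Analytic cumulative mass through the base of a membrane of thickness
# h with constant surface concentration c0 at z = 0, a perfect sink at
# z = h, and an initial condition c(z,0) = c0 on [0, a), 0 elsewhere.
# Eigenfunction series: c = c0 (1 - z/h) + sum B_n sin(n pi z / h)
# exp(-lambda_n t) with B_n = -(2 c0 / (n pi)) cos(n pi a / h), from
# projecting (IC - steady state) on the sine basis. Cumulative flux
# through z = h follows by integrating -D dc/dz|_h in time. With a = 0
# this reduces to the classical lag-time solution
# Q = (D c0 / h)(t - h^2/(6D)) + transients.
membrane_lag_cumulative <- function(t, D, h, c0, a = 0, n_terms = 400) {
  n <- seq_len(n_terms)
  lam <- D * n^2 * pi^2 / h^2
  Bn <- -(2 * c0 / (n * pi)) * cos(n * pi * a / h)
  vapply(t, function(tt) {
    D * c0 * tt / h -
      sum(Bn * (-1)^n * (h / (n * pi)) * (1 - exp(-lam * tt)))
  }, numeric(1))
}

make_permeant <- function(name = "probe", sw = 100, sv = 5000,
                          ksc_w = 50, dsc = 1e-7, kevap_per = 0.02,
                          mw = 250) {
  permeant(name, mw = mw, sw = sw, sv = sv, ksc_w = ksc_w, dsc = dsc,
           kevap_per = kevap_per)
}

make_vehicle <- function(name = "pbs", kevap_veh = 0.0055,
                         eta_dep = 0.03, occluded = FALSE) {
  vehicle_spec(name, kevap_veh = kevap_veh, eta_dep = eta_dep,
               occluded = occluded)
}

# 3 compounds x 2 solvents, slow diffusivities so all three outputs stay
# informative at 24 h; used by the synthetic-recovery tests
recovery_scenarios <- function() {
  tibble::tibble(
    compound = rep(c("cmpd_lipophilic", "cmpd_moderate", "cmpd_polar"),
                   each = 2),
    mw       = rep(c(228, 194, 362), each = 2),
    sw       = rep(c(120, 500, 320), each = 2),
    ksc_w    = rep(c(80, 25, 8), each = 2),
    dsc      = rep(c(3e-10, 1.2e-9, 1e-10), each = 2),
    solvent  = rep(c("pbs", "ethanol"), 3),
    sv       = c(120, 4e5, 500, 3e5, 320, 2e5),
    dose     = c(1.0, 8.0, 4.0, 15.0, 2.5, 10.0),
    hv0      = 0.01
  )
}

recovery_truth_params <- function() {
  c(u = 0.68, eta_dep_pbs = 0.03, eta_dep_ethanol = 0.05,
    kevap_veh_pbs = 0.0055, kevap_veh_ethanol = 0.014)
}

recovery_correlation <- function() evaporation_correlation(0.001, 0.78)

# noise-free synthetic observations with nominal 5%-of-mean weighting
# SDs (the SD-weighted objective is undefined at literal zero SDs)
recovery_dataset <- function(geometry = skin_geometry(n_nodes = 40)) {
  truth <- synthetic_truth("B", recovery_truth_params(), cv = 0,
                           seed = 7L)
  data <- generate_ivpt_dataset(truth, recovery_scenarios(),
                                correlation = recovery_correlation(),
                                geometry = geometry,
                                times = c(0, 1440),
                                rtol = 1e-6, atol = 1e-9)
  data$sw_sd <- pmax(0.05 * data$sw_mean, 1e-3)
  data$sc_sd <- pmax(0.05 * data$sc_mean, 1e-3)
  data$dd_sd <- pmax(0.05 * data$dd_mean, 1e-3)
  data
}

expect_mass_conserved <- function(sim, tol = 1e-6) {
  expect_lt(sim$diagnostics$mass_error_max, tol)
}
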