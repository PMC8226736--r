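# Synthetic IVPT generator. Emulates the replicate design of a
# finite-dose permeation test: the designated model is simulated at
# known parameters and replicate outcomes are drawn by multiplicative
# lognormal noise around each terminal output, so the generated table
# carries a ground truth against which calibration can be scored.

#' Define the ground truth for a synthetic IVPT set
#'
#' @param model `"A"` or `"B"`.
#' @param parameters Named list/vector of generating parameters: `u`
#'   plus, for model B, per-solvent `eta_dep_*` and `kevap_veh_*`
#'   (the names used by [model_b_objective()]).
#' @param cv Coefficient of variation of the multiplicative replicate
#'   noise (>= 0; 0 gives noise-free observations).
#' @param n_replicates Replicates per output (>= 2 whenever `cv > 0`,
#'   mirroring multi-section experimental designs; default 12, i.e.
#'   three sections from each of four donors).
#' @param seed Integer seed; all randomness in generation flows from
#'   it.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(model = c("A", "B"), parameters, cv = 0,
                            n_replicates = 12, seed = 1L) {
  model <- match.arg(model)
  check_scalar(cv, "cv", nonneg = TRUE)
  check_scalar(n_replicates, "n_replicates", positive = TRUE)
  if (cv > 0 && n_replicates < 2) {
    stop("`n_replicates` must be >= 2 when replicate SDs are requested",
         call. = FALSE)
  }
  if (!"u" %in% names(parameters)) {
    stop("`parameters` must include the wind velocity `u`", call. = FALSE)
  }
  structure(
    list(model = model, parameters = unlist(parameters), cv = cv,
         n_replicates = as.integer(n_replicates), seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

# mean-preserving multiplicative lognormal noise at a given CV
.replicate_noise <- function(values, cv, n) {
  if (cv == 0) {
    return(lapply(values, function(v) rep(v, n)))
  }
  sdlog <- sqrt(log(1 + cv^2))
  lapply(values, function(v) {
    v * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  })
}

#' Generate one synthetic IVPT observation
#'
#' Simulates the truth's model for the given compound/vehicle/exposure,
#' then draws `n_replicates` noisy replicate outcomes of the three 24 h
#' outputs and summarises them into an observation row (means and SDs).
#' With `cv = 0` the observation equals the simulation exactly and the
#' SDs are zero. Fully reproducible from the truth's seed.
#'
#' @param truth A [synthetic_truth()].
#' @param permeant A [permeant()].
#' @param exposure An [exposure_scenario()] (its `u` is overridden by
#'   the truth's).
#' @param solvent Solvent label routing model B to its per-solvent
#'   parameters (`"pbs"` or `"ethanol"`).
#' @param correlation Evaporation correlation used to map the truth's
#'   wind velocity to `kevap_per`.
#' @param geometry A [skin_geometry()].
#' @param ... Further arguments passed to the simulator (e.g. `times`,
#'   `rtol`).
#' @return A list with `observation` (one-row tibble in the
#'   [read_ivpt_table()] format) and `simulation` (the underlying
#'   `sc_simulation`).
#' @export
generate_synthetic_ivpt <- function(truth, permeant, exposure,
                                    solvent = "pbs", correlation = NULL,
                                    geometry = skin_geometry(), ...) {
  stopifnot(inherits(truth, "synthetic_truth"))
  th <- truth$parameters
  expo <- exposure_scenario(m0 = exposure$m0, hv0 = exposure$hv0,
                            u = th[["u"]], t_end = exposure$t_end)
  sim <- if (truth$model == "A") {
    simulate_model_a(permeant, expo, geometry, correlation = correlation,
                     ...)
  } else {
    veh <- vehicle_spec(solvent,
                        kevap_veh = th[[paste0("kevap_veh_", solvent)]],
                        eta_dep = th[[paste0("eta_dep_", solvent)]])
    simulate_model_b(permeant, veh, expo, geometry,
                     correlation = correlation, ...)
  }
  outputs <- c(sw = sim$terminal$sw, sc = sim$terminal$sc_accum,
               dd = sim$terminal$dd)
  reps <- withr_seed(truth$seed, function() {
    .replicate_noise(outputs, truth$cv, truth$n_replicates)
  })
  obs <- tibble::tibble(
    compound = permeant$name, solvent = solvent, dose = expo$m0,
    sw_mean = mean(reps[[1]]), sw_sd = stats::sd(reps[[1]]),
    sc_mean = mean(reps[[2]]), sc_sd = stats::sd(reps[[2]]),
    dd_mean = mean(reps[[3]]), dd_sd = stats::sd(reps[[3]])
  )
  list(observation = obs, simulation = sim)
}

#' Generate a synthetic IVPT dataset
#'
#' Applies [generate_synthetic_ivpt()] to every row of a scenario
#' table, advancing the seed per experiment so the whole set is
#' reproducible from the truth's single seed.
#'
#' @param truth A [synthetic_truth()].
#' @param scenarios Tibble with one row per IVPT: compound parameter
#'   columns (`compound`, `mw`, `sw`, `sv`, `ksc_w`, `dsc`), `solvent`,
#'   `dose`, `hv0` and optional `t_end` (default 1440).
#' @param correlation Evaporation correlation for the permeant flux.
#' @param geometry A [skin_geometry()].
#' @param ... Passed to the simulators.
#' @return Tibble of synthetic observations (one row per scenario)
#'   carrying the scenario's compound parameters, ready for
#'   [calibration_problem()].
#' @export
generate_ivpt_dataset <- function(truth, scenarios, correlation = NULL,
                                  geometry = skin_geometry(), ...) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!"t_end" %in% names(scenarios)) scenarios$t_end <- 1440
  purrr::map_dfr(seq_len(nrow(scenarios)), function(i) {
    row <- scenarios[i, ]
    perm <- permeant(row$compound, mw = row$mw, sw = row$sw, sv = row$sv,
                     ksc_w = row$ksc_w, dsc = row$dsc)
    expo <- exposure_scenario(m0 = row$dose, hv0 = row$hv0,
                              u = truth$parameters[["u"]],
                              t_end = row$t_end)
    truth_i <- truth
    truth_i$seed <- truth$seed + i - 1L
    out <- generate_synthetic_ivpt(truth_i, perm, expo,
                                   solvent = row$solvent,
                                   correlation = correlation,
                                   geometry = geometry, ...)
    dplyr::bind_cols(out$observation,
                     dplyr::select(row, "mw", "sw", "sv", "ksc_w", "dsc",
                                   "hv0", "t_end"),
                     .name_repair = "minimal")
  })
}

#' Deposition-layer capacity report
#'
#' For each record, evaluates the fixed-deposition model's theoretical
#' capacity `Msat = 0.1 * hsc * Csat` and flags experiments whose
#' capacity exceeds the applied dose (where that model would predict
#' complete uptake on application, leaving no skin wash).
#'
#' @param records Tibble with columns `compound`, `dose`, `sw_mean`,
#'   `ksc_w` and `sw` (water solubility). Records with missing
#'   `ksc_w`/`sw` are skipped with a warning.
#' @param eta_dep Deposition-layer proportion (default 0.1).
#' @param hsc SC thickness in cm (default 1.3e-3).
#' @return Tibble of `compound`, `dose`, `msat`,
#'   `capacity_exceeds_dose`, `sw_mean`.
#' @export
deposition_capacity_report <- function(records, eta_dep = 0.1,
                                       hsc = 1.3e-3) {
  need <- c("compound", "dose", "sw_mean", "ksc_w", "sw")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("`records` is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ok <- !is.na(records$ksc_w) & !is.na(records$sw)
  if (any(!ok)) {
    warning(sum(!ok), " record(s) skipped for missing Csat inputs (",
            paste(records$compound[!ok], collapse = ", "), ")",
            call. = FALSE)
    records <- records[ok, ]
  }
  dplyr::transmute(
    tibble::as_tibble(records),
    compound = .data$compound,
    dose = .data$dose,
    msat = purrr::map2_dbl(.data$ksc_w, .data$sw, function(k, s) {
      deposition_capacity(eta_dep, hsc, saturation_concentration(k, s))
    }),
    capacity_exceeds_dose = .data$msat > .data$dose,
    sw_mean = .data$sw_mean
  )
}
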