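# Maximum-likelihood calibration. The fixed-deposition model exposes a
# single free parameter (the wind velocity u, acting through the
# permeant evaporation correlation) fitted by minimising the summed
# squared mass-balance errors; the evaporating-vehicle model exposes
# five (u plus per-solvent eta_dep and kevap_veh) fitted by minimising
# the summed SD-weighted squared output errors. Both objectives are the
# negated log-likelihood up to an additive constant, so the minimiser
# is the maximum-likelihood estimate and differences feed straight into
# AIC comparison.

.default_parameters <- function(model) {
  if (model == "A") {
    tibble::tibble(name = "u", init = 10, lower = 1e-3, upper = 1e4,
                   transform = "log")
  } else {
    tibble::tibble(
      name = c("u", "eta_dep_pbs", "eta_dep_ethanol",
               "kevap_veh_pbs", "kevap_veh_ethanol"),
      init = c(1, 0.05, 0.05, 0.005, 0.01),
      lower = c(1e-3, 1e-4, 1e-4, 1e-6, 1e-6),
      upper = c(1e4, 1, 1, 10, 10),
      transform = c("log", "logit", "logit", "log", "log")
    )
  }
}

#' Define a calibration problem
#'
#' Binds the model choice, the IVPT observations with their compound
#' parameters, the free-parameter table and the optimiser options into
#' one object consumed by [model_a_objective()], [model_b_objective()]
#' and [calibrate()].
#'
#' @param model `"A"` or `"B"`.
#' @param data A tibble with one row per IVPT carrying the observation
#'   columns (`compound`, `solvent`, `dose`, `sw_mean`, `sw_sd`,
#'   `sc_mean`, `sc_sd`, `dd_mean`, `dd_sd`; SDs may be `NA`), the
#'   compound parameters (`mw`, `sw`, `sv`, `ksc_w`, `dsc` — note `sw`
#'   is the water solubility while `sw_mean`/`sw_sd` are the skin
#'   wash), and the exposure (`hv0`; optional `t_end`, default 1440).
#' @param correlation Evaporation correlation mapping the candidate
#'   wind velocity to `kevap_per` (see [evaporation_correlation()]).
#'   Required: without it the wind velocity has no effect on either
#'   model.
#' @param parameters Free-parameter table with columns `name`, `init`,
#'   `lower`, `upper`, `transform` (`"log"`, `"logit"` or
#'   `"identity"`). Defaults to the model's standard parameter space.
#' @param geometry [skin_geometry()] used for the embedded simulations
#'   (a coarser grid than the reporting default keeps the fit cheap;
#'   the same grid is used for every candidate, so discretisation
#'   error cancels across the comparison).
#' @param options List of optimiser options: `maxit` (default 800),
#'   `reltol` (1e-10), `rtol`/`atol` solver tolerances (1e-6/1e-9),
#'   `penalty` for failed simulations (1e12), `n_starts` additional
#'   seeded multistarts (default 0, fully deterministic), `seed` for
#'   the multistart jitter.
#' @return An object of class `calibration_problem`.
#' @export
calibration_problem <- function(model = c("A", "B"), data,
                                correlation,
                                parameters = NULL,
                                geometry = skin_geometry(n_nodes = 40),
                                options = list()) {
  model <- match.arg(model)
  if (!is.null(data)) {
    need <- c("compound", "solvent", "dose", "sw_mean", "sc_mean", "dd_mean",
              "hv0", "mw", "sw", "sv", "ksc_w", "dsc")
    if (model == "B") need <- c(need, "sw_sd", "sc_sd", "dd_sd")
    miss <- setdiff(need, names(data))
    if (length(miss)) {
      stop("calibration data is missing columns: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    if (model == "B" && !all(data$solvent %in% c("pbs", "ethanol"))) {
      stop("model B calibration supports pbs and ethanol solvents only",
           call. = FALSE)
    }
  }
  if (is.null(parameters)) parameters <- .default_parameters(model)
  stopifnot(all(c("name", "init", "lower", "upper", "transform") %in%
                  names(parameters)))
  if (!all(parameters$transform %in% c("log", "logit", "identity"))) {
    stop("transforms must be log, logit or identity", call. = FALSE)
  }
  if (any(parameters$init <= parameters$lower |
            parameters$init >= parameters$upper)) {
    stop("initial values must lie strictly inside their bounds",
         call. = FALSE)
  }
  opts <- utils::modifyList(
    list(maxit = 800, reltol = 1e-10, rtol = 1e-6, atol = 1e-9,
         penalty = 1e12, n_starts = 0, seed = 1L),
    options
  )
  if (!is.null(data) && !"t_end" %in% names(data)) data$t_end <- 1440
  structure(
    list(model = model,
         data = if (is.null(data)) NULL else tibble::as_tibble(data),
         correlation = correlation, parameters = parameters,
         geometry = geometry, options = opts,
         log_env = new.env(parent = emptyenv())),
    class = "calibration_problem"
  )
}

# parameter transforms keep every Nelder-Mead iterate feasible
.to_internal <- function(x, par_tbl) {
  mapply(function(v, tr, lo, up) {
    switch(tr,
           log = log(v),
           logit = stats::qlogis((v - lo) / (up - lo)),
           identity = v)
  }, x, par_tbl$transform, par_tbl$lower, par_tbl$upper)
}

.from_internal <- function(z, par_tbl) {
  out <- mapply(function(v, tr, lo, up) {
    switch(tr,
           log = exp(v),
           logit = lo + (up - lo) * stats::plogis(v),
           identity = v)
  }, z, par_tbl$transform, par_tbl$lower, par_tbl$upper)
  stats::setNames(out, par_tbl$name)
}

# simulate every IVPT row of a problem at the candidate parameters;
# returns the data with sw_pred/sc_pred/dd_pred columns appended
.predict_problem <- function(problem, theta) {
  data <- problem$data
  opts <- problem$options
  u <- theta[["u"]]
  preds <- purrr::map(seq_len(nrow(data)), function(i) {
    row <- data[i, ]
    perm <- permeant(row$compound, mw = row$mw, sw = row$sw, sv = row$sv,
                     ksc_w = row$ksc_w, dsc = row$dsc)
    expo <- exposure_scenario(m0 = row$dose, hv0 = row$hv0, u = u,
                              t_end = row$t_end)
    sim <- if (problem$model == "A") {
      simulate_model_a(perm, expo, problem$geometry,
                       correlation = problem$correlation,
                       times = c(0, row$t_end),
                       rtol = opts$rtol, atol = opts$atol)
    } else {
      veh <- vehicle_spec(row$solvent,
                          kevap_veh = theta[[paste0("kevap_veh_",
                                                    row$solvent)]],
                          eta_dep = theta[[paste0("eta_dep_",
                                                  row$solvent)]])
      simulate_model_b(perm, veh, expo, problem$geometry,
                       correlation = problem$correlation,
                       times = c(0, row$t_end),
                       rtol = opts$rtol, atol = opts$atol)
    }
    sim$terminal
  })
  data$sw_pred <- purrr::map_dbl(preds, "sw")
  data$sc_pred <- purrr::map_dbl(preds, "sc_accum")
  data$dd_pred <- purrr::map_dbl(preds, "dd")
  data
}

.log_failure <- function(problem, theta, err) {
  env <- problem$log_env
  env$failures <- c(env$failures %||% character(0),
                    paste0("theta = (",
                           paste(signif(theta, 4), collapse = ", "),
                           "): ", conditionMessage(err)))
}

#' Calibration objective for the fixed-deposition model
#'
#' Simulates every IVPT in the problem at the candidate wind velocity
#' and returns the sum of squared mass-balance errors (percentage
#' points); its negation is the model's log-likelihood up to a
#' constant.
#'
#' @param u Candidate wind velocity (cm/min, >= 0).
#' @param problem A [calibration_problem()] with `model = "A"`.
#' @return The objective value (>= 0); failed simulations contribute
#'   the configured penalty and are logged on the problem.
#' @export
model_a_objective <- function(u, problem) {
  stopifnot(inherits(problem, "calibration_problem"),
            problem$model == "A")
  theta <- c(u = u)
  tryCatch({
    pred <- .predict_problem(problem, theta)
    sum(mass_balance_error(pred)^2)
  }, error = function(e) {
    .log_failure(problem, theta, e)
    problem$options$penalty
  })
}

#' Calibration objective for the evaporating-vehicle model
#'
#' Simulates every IVPT at the candidate parameter vector, routing each
#' experiment to its solvent's `eta_dep` and `kevap_veh`, and returns
#' the summed SD-weighted squared errors of skin wash, SC accumulation
#' and dermal delivery (terms with missing SDs are skipped).
#'
#' @param theta Named vector with elements `u`, `eta_dep_pbs`,
#'   `eta_dep_ethanol`, `kevap_veh_pbs`, `kevap_veh_ethanol` (only the
#'   solvents present in the data are required).
#' @param problem A [calibration_problem()] with `model = "B"`.
#' @return The objective value (>= 0).
#' @export
model_b_objective <- function(theta, problem) {
  stopifnot(inherits(problem, "calibration_problem"),
            problem$model == "B")
  tryCatch({
    pred <- .predict_problem(problem, theta)
    err <- suppressWarnings(ivpt_error(pred))
    sum(err$e_total2)
  }, error = function(e) {
    .log_failure(problem, theta, e)
    problem$options$penalty
  })
}

.problem_objective <- function(problem) {
  if (problem$model == "A") {
    function(theta) model_a_objective(theta[["u"]], problem)
  } else {
    function(theta) model_b_objective(theta, problem)
  }
}

#' Fit a calibration problem by Nelder-Mead search
#'
#' Minimises the problem's objective over log/logit-transformed
#' parameters with the Nelder-Mead simplex, so every iterate respects
#' the bounds. Deterministic given the problem (optional multistarts
#' draw their jitter from the problem's seed). A custom objective can
#' be supplied for testing the optimiser in isolation.
#'
#' @param problem A [calibration_problem()].
#' @param objective Objective function of a named natural-scale
#'   parameter vector; defaults to the problem's model objective.
#' @return An object of class `dermavol_fit`: parameter table with
#'   estimates, objective at the optimum and at the initial point,
#'   evaluation count, convergence flag, evaluation trace, per-IVPT
#'   error breakdown at the optimum and any logged simulation
#'   failures.
#' @export
calibrate <- function(problem, objective = NULL) {
  stopifnot(inherits(problem, "calibration_problem"))
  par_tbl <- problem$parameters
  opts <- problem$options
  model_objective <- is.null(objective)
  if (model_objective) objective <- .problem_objective(problem)

  trace <- new.env(parent = emptyenv())
  trace$values <- numeric(0)
  f_internal <- function(z) {
    theta <- .from_internal(z, par_tbl)
    val <- objective(theta)
    trace$values <- c(trace$values, val)
    val
  }

  z0 <- .to_internal(par_tbl$init, par_tbl)
  f0 <- f_internal(z0)

  run_one <- function(z_start) {
    if (opts$maxit <= 0) {
      return(list(par = z_start, value = f_internal(z_start),
                  counts = c(`function` = 1), convergence = 1L,
                  message = "zero-iteration budget: initial point returned"))
    }
    if (length(z_start) == 1L) {
      # Nelder-Mead is unreliable in 1-D; golden-section bracketing on
      # the transformed axis is the standard substitute
      o <- stats::optimize(function(z) f_internal(z),
                           interval = z_start + c(-8, 8),
                           tol = opts$reltol^0.5)
      return(list(par = o$minimum, value = o$objective,
                  counts = c(`function` = NA), convergence = 0L,
                  message = NULL))
    }
    stats::optim(z_start, f_internal, method = "Nelder-Mead",
                 control = list(maxit = opts$maxit,
                                reltol = opts$reltol))
  }

  fits <- list(run_one(z0))
  if (opts$n_starts > 0) {
    jitter <- withr_seed(opts$seed, function() {
      matrix(stats::rnorm(opts$n_starts * length(z0), sd = 0.25),
             nrow = opts$n_starts)
    })
    for (s in seq_len(opts$n_starts)) {
      fits[[s + 1]] <- run_one(z0 + jitter[s, ])
    }
  }
  best <- fits[[which.min(purrr::map_dbl(fits, "value"))]]

  theta_hat <- .from_internal(best$par, par_tbl)
  value_check <- objective(theta_hat)
  par_out <- dplyr::mutate(par_tbl, estimate = as.numeric(theta_hat))

  per_ivpt <- NULL
  if (model_objective && inherits(problem$data, "data.frame") &&
      nrow(problem$data) > 0) {
    per_ivpt <- tryCatch({
      pred <- .predict_problem(problem, theta_hat)
      pred$emb <- mass_balance_error(pred)
      if (problem$model == "B") suppressWarnings(ivpt_error(pred))
      else pred
    }, error = function(e) NULL)
  }

  structure(
    list(model = problem$model, parameters = par_out,
         objective = value_check, objective_init = f0,
         n_evals = length(trace$values),
         convergence = best$convergence,
         converged = identical(best$convergence, 0L),
         message = best$message,
         trace = tibble::tibble(eval = seq_along(trace$values),
                                value = trace$values),
         per_ivpt = per_ivpt,
         failures = problem$log_env$failures %||% character(0)),
    class = "dermavol_fit"
  )
}

# seeded evaluation without touching the caller's RNG stream
withr_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dermavol_fit <- function(x, ...) {
  cat("<dermavol_fit> Model ", x$model, " calibration\n", sep = "")
  cat(sprintf("  objective %.6g (from %.6g at start) after %d evaluations%s\n",
              x$objective, x$objective_init, x$n_evals,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(dplyr::select(x$parameters, "name", "init", "estimate"))
  if (length(x$failures)) {
    cat("  ", length(x$failures), "simulation failure(s) penalised\n")
  }
  invisible(x)
}

#' Tidy the parameter estimates of a calibration fit
#'
#' @param x A `dermavol_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `name`, `init`,
#'   `estimate`, bounds and transform.
#' @method tidy dermavol_fit
#' @export
tidy.dermavol_fit <- function(x, ...) {
  dplyr::select(x$parameters, "name", "init", "estimate", "lower",
                "upper", "transform")
}

#' One-row summary of a calibration fit
#'
#' @param x A `dermavol_fit`.
#' @param ... Unused.
#' @return One-row tibble: model, objective at optimum and start,
#'   evaluation count, convergence, failure count.
#' @method glance dermavol_fit
#' @export
glance.dermavol_fit <- function(x, ...) {
  tibble::tibble(model = x$model, objective = x$objective,
                 objective_init = x$objective_init,
                 n_evals = x$n_evals, converged = x$converged,
                 n_failures = length(x$failures))
}
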