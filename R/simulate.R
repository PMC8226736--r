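# Finite-volume method-of-lines transport engine.
#
# Both models integrate the 1-D Fickian diffusion equation
#   dc/dt = Dsc d2c/dz2   on z in [0, hsc]
# with a perfect sink at z = hsc and a model-specific surface condition,
# using a conservative finite-volume discretisation on the two-zone grid
# from build_grid(). The ODE state is ordered
#   y = (Msurf, c_1, ..., c_n, dd_cum, evap_cum)
# so the Jacobian is tridiagonal and deSolve's banded lsoda/lsodar can
# be used. The right-hand side is discontinuous across regimes (vehicle
# present / dried out / surface depleted), so each regime gets its own
# branch-free RHS and the integration is restarted at the analytic
# dry-out time and at the Msurf = 0 root.

# flux on every interior face plus the sink face; F = -D dc/dz, positive
# into the skin
.face_fluxes <- function(cs, D, zc, hsc) {
  n <- length(cs)
  Ff <- numeric(n + 1)
  if (n > 1) Ff[2:n] <- -D * diff(cs) / diff(zc)
  Ff[n + 1] <- D * cs[n] / (hsc - zc[n])
  Ff
}

# Model B regime (i): vehicle film present, surface mass present.
# Top boundary in partition equilibrium with the dissolved vehicle
# concentration: c(0, t) = min(Sv, Msurf/hv) / Kv_sc.
.rhs_donor <- function(t, y, p) {
  n <- p$n
  ms <- y[1]
  cs <- y[2:(n + 1)]
  hv <- max(p$hv0 - p$kveh * t, 1e-300)
  c0 <- min(p$sv, max(ms, 0) / hv) / p$kv_sc
  Ff <- .face_fluxes(cs, p$dsc, p$zc, p$hsc)
  Ff[1] <- -p$dsc * (cs[1] - c0) / p$zc[1]
  list(c(-p$kper - Ff[1],
         (Ff[1:n] - Ff[2:(n + 1)]) / p$dz,
         Ff[n + 1],
         p$kper))
}

# Zero-flux top boundary; `evaporating` controls whether Msurf is still
# being stripped by permeant evaporation (Model B dried-out regime) or
# is frozen (post-depletion regime in both models).
.rhs_sealed <- function(evaporating) {
  force(evaporating)
  function(t, y, p) {
    n <- p$n
    cs <- y[2:(n + 1)]
    Ff <- .face_fluxes(cs, p$dsc, p$zc, p$hsc)
    dms <- if (evaporating) -p$kper else 0
    list(c(dms,
           (Ff[1:n] - Ff[2:(n + 1)]) / p$dz,
           Ff[n + 1],
           -dms))
  }
}

# Model A while Msurf > 0: cells above the interface are held at Csat;
# the state carries only the free cells. Interface Dirichlet value Csat
# is imposed at z = a (the deposition boundary), and the surface mass
# balances the flux crossing it.
.rhs_clamped <- function(t, y, p) {
  m <- p$n_free
  if (m == 0L) {
    # whole-SC deposition layer (eta_dep = 1): interface is the sink face
    f_int <- p$dsc * p$csat / (p$hsc - p$zc_last)
    return(list(c(-p$kper - f_int, f_int, p$kper)))
  }
  cs <- y[2:(m + 1)]
  Ff <- numeric(m + 1)
  Ff[1] <- -p$dsc * (cs[1] - p$csat) / (p$zc_free[1] - p$a)
  if (m > 1) Ff[2:m] <- -p$dsc * diff(cs) / diff(p$zc_free)
  Ff[m + 1] <- p$dsc * cs[m] / (p$hsc - p$zc_free[m])
  list(c(-p$kper - Ff[1],
         (Ff[1:m] - Ff[2:(m + 1)]) / p$dz_free,
         Ff[m + 1],
         p$kper))
}

.root_msurf <- function(t, y, p) y[1]

# run one regime; returns the deSolve matrix
.run_segment <- function(y, ts, rhs, p, rtol, atol, maxsteps, root = FALSE) {
  if (root) {
    out <- deSolve::lsodar(y, ts, rhs, p, rtol = rtol, atol = atol,
                           rootfunc = .root_msurf, jactype = "bandint",
                           bandup = 1, banddown = 1, maxsteps = maxsteps)
  } else {
    out <- deSolve::lsoda(y, ts, rhs, p, rtol = rtol, atol = atol,
                          jactype = "bandint", bandup = 1, banddown = 1,
                          maxsteps = maxsteps)
  }
  if (utils::tail(out[, 1], 1) < utils::tail(ts, 1) - 1e-9 &&
      is.null(attr(out, "iroot")) && !isTRUE(attr(out, "istate")[1] == 3)) {
    # lsodar stops early legitimately only at a root
    if (!root || abs(utils::tail(out[, 2], 1)) > atol * 100) {
      stop("transport solver stopped at t = ", utils::tail(out[, 1], 1),
           " min before reaching ", utils::tail(ts, 1),
           " min; raise `maxsteps` or loosen tolerances", call. = FALSE)
    }
  }
  out
}

.segment_times <- function(times, t0, t1) {
  unique(sort(c(t0, times[times > t0 & times < t1], t1)))
}

#' Simulate the fixed-deposition (saturated reservoir) model
#'
#' Model of finite-dose absorption in which a fixed fraction
#' (`eta_dep`, default 0.1) of the SC is instantaneously loaded on
#' application and, while surface mass remains, is held saturated at
#' `Csat`: the surface reservoir replaces whatever diffuses across the
#' deposition interface, and is additionally stripped by permeant
#' evaporation. Once the surface is depleted the clamp is released, the
#' top boundary becomes zero-flux, and the whole profile relaxes by
#' diffusion towards the sink at the SC base.
#'
#' @param permeant A [permeant()].
#' @param exposure An [exposure_scenario()].
#' @param geometry A [skin_geometry()].
#' @param eta_dep Deposition-layer proportion of the SC (default 0.1,
#'   the fixed assumption of this model for solvent-applied doses).
#' @param occluded If `TRUE`, permeant evaporation is disabled.
#' @param correlation Optional evaporation correlation plug-in mapping
#'   the scenario wind velocity to `kevap_per` (see
#'   [permeant_evaporation_rate()]).
#' @param times Output times in minutes (default: every minute plus
#'   event times).
#' @param rtol,atol Relative and absolute solver tolerances.
#' @param maxsteps Maximum internal solver steps per segment.
#' @param keep_profile If `TRUE`, the full concentration profile at
#'   every output time is returned in `$profile`.
#'
#' @return An object of class `sc_simulation`; see
#'   [simulate_model_b()] for the shared structure.
#' @export
simulate_model_a <- function(permeant, exposure, geometry = skin_geometry(),
                             eta_dep = 0.1, occluded = FALSE,
                             correlation = NULL, times = NULL,
                             rtol = 1e-8, atol = 1e-10, maxsteps = 20000,
                             keep_profile = FALSE) {
  stopifnot(inherits(permeant, "permeant"),
            inherits(exposure, "exposure_scenario"))
  grid <- build_grid(geometry, eta_dep)
  kper <- if (occluded) 0 else
    permeant_evaporation_rate(exposure$u, permeant, correlation)
  csat <- saturation_concentration(permeant$ksc_w, permeant$sw)
  msat <- deposition_capacity(eta_dep, geometry$hsc, csat)
  m0 <- exposure$m0
  msurf0 <- initial_surface_mass(m0, msat)
  cs0 <- initial_sc_profile(m0, grid, csat)
  t_end <- exposure$t_end
  if (is.null(times)) times <- seq(0, t_end, by = min(1, t_end))
  times <- unique(sort(c(pmin(times, t_end), 0, t_end)))

  n <- grid$n
  k <- grid$n_dep
  free_idx <- if (k < n) (k + 1):n else integer(0)
  p_full <- list(n = n, zc = grid$z_centers, dz = grid$dz, hsc = grid$hsc,
                 dsc = permeant$dsc, kper = kper)
  events <- tibble::tibble(time = numeric(0), event = character(0))
  rows <- list()
  t0 <- 0
  y_full <- c(msurf0, cs0, 0, 0)

  if (msurf0 > 0) {
    p_cl <- list(n_free = length(free_idx), a = grid$a, csat = csat,
                 zc_free = grid$z_centers[free_idx],
                 dz_free = grid$dz[free_idx],
                 zc_last = grid$z_centers[n],
                 hsc = grid$hsc, dsc = permeant$dsc, kper = kper)
    y_cl <- c(msurf0, cs0[free_idx], 0, 0)
    ts <- .segment_times(times, 0, t_end)
    o <- .run_segment(y_cl, ts, .rhs_clamped, p_cl, rtol, atol, maxsteps,
                      root = TRUE)
    m <- length(free_idx)
    # expand clamped cells back to the full profile
    full <- matrix(0, nrow(o), n + 4)
    full[, 1] <- o[, 1]
    full[, 2] <- o[, 2]
    full[, 2 + seq_len(k)] <- csat
    if (m > 0) full[, 2 + k + seq_len(m)] <- o[, 2 + seq_len(m)]
    full[, n + 3] <- o[, m + 3]
    full[, n + 4] <- o[, m + 4]
    rows[[length(rows) + 1]] <-
      cbind(full, c_surface = rep(csat, nrow(full)))
    t0 <- o[nrow(o), 1]
    y_full <- as.numeric(full[nrow(full), -1])
    y_full[1] <- max(0, y_full[1])
    if (t0 < t_end || y_full[1] <= atol * 100) {
      events <- tibble::add_row(events, time = unname(t0),
                                event = "surface_depleted")
      y_full[1] <- 0
    }
  }

  if (t0 < t_end) {
    ts <- .segment_times(times, t0, t_end)
    o <- .run_segment(y_full, ts, .rhs_sealed(FALSE), p_full, rtol, atol,
                      maxsteps)
    o <- if (length(rows)) o[-1, , drop = FALSE] else o
    rows[[length(rows) + 1]] <- cbind(o, c_surface = NA_real_)
  }

  .assemble_simulation(do.call(rbind, rows), grid, m0, model = "A",
                       events = events, hv_fun = function(t) NA_real_,
                       permeant = permeant, keep_profile = keep_profile,
                       params = list(eta_dep = eta_dep, kevap_per = kper,
                                     csat = csat, msat = msat))
}

#' Simulate the evaporating-vehicle (solubility-limited) model
#'
#' Model of finite-dose absorption in which the solvent film thins at a
#' constant rate and only dissolved permeant diffuses into the SC.
#' Three regimes are integrated, switched by events: (i) while the film
#' and surface mass persist, the SC surface is held in partition
#' equilibrium with the dissolved concentration
#' `cv = min(Sv, Msurf/hv)`; (ii) once the film has dried, diffusion
#' from the surface ceases and the remaining surface permeant is lost
#' only to evaporation; (iii) once the surface mass is exhausted the
#' surface is inert and the interior keeps draining into the sink.
#'
#' @inheritParams simulate_model_a
#' @param vehicle A [vehicle_spec()]. Its `eta_dep` sets the
#'   deposition layer; `occluded = TRUE` disables all evaporation.
#'
#' @return An object of class `sc_simulation`: a list with
#'   \describe{
#'     \item{trajectory}{tibble of `t_min`, `msurf`, `hv`, `m_sc`,
#'       `dd_cum`, `evap_cum`, `mass_balance_pct`, `c_surface` (the
#'       surface/interface boundary concentration while a donor is
#'       active, else `NA`).}
#'     \item{terminal}{one-row tibble of the 24 h style summary:
#'       `sw` (skin wash, remaining surface mass), `sc_accum`
#'       (integral of the SC profile), `dd` (cumulative dermal
#'       delivery), `evap` and `mass_balance_pct`.}
#'     \item{events}{tibble of event times (`vehicle_dry`,
#'       `surface_depleted`).}
#'     \item{diagnostics}{list with the maximum relative mass-balance
#'       error of the trajectory and solver metadata.}
#'     \item{profile}{optional matrix of concentration profiles.}
#'   }
#' @export
simulate_model_b <- function(permeant, vehicle, exposure,
                             geometry = skin_geometry(),
                             correlation = NULL, times = NULL,
                             rtol = 1e-8, atol = 1e-10, maxsteps = 20000,
                             keep_profile = FALSE) {
  stopifnot(inherits(permeant, "permeant"),
            inherits(vehicle, "vehicle_spec"),
            inherits(exposure, "exposure_scenario"))
  eta_dep <- vehicle$eta_dep
  grid <- build_grid(geometry, eta_dep)
  occluded <- vehicle$occluded
  kveh <- if (occluded) 0 else vehicle$kevap_veh
  kper <- if (occluded) 0 else
    permeant_evaporation_rate(exposure$u, permeant, correlation)
  csat <- saturation_concentration(permeant$ksc_w, permeant$sw)
  msat <- deposition_capacity(eta_dep, geometry$hsc, csat)
  kv_w <- vehicle_water_partition(permeant$sv, permeant$sw)
  kv_sc <- vehicle_sc_partition(kv_w, permeant$ksc_w)
  m0 <- exposure$m0
  hv0 <- exposure$hv0
  msurf0 <- initial_surface_mass(m0, msat)
  cs0 <- initial_sc_profile(m0, grid, csat)
  t_end <- exposure$t_end
  if (is.null(times)) times <- seq(0, t_end, by = min(1, t_end))
  times <- unique(sort(c(pmin(times, t_end), 0, t_end)))

  n <- grid$n
  p <- list(n = n, zc = grid$z_centers, dz = grid$dz, hsc = grid$hsc,
            dsc = permeant$dsc, kper = kper, kveh = kveh, hv0 = hv0,
            sv = permeant$sv, kv_sc = kv_sc)
  t_dry <- drying_time(hv0, kveh)
  events <- tibble::tibble(time = numeric(0), event = character(0))
  rows <- list()
  t0 <- 0
  y <- c(msurf0, cs0, 0, 0)

  # regime (i): donor film present
  if (msurf0 > 0 && hv0 > 0 && kv_sc > 0) {
    t1 <- min(t_dry, t_end)
    ts <- .segment_times(times, t0, t1)
    o <- .run_segment(y, ts, .rhs_donor, p, rtol, atol, maxsteps,
                      root = TRUE)
    hv_seg <- vehicle_thickness(o[, 1], hv0, kveh)
    csurf <- pmin(permeant$sv, pmax(o[, 2], 0) / pmax(hv_seg, 1e-300)) / kv_sc
    rows[[length(rows) + 1]] <- cbind(o, c_surface = csurf)
    t0 <- o[nrow(o), 1]
    y <- as.numeric(o[nrow(o), -1])
    if (y[1] <= atol * 100 && t0 < t_dry) {
      events <- tibble::add_row(events, time = unname(t0),
                                event = "surface_depleted")
      y[1] <- 0
    }
    y[1] <- max(0, y[1])
  }
  if (is.finite(t_dry) && t_dry <= t_end && hv0 > 0) {
    events <- tibble::add_row(events, time = t_dry, event = "vehicle_dry")
  }

  # regime (ii): film dry, surface mass still evaporating
  if (t0 < t_end && y[1] > 0) {
    t_dep <- if (kper > 0) t0 + y[1] / kper else Inf
    t1 <- min(t_dep, t_end)
    ts <- .segment_times(times, t0, t1)
    o <- .run_segment(y, ts, .rhs_sealed(TRUE), p, rtol, atol, maxsteps)
    rows[[length(rows) + 1]] <-
      cbind(o, c_surface = NA_real_)[if (length(rows)) -1 else TRUE, ,
                                     drop = FALSE]
    t0 <- o[nrow(o), 1]
    y <- as.numeric(o[nrow(o), -1])
    if (y[1] <= atol * 100 && t0 < t_end) {
      events <- tibble::add_row(events, time = unname(t0),
                                event = "surface_depleted")
    }
    y[1] <- max(0, y[1])
  }

  # regime (iii): inert surface, interior drains into the sink
  if (t0 < t_end) {
    ts <- .segment_times(times, t0, t_end)
    o <- .run_segment(y, ts, .rhs_sealed(FALSE), p, rtol, atol, maxsteps)
    rows[[length(rows) + 1]] <-
      cbind(o, c_surface = NA_real_)[if (length(rows)) -1 else TRUE, ,
                                     drop = FALSE]
  }

  .assemble_simulation(do.call(rbind, rows), grid, m0, model = "B",
                       events = dplyr::arrange(events, .data$time),
                       hv_fun = function(t) vehicle_thickness(t, hv0, kveh),
                       permeant = permeant, keep_profile = keep_profile,
                       params = list(eta_dep = eta_dep, kevap_veh = kveh,
                                     kevap_per = kper, csat = csat,
                                     msat = msat, kv_sc = kv_sc,
                                     vehicle = vehicle$name))
}

.assemble_simulation <- function(out, grid, m0, model, events, hv_fun,
                                 permeant, params, keep_profile) {
  n <- grid$n
  t <- out[, 1]
  msurf <- pmax(out[, 2], 0)
  profile <- out[, 2 + seq_len(n), drop = FALSE]
  m_sc <- as.numeric(profile %*% grid$dz)
  dd <- out[, n + 3]
  evap <- out[, n + 4]
  traj <- tibble::tibble(
    t_min = t, msurf = msurf, hv = hv_fun(t), m_sc = m_sc,
    dd_cum = dd, evap_cum = evap,
    mass_balance_pct = 100 * (msurf + m_sc + dd) / m0,
    c_surface = out[, n + 5]
  )
  mass_err <- max(abs((msurf + m_sc + dd + evap) / m0 - 1))
  last <- nrow(traj)
  terminal <- tibble::tibble(
    sw = traj$msurf[last], sc_accum = traj$m_sc[last],
    dd = traj$dd_cum[last], evap = traj$evap_cum[last],
    mass_balance_pct = traj$mass_balance_pct[last]
  )
  structure(
    list(trajectory = traj, terminal = terminal, events = events,
         model = model, m0 = m0, grid = grid,
         permeant = permeant$name, params = params,
         diagnostics = list(mass_error_max = mass_err,
                            n_times = nrow(traj)),
         profile = if (keep_profile) {
           colnames(profile) <- signif(grid$z_centers, 8)
           cbind(t_min = t, profile)
         }),
    class = "sc_simulation"
  )
}

#' Compartment masses along a simulated trajectory
#'
#' @param sim An `sc_simulation`.
#' @return A tibble of `t_min`, `msurf`, `m_sc`, `dd_cum`, `evap_cum`
#'   (all µg/cm²).
#' @export
compartment_masses <- function(sim) {
  stopifnot(inherits(sim, "sc_simulation"))
  dplyr::select(sim$trajectory, "t_min", "msurf", "m_sc", "dd_cum",
                "evap_cum")
}

#' Terminal mass balance of a simulation
#'
#' Percentage of the applied dose accounted for on the surface, in the
#' SC and in dermal delivery at the end of the run; the shortfall from
#' 100 is the evaporated fraction.
#'
#' @param sim An `sc_simulation`.
#' @param m0 Applied dose (defaults to the simulation's own).
#' @return Percent of dose.
#' @export
mass_balance_percent <- function(sim, m0 = sim$m0) {
  stopifnot(inherits(sim, "sc_simulation"))
  check_scalar(m0, "m0", positive = TRUE)
  100 * (sim$terminal$sw + sim$terminal$sc_accum + sim$terminal$dd) / m0
}

#' @export
print.sc_simulation <- function(x, ...) {
  cat("<sc_simulation> Model ", x$model, " | ", x$permeant,
      " | M0 = ", signif(x$m0, 4), " ug/cm2\n", sep = "")
  tf <- utils::tail(x$trajectory$t_min, 1)
  cat(sprintf("  t_end %.4g min | skin wash %.4g | SC %.4g | delivered %.4g | evaporated %.4g ug/cm2\n",
              tf, x$terminal$sw, x$terminal$sc_accum, x$terminal$dd,
              x$terminal$evap))
  cat(sprintf("  mass balance %.2f%% of dose | max conservation error %.2g\n",
              x$terminal$mass_balance_pct, x$diagnostics$mass_error_max))
  if (nrow(x$events)) {
    cat("  events:",
        paste(sprintf("%s @ %.3g min", x$events$event, x$events$time),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a simulation into its trajectory tibble
#'
#' @param x An `sc_simulation`.
#' @param ... Unused.
#' @return The trajectory tibble (one row per output time).
#' @method tidy sc_simulation
#' @export
tidy.sc_simulation <- function(x, ...) x$trajectory

#' One-row summary of a simulation
#'
#' @param x An `sc_simulation`.
#' @param ... Unused.
#' @return A one-row tibble with the model label, dose and terminal
#'   compartment masses.
#' @method glance sc_simulation
#' @export
glance.sc_simulation <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(model = x$model, permeant = x$permeant, m0 = x$m0),
    x$terminal,
    tibble::tibble(mass_error_max = x$diagnostics$mass_error_max)
  )
}

#' Plot the compartment masses of a simulation over time
#'
#' @param object An `sc_simulation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sc_simulation
#' @export
autoplot.sc_simulation <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object$trajectory, "t_min", "msurf", "m_sc", "dd_cum",
                  "evap_cum"),
    -"t_min", names_to = "compartment", values_to = "mass"
  )
  labs <- c(msurf = "skin surface", m_sc = "stratum corneum",
            dd_cum = "dermally delivered", evap_cum = "evaporated")
  long$compartment <- factor(labs[long$compartment], levels = labs)
  ggplot2::ggplot(long, ggplot2::aes(.data$t_min, .data$mass,
                                     colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)",
                  y = expression("mass per area (" * mu * g / cm^2 * ")"),
                  colour = NULL,
                  title = paste0("Model ", object$model, ": ",
                                 object$permeant)) +
    ggplot2::theme_minimal()
}
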