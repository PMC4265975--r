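#' Tissue thermal properties for the Pennes bioheat model
#'
#' @param conductivity_w_m_k thermal conductivity k (W/m/K).
#' @param vol_heat_capacity_j_m3_k volumetric heat capacity rho*c (J/m^3/K).
#' @param perfusion_w_m3_k perfusion heat-sink coefficient w_b*c_b
#'   (W/m^3/K); 0 for a phantom.
#' @param arterial_temp_c arterial (equilibrium) temperature (deg C).
#' @return A `thermal_properties` list.
#' @export
thermal_properties <- function(conductivity_w_m_k = 0.5,
                               vol_heat_capacity_j_m3_k = 3.6e6,
                               perfusion_w_m3_k = 0,
                               arterial_temp_c = 37) {
  check_scalar_number(conductivity_w_m_k, "conductivity_w_m_k", positive = TRUE)
  check_scalar_number(vol_heat_capacity_j_m3_k, "vol_heat_capacity_j_m3_k",
                      positive = TRUE)
  check_scalar_number(perfusion_w_m3_k, "perfusion_w_m3_k", nonneg = TRUE)
  check_scalar_number(arterial_temp_c, "arterial_temp_c")
  structure(list(conductivity_w_m_k = conductivity_w_m_k,
                 vol_heat_capacity_j_m3_k = vol_heat_capacity_j_m3_k,
                 perfusion_w_m3_k = perfusion_w_m3_k,
                 arterial_temp_c = arterial_temp_c),
            class = "thermal_properties")
}

#' 3D temperature field on a simulation grid
#'
#' @param values 3D array of absolute temperature (deg C), dims matching the
#'   grid.
#' @param grid a [sim_grid()].
#' @param time_s timestamp (s).
#' @export
temperature_field <- function(values, grid, time_s = 0) {
  values <- as.array(values)
  stopifnot(identical(dim(values), as.integer(grid$dims)))
  if (!all(is.finite(values))) {
    stop_validation("values", "temperatures must be finite")
  }
  structure(list(values = values, grid = grid, time_s = as.numeric(time_s)),
            class = "temperature_field")
}

#' @export
print.temperature_field <- function(x, ...) {
  cat(sprintf("<temperature field %s @ t=%.3g s: range %.2f..%.2f degC>\n",
              paste(dim(x$values), collapse = "x"), x$time_s,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Maximum stable explicit time step
#'
#' FTCS stability bound `dt <= dx^2 rho c / (6 k)` (smallest spacing).
#'
#' @param grid a [sim_grid()].
#' @param properties a [thermal_properties()].
#' @export
pennes_stable_dt <- function(grid, properties) {
  dx <- min(grid$spacing_mm) * 1e-3
  dx^2 * properties$vol_heat_capacity_j_m3_k /
    (6 * properties$conductivity_w_m_k)
}

#' One explicit step of the Pennes bioheat equation
#'
#' `T' = T + dt / (rho c) * (k lap(T) - w_b c_b (T - T_a) + Q)` on the
#' voxel grid, with either fixed-temperature (Dirichlet, at `bc_value`) or
#' insulated (Neumann) boundaries. Refuses an unstable `dt`, stating the
#' bound.
#'
#' @param temp 3D array of absolute temperature (deg C).
#' @param q 3D array of heat deposition (W/m^3) or 0.
#' @param dt time step (s).
#' @param grid a [sim_grid()].
#' @param properties a [thermal_properties()].
#' @param boundary `"dirichlet"` (fixed at `bc_value`) or `"neumann"`
#'   (insulated).
#' @param bc_value boundary temperature for Dirichlet (deg C).
#' @return Updated temperature array.
#' @export
pennes_step <- function(temp, q, dt, grid, properties,
                        boundary = c("dirichlet", "neumann"),
                        bc_value = properties$arterial_temp_c) {
  boundary <- match.arg(boundary)
  dt_max <- pennes_stable_dt(grid, properties)
  if (dt > dt_max * (1 + 1e-9)) {
    stop(sprintf(
      "unstable time step: dt = %.4g s exceeds the explicit-scheme bound dx^2*rho*c/(6k) = %.4g s",
      dt, dt_max), call. = FALSE)
  }
  rc <- properties$vol_heat_capacity_j_m3_k
  k <- properties$conductivity_w_m_k
  lap <- array(
    laplacian3_cpp(as.double(temp), as.integer(dim(temp)),
                   1 / (grid$spacing_mm * 1e-3)^2,
                   boundary == "dirichlet", bc_value),
    dim = dim(temp))
  temp + dt / rc * (k * lap -
                      properties$perfusion_w_m3_k *
                        (temp - properties$arterial_temp_c) + q)
}

#' Advance a temperature array over an interval with automatic sub-stepping
#'
#' Splits `duration_s` into explicit steps no longer than the stability
#' bound (times `safety`).
#'
#' @inheritParams pennes_step
#' @param duration_s interval length (s).
#' @param safety fraction of the stability bound to use (default 0.9).
#' @export
pennes_advance <- function(temp, q, duration_s, grid, properties,
                           boundary = "dirichlet",
                           bc_value = properties$arterial_temp_c,
                           safety = 0.9) {
  if (duration_s <= 0) return(temp)
  dt_max <- pennes_stable_dt(grid, properties) * safety
  n <- max(1L, ceiling(duration_s / dt_max))
  dt <- duration_s / n
  for (i in seq_len(n)) {
    temp <- pennes_step(temp, q, dt, grid, properties, boundary, bc_value)
  }
  temp
}

# Extract exposure intervals (with drive details) from an engine event log.
exposure_intervals <- function(events) {
  out <- list()
  open <- NULL
  for (e in events) {
    if (e$type == "exposure_on") {
      open <- list(t_on = e$time, detail = e$detail)
    } else if (e$type == "exposure_off" && !is.null(open)) {
      open$t_off <- e$time
      out[[length(out) + 1L]] <- open
      open <- NULL
    }
  }
  if (!is.null(open)) {
    open$t_off <- Inf
    out[[length(out) + 1L]] <- open
  }
  out
}

# Time-averaged heat deposition for one exposure event detail: the focal
# point cycles through the trajectory, so Q is averaged uniformly over the
# trajectory points (exact over whole passes; the stated approximation for
# partial passes). `support_mm` optionally restricts computation to voxels
# within that distance of any focal target (Q ~ 0 elsewhere at the focus).
exposure_qbar <- function(detail, geometry, grid, medium,
                          support_mm = Inf) {
  pos <- detail$transducer_position_mm %||% c(0, 0, 0)
  geo <- translate_geometry(geometry, pos)
  traj <- detail$trajectory
  offsets <- if (is.null(traj)) matrix(0, 1, 3) else traj$points
  targets <- sweep(offsets, 2, pos, "+")
  pts <- grid_points(grid)
  sel <- seq_len(nrow(pts))
  if (is.finite(support_mm)) {
    dmin <- rep(Inf, nrow(pts))
    for (i in seq_len(nrow(targets))) {
      d <- sqrt(rowSums(sweep(pts, 2, targets[i, ], "-")^2))
      dmin <- pmin(dmin, d)
    }
    sel <- which(dmin <= support_mm)
  }
  qv <- numeric(nrow(pts))
  if (length(sel)) {
    power <- detail$acoustic_power_w * (detail$duty_cycle %||% 1)
    mask <- detail$active_mask %||% rep(TRUE, geo$n_elements)
    for (i in seq_len(nrow(targets))) {
      drv <- steering_drive(geo, targets[i, ], detail$frequency_mhz, medium,
                            active_mask = mask,
                            phase_overrides = detail$phases_rad,
                            amplitude_overrides = detail$amplitudes)
      # far-field disc model: exact enough at the focus, fast on volumes
      qv[sel] <- qv[sel] + heat_deposition(geo, drv, pts[sel, , drop = FALSE],
                                           medium, power,
                                           element_model = "far_field")
    }
    qv <- qv / nrow(targets)
  }
  array(qv, dim = grid$dims)
}

#' Simulate the temperature timeline of an executed protocol
#'
#' Turns an engine event log into a 4D temperature record: every
#' `exposure_on`/`exposure_off` pair contributes its (trajectory-averaged)
#' heat deposition while active; elsewhere the field cools. Returns
#' [temperature_field()] snapshots at `output_times_s`.
#'
#' @param events engine event log (list from `HifuEngine$event_log()`).
#' @param geometry an `array_geometry`.
#' @param grid a [sim_grid()].
#' @param medium a [medium_properties()].
#' @param properties a [thermal_properties()].
#' @param output_times_s times (s, sorted) at which to snapshot.
#' @param baseline_temp_c initial/boundary temperature (deg C).
#' @param boundary boundary condition (see [pennes_step()]).
#' @param support_mm restrict heat-source evaluation to voxels within this
#'   distance of the focal targets (Inf = everywhere).
#' @return List of `temperature_field` snapshots.
#' @export
simulate_timeline <- function(events, geometry, grid, medium, properties,
                              output_times_s,
                              baseline_temp_c = properties$arterial_temp_c,
                              boundary = "dirichlet", support_mm = Inf) {
  ivs <- exposure_intervals(events)
  qcache <- vector("list", length(ivs))
  q_at <- function(t) {
    q <- 0
    for (i in seq_along(ivs)) {
      if (t >= ivs[[i]]$t_on - 1e-9 && t < ivs[[i]]$t_off - 1e-9) {
        if (is.null(qcache[[i]])) {
          qcache[[i]] <<- exposure_qbar(ivs[[i]]$detail, geometry, grid,
                                        medium, support_mm)
        }
        q <- q + qcache[[i]]
      }
    }
    q
  }
  boundaries <- sort(unique(c(0, output_times_s,
                              unlist(lapply(ivs, function(v)
                                c(v$t_on, min(v$t_off, max(output_times_s))))))))
  boundaries <- boundaries[boundaries <= max(output_times_s) + 1e-9]
  temp <- array(baseline_temp_c, dim = grid$dims)
  out <- vector("list", length(output_times_s))
  for (h in which(abs(output_times_s) < 1e-9)) {
    out[[h]] <- temperature_field(temp, grid, 0)
  }
  t_cur <- 0
  for (b in boundaries[boundaries > 0]) {
    q <- q_at((t_cur + b) / 2)
    temp <- pennes_advance(temp, q, b - t_cur, grid, properties, boundary,
                           bc_value = baseline_temp_c)
    t_cur <- b
    hit <- which(abs(output_times_s - b) < 1e-9)
    for (h in hit) out[[h]] <- temperature_field(temp, grid, b)
  }
  out
}
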