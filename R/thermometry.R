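#' Thermometry configuration
#'
#' Constants for PRFS phase-to-temperature conversion and two-echo T2
#' calibration. The PRFS coefficient applies to water protons only; fatty
#' tissue (marrow) carries no PRFS phase, which is why the T2 route exists.
#'
#' @param alpha_ppm_per_c PRFS coefficient (ppm/degC, nonzero;
#'   default -0.01).
#' @param gamma_mhz_per_t gyromagnetic ratio (MHz/T).
#' @param b0_t field strength (T).
#' @param te_ms echo time (ms); taken from the frames when `NULL`.
#' @param magnitude_threshold validity threshold as a fraction of the
#'   per-frame maximum magnitude (default 0.05).
#' @param t2_slope_ms_per_c T2-temperature calibration slope (ms/degC;
#'   positive for fat; default 20).
#' @export
thermometry_config <- function(alpha_ppm_per_c = ALPHA_PRFS_PPM_PER_C,
                               gamma_mhz_per_t = GAMMA_MHZ_PER_T,
                               b0_t = 3, te_ms = NULL,
                               magnitude_threshold = 0.05,
                               t2_slope_ms_per_c = 20) {
  if (alpha_ppm_per_c == 0) stop_validation("alpha_ppm_per_c", "must be nonzero")
  if (t2_slope_ms_per_c <= 0) {
    stop_validation("t2_slope_ms_per_c", "must be > 0 for fat calibration")
  }
  structure(list(alpha_ppm_per_c = alpha_ppm_per_c,
                 gamma_mhz_per_t = gamma_mhz_per_t, b0_t = b0_t,
                 te_ms = te_ms, magnitude_threshold = magnitude_threshold,
                 t2_slope_ms_per_c = t2_slope_ms_per_c),
            class = "thermometry_config")
}

new_temperature_map <- function(delta_t, valid, dynamic = NA_integer_,
                                time_s = NA_real_) {
  structure(list(delta_t_c = delta_t, valid = valid,
                 dynamic = as.integer(dynamic), time_s = time_s),
            class = "temperature_map")
}

#' @export
print.temperature_map <- function(x, ...) {
  v <- x$delta_t_c[x$valid]
  cat(sprintf("<temperature map %dx%d dyn %s: %d valid px, dT %.2f..%.2f degC>\n",
              nrow(x$delta_t_c), ncol(x$delta_t_c),
              ifelse(is.na(x$dynamic), "?", x$dynamic), sum(x$valid),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' PRFS temperature change map from a phase-image pair
#'
#' `dT = wrap(phi - phi_ref) / (2 pi gamma B0 alpha TE)`. Phase differences
#' are wrapped to `(-pi, pi]` before scaling; temperature excursions whose
#' inter-dynamic phase difference exceeds pi alias (unwrapping beyond that
#' is out of scope). Pixels whose magnitude falls below the configured
#' fraction of the frame maximum (in either frame) are flagged invalid, not
#' silently zeroed.
#'
#' @param frame,reference `image_frame`s sharing TE and geometry.
#' @param config a [thermometry_config()]; `b0`/`te` default from the frame.
#' @param drift_roi optional logical matrix: when given, the circular mean
#'   of the phase difference over this non-heated region is subtracted
#'   *before* wrapping and scaling. Unlike the map-domain
#'   [drift_correct()], this remains correct when the accumulated drift
#'   relative to an old reference exceeds +/- pi (the heating-induced phase
#'   still must stay within +/- pi of the drift).
#' @return A `temperature_map` (`delta_t_c`, `valid`, dynamic, time).
#' @export
prfs_delta_t <- function(frame, reference, config = thermometry_config(),
                         drift_roi = NULL) {
  stopifnot(inherits(frame, "image_frame"), inherits(reference, "image_frame"))
  te <- config$te_ms %||% frame$seq$te_ms[1]
  if (abs(frame$seq$te_ms[1] - reference$seq$te_ms[1]) > 1e-9) {
    stop("TE mismatch between frame and reference", call. = FALSE)
  }
  if (!isTRUE(all.equal(frame$geometry, reference$geometry, tolerance = 1e-9))) {
    stop("geometry mismatch between frame and reference", call. = FALSE)
  }
  b0 <- config$b0_t %||% frame$seq$b0_t
  denom <- 2 * pi * (config$gamma_mhz_per_t * 1e6) * b0 *
    (config$alpha_ppm_per_c * 1e-6) * (te * 1e-3)
  dphi <- frame$phase_rad - reference$phase_rad
  m1 <- frame$magnitude[[1]]; m0 <- reference$magnitude[[1]]
  thr <- config$magnitude_threshold
  valid <- (m1 >= thr * max(m1)) & (m0 >= thr * max(m0))
  if (!is.null(drift_roi)) {
    sel <- drift_roi & valid
    if (!any(sel)) {
      stop("empty drift ROI: no valid pixels to estimate drift from",
           call. = FALSE)
    }
    dphi <- dphi - Arg(mean(exp(1i * dphi[sel])))
  }
  dT <- wrap_phase(dphi) / denom
  dT[!valid] <- NA_real_
  new_temperature_map(dT, valid, frame$dynamic, frame$acq_time_s)
}

#' Drift correction against a non-heated reference region
#'
#' Subtracts the mean temperature change over the reference ROI (monitored
#' in a region known not to heat) from every pixel, removing spatially
#' uniform B0-drift bias; the corrected ROI mean is exactly zero. The
#' operation is idempotent. With `order = 1`, a first-degree plane is
#' fitted over the ROI and subtracted instead.
#'
#' @param map a `temperature_map`.
#' @param roi_mask logical matrix, `TRUE` in the drift-monitoring region
#'   (must contain at least one valid pixel; keep it disjoint from heating).
#' @param order 0 (mean, default) or 1 (planar fit).
#' @return The corrected `temperature_map`.
#' @export
drift_correct <- function(map, roi_mask, order = 0L) {
  stopifnot(inherits(map, "temperature_map"))
  sel <- roi_mask & map$valid
  if (!any(sel)) {
    stop("empty drift ROI: no valid pixels to estimate drift from",
         call. = FALSE)
  }
  if (order == 0L) {
    map$delta_t_c <- map$delta_t_c - mean(map$delta_t_c[sel])
  } else {
    idx <- which(sel, arr.ind = TRUE)
    fit <- stats::lm.fit(cbind(1, idx[, 1], idx[, 2]), map$delta_t_c[sel])
    all_idx <- expand.grid(r = seq_len(nrow(map$delta_t_c)),
                           c = seq_len(ncol(map$delta_t_c)))
    plane <- fit$coefficients[1] + fit$coefficients[2] * all_idx$r +
      fit$coefficients[3] * all_idx$c
    map$delta_t_c <- map$delta_t_c - matrix(plane, nrow(map$delta_t_c))
  }
  map$delta_t_c[!map$valid] <- NA_real_
  map
}

#' Two-echo T2 map
#'
#' `T2 = (TE2 - TE1) / ln(S1 / S2)` per pixel. Pixels where `S1 <= S2`
#' (non-physical decay) or where the first echo falls below the magnitude
#' threshold are masked invalid; degeneracy is handled by masking, never by
#' an error.
#'
#' @param echo1,echo2 magnitude matrices, or a single two-echo
#'   `image_frame` passed as `echo1` (then `te1_ms`/`te2_ms` default from
#'   its sequence).
#' @param te1_ms,te2_ms echo times (ms, `te2 > te1`).
#' @param magnitude_threshold validity threshold (fraction of echo-1 max).
#' @return List with `t2_ms` matrix (NA where invalid) and `valid` mask.
#' @export
t2_map <- function(echo1, echo2 = NULL, te1_ms = NULL, te2_ms = NULL,
                   magnitude_threshold = 0.05) {
  if (inherits(echo1, "image_frame")) {
    frame <- echo1
    if (length(frame$magnitude) < 2L) {
      stop("frame has no second echo", call. = FALSE)
    }
    te1_ms <- te1_ms %||% frame$seq$te_ms[1]
    te2_ms <- te2_ms %||% frame$seq$te_ms[2]
    echo2 <- frame$magnitude[[2]]
    echo1 <- frame$magnitude[[1]]
  }
  stopifnot(te2_ms > te1_ms)
  s1 <- as.matrix(echo1); s2 <- as.matrix(echo2)
  valid <- s1 > s2 & s2 > 0 & s1 >= magnitude_threshold * max(s1)
  t2 <- matrix(NA_real_, nrow(s1), ncol(s1))
  t2[valid] <- (te2_ms - te1_ms) / log(s1[valid] / s2[valid])
  list(t2_ms = t2, valid = valid)
}

#' Temperature change from a T2 change
#'
#' `dT = (T2 - T2_ref) / slope`, using the fat T2-temperature calibration
#' slope (ms/degC).
#'
#' @param t2 a [t2_map()] result (or matrix).
#' @param t2_ref reference [t2_map()] (or matrix) at baseline temperature.
#' @param slope_ms_per_c calibration slope (default 20 ms/degC).
#' @param dynamic,time_s metadata for the returned map.
#' @return A `temperature_map`.
#' @export
t2_to_temp <- function(t2, t2_ref, slope_ms_per_c = 20,
                       dynamic = NA_integer_, time_s = NA_real_) {
  get_vals <- function(x) if (is.list(x)) x$t2_ms else as.matrix(x)
  get_valid <- function(x) if (is.list(x)) x$valid else !is.na(as.matrix(x))
  v <- get_vals(t2); vr <- get_vals(t2_ref)
  valid <- get_valid(t2) & get_valid(t2_ref)
  dT <- (v - vr) / slope_ms_per_c
  dT[!valid] <- NA_real_
  new_temperature_map(dT, valid, dynamic, time_s)
}

#' Maximum temperature-change projection over dynamics
#'
#' Per-pixel maximum over a sequence of temperature maps, ignoring invalid
#' pixels; a pixel is valid in the projection if it was valid in any input
#' map. Commutative in the order of dynamics and monotone: adding a dynamic
#' never decreases any pixel.
#'
#' @param maps list of `temperature_map`s (or a single map).
#' @return A `temperature_map` holding the projection.
#' @export
max_projection <- function(maps) {
  if (inherits(maps, "temperature_map")) maps <- list(maps)
  stopifnot(length(maps) >= 1L)
  acc <- maps[[1]]$delta_t_c
  acc[!maps[[1]]$valid] <- -Inf
  valid <- maps[[1]]$valid
  for (m in maps[-1]) {
    v <- m$delta_t_c
    v[!m$valid] <- -Inf
    acc <- pmax(acc, v)
    valid <- valid | m$valid
  }
  acc[!valid] <- NA_real_
  new_temperature_map(acc, valid,
                      dynamic = maps[[length(maps)]]$dynamic,
                      time_s = maps[[length(maps)]]$time_s)
}
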