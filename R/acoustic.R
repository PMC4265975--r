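#' Acoustic medium properties
#'
#' Single homogeneous propagation medium (water or tissue-mimicking
#' phantom); no refraction or aberration is modelled.
#'
#' @param sound_speed_m_s speed of sound c (m/s).
#' @param density_kg_m3 mass density rho (kg/m^3).
#' @param attenuation_np_m_mhz amplitude attenuation coefficient
#'   (Np/m/MHz); 0 for degassed water, ~5.76 (0.5 dB/cm/MHz) for soft
#'   tissue / heating phantom.
#' @param absorption_fraction fraction of attenuation converted to heat.
#' @return A `medium_properties` list.
#' @export
medium_properties <- function(sound_speed_m_s = 1500,
                              density_kg_m3 = 1000,
                              attenuation_np_m_mhz = 0,
                              absorption_fraction = 1) {
  for (nm in c("sound_speed_m_s", "density_kg_m3")) {
    check_scalar_number(get(nm), nm, positive = TRUE)
  }
  check_scalar_number(attenuation_np_m_mhz, "attenuation_np_m_mhz",
                      nonneg = TRUE)
  check_scalar_number(absorption_fraction, "absorption_fraction",
                      nonneg = TRUE)
  structure(list(sound_speed_m_s = sound_speed_m_s,
                 density_kg_m3 = density_kg_m3,
                 attenuation_np_m_mhz = attenuation_np_m_mhz,
                 absorption_fraction = absorption_fraction),
            class = "medium_properties")
}

#' @rdname medium_properties
#' @export
water_medium <- function() medium_properties(1500, 1000, 0, 0)

#' @rdname medium_properties
#' @export
phantom_medium <- function() {
  # 0.5 dB/cm/MHz = 0.5 / 8.686 * 100 Np/m/MHz
  medium_properties(1500, 1030, 5.756, 1)
}

#' Phased-array transducer geometry
#'
#' Places `n_elements` circular elements on a spherical-shell cap (radius of
#' curvature = focal length) using a deterministic sunflower-spiral packing;
#' the true clinical element arrangement is proprietary, so only the element
#' count, focal length, aperture and frequency band are device-anchored and
#' the layout itself is pluggable. The device frame has the natural focus at
#' the origin, x = left-right, y = head-foot, z = beam axis (elements sit at
#' negative z and radiate toward +z).
#'
#' @param n_elements number of elements (default 256).
#' @param focal_length_mm radius of curvature / focal length (default 120).
#' @param aperture_diameter_mm shell aperture diameter (default 130).
#' @param element_radius_mm element disc radius; by default the discrete
#'   circular elements fill ~55% of the shell area (circles cannot tile a
#'   cap, and sparse layouts with sub-unity fill are typical of clinical
#'   randomized arrays), giving ~3.1 mm radius elements for the default
#'   256-element shell.
#' @param seed integer; rotates the spiral's starting azimuth so layouts are
#'   reproducibly distinct per seed.
#' @return An `array_geometry`: element `centers_mm` and unit `normals`
#'   (toward the focus), element radius/area, and the device constants.
#' @export
make_array_geometry <- function(n_elements = SONASIM_N_ELEMENTS,
                                focal_length_mm = 120,
                                aperture_diameter_mm = 130,
                                element_radius_mm = NULL,
                                seed = 1L) {
  n <- as.integer(n_elements)
  stopifnot(n >= 1L)
  R <- focal_length_mm
  theta_max <- asin((aperture_diameter_mm / 2) / R)
  # equal-area spiral on the cap: uniform in cos(theta), golden-angle azimuth
  i <- seq_len(n)
  if (n == 1L) {
    cth <- 1
  } else {
    cth <- 1 - (i - 0.5) / n * (1 - cos(theta_max))
  }
  theta <- acos(pmin(1, cth))
  golden <- pi * (3 - sqrt(5))
  phi0 <- with_seed(seed, stats::runif(1, 0, 2 * pi))
  phi <- phi0 + i * golden
  centers <- cbind(R * sin(theta) * cos(phi),
                   R * sin(theta) * sin(phi),
                   -R * cos(theta))
  normals <- -centers / R  # unit vectors toward the focus (origin)
  cap_area <- 2 * pi * R^2 * (1 - cos(theta_max))
  if (is.null(element_radius_mm)) {
    element_radius_mm <- sqrt(0.55 * cap_area / n / pi)
  }
  structure(list(n_elements = n,
                 focal_length_mm = R,
                 aperture_diameter_mm = aperture_diameter_mm,
                 element_radius_mm = element_radius_mm,
                 element_area_mm2 = pi * element_radius_mm^2,
                 centers_mm = centers,
                 normals = normals,
                 frequency_band_mhz = c(1.0, 1.5)),
            class = "array_geometry")
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf(
    "<array geometry: %d elements, F=%.0f mm, D=%.0f mm, a=%.2f mm>\n",
    x$n_elements, x$focal_length_mm, x$aperture_diameter_mm,
    x$element_radius_mm))
  invisible(x)
}

#' Translate an array geometry (mechanical transducer move)
#' @param geometry an `array_geometry`.
#' @param offset_mm 3-vector translation (mm).
#' @export
translate_geometry <- function(geometry, offset_mm) {
  offset_mm <- as.numeric(offset_mm)
  geometry$centers_mm <- sweep(geometry$centers_mm, 2, offset_mm, "+")
  geometry
}

#' Per-element drive vector
#'
#' Per-element complex drive: amplitude fraction in `[0, 1]` and phase in
#' radians, at a common frequency. Inactive elements have amplitude 0.
#'
#' @param amplitudes amplitude fractions, length = element count.
#' @param phases_rad phases (radians), same length.
#' @param frequency_mhz driving frequency (MHz).
#' @export
drive_vector <- function(amplitudes, phases_rad, frequency_mhz) {
  amplitudes <- as.numeric(amplitudes)
  phases_rad <- as.numeric(phases_rad)
  if (length(amplitudes) != length(phases_rad)) {
    stop_validation("phases_rad", "length must match amplitudes")
  }
  if (any(amplitudes < 0 | amplitudes > 1)) {
    stop_validation("amplitudes", "must be in [0, 1]")
  }
  check_scalar_number(frequency_mhz, "frequency_mhz", positive = TRUE)
  structure(list(amplitudes = amplitudes, phases_rad = phases_rad,
                 frequency_mhz = frequency_mhz),
            class = "drive_vector")
}

wavenumber <- function(frequency_mhz, medium) {
  2 * pi * frequency_mhz * 1e6 / medium$sound_speed_m_s  # rad/m
}

#' Electronic steering phases
#'
#' Phases that relocate the focal point to `focus_offset_mm` (relative to
#' the natural focus): `phi_n = k * (|r_n - r_f| - F)`, wrapped to
#' `(-pi, pi]`. At zero offset all phases are 0.
#'
#' @param geometry an `array_geometry`.
#' @param focus_offset_mm 3-vector offset from the natural focus (mm).
#' @param frequency_mhz driving frequency (MHz).
#' @param medium a `medium_properties`.
#' @return Numeric vector of per-element phases (radians).
#' @export
steering_phases <- function(geometry, focus_offset_mm, frequency_mhz, medium) {
  focus_offset_mm <- as.numeric(focus_offset_mm)
  stopifnot(length(focus_offset_mm) == 3L)
  k <- wavenumber(frequency_mhz, medium)
  d <- sqrt(rowSums(sweep(geometry$centers_mm, 2, focus_offset_mm, "-")^2))
  wrap_phase(k * (d - geometry$focal_length_mm) * 1e-3)
}

#' Steering drive for a focal offset
#'
#' Convenience constructor: full-amplitude drive with [steering_phases()],
#' optionally restricted to an active-element mask and overridden by
#' R&D per-element phases/amplitudes.
#'
#' @inheritParams steering_phases
#' @param active_mask logical element mask (default all on).
#' @param phase_overrides,amplitude_overrides optional per-element values
#'   replacing the steering phases / unit amplitudes.
#' @export
steering_drive <- function(geometry, focus_offset_mm = c(0, 0, 0),
                           frequency_mhz = 1.2, medium = water_medium(),
                           active_mask = NULL, phase_overrides = NULL,
                           amplitude_overrides = NULL) {
  n <- geometry$n_elements
  amp <- rep(1, n)
  if (!is.null(amplitude_overrides)) amp <- as.numeric(amplitude_overrides)
  if (!is.null(active_mask)) amp[!active_mask] <- 0
  ph <- steering_phases(geometry, focus_offset_mm, frequency_mhz, medium)
  if (!is.null(phase_overrides)) ph <- as.numeric(phase_overrides)
  drive_vector(amp, ph, frequency_mhz)
}

# Discretize an element disc into flat patches on its tangent plane,
# equal-area polar cells with spacing <= `spacing_mm`. Returns positions
# (n x 3, mm), areas (mm^2) and regularization radii (mm).
element_patches <- function(geometry, element, spacing_mm) {
  a <- geometry$element_radius_mm
  ctr <- geometry$centers_mm[element, ]
  nrm <- geometry$normals[element, ]
  # tangent basis
  ref <- if (abs(nrm[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * nrm) * nrm
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
          nrm[3] * e1[1] - nrm[1] * e1[3],
          nrm[1] * e1[2] - nrm[2] * e1[1])
  nr <- max(1L, ceiling(a / spacing_mm))
  pos <- vector("list", nr)
  areas <- vector("list", nr)
  for (j in seq_len(nr)) {
    r_in <- (j - 1) * a / nr; r_out <- j * a / nr
    r_mid <- (r_in + r_out) / 2
    m <- max(1L, round(2 * pi * r_mid / (a / nr)))
    psi <- (seq_len(m) - 0.5) / m * 2 * pi
    pos[[j]] <- outer(r_mid * cos(psi), e1) + outer(r_mid * sin(psi), e2)
    areas[[j]] <- rep(pi * (r_out^2 - r_in^2) / m, m)
  }
  pos <- sweep(do.call(rbind, pos), 2, ctr, "+")
  areas <- unlist(areas)
  list(positions_mm = pos, areas_mm2 = areas,
       reg_mm = sqrt(areas / pi))
}

default_patch_spacing <- function(medium) {
  # lambda / 8 at the top of the device band (1.5 MHz): keeps the on-axis
  # near field within 1% of the closed-form piston solution
  medium$sound_speed_m_s / 1.5e6 / 8 * 1e3  # mm
}

rayleigh_field <- function(points_mm, patches, u_complex, frequency_mhz,
                           medium) {
  k <- wavenumber(frequency_mhz, medium)
  alpha <- medium$attenuation_np_m_mhz * frequency_mhz  # Np/m
  raw <- rayleigh_sum_cpp(points_mm * 1e-3, patches$positions_mm * 1e-3,
                          patches$areas_mm2 * 1e-6, u_complex, k, alpha,
                          patches$reg_mm * 1e-3)
  pref <- 1i * medium$density_kg_m3 * medium$sound_speed_m_s * k / (2 * pi)
  pref * as.complex(raw)
}

#' Pressure field of a single element
#'
#' Rayleigh-Sommerfeld integral over the discretized element surface, with
#' amplitude attenuation `exp(-alpha f d)`. A field point closer to a patch
#' than the patch's own radius uses a regularized distance (the patch
#' radius) instead of diverging.
#'
#' @param geometry an `array_geometry`.
#' @param element element index (1-based).
#' @param points_mm N x 3 matrix of field points (mm, device frame).
#' @param frequency_mhz driving frequency (MHz).
#' @param medium a `medium_properties`.
#' @param u0_m_s surface normal velocity amplitude (m/s).
#' @param patch_spacing_mm surface discretization spacing; default
#'   lambda/4 at 1.5 MHz.
#' @return Complex pressure (Pa) at each point.
#' @export
element_field <- function(geometry, element, points_mm, frequency_mhz,
                          medium = water_medium(), u0_m_s = 1,
                          patch_spacing_mm = default_patch_spacing(medium)) {
  points_mm <- as_points_matrix(points_mm, "points_mm")
  patches <- element_patches(geometry, element, patch_spacing_mm)
  u <- rep(complex(real = u0_m_s), nrow(patches$positions_mm))
  rayleigh_field(points_mm, patches, u, frequency_mhz, medium)
}

#' Pressure field of the full array
#'
#' Exactly the superposition of [element_field()] over active elements
#' (amplitude > 0), with per-element drive amplitude and phase. The
#' `"far_field"` element model replaces each element's surface integral by
#' the closed-form baffled-disc directivity `2 J1(ka sin theta)/(ka sin
#' theta)`; it is accurate beyond the element Rayleigh distance
#' `a^2/lambda` (a few mm, versus the 120-mm working distance) and much
#' faster for volumetric maps.
#'
#' @inheritParams element_field
#' @param drive a [drive_vector()].
#' @param element_model `"patch"` (surface integral, default) or
#'   `"far_field"` (disc directivity).
#' @return Complex pressure (Pa) at each point.
#' @export
array_field <- function(geometry, drive, points_mm,
                        medium = water_medium(), u0_m_s = 1,
                        patch_spacing_mm = default_patch_spacing(medium),
                        element_model = c("patch", "far_field")) {
  stopifnot(inherits(drive, "drive_vector"),
            length(drive$amplitudes) == geometry$n_elements)
  element_model <- match.arg(element_model)
  points_mm <- as_points_matrix(points_mm, "points_mm")
  active <- which(drive$amplitudes > 0)
  if (length(active) == 0L) {
    return(complex(length.out = nrow(points_mm)))
  }
  if (element_model == "far_field") {
    k <- wavenumber(drive$frequency_mhz, medium)
    alpha <- medium$attenuation_np_m_mhz * drive$frequency_mhz
    u <- complex(real = 0, imaginary = 0, length.out = geometry$n_elements)
    u[active] <- u0_m_s * drive$amplitudes[active] *
      exp(1i * drive$phases_rad[active])
    raw <- element_farfield_cpp(
      points_mm * 1e-3, geometry$centers_mm * 1e-3, geometry$normals,
      rep(geometry$element_area_mm2 * 1e-6, geometry$n_elements),
      u, k, alpha, geometry$element_radius_mm * 1e-3)
    pref <- 1i * medium$density_kg_m3 * medium$sound_speed_m_s * k / (2 * pi)
    return(pref * as.complex(raw))
  }
  plist <- lapply(active, element_patches, geometry = geometry,
                  spacing_mm = patch_spacing_mm)
  counts <- vapply(plist, function(p) nrow(p$positions_mm), integer(1))
  u <- rep(u0_m_s * drive$amplitudes[active] *
             exp(1i * drive$phases_rad[active]), counts)
  patches <- list(
    positions_mm = do.call(rbind, lapply(plist, `[[`, "positions_mm")),
    areas_mm2 = unlist(lapply(plist, `[[`, "areas_mm2")),
    reg_mm = unlist(lapply(plist, `[[`, "reg_mm")))
  rayleigh_field(points_mm, patches, u, drive$frequency_mhz, medium)
}

#' Volumetric heat deposition of a drive
#'
#' Scales the drive so that the radiated acoustic power (plane-wave
#' intensity integrated over the active element surfaces, i.e. over a plane
#' just past the aperture) equals `acoustic_power_w`, computes the pressure
#' field, and converts it to a volumetric heat source
#' `Q = alpha_abs f |p|^2 / (rho c)` (W/m^3).
#'
#' @inheritParams array_field
#' @param grid a [sim_grid()] (or N x 3 point matrix).
#' @param acoustic_power_w total radiated acoustic power (W, >= 0).
#' @return Array of Q values (W/m^3) with the grid's dimensions (or a vector
#'   for a point matrix).
#' @export
heat_deposition <- function(geometry, drive, grid, medium,
                            acoustic_power_w,
                            patch_spacing_mm = default_patch_spacing(medium),
                            element_model = "patch") {
  check_scalar_number(acoustic_power_w, "acoustic_power_w", nonneg = TRUE)
  pts <- if (inherits(grid, "sim_grid")) grid_points(grid) else
    as_points_matrix(grid, "grid")
  if (acoustic_power_w == 0) {
    q <- numeric(nrow(pts))
  } else {
    rho_c <- medium$density_kg_m3 * medium$sound_speed_m_s
    area_m2 <- sum(drive$amplitudes^2) * geometry$element_area_mm2 * 1e-6
    if (area_m2 <= 0) stop("drive has no active elements", call. = FALSE)
    u0 <- sqrt(2 * acoustic_power_w / (rho_c * area_m2))
    p <- array_field(geometry, drive, pts, medium, u0_m_s = u0,
                     patch_spacing_mm = patch_spacing_mm,
                     element_model = element_model)
    alpha_abs <- medium$absorption_fraction * medium$attenuation_np_m_mhz *
      drive$frequency_mhz  # Np/m
    q <- alpha_abs * Mod(p)^2 / rho_c
  }
  if (inherits(grid, "sim_grid")) array(q, dim = grid$dims) else q
}

#' Regular simulation grid
#'
#' Axis-aligned voxel grid in the device frame; voxel centers at
#' `origin + (index - 1) * spacing` per axis.
#'
#' @param origin_mm 3-vector, position of the first voxel center (mm).
#' @param spacing_mm scalar or 3-vector voxel spacing (mm).
#' @param dims integer 3-vector of voxel counts.
#' @export
sim_grid <- function(origin_mm, spacing_mm, dims) {
  spacing_mm <- rep(as.numeric(spacing_mm), length.out = 3L)
  stopifnot(all(spacing_mm > 0), length(dims) == 3L)
  structure(list(origin_mm = as.numeric(origin_mm),
                 spacing_mm = spacing_mm,
                 dims = as.integer(dims)),
            class = "sim_grid")
}

#' @rdname sim_grid
#' @param grid a `sim_grid`.
#' @return `grid_points()`: an N x 3 matrix of voxel-center coordinates in
#'   column-major (x fastest) order, matching `array(dim = grid$dims)`.
#' @export
grid_points <- function(grid) {
  ax <- lapply(1:3, function(a) {
    grid$origin_mm[a] + (seq_len(grid$dims[a]) - 1) * grid$spacing_mm[a]
  })
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                   KEEP.OUT.ATTRS = FALSE)
  unname(as.matrix(g))
}

#' @rdname sim_grid
#' @export
grid_axes <- function(grid) {
  lapply(1:3, function(a) {
    grid$origin_mm[a] + (seq_len(grid$dims[a]) - 1) * grid$spacing_mm[a]
  })
}

#' Virtual hydrophone recording of a tone burst
#'
#' Simulates a fiber-optic hydrophone capture of one pulsed burst from a
#' single driven element: a `cycles`-cycle tone burst at the element's
#' steady-state pressure amplitude at the measurement point, repeated and
#' averaged `averages` times with additive Gaussian sample noise (averaging
#' reduces the noise variance by `1/averages`). The summary amplitude is
#' half the peak-to-peak excursion of the averaged burst.
#'
#' @inheritParams element_field
#' @param point_mm measurement point (3-vector, mm).
#' @param cycles cycles per burst.
#' @param prf_hz pulse repetition frequency (Hz; metadata, sets the
#'   repetition period the burst must fit in).
#' @param averages number of repeats averaged.
#' @param noise_sd additive noise standard deviation (Pa) per raw sample.
#' @param seed RNG seed for the noise.
#' @param samples_per_cycle waveform sampling density.
#' @return List with `time_s`, `waveform_pa` (averaged), `clean_pa`,
#'   `summary_amplitude_pa`, `burst_duration_s`.
#' @export
hydrophone_record <- function(geometry, element, point_mm, frequency_mhz = 1.2,
                              cycles = 40, prf_hz = 40, averages = 64,
                              noise_sd = 0, seed = 1L,
                              medium = water_medium(), u0_m_s = 0.05,
                              patch_spacing_mm = default_patch_spacing(medium),
                              samples_per_cycle = 16) {
  f <- frequency_mhz * 1e6
  burst <- cycles / f
  if (burst > 1 / prf_hz) {
    stop_validation("cycles", "burst longer than the repetition period")
  }
  p <- element_field(geometry, element, matrix(point_mm, ncol = 3),
                     frequency_mhz, medium, u0_m_s, patch_spacing_mm)[1]
  amp <- Mod(p); ph <- Arg(p)
  dt <- 1 / (samples_per_cycle * f)
  t <- seq(0, burst * 1.25, by = dt)
  clean <- ifelse(t <= burst, amp * sin(2 * pi * f * t + ph), 0)
  if (noise_sd > 0) {
    avg <- with_seed(seed, {
      acc <- numeric(length(t))
      for (i in seq_len(averages)) {
        acc <- acc + clean + stats::rnorm(length(t), sd = noise_sd)
      }
      acc / averages
    })
  } else {
    avg <- clean
  }
  list(time_s = t, waveform_pa = avg, clean_pa = clean,
       summary_amplitude_pa = (max(avg) - min(avg)) / 2,
       burst_duration_s = burst, n_averages = as.integer(averages))
}

# Evaluate an expression with a temporary RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
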