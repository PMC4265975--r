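#' Digital phantom (tissue property maps)
#'
#' 3D maps on a [sim_grid()]: proton density, baseline T2, the linear
#' T2-temperature slope (fat T2 rises with temperature; this is what makes
#' T2 thermometry work in marrow), and the water fraction (PRFS phase is
#' carried by water protons only — fat contributes none). Labels identify
#' tissue classes.
#'
#' @param grid a [sim_grid()].
#' @param pd proton density array (arbitrary units, >= 0).
#' @param t2_ms baseline T2 array (ms, > 0 where pd > 0).
#' @param t2_slope_ms_per_c T2 temperature slope array (ms/degC).
#' @param water_fraction array in `[0, 1]`.
#' @param labels integer array of tissue classes (see `PHANTOM_LABELS`).
#' @param baseline_temp_c baseline temperature (deg C).
#' @return A `phantom` object.
#' @export
phantom <- function(grid, pd, t2_ms, t2_slope_ms_per_c, water_fraction,
                    labels = NULL, baseline_temp_c = 37) {
  dims <- as.integer(grid$dims)
  as_map <- function(x, nm) {
    if (length(x) == 1L) x <- array(x, dim = dims)
    x <- as.array(x)
    if (!identical(dim(x), dims)) {
      stop_validation(nm, "dimensions must match the grid")
    }
    x
  }
  pd <- as_map(pd, "pd"); t2_ms <- as_map(t2_ms, "t2_ms")
  t2_slope_ms_per_c <- as_map(t2_slope_ms_per_c, "t2_slope_ms_per_c")
  water_fraction <- as_map(water_fraction, "water_fraction")
  if (any(water_fraction < 0 | water_fraction > 1)) {
    stop_validation("water_fraction", "must be within [0, 1]")
  }
  if (any(pd > 0 & t2_ms <= 0)) {
    stop_validation("t2_ms", "must be > 0 wherever pd > 0")
  }
  labels <- if (is.null(labels)) array(1L, dim = dims) else as_map(labels, "labels")
  structure(list(grid = grid, pd = pd, t2_ms = t2_ms,
                 t2_slope_ms_per_c = t2_slope_ms_per_c,
                 water_fraction = water_fraction, labels = labels,
                 baseline_temp_c = baseline_temp_c),
            class = "phantom")
}

#' Tissue label codes used by the fixture phantoms
#' @export
PHANTOM_LABELS <- c(water = 0L, soft_tissue = 1L, cortical_bone = 2L,
                    marrow = 3L, polymer_phantom = 4L)

#' Homogeneous tissue-mimicking phantom
#'
#' Emulates a polymer heating phantom: uniform proton density, water
#' fraction 1 (full PRFS sensitivity), no T2-temperature dependence.
#'
#' @inheritParams phantom
#' @param t2_ms baseline T2 (scalar, ms).
#' @export
uniform_phantom <- function(grid, pd = 1, t2_ms = 80, baseline_temp_c = 20) {
  phantom(grid, pd = pd, t2_ms = t2_ms, t2_slope_ms_per_c = 0,
          water_fraction = 1,
          labels = array(PHANTOM_LABELS[["polymer_phantom"]], grid$dims),
          baseline_temp_c = baseline_temp_c)
}

#' Bone cross-section phantom (marrow / cortical bone / soft tissue)
#'
#' A femur-diaphysis-like cylinder along the z axis: a fatty marrow core
#' (water fraction ~0, strong positive T2-temperature slope), a cortical
#' shell (low signal), and surrounding soft tissue (water fraction 1, no T2
#' slope). Built for the two-echo T2 thermometry experiments.
#'
#' @inheritParams phantom
#' @param center_mm cylinder axis position in x/y (mm).
#' @param r_marrow_mm,r_cortical_mm radii (mm).
#' @param marrow_t2_ms marrow baseline T2 (ms).
#' @param marrow_slope_ms_per_c marrow T2-temperature slope (ms/degC,
#'   default 20).
#' @export
bone_phantom <- function(grid, center_mm = c(0, 0), r_marrow_mm = 10,
                         r_cortical_mm = 15, marrow_t2_ms = 120,
                         marrow_slope_ms_per_c = 20, baseline_temp_c = 20) {
  ax <- grid_axes(grid)
  r2 <- outer((ax[[1]] - center_mm[1])^2, (ax[[2]] - center_mm[2])^2, "+")
  r <- sqrt(array(rep(r2, grid$dims[3]), dim = grid$dims))
  lab <- array(PHANTOM_LABELS[["soft_tissue"]], grid$dims)
  lab[r <= r_cortical_mm] <- PHANTOM_LABELS[["cortical_bone"]]
  lab[r <= r_marrow_mm] <- PHANTOM_LABELS[["marrow"]]
  pd <- array(1, grid$dims); pd[lab == PHANTOM_LABELS[["cortical_bone"]]] <- 0.05
  t2 <- array(60, grid$dims)  # soft tissue
  t2[lab == PHANTOM_LABELS[["cortical_bone"]]] <- 1
  t2[lab == PHANTOM_LABELS[["marrow"]]] <- marrow_t2_ms
  slope <- array(0, grid$dims)
  slope[lab == PHANTOM_LABELS[["marrow"]]] <- marrow_slope_ms_per_c
  wf <- array(1, grid$dims)
  wf[lab == PHANTOM_LABELS[["marrow"]]] <- 0.05
  wf[lab == PHANTOM_LABELS[["cortical_bone"]]] <- 0.2
  phantom(grid, pd, t2, slope, wf, lab, baseline_temp_c)
}

# Trilinear sample of a map defined on `grid` at world points (mm).
sample_map <- function(map, grid, points_mm, fill = 0) {
  idx <- sweep(sweep(points_mm, 2, grid$origin_mm, "-"), 2,
               grid$spacing_mm, "/")
  trilinear_cpp(as.double(map), as.integer(grid$dims), idx, fill)
}
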