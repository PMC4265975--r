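# Shared fixtures: small geometries and aligned phantom/sequence pairs so
# pixel centers coincide with phantom voxel centers (interpolation-exact).

tiny_geometry <- function(n = 16L) {
  make_array_geometry(n_elements = n, focal_length_mm = 120,
                      aperture_diameter_mm = 130)
}

# phantom grid and a sequence whose pixel grid lands on the voxel centers
aligned_setup <- function(n_xy = 41L, n_z = 21L, spacing = 1,
                          te_ms = 20, tr_ms = 30, b0_t = 3,
                          baseline = 20) {
  half <- (n_xy - 1) / 2 * spacing
  grid <- sim_grid(c(-half, -half, -(n_z - 1) / 2 * spacing),
                   spacing, c(n_xy, n_xy, n_z))
  ph <- uniform_phantom(grid, baseline_temp_c = baseline)
  sq <- sequence_params(fov_mm = n_xy * spacing, matrix_recon = n_xy,
                        slice_thickness_mm = 7, te_ms = te_ms, tr_ms = tr_ms,
                        dynamic_time_s = 0.59, b0_t = b0_t)
  list(grid = grid, phantom = ph, seq = sq, stack = stack_geometry())
}

# Gaussian in-plane temperature bump replicated along z, on the grid above
gaussian_delta_t <- function(grid, amp = 10, sigma_mm = 4, baseline = 20) {
  ax <- grid_axes(grid)
  plane <- outer(exp(-ax[[1]]^2 / (2 * sigma_mm^2)),
                 exp(-ax[[2]]^2 / (2 * sigma_mm^2)))
  arr <- array(rep(amp * plane, grid$dims[3]), dim = grid$dims)
  list(delta = arr, field = temperature_field(baseline + arr, grid, 1))
}

demo_protocol <- function(power = 10, dur = 5) {
  assemble_protocol("Protocol_1", list(
    build_pause(1),
    build_continuous_exposure(power, 1.2, NULL, dur),
    build_pause(wait_for_previous = TRUE),
    build_pause(Inf)))
}

rad_per_degc <- function(te_ms, b0_t = 3) {
  2 * pi * 42.576e6 * b0_t * (-0.01e-6) * te_ms * 1e-3
}
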