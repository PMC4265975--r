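#' PRFS and gyromagnetic constants
#'
#' The water proton resonance frequency shifts by about -0.01 ppm per degC;
#' together with the gyromagnetic ratio (42.576 MHz/T) this turns MR phase
#' at echo time TE into a thermometer.
#' @export
GAMMA_MHZ_PER_T <- 42.576

#' @rdname GAMMA_MHZ_PER_T
#' @export
ALPHA_PRFS_PPM_PER_C <- -0.01

#' MR sequence parameters
#'
#' Acquisition metadata for synthesized frames. Echo train length, flip
#' angle and NEX are carried as metadata only (no k-space simulation).
#'
#' @param fov_mm field of view (mm).
#' @param matrix_acq acquisition matrix (metadata).
#' @param matrix_recon reconstruction matrix (pixels per side).
#' @param slice_thickness_mm slice thickness (mm).
#' @param te_ms echo time(s) (ms): one value, or `c(TE1, TE2)` for a
#'   two-echo T2 measurement.
#' @param tr_ms repetition time (ms), > max(TE).
#' @param flip_deg flip angle (degrees).
#' @param etl echo train length.
#' @param nex number of excitations.
#' @param dynamic_time_s time between successive dynamics (s).
#' @param b0_t main field strength (T).
#' @export
sequence_params <- function(fov_mm, matrix_acq = matrix_recon, matrix_recon,
                            slice_thickness_mm, te_ms, tr_ms, flip_deg = 19.5,
                            etl = 1, nex = 1, dynamic_time_s, b0_t = 3) {
  for (nm in c("fov_mm", "matrix_recon", "slice_thickness_mm", "tr_ms",
               "dynamic_time_s", "b0_t")) {
    check_scalar_number(get(nm), nm, positive = TRUE)
  }
  te_ms <- as.numeric(te_ms)
  if (length(te_ms) < 1L || length(te_ms) > 2L || any(te_ms <= 0)) {
    stop_validation("te_ms", "must be one or two positive echo times")
  }
  if (max(te_ms) >= tr_ms) stop_validation("te_ms", "must be < tr_ms")
  structure(list(fov_mm = fov_mm, matrix_acq = matrix_acq,
                 matrix_recon = as.integer(matrix_recon),
                 pixel_mm = fov_mm / matrix_recon,
                 slice_thickness_mm = slice_thickness_mm,
                 te_ms = te_ms, tr_ms = tr_ms, flip_deg = flip_deg,
                 etl = etl, nex = nex, dynamic_time_s = dynamic_time_s,
                 b0_t = b0_t),
            class = "sequence_params")
}

#' Imaging stack geometry
#'
#' Position and orientation of an imaging stack; redefinable in real time on
#' the virtual scanner. `axes` rows are (row direction, column direction,
#' slice normal) and must form a right-handed orthonormal triad.
#'
#' @param center_mm stack center (mm, device frame).
#' @param axes 3 x 3 matrix of row-wise unit axes.
#' @param n_slices number of slices.
#' @param slice_spacing_mm spacing between slice centers (mm).
#' @export
stack_geometry <- function(center_mm = c(0, 0, 0), axes = diag(3),
                           n_slices = 1L, slice_spacing_mm = 5) {
  axes <- as.matrix(axes)
  if (!isTRUE(all.equal(axes %*% t(axes), diag(3), tolerance = 1e-8))) {
    stop_validation("axes", "must be orthonormal")
  }
  if (det(axes) < 0) {
    stop_validation("axes", "must be right-handed (det = +1)")
  }
  structure(list(center_mm = as.numeric(center_mm), axes = axes,
                 n_slices = as.integer(n_slices),
                 slice_spacing_mm = slice_spacing_mm),
            class = "stack_geometry")
}

slice_center <- function(stack, slice) {
  off <- (slice - (stack$n_slices + 1) / 2) * stack$slice_spacing_mm
  stack$center_mm + off * stack$axes[3, ]
}

#' Synthesize one MR image frame from a phantom and a temperature field
#'
#' Pixel-wise signal model on the reconstructed grid (trilinear sampling of
#' the phantom at voxel centers; pixel grid defined by FOV/matrix, LR
#' increasing with +x):
#' magnitude per echo `S_e = PD * exp(-TE_e / T2(T))` with
#' `T2(T) = T2_baseline + slope * dT`, and phase
#' `phi = wrap(2 pi gamma B0 alpha_PRFS TE1 dT * water_fraction + drift)`.
#' Complex Gaussian noise is added before magnitude/phase extraction.
#' Slices outside the phantom yield frames of zeros (not an error).
#'
#' @param phantom a [phantom()].
#' @param temp a [temperature_field()] on the phantom grid, or `NULL` for
#'   baseline temperature.
#' @param stack a [stack_geometry()].
#' @param seq a [sequence_params()].
#' @param slice slice number (1-based).
#' @param dynamic dynamic number (0-based counter).
#' @param acq_time_s acquisition timestamp (s).
#' @param drift_phase_rad spatially uniform B0-drift phase (radians).
#' @param noise_sd complex-noise standard deviation (signal units).
#' @param seed RNG seed for the noise (`NULL` = use current RNG state).
#' @param image_type image type tag.
#' @param stack_id stack identifier.
#' @param statics optional precomputed static pixel samples (internal
#'   caching hook used by [VirtualScanner]).
#' @return An `image_frame`: `magnitude` (list, one matrix per echo),
#'   `phase_rad` matrix in `(-pi, pi]`, geometry and acquisition metadata.
#' @export
synthesize_frame <- function(phantom, temp = NULL, stack, seq, slice = 1L,
                             dynamic = 0L, acq_time_s = 0,
                             drift_phase_rad = 0, noise_sd = 0, seed = NULL,
                             image_type = "FFE", stack_id = 1L,
                             statics = NULL) {
  n <- seq$matrix_recon
  if (is.null(statics)) statics <- frame_statics(phantom, stack, seq, slice)
  pts <- statics$pts; pd <- statics$pd; t2 <- statics$t2
  slope <- statics$slope; wf <- statics$wf; ctr <- statics$ctr
  gr <- phantom$grid
  dT <- if (is.null(temp)) numeric(n * n) else
    sample_map(temp$values - phantom$baseline_temp_c, gr, pts, fill = 0)
  t2_hot <- pmax(t2 + slope * dT, 1e-3)
  phi <- wrap_phase(2 * pi * (GAMMA_MHZ_PER_T * 1e6) * seq$b0_t *
                      (ALPHA_PRFS_PPM_PER_C * 1e-6) * (seq$te_ms[1] * 1e-3) *
                      dT * wf + drift_phase_rad)
  make_echo <- function(te) pd * exp(-te / t2_hot)
  signals <- lapply(seq$te_ms, make_echo)
  if (noise_sd > 0) {
    noise_fun <- function() {
      lapply(seq_along(signals), function(e) {
        s <- signals[[e]] * exp(1i * phi)
        s + complex(real = stats::rnorm(n * n, sd = noise_sd),
                    imaginary = stats::rnorm(n * n, sd = noise_sd))
      })
    }
    cx <- if (is.null(seed)) noise_fun() else with_seed(seed, noise_fun())
    mags <- lapply(cx, Mod)
    phase <- Arg(cx[[1]])
  } else {
    mags <- signals
    phase <- phi
  }
  structure(list(
    magnitude = lapply(mags, matrix, nrow = n, ncol = n),
    phase_rad = matrix(phase, nrow = n, ncol = n),
    image_type = image_type, stack_id = as.integer(stack_id),
    slice = as.integer(slice), dynamic = as.integer(dynamic),
    acq_time_s = acq_time_s,
    geometry = list(center_mm = ctr, axes = stack$axes),
    seq = seq), class = "image_frame")
}

# static (temperature-independent) per-pixel samples for a stack/slice:
# world coordinates of the pixel centers and the phantom property maps
frame_statics <- function(phantom, stack, seq, slice) {
  n <- seq$matrix_recon
  px <- seq$pixel_mm
  u <- (seq_len(n) - (n + 1) / 2) * px
  ctr <- slice_center(stack, slice)
  g <- expand.grid(u = u, v = u, KEEP.OUT.ATTRS = FALSE)
  pts <- cbind(ctr[1] + g$u * stack$axes[1, 1] + g$v * stack$axes[2, 1],
               ctr[2] + g$u * stack$axes[1, 2] + g$v * stack$axes[2, 2],
               ctr[3] + g$u * stack$axes[1, 3] + g$v * stack$axes[2, 3])
  gr <- phantom$grid
  list(pts = pts, ctr = ctr,
       pd = sample_map(phantom$pd, gr, pts, fill = 0),
       t2 = pmax(sample_map(phantom$t2_ms, gr, pts, fill = 1), 1e-3),
       slope = sample_map(phantom$t2_slope_ms_per_c, gr, pts, fill = 0),
       wf = sample_map(phantom$water_fraction, gr, pts, fill = 0))
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image frame: %s stack %d slice %d dyn %d t=%.3g s, %d echo(es)>\n",
              x$image_type, x$stack_id, x$slice, x$dynamic, x$acq_time_s,
              length(x$magnitude)))
  invisible(x)
}

#' Virtual MR scanner with a dynamic image stream
#'
#' Synthesizes dynamic frames from a phantom plus a (time-dependent)
#' temperature field, and exposes the real-time stream interface:
#' subscribe / query / unsubscribe, pause / resume, stack repositioning and
#' volumetric acquisition. Every subscriber receives every frame in its own
#' FIFO queue; a continuously querying consumer keeps its queue at length
#' <= 1. Frame timestamps advance by exactly `dynamic_time_s` while
#' running; dynamic numbering continues without gaps across pause/resume.
#'
#' @export
VirtualScanner <- R6::R6Class("VirtualScanner",
  public = list(
    #' @field phantom the [phantom()] being imaged.
    phantom = NULL,
    #' @field seq the [sequence_params()].
    seq = NULL,
    #' @field temp_provider `function(t)` returning a [temperature_field()]
    #'   (or `NULL` for baseline).
    temp_provider = NULL,

    #' @description Create a scanner.
    #' @param phantom a [phantom()].
    #' @param seq a [sequence_params()].
    #' @param stack a [stack_geometry()] (the real-time stack), or a list of
    #'   stacks for volumetric acquisition.
    #' @param temp_provider `function(t)` -> [temperature_field()] or NULL.
    #' @param drift_rad_per_dynamic spatially uniform phase drift added per
    #'   dynamic (linear in dynamic number), emulating slow B0 drift.
    #' @param noise_sd complex noise sd.
    #' @param seed base RNG seed; frame `d` uses `seed + d`.
    #' @param image_types character vector of image type tags for
    #'   volumetric acquisition (real-time frames use the first).
    initialize = function(phantom, seq, stack = stack_geometry(),
                          temp_provider = NULL, drift_rad_per_dynamic = 0.02,
                          noise_sd = 0, seed = 1L, image_types = "FFE") {
      self$phantom <- phantom; self$seq <- seq
      private$stacks <- if (inherits(stack, "stack_geometry")) list(stack)
                        else stack
      self$temp_provider <- temp_provider
      private$drift <- drift_rad_per_dynamic
      private$noise_sd <- noise_sd
      private$seed <- as.integer(seed)
      private$types <- image_types
      private$next_acq <- seq$dynamic_time_s
      invisible(self)
    },

    #' @description Subscribe to the image stream.
    #' @return An opaque stream handle.
    subscribe = function() {
      h <- sprintf("sub%d", private$next_handle)
      private$next_handle <- private$next_handle + 1L
      private$queues[[h]] <- list()
      h
    },

    #' @description Stop delivery to a handle.
    #' @param handle stream handle from `$subscribe()`.
    unsubscribe = function(handle) {
      private$check_handle(handle)
      private$queues[[handle]] <- NULL
      invisible(self)
    },

    #' @description Pull the oldest queued frame (FIFO), or `NULL` when the
    #'   queue is empty. Non-blocking.
    #' @param handle stream handle.
    query_new_image = function(handle) {
      private$check_handle(handle)
      q <- private$queues[[handle]]
      if (length(q) == 0L) return(NULL)
      frame <- q[[1L]]
      private$queues[[handle]] <- q[-1L]
      frame
    },

    #' @description Queue length for a handle.
    #' @param handle stream handle.
    queue_length = function(handle) {
      private$check_handle(handle)
      length(private$queues[[handle]])
    },

    #' @description Pause frame production (no-op if already paused).
    pause_scan = function() { private$paused <- TRUE; invisible(self) },

    #' @description Resume frame production; the next frame is acquired one
    #'   dynamic time after resuming and continues the dynamic numbering.
    resume_scan = function() {
      if (private$paused) {
        private$paused <- FALSE
        private$next_acq <- private$time + self$seq$dynamic_time_s
      }
      invisible(self)
    },

    #' @description Reposition/reorient an imaging stack; takes effect from
    #'   the next synthesized frame. Non-orthonormal axes are rejected.
    #' @param stack a [stack_geometry()].
    #' @param stack_id which stack to replace (default 1, the real-time one).
    set_stack_geometry = function(stack, stack_id = 1L) {
      stopifnot(inherits(stack, "stack_geometry"))
      private$stacks[[stack_id]] <- stack
      private$statics <- list()  # pixel grid changed; drop cached samples
      invisible(self)
    },

    #' @description Current stack geometry.
    #' @param stack_id which stack (default 1).
    get_stack_geometry = function(stack_id = 1L) private$stacks[[stack_id]],

    #' @description Advance the scanner clock, producing one frame per
    #'   elapsed dynamic time (unless paused) into every subscriber queue.
    #' @param dt seconds (>= 0).
    #' @return Invisibly, the frames produced during this call.
    advance = function(dt) {
      check_scalar_number(dt, "dt", nonneg = TRUE)
      t_end <- private$time + dt
      produced <- list()
      while (!private$paused && private$next_acq <= t_end + 1e-9) {
        private$time <- private$next_acq
        frame <- private$make_frame(private$types[1], 1L, 1L)
        private$dynamic <- private$dynamic + 1L
        private$next_acq <- private$next_acq + self$seq$dynamic_time_s
        for (h in names(private$queues)) {
          private$queues[[h]] <- c(private$queues[[h]], list(frame))
        }
        produced <- c(produced, list(frame))
      }
      private$time <- max(private$time, t_end)
      invisible(produced)
    },

    #' @description Acquire a full volume now: one frame per (image type,
    #'   stack, slice), ordered by type, then stack, then slice number.
    #' @param handle stream handle (must be subscribed).
    #' @return Ordered list of `image_frame`s.
    acquire_volume = function(handle) {
      private$check_handle(handle)
      frames <- list()
      for (ty in sort(private$types)) {
        for (st in seq_along(private$stacks)) {
          for (sl in seq_len(private$stacks[[st]]$n_slices)) {
            frames <- c(frames, list(private$make_frame(ty, st, sl)))
          }
        }
      }
      private$dynamic <- private$dynamic + 1L
      frames
    },

    #' @description Scanner clock (s).
    now = function() private$time,
    #' @description Number of frames produced so far.
    frames_produced = function() private$dynamic
  ),

  private = list(
    stacks = NULL, drift = 0, noise_sd = 0, seed = 1L, types = "FFE",
    time = 0, next_acq = 0, dynamic = 0L, paused = FALSE,
    queues = list(), next_handle = 1L, statics = list(),

    check_handle = function(handle) {
      if (!is.character(handle) || !handle %in% names(private$queues)) {
        stop("not subscribed: query/unsubscribe requires a live stream handle",
             call. = FALSE)
      }
    },

    make_frame = function(type, stack_id, slice) {
      temp <- if (is.null(self$temp_provider)) NULL else
        self$temp_provider(private$time)
      key <- sprintf("%d.%d", stack_id, slice)
      if (is.null(private$statics[[key]])) {
        private$statics[[key]] <- frame_statics(
          self$phantom, private$stacks[[stack_id]], self$seq, slice)
      }
      synthesize_frame(self$phantom, temp, private$stacks[[stack_id]], self$seq,
                       statics = private$statics[[key]],
                       slice = slice, dynamic = private$dynamic,
                       acq_time_s = private$time,
                       drift_phase_rad = private$drift * private$dynamic,
                       noise_sd = private$noise_sd,
                       seed = if (private$noise_sd > 0)
                         private$seed + private$dynamic else NULL,
                       image_type = type, stack_id = stack_id)
    }
  )
)
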