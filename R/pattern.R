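#' Heating pattern spelling the word 'HIFU'
#'
#' Ten straight 18-mm segments grouped into four letters (H: 3, I: 1,
#' F: 3, U: 3), ordered 1-10, drawn left to right along +LR (x) in the
#' y = HF plane. Each letter fits a 20 x 18 mm bounding box; letter centers
#' are spaced `letter_pitch_mm` apart. The transducer is moved to the
#' center of each letter and each segment is then produced by electronic
#' steering along the line, so segment coordinates are stored both
#' absolutely and as offsets from their letter center.
#'
#' @param center_mm pattern center (3-vector, mm, device frame).
#' @param letter_pitch_mm spacing between letter centers (mm, default 25).
#' @param segment_length_mm segment length (mm, default 18).
#' @return A `hifu_pattern`: data frame `segments` with columns `order`,
#'   `letter`, start/end coordinates, and the letter centers.
#' @export
generate_hifu_pattern <- function(center_mm = c(0, 0, 0),
                                  letter_pitch_mm = 25,
                                  segment_length_mm = 18) {
  h <- segment_length_mm / 2       # strokes are segment_length long
  w <- 10                          # letter half-width (20-mm box)
  # per-letter strokes in letter-local (x, y) coordinates
  strokes <- list(
    H = list(c(-w, -h, -w, h),          # left vertical
             c(w, -h, w, h),            # right vertical
             c(-h, 0, h, 0)),           # crossbar
    I = list(c(0, -h, 0, h)),
    F = list(c(-w, -h, -w, h),          # vertical
             c(-w, h, -w + 2 * h, h),   # top horizontal
             c(-w, 0, -w + 2 * h, 0)),  # middle horizontal
    U = list(c(-w, h, -w, h - 2 * h),   # left vertical (downward)
             c(-h, -h, h, -h),          # bottom horizontal
             c(w, h, w, h - 2 * h)))    # right vertical
  letters <- names(strokes)
  n_letters <- length(letters)
  cx <- (seq_len(n_letters) - (n_letters + 1) / 2) * letter_pitch_mm
  rows <- list()
  ord <- 0L
  centers <- matrix(0, n_letters, 3)
  for (li in seq_len(n_letters)) {
    lc <- center_mm + c(cx[li], 0, 0)
    centers[li, ] <- lc
    for (s in strokes[[li]]) {
      ord <- ord + 1L
      rows[[ord]] <- data.frame(
        order = ord, letter = letters[li],
        x0 = lc[1] + s[1], y0 = lc[2] + s[2], z0 = lc[3],
        x1 = lc[1] + s[3], y1 = lc[2] + s[4], z1 = lc[3],
        # steering offsets relative to the letter center
        ox0 = s[1], oy0 = s[2], ox1 = s[3], oy1 = s[4],
        stringsAsFactors = FALSE)
    }
  }
  segments <- do.call(rbind, rows)
  rownames(centers) <- letters
  structure(list(segments = segments, letter_centers_mm = centers,
                 segment_length_mm = segment_length_mm,
                 letter_pitch_mm = letter_pitch_mm),
            class = "hifu_pattern")
}

#' @export
print.hifu_pattern <- function(x, ...) {
  cat(sprintf("<'HIFU' heating pattern: %d segments, %d letters, %.0f-mm lines>\n",
              nrow(x$segments), nrow(x$letter_centers_mm),
              x$segment_length_mm))
  invisible(x)
}

#' Steering trajectory for one pattern segment
#'
#' Samples segment `order` of the pattern at `step_mm` steps (endpoints
#' inclusive; 18 mm at 2-mm steps gives 10 points), as focal offsets from
#' the letter center the transducer is parked at.
#'
#' @param pattern a [generate_hifu_pattern()] result.
#' @param order segment number (1-10).
#' @param step_mm steering step (mm, default 2).
#' @param interval_ms trajectory interval (ms, default 25).
#' @return A [focus_trajectory()].
#' @export
segment_trajectory <- function(pattern, order, step_mm = 2, interval_ms = 25) {
  seg <- pattern$segments[pattern$segments$order == order, ]
  stopifnot(nrow(seg) == 1L)
  line_trajectory(c(seg$ox0, seg$oy0, 0), c(seg$ox1, seg$oy1, 0),
                  step_mm, interval_ms)
}

# distance (mm) of points (N x 2, in-plane) from a segment given in-plane
segment_distance <- function(px, py, x0, y0, x1, y1) {
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- vx^2 + vy^2
  t <- ((px - x0) * vx + (py - y0) * vy) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((px - (x0 + t * vx))^2 + (py - (y0 + t * vy))^2)
}
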