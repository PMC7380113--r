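#' Longest vertical chord of a mask
#'
#' For every column, the topmost and bottommost foreground pixels define a
#' candidate chord; the chord with the largest pixel distance is returned
#' (ties toward the smaller column index). Lengths are pixel-centre
#' distances, so a single-row mask has chord length 0.
#'
#' @param mask 0/1 matrix, non-empty.
#' @return list with `p_top`, `p_bottom` (0-based `(x, y)`) and `length_px`.
#' @export
max_vertical_chord <- function(mask) {
  mask <- as_binary_mask(mask)
  idx <- which(mask == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) abort_validation("empty mask")
  cols <- sort(unique(idx[, 2L]))
  top <- vapply(split(idx[, 1L], idx[, 2L]), min, numeric(1))
  bot <- vapply(split(idx[, 1L], idx[, 2L]), max, numeric(1))
  len <- bot - top
  k <- which.max(len)               # ties -> smaller column
  x <- cols[k] - 1L
  list(p_top = c(x, top[k] - 1L), p_bottom = c(x, bot[k] - 1L),
       length_px = as.numeric(len[k]))
}

#' Convert a pixel length to millimeters
#'
#' The PPC is the number of pixels in one centimeter, so
#' `width_mm = 10 * pixel_length / ppc`.
#'
#' @param pixel_length chord length in pixels (>= 0).
#' @param ppc pixels per centimeter (> 0).
#' @return length in millimeters.
#' @export
to_physical <- function(pixel_length, ppc) {
  if (!is.numeric(ppc) || ppc <= 0) abort_validation("ppc must be positive")
  if (pixel_length < 0) abort_validation("pixel length must be non-negative")
  10 * pixel_length / ppc
}

#' Measure the LV width from a segmentation mask
#'
#' The minimum-enclosing-rectangle method: fit the mask's minimum-area
#' rotated rectangle, rotate the mask so the rectangle's long edge is
#' horizontal, scan all columns for the longest vertical chord, map the chord
#' endpoints back to original image coordinates, and convert the pixel length
#' to millimeters with the PPC.
#'
#' @param mask 0/1 LV segmentation mask (largest component is used if
#'   several are present).
#' @param ppc pixels-per-centimeter: a number or an `lv_ppc_estimate`.
#' @return an `lv_diameter_measurement`: `endpoint_a`, `endpoint_b` (0-based
#'   `(x, y)` in the original image), `pixel_length`, `theta_deg` (enclosing
#'   rectangle angle), `width_mm`, `ppc_used`.
#' @export
measure_lv <- function(mask, ppc) {
  ppc_val <- if (inherits(ppc, "lv_ppc_estimate")) ppc$ppc else ppc
  if (!is.numeric(ppc_val) || length(ppc_val) != 1L || ppc_val <= 0)
    abort_validation("ppc must be a positive number or an lv_ppc_estimate")
  mask <- as_binary_mask(mask)
  if (sum(mask) == 0L) abort_validation("empty mask")
  mask <- largest_component(mask, warn = TRUE)
  rect <- min_enclosing_rect(mask)
  rot <- rotate_to_horizontal(mask, rect$long_angle_deg)
  chord <- max_vertical_chord(rot$mask)
  ends <- transform_points(rbind(chord$p_top, chord$p_bottom),
                           rot$transform, inverse = TRUE)
  structure(list(endpoint_a = as.numeric(ends[1L, ]),
                 endpoint_b = as.numeric(ends[2L, ]),
                 pixel_length = chord$length_px,
                 theta_deg = rect$theta_deg,
                 width_mm = to_physical(chord$length_px, ppc_val),
                 ppc_used = ppc_val),
            class = "lv_diameter_measurement")
}

#' @export
print.lv_diameter_measurement <- function(x, ...) {
  cat(sprintf(
    "<LV width: %.1f mm (%.1f px at %.1f px/cm, theta %.1f deg)>\n",
    round(x$width_mm, 1), x$pixel_length, x$ppc_used, x$theta_deg))
  invisible(x)
}

#' Serialise a diameter measurement to JSON
#'
#' `width_mm` is reported to 0.1 mm, the on-screen display convention of
#' clinical scanners; all other fields keep full precision.
#'
#' @param measurement an `lv_diameter_measurement`.
#' @param ppc_estimate optional `lv_ppc_estimate` whose caliper type is
#'   recorded alongside.
#' @param path output file.
#' @export
write_measurement_json <- function(measurement, path, ppc_estimate = NULL) {
  jsonlite::write_json(measurement_record(measurement, ppc_estimate),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

measurement_record <- function(measurement, ppc_estimate = NULL) {
  list(width_mm = round(measurement$width_mm, 1),
       pixel_length = measurement$pixel_length,
       ppc = measurement$ppc_used,
       caliper_type = if (is.null(ppc_estimate)) NULL else
         ppc_estimate$caliper_type,
       theta_deg = measurement$theta_deg,
       endpoints = list(measurement$endpoint_a, measurement$endpoint_b))
}
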