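#' Specification of a synthetic caliper ruler
#'
#' Describes the on-screen ruler rendered by [generate_caliper()]: a column
#' of short bright horizontal bars. A `"10"` ruler has identical bars 10 mm
#' apart; a `"5"` ruler alternates long ("big") and short ("small") bars 5 mm
#' apart. Bars are `tick_height` rows tall and centred on `column_x`; a
#' tick's reference point is the top-left pixel of its bar.
#'
#' @param caliper_type `"5"` or `"10"`.
#' @param spacing_px pixel distance between adjacent tick reference points
#'   (> 3).
#' @param n_ticks number of ticks (>= 3).
#' @param big_tick_len,small_tick_len bar lengths in pixels; the `"5"` type
#'   alternates both (ratio at least 1.5), the `"10"` type uses
#'   `big_tick_len` only.
#' @param tick_height bar thickness in rows (2 or 3).
#' @param column_x 0-based column of the ruler line.
#' @param tick_intensity bar intensity, 0--255.
#' @return a list of class `lv_caliper_spec`.
#' @export
caliper_spec <- function(caliper_type = c("10", "5"), spacing_px, n_ticks,
                         big_tick_len = 9L, small_tick_len = 4L,
                         tick_height = 2L, column_x = 20L,
                         tick_intensity = 255L) {
  caliper_type <- match.arg(as.character(caliper_type), c("10", "5"))
  if (spacing_px <= 3L) abort_validation("spacing_px must exceed 3")
  if (n_ticks < 3L) abort_validation("need at least 3 ticks")
  if (caliper_type == "5" && big_tick_len < 1.5 * small_tick_len)
    abort_validation("5-caliper needs big/small tick ratio >= 1.5")
  if (!tick_height %in% 2:3)
    abort_validation("tick_height must be 2 or 3")
  structure(list(caliper_type = caliper_type,
                 spacing_px = as.integer(spacing_px),
                 n_ticks = as.integer(n_ticks),
                 big_tick_len = as.integer(big_tick_len),
                 small_tick_len = as.integer(small_tick_len),
                 tick_height = as.integer(tick_height),
                 column_x = as.integer(column_x),
                 tick_intensity = as.integer(tick_intensity)),
            class = "lv_caliper_spec")
}

# PPC implied by a ruler spec: ticks are 10 mm apart on a "10" ruler,
# 5 mm on a "5" ruler.
spec_ppc <- function(spec) {
  if (spec$caliper_type == "5") 2 * spec$spacing_px else
    as.numeric(spec$spacing_px)
}

# multiplicative uniform speckle on a low-intensity background
speckle_background <- function(nrow, ncol, noise_level, base_intensity = 20) {
  if (noise_level < 0 || noise_level > 1)
    abort_validation("noise_level must be in [0, 1]")
  u <- matrix(stats::runif(nrow * ncol, -1, 1), nrow, ncol)
  px <- round(base_intensity * (1 + noise_level * u))
  px[px < 0] <- 0; px[px > 255] <- 255
  px
}

# paint the ruler bars onto an existing image; returns image + tick geometry
paint_caliper <- function(image, spec, y0) {
  tick_y <- y0 + (seq_len(spec$n_ticks) - 1L) * spec$spacing_px
  lens <- if (spec$caliper_type == "5") {
    ifelse(seq_len(spec$n_ticks) %% 2L == 1L, spec$big_tick_len,
           spec$small_tick_len)
  } else rep(spec$big_tick_len, spec$n_ticks)
  for (i in seq_len(spec$n_ticks)) {
    x0 <- spec$column_x - lens[i] %/% 2L
    rows <- (tick_y[i] + 1L):(tick_y[i] + spec$tick_height)
    cols <- (x0 + 1L):(x0 + lens[i])
    if (min(cols) < 1L || max(cols) > ncol(image))
      abort_dimension("tick bar exceeds canvas width")
    image[rows, cols] <- spec$tick_intensity
  }
  xs <- spec$column_x - max(lens) %/% 2L
  box <- c(max(0L, xs - 3L), max(0L, tick_y[1L] - 3L),
           min(ncol(image), xs + max(lens) + 3L),
           min(nrow(image), tick_y[spec$n_ticks] + spec$tick_height + 3L))
  list(image = image, tick_y = tick_y, box = as.integer(box))
}

#' Render a synthetic caliper ruler on a speckled background
#'
#' @param spec [caliper_spec()].
#' @param image_height,image_width canvas size in pixels.
#' @param noise_level speckle amplitude in \[0, 1\] (multiplicative, on the
#'   background only).
#' @param seed RNG seed; identical inputs give bit-identical images.
#' @return list with `image` (gray matrix) and `truth`: `tick_y` (0-based
#'   reference rows), `spacing_px`, `caliper_type`, `ppc`, `column_x`, `box`,
#'   `seed`.
#' @export
generate_caliper <- function(spec, image_height, noise_level = 0, seed = 0L,
                             image_width = 64L) {
  span <- (spec$n_ticks - 1L) * spec$spacing_px + spec$tick_height
  margin <- (image_height - span) %/% 2L
  if (margin < 3L)
    abort_dimension("caliper does not fit the canvas height")
  img <- with_seed(seed, speckle_background(image_height, image_width,
                                            noise_level))
  painted <- paint_caliper(img, spec, y0 = margin)
  list(image = as_gray_image(painted$image),
       truth = list(tick_y = painted$tick_y, spacing_px = spec$spacing_px,
                    caliper_type = spec$caliper_type, ppc = spec_ppc(spec),
                    column_x = spec$column_x, box = painted$box,
                    seed = as.integer(seed)))
}

#' Render a rotated elliptical LV-like blob
#'
#' A filled bright ellipse whose minor axis has a known physical width: the
#' minor axis in pixels is `ppc * width_mm / 10`, the major axis is
#' `major_minor_ratio` times that, and the ellipse is rotated by `theta_deg`.
#' The returned mask is the exact rasterisation (pixel centres inside the
#' ellipse).
#'
#' @param width_mm physical minor-axis width (> 0).
#' @param ppc pixels per centimeter.
#' @param major_minor_ratio major/minor axis ratio (>= 1).
#' @param theta_deg rotation of the major axis from horizontal, degrees.
#' @param center `(x, y)` ellipse centre (0-based pixel coordinates; may be
#'   fractional).
#' @param canvas `c(height, width)` of the output.
#' @param intensity blob intensity.
#' @return list with `image` (blob on black) and `mask` (0/1).
#' @export
generate_lv_blob <- function(width_mm, ppc, major_minor_ratio = 1.8,
                             theta_deg = 0, center, canvas,
                             intensity = 200L) {
  if (width_mm <= 0) abort_validation("width_mm must be positive")
  if (major_minor_ratio < 1) abort_validation("major_minor_ratio must be >= 1")
  b <- ppc * width_mm / 10 / 2          # semi-minor, px
  a <- major_minor_ratio * b            # semi-major, px
  t <- theta_deg * pi / 180
  ex <- sqrt((a * cos(t))^2 + (b * sin(t))^2)
  ey <- sqrt((a * sin(t))^2 + (b * cos(t))^2)
  nr <- canvas[1L]; nc <- canvas[2L]
  if (center[1L] - ex < 0 || center[1L] + ex > nc - 1 ||
      center[2L] - ey < 0 || center[2L] + ey > nr - 1)
    abort_dimension("ellipse exceeds canvas")
  x <- rep(0:(nc - 1L), each = nr) - center[1L]
  y <- rep(0:(nr - 1L), times = nc) - center[2L]
  u <- x * cos(t) + y * sin(t)
  v <- -x * sin(t) + y * cos(t)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  mask <- matrix(as.integer(inside), nr, nc)
  img <- mask * as.integer(intensity)
  list(image = as_gray_image(img), mask = as_binary_mask(mask))
}

#' Compose a full synthetic ultrasound phantom scene
#'
#' One canvas holding a caliper ruler, an LV blob and a speckled background
#' (noise applied to the background only), with complete ground truth. The
#' caliper and LV regions must not overlap.
#'
#' @param caliper_spec [caliper_spec()].
#' @param lv_params list with `width_mm`, and optionally `theta_deg` (default
#'   0), `major_minor_ratio` (default 1.8), `center` (default: right of
#'   centre), `intensity` (default 200).
#' @param canvas `c(height, width)` (default `c(400, 520)`).
#' @param noise_level speckle amplitude in \[0, 1\].
#' @param seed RNG seed.
#' @param n_distractors optional count of small bright distractor blobs
#'   emulating LV-like structures elsewhere in the image (default 0).
#' @return list of class `lv_scene`: `image`, `truth` (an
#'   `lv_scene_truth` with `true_ppc`, `caliper_type`, `spacing_px`,
#'   `true_width_mm`, `true_width_px`, `theta_true_deg`, `lv_mask`, `lv_box`,
#'   `caliper_box`, `tick_y`, `column_x`, `seed`).
#' @export
compose_scene <- function(caliper_spec, lv_params, canvas = c(400L, 520L),
                          noise_level = 0, seed = 0L, n_distractors = 0L) {
  p <- lv_params
  if (is.null(p$width_mm)) abort_validation("lv_params$width_mm is required")
  theta <- if (is.null(p$theta_deg)) 0 else p$theta_deg
  ratio <- if (is.null(p$major_minor_ratio)) 1.8 else p$major_minor_ratio
  intensity <- if (is.null(p$intensity)) 200L else p$intensity
  center <- if (is.null(p$center))
    c((canvas[2L] - 1) / 2 + canvas[2L] / 6, (canvas[1L] - 1) / 2) else
    p$center
  ppc <- spec_ppc(caliper_spec)

  img <- with_seed(seed, speckle_background(canvas[1L], canvas[2L],
                                            noise_level))
  span <- (caliper_spec$n_ticks - 1L) * caliper_spec$spacing_px +
    caliper_spec$tick_height
  y0 <- (canvas[1L] - span) %/% 2L
  if (y0 < 3L) abort_dimension("caliper does not fit the canvas height")
  painted <- paint_caliper(img, caliper_spec, y0)
  img <- painted$image

  blob <- generate_lv_blob(p$width_mm, ppc, ratio, theta, center, canvas,
                           intensity)
  lv_box <- box_from_mask(blob$mask)
  if (box_iou(lv_box, painted$box) > 0 ||
      lv_box[1L] < painted$box[3L] && lv_box[3L] > painted$box[1L] &&
      lv_box[2L] < painted$box[4L] && lv_box[4L] > painted$box[2L])
    abort_layout("LV and caliper regions overlap")
  img[blob$mask == 1L] <- intensity

  if (n_distractors > 0L) {
    img <- with_seed(seed + 1L, {
      for (k in seq_len(n_distractors)) {
        dc <- c(stats::runif(1, painted$box[3L] + 30, canvas[2L] - 30),
                stats::runif(1, 30, canvas[1L] - 30))
        d <- generate_lv_blob(2.5, ppc, 1.2, stats::runif(1, 0, 180), dc,
                              canvas, intensity)
        clash <- d$mask == 1L & blob$mask == 1L
        if (!any(clash)) img[d$mask == 1L] <- intensity
      }
      img
    })
  }

  truth <- structure(
    list(true_ppc = ppc, caliper_type = caliper_spec$caliper_type,
         spacing_px = caliper_spec$spacing_px,
         true_width_mm = p$width_mm,
         true_width_px = ppc * p$width_mm / 10,
         theta_true_deg = theta, lv_mask = blob$mask, lv_box = lv_box,
         caliper_box = painted$box, tick_y = painted$tick_y,
         column_x = caliper_spec$column_x, seed = as.integer(seed)),
    class = "lv_scene_truth")
  structure(list(image = as_gray_image(img), truth = truth),
            class = "lv_scene")
}

#' Write a scene to disk (PNG image, PNG mask, JSON sidecars)
#'
#' Writes `<stem>.png`, `<stem>_mask.png`, the ground-truth sidecar
#' `<stem>_truth.json` and a detections sidecar `<stem>_detections.json`
#' in the schema read by [load_detections()].
#'
#' @param scene an `lv_scene` from [compose_scene()].
#' @param dir output directory (created if missing).
#' @param stem file-name stem.
#' @return named character vector of the paths written.
#' @export
write_scene <- function(scene, dir, stem = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- scene$truth
  paths <- c(image = file.path(dir, paste0(stem, ".png")),
             mask = file.path(dir, paste0(stem, "_mask.png")),
             truth = file.path(dir, paste0(stem, "_truth.json")),
             detections = file.path(dir, paste0(stem, "_detections.json")))
  write_gray(scene$image, paths[["image"]])
  write_mask(tr$lv_mask, paths[["mask"]])
  jsonlite::write_json(
    list(seed = tr$seed, ppc = tr$true_ppc, caliper_type = tr$caliper_type,
         spacing_px = tr$spacing_px,
         lv = list(width_mm = tr$true_width_mm,
                   theta_deg = tr$theta_true_deg,
                   box = tr$lv_box),
         caliper = list(box = tr$caliper_box, tick_y = tr$tick_y)),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(detections = list(
      list(label = "LV", box = tr$lv_box,
           mask_path = paste0(stem, "_mask.png"), confidence = 1.0),
      list(label = "CALIPER", box = tr$caliper_box, confidence = 1.0))),
    paths[["detections"]], auto_unbox = TRUE, digits = NA)
  paths
}

#' @rdname write_scene
#' @param path path to a `*_truth.json` sidecar.
#' @export
read_scene_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
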