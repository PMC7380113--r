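#' Configuration for caliper scale extraction
#'
#' All tunables of the PPC pipeline in one object. The binarisation threshold
#' (127) and the large-contour cutoff (30 boundary points) are the method's
#' fixed prior-knowledge values; the rest are documented defaults.
#'
#' @param binarize_threshold Laplacian responses strictly above this are
#'   foreground (0--255 scale).
#' @param max_contour_points contours with more boundary points are discarded.
#' @param spacing_tolerance_px allowed deviation of an inter-tick gap from the
#'   modal spacing when chaining scale ticks.
#' @param ruler_axis `"vertical"` (ticks stacked along a column, the common
#'   on-screen layout) or `"horizontal"`.
#' @param laplacian_kernel odd size of the Laplacian stencil (3 = standard
#'   4-neighbour stencil).
#' @param open_kernel odd side of the square structuring element for the
#'   morphological opening.
#' @param five_ratio_min minimal big/small tick-size ratio to accept the
#'   alternating 5-mm ruler pattern.
#' @param ten_cv_max maximal coefficient of variation of tick sizes to accept
#'   the uniform 10-mm ruler pattern.
#' @return a list of class `lv_ppc_config`.
#' @export
ppc_config <- function(binarize_threshold = 127L,
                       max_contour_points = 30L,
                       spacing_tolerance_px = 2L,
                       ruler_axis = c("vertical", "horizontal"),
                       laplacian_kernel = 3L,
                       open_kernel = 3L,
                       five_ratio_min = 1.5,
                       ten_cv_max = 0.2) {
  ruler_axis <- match.arg(ruler_axis)
  if (laplacian_kernel %% 2L != 1L || open_kernel %% 2L != 1L)
    abort_validation("kernel sizes must be odd")
  structure(list(binarize_threshold = binarize_threshold,
                 max_contour_points = max_contour_points,
                 spacing_tolerance_px = spacing_tolerance_px,
                 ruler_axis = ruler_axis,
                 laplacian_kernel = laplacian_kernel,
                 open_kernel = open_kernel,
                 five_ratio_min = five_ratio_min,
                 ten_cv_max = ten_cv_max),
            class = "lv_ppc_config")
}

# |Laplacian| with replicate padding, clipped to 0-255. For kernel sizes
# above 3 the stencil is dilated (neighbours sampled k%/%2 pixels away).
laplacian_response <- function(image, kernel = 3L) {
  s <- kernel %/% 2L
  nr <- nrow(image); nc <- ncol(image)
  pad_r <- c(rep(1L, s), seq_len(nr), rep(nr, s))
  pad_c <- c(rep(1L, s), seq_len(nc), rep(nc, s))
  p <- image[pad_r, pad_c, drop = FALSE]
  ctr <- p[(s + 1):(s + nr), (s + 1):(s + nc), drop = FALSE]
  up <- p[1:nr, (s + 1):(s + nc), drop = FALSE]
  dn <- p[(2 * s + 1):(2 * s + nr), (s + 1):(s + nc), drop = FALSE]
  lf <- p[(s + 1):(s + nr), 1:nc, drop = FALSE]
  rt <- p[(s + 1):(s + nr), (2 * s + 1):(2 * s + nc), drop = FALSE]
  resp <- abs(up + dn + lf + rt - 4 * ctr)
  resp[resp > 255] <- 255
  resp
}

#' Background-noise filtering of a caliper crop
#'
#' The chain gray -> Laplacian edge magnitude -> binarise (strictly above the
#' threshold) -> morphological open. The Laplacian suppresses large smooth
#' bright structures (zero response in their interior) while the small bright
#' scale ticks respond strongly along their whole extent; the opening then
#' removes sub-kernel specks.
#'
#' @param caliper_crop gray image (matrix, 0--255), the caliper bounding-box
#'   crop.
#' @param config [ppc_config()].
#' @return 0/1 mask of candidate scale structure.
#' @export
preprocess_caliper <- function(caliper_crop, config = ppc_config()) {
  caliper_crop <- as_gray_image(caliper_crop)
  resp <- laplacian_response(caliper_crop, config$laplacian_kernel)
  bin <- (resp > config$binarize_threshold) * 1
  opened <- EBImage::opening(bin, EBImage::makeBrush(config$open_kernel, "box"))
  as_binary_mask(matrix(as.integer(opened > 0.5), nrow(bin), ncol(bin)))
}

# along-ruler and across-ruler coordinate accessors
axis_index <- function(axis) if (axis == "vertical") 2L else 1L

contour_range_across <- function(contour, axis) {
  i <- if (axis == "vertical") 1L else 2L   # across = x for a vertical ruler
  range(contour$points[, i])
}

#' Locate the ruler line by contour voting
#'
#' Scale ticks all sit on one line of the image; sweeping every candidate
#' line, the coordinate crossed by the most contours is taken as the ruler
#' axis (ties toward the smaller coordinate). For a vertical ruler the
#' coordinate is a column index.
#'
#' @param contours list of contours.
#' @param axis `"vertical"` or `"horizontal"` ruler orientation.
#' @return list with `axis_coord` (0-based) and `contours`, the subset
#'   crossing it.
#' @export
ruler_axis_vote <- function(contours, axis = c("vertical", "horizontal")) {
  axis <- match.arg(axis)
  if (length(contours) == 0L) abort_extraction("no caliper scales")
  rng <- vapply(contours, contour_range_across, numeric(2), axis = axis)
  hi <- max(rng[2L, ])
  votes <- integer(hi + 1L)
  for (k in seq_len(ncol(rng))) {
    i <- (rng[1L, k]:rng[2L, k]) + 1L
    votes[i] <- votes[i] + 1L
  }
  coord <- which.max(votes) - 1L          # which.max ties -> smaller index
  keep <- rng[1L, ] <= coord & rng[2L, ] >= coord
  list(axis_coord = coord, contours = contours[keep])
}

#' Modal spacing between adjacent scale contours
#'
#' Contours are ordered along the ruler by the along-axis coordinate of their
#' reference point (the contour's top-left corner); the mode of successive
#' differences is the inter-tick spacing. Ties break toward the smaller
#' distance so that a harmonic (a doubled gap from a missed tick) can never
#' beat the true spacing.
#'
#' @param contours on-axis contours (at least 3).
#' @param axis ruler orientation.
#' @return integer spacing in pixels.
#' @export
adjacent_spacing_mode <- function(contours, axis = "vertical") {
  if (length(contours) < 3L) abort_extraction("too few scales")
  ai <- axis_index(axis)
  pos <- sort(vapply(contours, function(ct) ct$ref_point[ai], numeric(1)))
  gaps <- diff(pos)
  tab <- table(gaps)
  spacing <- as.integer(names(tab)[which.max(tab)])  # ties -> smaller gap
  if (spacing < 1L) abort_extraction("degenerate scale spacing")
  spacing
}

new_scale_tick <- function(contour, rect) {
  structure(list(contour = contour,
                 rect_w = rect$width, rect_h = rect$height,
                 rect_angle = rect$theta_deg,
                 size_score = max(rect$width, rect$height)),
            class = "lv_scale_tick")
}

#' Keep the contours that form the tick chain
#'
#' Orders on-axis contours along the ruler and keeps the longest chain whose
#' successive along-axis gaps are within `tolerance_px` of the modal spacing;
#' stray contours between chain members (gaps far from the spacing) are
#' discarded. Each survivor is fitted with its minimum-area rotated rectangle,
#' whose larger side is the tick's size score.
#'
#' @param contours on-axis contours.
#' @param spacing_px modal spacing from [adjacent_spacing_mode()].
#' @param tolerance_px allowed gap deviation (default 2).
#' @param axis ruler orientation.
#' @return list of scale ticks (ordered along the ruler), length >= 3.
#' @export
select_scale_ticks <- function(contours, spacing_px, tolerance_px = 2L,
                               axis = "vertical") {
  if (spacing_px <= 0L) abort_validation("spacing must be positive")
  ai <- axis_index(axis)
  pos <- vapply(contours, function(ct) ct$ref_point[ai], numeric(1))
  sec <- vapply(contours, function(ct) ct$ref_point[3L - ai], numeric(1))
  ord <- order(pos, sec)
  contours <- contours[ord]; pos <- pos[ord]
  n <- length(contours)
  if (n < 3L) abort_extraction("too few scales")
  # longest chain with gaps ~ spacing (O(n^2) dynamic programme; n is tiny)
  best <- rep(1L, n); prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      gap <- pos[i] - pos[j]
      if (abs(gap - spacing_px) <= tolerance_px && best[j] + 1L > best[i]) {
        best[i] <- best[j] + 1L
        prev[i] <- j
      }
    }
  }
  end <- which.max(best)
  if (best[end] < 3L) abort_extraction("no chain of at least 3 scales")
  chain <- integer(0)
  while (!is.na(end)) { chain <- c(end, chain); end <- prev[end] }
  lapply(contours[chain], function(ct) {
    new_scale_tick(ct, min_area_rect_points(ct$points))
  })
}

#' Classify the caliper type from tick sizes
#'
#' The 5-mm ruler shows a big-small-big alternation of tick sizes; the 10-mm
#' ruler has ticks of identical size. Sizes are split into big/small at the
#' midpoint of their range: a strict alternation with a big/small ratio of at
#' least `five_ratio_min` is a 5-caliper; a coefficient of variation below
#' `ten_cv_max` is a 10-caliper; anything else is ambiguous.
#'
#' @param ticks list of scale ticks, ordered along the ruler (>= 3).
#' @param five_ratio_min,ten_cv_max pattern thresholds (see [ppc_config()]).
#' @return `"5"` or `"10"`.
#' @export
classify_caliper <- function(ticks, five_ratio_min = 1.5, ten_cv_max = 0.2) {
  if (length(ticks) < 3L) abort_extraction("too few scales")
  sizes <- vapply(ticks, `[[`, numeric(1), "size_score")
  mid <- (min(sizes) + max(sizes)) / 2
  big <- sizes > mid
  alternating <- all(diff(big) != 0L)
  if (alternating && max(sizes) / min(sizes) >= five_ratio_min) return("5")
  if (stats::sd(sizes) / mean(sizes) < ten_cv_max) return("10")
  abort_classification("ambiguous caliper")
}

#' PPC from spacing and caliper type
#'
#' Adjacent ticks are 10 mm apart on a 10-caliper, so the PPC (pixels per
#' centimeter) equals the spacing; on a 5-caliper they are 5 mm apart, so the
#' PPC is twice the spacing.
#'
#' @param spacing_px inter-tick spacing, pixels (>= 1).
#' @param caliper_type `"5"` or `"10"`.
#' @param axis_coord,ticks optional provenance carried into the estimate.
#' @return an `lv_ppc_estimate`: `ppc`, `caliper_type`, `spacing_px`,
#'   `axis_coord`, `ticks`, `n_ticks`.
#' @export
compute_ppc <- function(spacing_px, caliper_type, axis_coord = NA_integer_,
                        ticks = list()) {
  if (!is.numeric(spacing_px) || spacing_px < 1)
    abort_validation("spacing must be a positive number of pixels")
  caliper_type <- match.arg(as.character(caliper_type), c("5", "10"))
  ppc <- if (caliper_type == "5") 2 * spacing_px else as.numeric(spacing_px)
  structure(list(ppc = ppc, caliper_type = caliper_type,
                 spacing_px = as.integer(spacing_px),
                 axis_coord = axis_coord, ticks = ticks,
                 n_ticks = length(ticks)),
            class = "lv_ppc_estimate")
}

#' @export
print.lv_ppc_estimate <- function(x, ...) {
  cat(sprintf("<PPC estimate: %.1f px/cm (%s-caliper, spacing %d px, %d ticks)>\n",
              x$ppc, x$caliper_type, x$spacing_px, x$n_ticks))
  invisible(x)
}

#' Estimate the pixels-per-centimeter calibration from a caliper crop
#'
#' End-to-end scale extraction: morphological background filtering, contour
#' detection, the three prior-knowledge filters (small contours only, common
#' ruler axis, fixed adjacent spacing), caliper-type classification and the
#' PPC conversion rule.
#'
#' @param caliper_crop gray image of the caliper region.
#' @param config [ppc_config()].
#' @return an `lv_ppc_estimate`; see [compute_ppc()].
#' @export
estimate_ppc <- function(caliper_crop, config = ppc_config()) {
  mask <- preprocess_caliper(caliper_crop, config)
  contours <- find_contours(mask)
  contours <- filter_large(contours, config$max_contour_points)
  if (length(contours) == 0L) abort_extraction("no caliper scales")
  vote <- ruler_axis_vote(contours, config$ruler_axis)
  spacing <- adjacent_spacing_mode(vote$contours, config$ruler_axis)
  ticks <- select_scale_ticks(vote$contours, spacing,
                              config$spacing_tolerance_px, config$ruler_axis)
  type <- classify_caliper(ticks, config$five_ratio_min, config$ten_cv_max)
  compute_ppc(spacing, type, axis_coord = vote$axis_coord, ticks = ticks)
}

#' Serialise a PPC estimate to JSON
#'
#' @param estimate an `lv_ppc_estimate`.
#' @param path output file.
#' @export
write_ppc_json <- function(estimate, path) {
  jsonlite::write_json(
    list(ppc = estimate$ppc, caliper_type = estimate$caliper_type,
         spacing_px = estimate$spacing_px, n_ticks = estimate$n_ticks,
         axis_coord = estimate$axis_coord),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
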