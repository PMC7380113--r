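# Rotated-rectangle geometry: minimum-area enclosing rectangle of a point
# set, and rigid rotation of masks with an invertible coordinate transform.

# Minimum-area rotated rectangle of a set of pixel-centre coordinates
# (n x 2 matrix of x, y). The optimum has an edge collinear with a convex-hull
# edge, so we sweep hull-edge directions. Reported width/height are pixel
# extents (projection range + 1) so an axis-aligned w x h block reports
# exactly (w, h). Returns, besides the rect, the inclination of its longer
# edge in [0, 180) — the rotation that makes the shape horizontal.
min_area_rect_points <- function(pts) {
  pts <- unique(round(pts, 9))
  n <- nrow(pts)
  if (n == 0L) abort_validation("no points for enclosing rectangle")
  if (n == 1L) {
    return(new_rotated_rect(pts[1L, ], 1, 1, 0, 0))
  }
  # degenerate (collinear) sets: principal direction from the two extremes
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2L, ctr)
  sv <- svd(cen)
  if (n == 2L || sv$d[2L] < 1e-9) {
    d <- sv$v[, 1L]
    ang <- (atan2(d[2L], d[1L]) * 180 / pi) %% 180
    ext <- diff(range(cen %*% d))
    return(new_rotated_rect(ctr, ext + 1, 1, ang %% 90, ang))
  }
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  m <- nrow(hp)
  nxt <- c(2:m, 1L)
  ed <- hp[nxt, , drop = FALSE] - hp
  phis <- atan2(ed[, 2L], ed[, 1L]) %% pi
  best <- NULL; best_area <- Inf
  for (phi in phis) {
    u <- c(cos(phi), sin(phi))
    v <- c(-sin(phi), cos(phi))
    pu <- hp %*% u; pv <- hp %*% v
    wu <- max(pu) - min(pu); wv <- max(pv) - min(pv)
    area <- wu * wv
    if (area < best_area - 1e-9) {
      best_area <- area
      cu <- (max(pu) + min(pu)) / 2; cv <- (max(pv) + min(pv)) / 2
      best <- list(phi = phi, wu = wu, wv = wv, center = cu * u + cv * v)
    }
  }
  phi_deg <- best$phi * 180 / pi
  long_ang <- if (best$wu >= best$wv) phi_deg else (phi_deg + 90) %% 180
  theta <- min(angle_to_x(phi_deg), angle_to_x(phi_deg + 90))
  new_rotated_rect(best$center, best$wu + 1, best$wv + 1, theta, long_ang)
}

# inclination of a line at `deg` to the x-axis, in [0, 90]
angle_to_x <- function(deg) {
  d <- deg %% 180
  min(d, 180 - d)
}

new_rotated_rect <- function(center, width, height, theta_deg, long_angle_deg) {
  structure(list(center = as.numeric(center), width = width, height = height,
                 theta_deg = theta_deg, long_angle_deg = long_angle_deg),
            class = "lv_rotated_rect")
}

#' @export
print.lv_rotated_rect <- function(x, ...) {
  cat(sprintf(
    "<rotated rect: %.1f x %.1f px, center (%.1f, %.1f), theta %.1f deg>\n",
    x$width, x$height, x$center[1L], x$center[2L], x$theta_deg))
  invisible(x)
}

#' Minimum enclosing rectangle of a mask
#'
#' Smallest-area rotated rectangle containing the mask foreground (via its
#' convex hull). If the mask has several 8-connected components the largest
#' is used, with a warning. `theta_deg` is the angle between the x-axis and
#' the rectangle edge with the smallest inclination to it; `long_angle_deg`
#' is the inclination of the longer edge, the rotation that makes the shape
#' horizontal.
#'
#' @param mask 0/1 matrix with at least one foreground pixel.
#' @return an `lv_rotated_rect`: `center` (x, y), `width`, `height` (pixel
#'   extents), `theta_deg` in \[0, 90), `long_angle_deg` in \[0, 180).
#' @export
min_enclosing_rect <- function(mask) {
  mask <- as_binary_mask(mask)
  if (sum(mask) == 0L) abort_validation("empty mask")
  mask <- largest_component(mask, warn = TRUE)
  idx <- which(mask == 1L, arr.ind = TRUE)
  min_area_rect_points(cbind(idx[, 2L] - 1L, idx[, 1L] - 1L))
}

largest_component <- function(mask, warn = FALSE) {
  labels <- label_components(mask)
  k <- max(labels)
  if (k <= 1L) return(mask)
  if (warn) warning("mask has ", k, " components; keeping the largest")
  areas <- tabulate(labels[labels > 0L], nbins = k)
  (labels == which.max(areas)) * 1L
}

#' Rotate a mask so a given direction becomes horizontal
#'
#' Rigidly rotates the mask by `-theta_deg` about its centre on an enlarged
#' canvas (no clipping), and returns the invertible coordinate transform
#' between original and rotated pixel coordinates. Sampling is bilinear with
#' a 0.5 cut, which reproduces the rotated region's boundary about half a
#' pixel more faithfully than nearest-neighbour resampling (whose chipping
#' at the extremes biases chord lengths); the output is still strictly
#' binary.
#'
#' @param mask 0/1 matrix.
#' @param theta_deg rotation to undo, degrees.
#' @return list with `mask` (rotated 0/1 matrix) and `transform`; apply the
#'   transform with [transform_points()] (`inverse = TRUE` maps rotated
#'   coordinates back to the original image).
#' @export
rotate_to_horizontal <- function(mask, theta_deg) {
  mask <- as_binary_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  a <- -theta_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  c_src <- c((nc - 1) / 2, (nr - 1) / 2)
  corners <- rbind(c(0, 0), c(nc - 1, 0), c(0, nr - 1), c(nc - 1, nr - 1))
  rc <- sweep(corners, 2L, c_src)
  rx <- rc[, 1L] * ca - rc[, 2L] * sa
  ry <- rc[, 1L] * sa + rc[, 2L] * ca
  nc2 <- ceiling(max(rx) - min(rx) - 1e-9) + 1L
  nr2 <- ceiling(max(ry) - min(ry) - 1e-9) + 1L
  c_tgt <- c((nc2 - 1) / 2, (nr2 - 1) / 2)
  # inverse map: target pixel centre -> source coords (rotation by +theta)
  xt <- rep(0:(nc2 - 1L), each = nr2) - c_tgt[1L]
  yt <- rep(0:(nr2 - 1L), times = nc2) - c_tgt[2L]
  xs <- xt * ca + yt * sa + c_src[1L]
  ys <- -xt * sa + yt * ca + c_src[2L]
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  at <- function(yy, xx) {
    ok <- xx >= 0L & xx < nc & yy >= 0L & yy < nr
    v <- numeric(length(xx))
    v[ok] <- mask[cbind(yy[ok] + 1L, xx[ok] + 1L)]
    v
  }
  val <- (1 - fx) * (1 - fy) * at(y0, x0) +
    fx * (1 - fy) * at(y0, x0 + 1L) +
    (1 - fx) * fy * at(y0 + 1L, x0) +
    fx * fy * at(y0 + 1L, x0 + 1L)
  out <- matrix(as.integer(val >= 0.5), nr2, nc2)
  tf <- structure(list(theta_deg = theta_deg, c_src = c_src, c_tgt = c_tgt),
                  class = "lv_transform")
  list(mask = out, transform = tf)
}

#' @rdname rotate_to_horizontal
#' @param points n x 2 matrix (x, y) of coordinates.
#' @param transform transform returned by [rotate_to_horizontal()].
#' @param inverse if `TRUE`, map rotated-canvas coordinates back to original
#'   image coordinates.
#' @export
transform_points <- function(points, transform, inverse = FALSE) {
  points <- matrix(as.numeric(points), ncol = 2L)
  a <- (if (inverse) transform$theta_deg else -transform$theta_deg) * pi / 180
  from <- if (inverse) transform$c_tgt else transform$c_src
  to <- if (inverse) transform$c_src else transform$c_tgt
  px <- points[, 1L] - from[1L]; py <- points[, 2L] - from[2L]
  cbind(px * cos(a) - py * sin(a) + to[1L],
        px * sin(a) + py * cos(a) + to[2L])
}
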