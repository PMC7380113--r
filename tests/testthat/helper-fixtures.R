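# Shared fixture builders and independent oracles.

# rasterise a filled axis-aligned rectangle mask (0-based geometry args)
rect_mask <- function(nr, nc, y0, x0, h, w) {
  m <- matrix(0L, nr, nc)
  m[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w)] <- 1L
  m
}

# rasterise a filled disk of given radius centred at (cx, cy)
disk_mask <- function(nr, nc, cx, cy, r) {
  x <- rep(0:(nc - 1), each = nr) - cx
  y <- rep(0:(nr - 1), times = nc) - cy
  matrix(as.integer(x^2 + y^2 <= r^2), nr, nc)
}

# rasterise a filled convex polygon (vertices as n x 2 matrix of x, y):
# a pixel centre is inside iff it is on the inner side of every edge.
convex_polygon_mask <- function(nr, nc, verts) {
  h <- chull(verts)
  hv <- verts[h, , drop = FALSE]          # counter-clockwise from chull
  m <- nrow(hv)
  x <- rep(0:(nc - 1), each = nr)
  y <- rep(0:(nr - 1), times = nc)
  inside <- rep(TRUE, nr * nc)
  for (i in seq_len(m)) {
    a <- hv[i, ]; b <- hv[if (i == m) 1L else i + 1L, ]
    cr <- (b[1] - a[1]) * (y - a[2]) - (b[2] - a[2]) * (x - a[1])
    inside <- inside & cr <= 1e-9
  }
  matrix(as.integer(inside), nr, nc)
}

# Rotating-calipers minimum width of a point set: the minimal width of a
# convex polygon is attained perpendicular to one of its hull edges, so take
# the minimum over edges of the farthest vertex-to-edge-line distance.
# Independent of the rect-fitting code path (no projections/extents shared).
min_width_oracle <- function(pts) {
  h <- chull(pts)
  hv <- pts[h, , drop = FALSE]
  m <- nrow(hv)
  widths <- vapply(seq_len(m), function(i) {
    a <- hv[i, ]; b <- hv[if (i == m) 1L else i + 1L, ]
    e <- b - a
    len <- sqrt(sum(e^2))
    if (len < 1e-12) return(Inf)
    max(abs((hv[, 1] - a[1]) * e[2] - (hv[, 2] - a[2]) * e[1]) / len)
  }, numeric(1))
  min(widths)
}

# Random convex polygon with guaranteed elongation: vertices are a stretched
# uniform cloud, accepted only if the dense directional-extent profile of the
# vertex set has aspect ratio >= aspect_min (the LV-like shape family the
# width method is built for; round shapes are out of scope, see vignette).
random_elongated_polygon <- function(nv, half_long = 90, center = c(120, 120),
                                     aspect_min = 1.8) {
  repeat {
    raw <- cbind(runif(nv, -1, 1), runif(nv, -1, 1) * 0.5)
    ang <- runif(1, 0, pi)
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    verts <- sweep(raw %*% (half_long * t(R)), 2, center, "+")
    angs <- seq(0, pi, length.out = 181)
    ext <- vapply(angs, function(a)
      diff(range(verts %*% c(cos(a), sin(a)))), numeric(1))
    if (max(ext) / min(ext) >= aspect_min && min(ext) > 10) return(verts)
  }
}

# mask foreground as 0-based (x, y) points
mask_points <- function(mask) {
  idx <- which(mask == 1L, arr.ind = TRUE)
  cbind(idx[, 2L] - 1L, idx[, 1L] - 1L)
}
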