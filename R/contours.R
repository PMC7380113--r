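#' 8-connected component labelling
#'
#' Labels the foreground of a binary mask into 8-connected components.
#' Components are numbered deterministically in column-major order of their
#' first pixel.
#'
#' @param mask 0/1 matrix.
#' @return integer matrix of the same shape; 0 = background, components
#'   numbered from 1.
#' @export
label_components <- function(mask) {
  mask <- as_binary_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  fg <- which(mask == 1L)
  n <- length(fg)
  if (n == 0L) return(labels)
  is_fg <- logical(nr * nc)
  is_fg[fg] <- TRUE
  vid <- integer(nr * nc)
  vid[fg] <- seq_len(n)
  row <- ((fg - 1L) %% nr) + 1L
  col <- ((fg - 1L) %/% nr) + 1L
  # forward neighbour offsets in column-major linear indexing:
  # down, right, down-right, up-right
  edges <- list(
    list(off = 1L,       ok = row < nr),
    list(off = nr,       ok = col < nc),
    list(off = nr + 1L,  ok = row < nr & col < nc),
    list(off = nr - 1L,  ok = row > 1L & col < nc)
  )
  from <- integer(0); to <- integer(0)
  for (e in edges) {
    i <- fg[e$ok]
    j <- i + e$off
    keep <- is_fg[j]
    from <- c(from, vid[i[keep]])
    to <- c(to, vid[j[keep]])
  }
  if (length(from) == 0L) {
    labels[fg] <- seq_len(n)
    return(labels)
  }
  g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  memb <- igraph::components(g)$membership
  labels[fg] <- as.integer(memb)
  labels
}

# Boundary pixels: foreground with at least one 4-neighbour that is
# background or outside the image.
boundary_mask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
  up <- pad[1:nr, 2:(nc + 1L)]
  dn <- pad[3:(nr + 2L), 2:(nc + 1L)]
  lf <- pad[2:(nr + 1L), 1:nc]
  rt <- pad[2:(nr + 1L), 3:(nc + 2L)]
  (ctr == 1L) & (up + dn + lf + rt < 4L)
}

new_contour <- function(points, ref) {
  structure(list(points = points, ref_point = ref, n_points = nrow(points)),
            class = "lv_contour")
}

#' @export
print.lv_contour <- function(x, ...) {
  cat(sprintf("<contour: %d boundary points, ref (%d, %d)>\n",
              x$n_points, x$ref_point[1L], x$ref_point[2L]))
  invisible(x)
}

#' Extract outer contours of a binary mask
#'
#' One contour per 8-connected foreground component; each contour is the set
#' of the component's boundary pixels (foreground pixels 4-adjacent to
#' background or to the image border), listed in (y, x) raster order as
#' 0-based `(x, y)` coordinates. The contour's reference point is the top-left
#' corner of its bounding box, `(min x, min y)`. Contours are returned sorted
#' by `(ref y, ref x)`.
#'
#' @param mask 0/1 matrix.
#' @return list of contour objects with fields `points` (n x 2 matrix of x, y),
#'   `ref_point`, `n_points`.
#' @export
find_contours <- function(mask) {
  mask <- as_binary_mask(mask)
  labels <- label_components(mask)
  k <- max(labels)
  if (k == 0L) return(list())
  bnd <- boundary_mask(mask)
  out <- vector("list", k)
  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[labels > 0L]
  onb <- bnd[labels > 0L]
  for (i in seq_len(k)) {
    sel <- lab == i
    xs <- idx[sel, 2L] - 1L
    ys <- idx[sel, 1L] - 1L
    ref <- c(min(xs), min(ys))
    bsel <- sel & onb
    px <- idx[bsel, 2L] - 1L
    py <- idx[bsel, 1L] - 1L
    ord <- order(py, px)
    out[[i]] <- new_contour(cbind(x = px[ord], y = py[ord]), ref)
  }
  refs <- vapply(out, `[[`, integer(2), "ref_point")
  out[order(refs[2L, ], refs[1L, ])]
}

#' Drop large contours
#'
#' Keeps only contours whose boundary-point count does not exceed
#' `max_points`; caliper scale ticks are small, so large contours are
#' background structure that survived the morphological cleaning.
#'
#' @param contours list of contours from [find_contours()].
#' @param max_points keep contours with `n_points <= max_points` (default 30).
#' @return filtered list.
#' @export
filter_large <- function(contours, max_points = 30L) {
  contours[vapply(contours, `[[`, integer(1), "n_points") <= max_points]
}
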