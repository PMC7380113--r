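#' Grayscale images, binary masks and bounding boxes
#'
#' Images are plain integer matrices (`dim = c(height, width)`, intensities
#' 0--255); masks are 0/1 matrices of the same geometry. Boxes are length-4
#' integer vectors `c(x0, y0, x1, y1)`, 0-based and half-open, `x` = column,
#' `y` = row, origin top-left.
#'
#' @param x matrix to validate/coerce.
#' @return `as_gray_image()` and `as_binary_mask()` return validated integer
#'   matrices.
#' @name images
NULL

#' @rdname images
#' @export
as_gray_image <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    abort_validation("a gray image must be a numeric matrix")
  if (nrow(x) < 1L || ncol(x) < 1L)
    abort_validation("a gray image must be non-empty")
  if (anyNA(x) || min(x) < 0 || max(x) > 255)
    abort_validation("gray intensities must lie in [0, 255]")
  storage.mode(x) <- "integer"
  x
}

#' @rdname images
#' @export
as_binary_mask <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    abort_validation("a binary mask must be a numeric matrix")
  if (anyNA(x) || !all(x %in% c(0, 1)))
    abort_validation("mask values must be 0 or 1")
  storage.mode(x) <- "integer"
  x
}

#' Read and write 8-bit grayscale PNGs and 0/255 masks
#'
#' @param path file path.
#' @param image,mask matrix as produced by [as_gray_image()] /
#'   [as_binary_mask()].
#' @return `read_gray()` an integer matrix in 0--255; `read_mask()` a 0/1
#'   matrix (any value above 127 is foreground). Writers return `path`
#'   invisibly.
#' @export
read_gray <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]   # collapse grayscale+alpha / RGB
  as_gray_image(round(px * 255))
}

#' @rdname read_gray
#' @export
write_gray <- function(image, path) {
  image <- as_gray_image(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname read_gray
#' @export
read_mask <- function(path) {
  as_binary_mask((read_gray(path) > 127L) * 1L)
}

#' @rdname read_gray
#' @export
write_mask <- function(mask, path) {
  mask <- as_binary_mask(mask)
  png::writePNG(mask * 255 / 255, path)
  invisible(path)
}

#' Bounding-box helpers
#'
#' @param box integer vector `c(x0, y0, x1, y1)`, 0-based half-open.
#' @param image matrix the box must fit inside (optional bounds check).
#' @export
validate_box <- function(box, image = NULL) {
  if (length(box) != 4L || anyNA(box) || !is.numeric(box))
    abort_validation("a box must be c(x0, y0, x1, y1)")
  box <- as.integer(box)
  if (box[3L] <= box[1L] || box[4L] <= box[2L])
    abort_validation("box must satisfy x1 > x0 and y1 > y0")
  if (box[1L] < 0L || box[2L] < 0L)
    abort_validation("box origin must be non-negative")
  if (!is.null(image) && (box[3L] > ncol(image) || box[4L] > nrow(image)))
    abort_validation("box exceeds image bounds")
  box
}

#' @rdname validate_box
#' @param mask 0/1 matrix; the box of its foreground.
#' @export
box_from_mask <- function(mask) {
  mask <- as_binary_mask(mask)
  idx <- which(mask == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) abort_validation("empty mask has no bounding box")
  c(min(idx[, 2L]) - 1L, min(idx[, 1L]) - 1L, max(idx[, 2L]), max(idx[, 1L]))
}

#' @rdname validate_box
#' @param a,b boxes.
#' @export
box_iou <- function(a, b) {
  a <- validate_box(a); b <- validate_box(b)
  iw <- max(0L, min(a[3L], b[3L]) - max(a[1L], b[1L]))
  ih <- max(0L, min(a[4L], b[4L]) - max(a[2L], b[2L]))
  inter <- as.numeric(iw) * ih
  area <- function(z) as.numeric(z[3L] - z[1L]) * (z[4L] - z[2L])
  inter / (area(a) + area(b) - inter)
}

#' Crop an image to a bounding box
#'
#' Extracts the half-open window `[x0, x1) x [y0, y1)`; pixel values are
#' preserved and the output has dimensions `(y1 - y0) x (x1 - x0)`.
#'
#' @param image integer matrix (gray image or mask).
#' @param box `c(x0, y0, x1, y1)`, 0-based half-open, within bounds.
#' @return the cropped matrix.
#' @export
crop <- function(image, box) {
  if (!is.matrix(image)) abort_validation("`image` must be a matrix")
  box <- validate_box(box, image)
  image[(box[2L] + 1L):box[4L], (box[1L] + 1L):box[3L], drop = FALSE]
}
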