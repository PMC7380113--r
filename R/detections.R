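#' Load detection records from a JSON sidecar
#'
#' Reads the stand-in for an upstream segmenter's output: a JSON file
#' `{"detections": [{"label": "LV"|"CALIPER", "box": [x0,y0,x1,y1],
#' "mask_path": optional, "confidence": float}, ...]}`. Boxes are validated
#' against the image dimensions; masks (0/255 PNG, path relative to the
#' sidecar) are loaded when present and must be zero outside their box.
#'
#' @param image_path path of the image the detections refer to.
#' @param sidecar_path path of the JSON sidecar.
#' @return list of detection records (`label`, `box`, `mask` or `NULL`,
#'   `confidence`); empty list for a negative sample.
#' @export
load_detections <- function(image_path, sidecar_path) {
  image <- read_gray(image_path)
  doc <- tryCatch(jsonlite::read_json(sidecar_path, simplifyVector = FALSE),
                  error = function(e)
                    abort_parse(paste0("malformed sidecar JSON: ",
                                       conditionMessage(e))))
  dets <- doc$detections
  if (is.null(dets)) abort_parse("sidecar lacks a 'detections' array")
  lapply(dets, function(d) {
    if (is.null(d$label) || !d$label %in% c("LV", "CALIPER"))
      abort_validation("detection label must be 'LV' or 'CALIPER'")
    box <- validate_box(unlist(d$box), image)
    conf <- if (is.null(d$confidence)) 1.0 else as.numeric(d$confidence)
    if (conf < 0 || conf > 1)
      abort_validation("confidence must be in [0, 1]")
    mask <- NULL
    if (!is.null(d$mask_path)) {
      mask <- read_mask(file.path(dirname(sidecar_path), d$mask_path))
      if (!all(dim(mask) == dim(image)))
        abort_validation("mask geometry differs from image")
      outside <- mask
      outside[(box[2L] + 1L):box[4L], (box[1L] + 1L):box[3L]] <- 0L
      if (any(outside == 1L))
        abort_validation("mask has foreground outside its box")
    }
    list(label = d$label, box = box, mask = mask, confidence = conf)
  })
}

#' Configuration for the naive brightness detector
#'
#' @param threshold foreground intensity cutoff (strictly above).
#' @param tick_area_max components at most this many pixels are ruler-tick
#'   candidates.
#' @param min_lv_area smallest component accepted as an LV blob.
#' @param min_ticks least tick candidates on a common column to report a
#'   caliper.
#' @export
detect_config <- function(threshold = 127L, tick_area_max = 60L,
                          min_lv_area = 100L, min_ticks = 3L) {
  list(threshold = threshold, tick_area_max = tick_area_max,
       min_lv_area = min_lv_area, min_ticks = min_ticks)
}

#' Naive brightness-based detector for synthetic scenes
#'
#' A fixture-only stand-in for a trained segmenter: thresholds the image,
#' finds 8-connected bright components, votes the vertical strip holding the
#' most small components (the ruler), and reports the largest remaining
#' bright component as the LV. Confidence is fixed at 1.0.
#'
#' @param image gray matrix.
#' @param config [detect_config()].
#' @return list of detection records as in [load_detections()]; possibly
#'   empty.
#' @export
naive_detect <- function(image, config = detect_config()) {
  image <- as_gray_image(image)
  bin <- (image > config$threshold) * 1L
  labels <- label_components(bin)
  k <- max(labels)
  if (k == 0L) return(list())
  areas <- tabulate(labels[labels > 0L], nbins = k)
  boxes <- lapply(seq_len(k), function(i) box_from_mask((labels == i) * 1L))

  out <- list()
  small <- which(areas <= config$tick_area_max)
  caliper_ids <- integer(0)
  if (length(small) >= config$min_ticks) {
    hi <- max(vapply(boxes[small], `[[`, integer(1), 3L))
    votes <- integer(hi)
    for (i in small) {
      cols <- (boxes[[i]][1L] + 1L):boxes[[i]][3L]
      votes[cols] <- votes[cols] + 1L
    }
    if (max(votes) >= config$min_ticks) {
      coord <- which.max(votes) - 1L
      caliper_ids <- small[vapply(
        boxes[small],
        function(b) b[1L] <= coord && b[3L] > coord, logical(1))]
      cb <- Reduce(function(a, b) c(pmin(a[1:2], b[1:2]), pmax(a[3:4], b[3:4])),
                   boxes[caliper_ids])
      cb <- c(max(0L, cb[1L] - 3L), max(0L, cb[2L] - 3L),
              min(ncol(image), cb[3L] + 3L), min(nrow(image), cb[4L] + 3L))
      out[[length(out) + 1L]] <-
        list(label = "CALIPER", box = as.integer(cb), mask = NULL,
             confidence = 1.0)
    }
  }

  big <- setdiff(which(areas >= config$min_lv_area), caliper_ids)
  if (length(big) > 0L) {
    lv <- big[which.max(areas[big])]
    mask <- (labels == lv) * 1L
    out[[length(out) + 1L]] <-
      list(label = "LV", box = boxes[[lv]], mask = as_binary_mask(mask),
           confidence = 1.0)
  }
  out
}

# pick one record of a label; highest confidence wins, with a warning when
# several compete (upstream segmenters may emit duplicates)
pick_detection <- function(records, label) {
  hits <- Filter(function(r) r$label == label, records)
  if (length(hits) == 0L) return(NULL)
  if (length(hits) > 1L) {
    warning("multiple ", label, " detections; keeping the most confident")
    hits <- hits[order(-vapply(hits, `[[`, numeric(1), "confidence"))]
  }
  hits[[1L]]
}
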