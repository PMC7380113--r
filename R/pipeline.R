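#' Pipeline configuration
#'
#' Bundles the caliper-extraction and detector settings plus run metadata.
#' `load_pipeline_config()` reads the same keys from a YAML or JSON file;
#' unknown keys are rejected.
#'
#' @param ppc [ppc_config()] settings.
#' @param detect [detect_config()] settings (used only when no detections
#'   sidecar is supplied).
#' @param seed integer seed recorded with every run.
#' @export
pipeline_config <- function(ppc = ppc_config(), detect = detect_config(),
                            seed = 0L) {
  structure(list(ppc = ppc, detect = detect, seed = as.integer(seed)),
            class = "lv_pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML or JSON file with any of the keys of [ppc_config()] /
#'   [detect_config()] under `ppc:` / `detect:`, plus optional `seed`.
#' @export
load_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- c("ppc", "detect", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L)
    abort_parse(paste("unknown config keys:", paste(bad, collapse = ", ")))
  ppc <- do.call(ppc_config, as.list(raw$ppc))
  detect <- do.call(detect_config, as.list(raw$detect))
  pipeline_config(ppc = ppc, detect = detect,
                  seed = if (is.null(raw$seed)) 0L else raw$seed)
}

#' Measure the LV width of one image end to end
#'
#' Crops the caliper with its detection box, estimates the PPC, selects the
#' LV mask (from the detection record, or by thresholding inside the LV box
#' when the record has no mask), measures the diameter, and optionally writes
#' the result JSON. A missing LV or caliper detection, or a stage failure, is
#' reported as a structured failure record (`lv_failure`) rather than an
#' error: unmeasurable images are an expected outcome, not a crash.
#'
#' @param image_path path to the image (8-bit grayscale PNG).
#' @param detections_path path to the detections sidecar JSON; `NULL` to run
#'   the naive detector instead.
#' @param config [pipeline_config()].
#' @param out optional path for the result JSON.
#' @return on success a list of class `lv_result` (`status = "ok"`, `record`
#'   with `width_mm` to 0.1 mm, `pixel_length`, `ppc`, `caliper_type`,
#'   `theta_deg`, `endpoints`, and the full `measurement` / `ppc_estimate`
#'   objects); on failure a list of class `lv_failure`
#'   (`status = "failed"`, `stage`, `reason`).
#' @export
run_measure <- function(image_path, detections_path = NULL,
                        config = pipeline_config(), out = NULL) {
  image <- read_gray(image_path)
  failure <- function(stage, reason) {
    structure(list(status = "failed", stage = stage, reason = reason,
                   image = image_path), class = "lv_failure")
  }
  records <- tryCatch(
    if (is.null(detections_path)) naive_detect(image, config$detect)
    else load_detections(image_path, detections_path),
    lvmeasure_error = function(e) e)
  if (inherits(records, "condition"))
    return(failure("detection", conditionMessage(records)))
  cal <- pick_detection(records, "CALIPER")
  lv <- pick_detection(records, "LV")
  if (is.null(cal)) return(failure("detection", "no caliper detected"))
  if (is.null(lv)) return(failure("detection", "no LV detected"))

  est <- tryCatch(estimate_ppc(crop(image, cal$box), config$ppc),
                  lvmeasure_error = function(e) e)
  if (inherits(est, "condition"))
    return(failure("ppc", conditionMessage(est)))

  mask <- lv$mask
  if (is.null(mask)) {
    mask <- matrix(0L, nrow(image), ncol(image))
    sub <- crop(image, lv$box)
    mask[(lv$box[2L] + 1L):lv$box[4L], (lv$box[1L] + 1L):lv$box[3L]] <-
      (sub > config$detect$threshold) * 1L
  }
  meas <- tryCatch(measure_lv(mask, est), lvmeasure_error = function(e) e)
  if (inherits(meas, "condition"))
    return(failure("measure", conditionMessage(meas)))

  result <- structure(list(status = "ok",
                           record = measurement_record(meas, est),
                           measurement = meas, ppc_estimate = est),
                      class = "lv_result")
  if (!is.null(out)) {
    jsonlite::write_json(result$record, out, auto_unbox = TRUE, digits = NA)
  }
  result
}

#' @export
print.lv_result <- function(x, ...) {
  r <- x$record
  cat(sprintf("LV width: %.1f mm  (%.1f px / PPC %.1f, %s-caliper, theta %.1f deg)\n",
              r$width_mm, r$pixel_length, r$ppc, r$caliper_type, r$theta_deg))
  invisible(x)
}

#' @export
print.lv_failure <- function(x, ...) {
  cat(sprintf("measurement failed at stage '%s': %s\n", x$stage, x$reason))
  invisible(x)
}

#' Generate a cohort of synthetic scenes on disk
#'
#' Writes `n` scenes (image, mask, truth and detections sidecars) with
#' parameters drawn reproducibly from `seed`: caliper type alternates,
#' spacing 30--70 px, width 5--15 mm, orientation 0--180 degrees.
#'
#' @param n number of scenes.
#' @param dir output directory.
#' @param noise_level speckle amplitude.
#' @param seed cohort seed; scene `i` uses `seed + i`.
#' @return data frame with one row per scene (stem, paths and ground truth).
#' @export
synthesize_cohort <- function(n, dir, noise_level = 0.2, seed = 0L) {
  params <- with_seed(seed, data.frame(
    stem = sprintf("scene%03d", seq_len(n)),
    caliper_type = rep(c("10", "5"), length.out = n),
    spacing_px = sample(30:70, n, replace = TRUE),
    width_mm = round(stats::runif(n, 5, 15), 1),
    theta_deg = round(stats::runif(n, 0, 180), 1),
    stringsAsFactors = FALSE))
  rows <- lapply(seq_len(n), function(i) {
    sp <- caliper_spec(params$caliper_type[i], params$spacing_px[i],
                       n_ticks = 5L, column_x = 30L)
    scene <- compose_scene(
      sp, list(width_mm = params$width_mm[i],
               theta_deg = params$theta_deg[i]),
      noise_level = noise_level, seed = seed + i)
    paths <- write_scene(scene, dir, params$stem[i])
    data.frame(stem = params$stem[i], image = paths[["image"]],
               detections = paths[["detections"]],
               truth = paths[["truth"]],
               gt_width_mm = scene$truth$true_width_mm,
               gt_ppc = scene$truth$true_ppc,
               true_type = scene$truth$caliper_type,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Measure a batch of images into a predictions table
#'
#' Runs [run_measure()] on each row of a cohort table and returns the
#' predictions CSV schema consumed by [run_eval()]: one row per image with
#' empty predictions for failures.
#'
#' @param cohort data frame as from [synthesize_cohort()] (columns `stem`,
#'   `image`, `detections`, plus ground-truth columns carried through).
#' @param config [pipeline_config()].
#' @param out optional path to write the CSV.
#' @return data frame with `image_id`, `gt_width_mm`, `pred_width_mm`,
#'   `true_type`, `pred_type`.
#' @export
batch_measure <- function(cohort, config = pipeline_config(), out = NULL) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    res <- run_measure(cohort$image[i], cohort$detections[i], config)
    ok <- inherits(res, "lv_result")
    data.frame(image_id = cohort$stem[i],
               gt_width_mm = cohort$gt_width_mm[i],
               pred_width_mm = if (ok) res$record$width_mm else NA_real_,
               true_type = cohort$true_type[i],
               pred_type = if (ok) res$record$caliper_type else NA_character_,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (!is.null(out)) utils::write.csv(df, out, row.names = FALSE, na = "")
  df
}

#' Evaluate a predictions table
#'
#' Computes the evaluation summaries from a predictions CSV/data frame
#' (columns `image_id`, `gt_width_mm`, `pred_width_mm` with empty/NA for
#' failures, `true_type`, `pred_type`; optional `stratum`, and optional
#' `gt_present`/`pred_present` 0/1 columns for detection confusion metrics).
#'
#' @param predictions data frame or path to a CSV file.
#' @param out optional path for the metrics JSON.
#' @return list with `width` ([width_error_stats()]), `type`
#'   ([type_accuracy()]) and, when presence columns exist, `detection`
#'   ([confusion_metrics()]).
#' @export
run_eval <- function(predictions, out = NULL) {
  df <- if (is.character(predictions)) {
    utils::read.csv(predictions, stringsAsFactors = FALSE)
  } else predictions
  if (nrow(df) == 0L) abort_validation("empty predictions table")
  need <- c("image_id", "gt_width_mm", "pred_width_mm", "true_type",
            "pred_type")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    abort_parse(paste("predictions table lacks columns:",
                      paste(miss, collapse = ", ")))
  pred_type <- df$pred_type
  pred_type[pred_type %in% c("", NA)] <- NA_character_
  wrows <- !is.na(df$gt_width_mm)
  res <- list(
    width = if (any(wrows))
      width_error_stats(df$gt_width_mm[wrows], df$pred_width_mm[wrows]),
    type = type_accuracy(as.character(df$true_type),
                         as.character(pred_type),
                         stratum = df$stratum))
  if (all(c("gt_present", "pred_present") %in% names(df))) {
    gt <- df$gt_present == 1; pr <- df$pred_present == 1
    tab <- confusion_table(tp = sum(gt & pr), fn = sum(gt & !pr),
                           fp = sum(!gt & pr), tn = sum(!gt & !pr))
    res$detection <- confusion_metrics(tab)
  }
  if (!is.null(out)) {
    jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  }
  res
}
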