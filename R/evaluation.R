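#' Confusion table and its detection metrics
#'
#' Builds a 2x2 confusion table (rows = ground truth yes/no, columns =
#' predicted yes/no) and the metric set used to summarise detection
#' performance. Besides the textbook row-wise definitions, the report
#' carries `sensitivity_paper = tp / (tp + fp)` (equal to precision) and
#' `specificity_paper = tn / (tn + fn)` (the negative predictive value):
#' these column-wise variants are what some clinical reports print under the
#' names "sensitivity" and "specificity", so both conventions are exposed,
#' clearly labelled.
#'
#' @param tp,fn,fp,tn non-negative counts.
#' @return `confusion_table()`: a validated table object.
#' @export
confusion_table <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    abort_validation("counts must be non-negative integers")
  if (sum(counts) == 0) abort_validation("all-zero confusion table")
  structure(as.list(counts), class = "lv_confusion_table")
}

#' @rdname confusion_table
#' @param table an `lv_confusion_table`.
#' @return `confusion_metrics()`: a list with `precision`, `recall`,
#'   `accuracy`, `sensitivity`, `specificity` (row-wise), and
#'   `sensitivity_paper`, `specificity_paper` (column-wise). A zero
#'   denominator yields `NA` for that metric.
#' @export
confusion_metrics <- function(table) {
  stopifnot(inherits(table, "lv_confusion_table"))
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  with(table, list(
    precision = frac(tp, tp + fp),
    recall = frac(tp, tp + fn),
    accuracy = frac(tp + tn, tp + fn + fp + tn),
    sensitivity = frac(tp, tp + fn),
    specificity = frac(tn, tn + fp),
    sensitivity_paper = frac(tp, tp + fp),
    specificity_paper = frac(tn, tn + fn)
  ))
}

#' Average an expert score distribution
#'
#' Scores run 0--4 (degree of fit between a predicted contour and ground
#' truth); given the per-score counts, returns the weighted mean and the
#' per-score percentages, each also rounded to 1 decimal for display.
#'
#' @param counts_by_score named numeric vector or list; names are scores
#'   `"0"`..`"4"`, values are counts.
#' @return list with `mean`, `mean_display` (1 decimal), `percentages`,
#'   `percentages_display`, `total`.
#' @export
score_average <- function(counts_by_score) {
  counts <- unlist(counts_by_score)
  if (length(counts) == 0L || sum(counts) == 0)
    abort_validation("empty score distribution")
  scores <- as.numeric(names(counts))
  if (anyNA(scores) || any(!scores %in% 0:4))
    abort_validation("scores must be named 0..4")
  total <- sum(counts)
  m <- sum(scores * counts) / total
  pct <- 100 * counts / total
  list(mean = m, mean_display = round(m, 1),
       percentages = pct, percentages_display = round(pct, 1),
       total = total)
}

#' Caliper-type classification accuracy
#'
#' Accuracy = correct / total, overall and per stratum (e.g. black vs complex
#' image background). A failed prediction (`NA`) counts as incorrect.
#'
#' @param true_type,pred_type character vectors; `pred_type` may contain `NA`
#'   for failures.
#' @param stratum optional stratification factor.
#' @return list with `overall` (`n`, `correct`, `accuracy`) and, when strata
#'   are given, `by_stratum` (one row per stratum).
#' @export
type_accuracy <- function(true_type, pred_type, stratum = NULL) {
  n <- length(true_type)
  if (n == 0L) abort_validation("no records")
  if (length(pred_type) != n) abort_validation("length mismatch")
  ok <- !is.na(pred_type) & pred_type == true_type
  res <- list(overall = list(n = n, correct = sum(ok),
                             accuracy = sum(ok) / n))
  if (!is.null(stratum)) {
    by <- lapply(split(ok, stratum), function(v)
      list(n = length(v), correct = sum(v), accuracy = sum(v) / length(v)))
    res$by_stratum <- by
  }
  res
}

#' Width-error statistics with the missing-as-0-mm rule
#'
#' A failed measurement (missing prediction) is scored as 0 mm, so its
#' absolute error equals the ground-truth width. Over the (possibly
#' substituted) errors `e = pred - gt`:
#' MAE = mean(|e|), RMSE = sqrt(mean(e^2)), SD = standard deviation of |e|
#' (population form; the sample form is also reported), and
#' `mae_pct = 100 * MAE / mean(gt)`.
#'
#' @param gt_mm ground-truth widths (> 0).
#' @param pred_mm predicted widths; `NA` = measurement failure.
#' @return list of class `lv_width_error_stats`: `mae_mm`, `sd_mm`,
#'   `sd_mm_sample`, `rmse_mm`, `mae_pct`, `n`, `n_missing`.
#' @export
width_error_stats <- function(gt_mm, pred_mm) {
  n <- length(gt_mm)
  if (n == 0L) abort_validation("no measurement pairs")
  if (length(pred_mm) != n) abort_validation("length mismatch")
  if (anyNA(gt_mm) || any(gt_mm <= 0))
    abort_validation("ground-truth widths must be positive")
  n_missing <- sum(is.na(pred_mm))
  pred <- ifelse(is.na(pred_mm), 0, pred_mm)
  e <- pred - gt_mm
  ae <- abs(e)
  mae <- mean(ae)
  structure(list(
    mae_mm = mae,
    sd_mm = sqrt(mean((ae - mae)^2)),
    sd_mm_sample = if (n > 1L) stats::sd(ae) else 0,
    rmse_mm = sqrt(mean(e^2)),
    mae_pct = 100 * mae / mean(gt_mm),
    n = n, n_missing = n_missing), class = "lv_width_error_stats")
}

#' @export
print.lv_width_error_stats <- function(x, ...) {
  cat(sprintf(
    "<width errors: MAE %.2f mm (%.2f%%), SD %.2f mm, RMSE %.2f mm, n = %d (%d missing)>\n",
    x$mae_mm, x$mae_pct, x$sd_mm, x$rmse_mm, x$n, x$n_missing))
  invisible(x)
}
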