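# Classed conditions so callers can distinguish failure modes
# (validation / dimension / layout / parse / extraction / classification).

lv_abort <- function(message, class) {
  cond <- structure(
    class = c(class, "lvmeasure_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  )
  stop(cond)
}

abort_validation     <- function(msg) lv_abort(msg, "lv_validation_error")
abort_dimension      <- function(msg) lv_abort(msg, "lv_dimension_error")
abort_layout         <- function(msg) lv_abort(msg, "lv_layout_error")
abort_parse          <- function(msg) lv_abort(msg, "lv_parse_error")
abort_extraction     <- function(msg) lv_abort(msg, "lv_extraction_error")
abort_classification <- function(msg) lv_abort(msg, "lv_classification_error")

# Run expr with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards so generators never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    abort_validation("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
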