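#' Create a fetal heart rate record
#'
#' An `fhr_record` is a uniformly sampled fetal heart rate (FHR) trace in
#' beats per minute, with the sampling rate and optional delivery-outcome
#' metadata (umbilical-artery pH and a normal/pathological class label)
#' attached. A sample value of exactly 0 encodes a signal dropout (missing
#' data), as in clinical cardiotocography exports.
#'
#' @param samples Numeric vector of heart-rate samples in bpm; finite, at
#'   least 0 (0 means missing).
#' @param fs Sampling frequency in Hz (cardiotocographs record at 4 Hz).
#' @param record_id Character identifier.
#' @param ph Optional umbilical-artery pH at delivery.
#' @param label Optional class label, `"normal"` or `"pathological"`.
#'
#' @return An object of class `fhr_record`.
#' @seealso [generate_fhr()], [preprocess_fhr()], [as_tibble.fhr_record()]
#' @export
#' @examples
#' rec <- fhr_record(c(130, 132, 131, 129), fs = 4)
#' rec
fhr_record <- function(samples, fs = 4, record_id = "record",
                       ph = NA_real_, label = NA_character_) {
  if (!is.numeric(samples) || length(samples) < 1L)
    abort("`samples` must be a non-empty numeric vector")
  if (any(!is.finite(samples)) || any(samples < 0))
    abort("`samples` must be finite and >= 0 (0 encodes missing)")
  check_scalar_number(fs, "fs")
  if (fs <= 0) abort("`fs` must be > 0")
  if (!is.na(label) && !label %in% c("normal", "pathological"))
    abort("`label` must be \"normal\" or \"pathological\"")
  structure(
    list(record_id = as.character(record_id),
         samples = as.numeric(samples),
         fs = fs, ph = as.numeric(ph), label = label),
    class = "fhr_record"
  )
}

is_fhr_record <- function(x) inherits(x, "fhr_record")

#' @export
print.fhr_record <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf("<fhr_record> %s: %d samples @ %g Hz (%.1f min)\n",
              x$record_id, length(x$samples), x$fs, dur / 60))
  if (!is.na(x$ph)) cat(sprintf("  pH %.2f", x$ph))
  if (!is.na(x$label)) cat(sprintf("  label %s", x$label))
  if (!is.na(x$ph) || !is.na(x$label)) cat("\n")
  invisible(x)
}

#' Convert an FHR record to a tibble
#'
#' @param x An [fhr_record].
#' @param ... Unused.
#' @return A tibble with columns `time_s` and `fhr_bpm`.
#' @method as_tibble fhr_record
#' @export
as_tibble.fhr_record <- function(x, ...) {
  tibble(time_s = (seq_along(x$samples) - 1) / x$fs, fhr_bpm = x$samples)
}

#' @export
length.fhr_record <- function(x) length(x$samples)

# Replace samples, keeping metadata.
set_samples <- function(record, samples) {
  record$samples <- as.numeric(samples)
  record
}
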