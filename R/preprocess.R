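#' Preprocessing configuration
#'
#' Thresholds for the three-step rule-based FHR denoising: dropout (gap)
#' handling, adjacent-jump stabilisation, and physiological-range outlier
#' repair.
#'
#' @param long_gap_s Zero-runs strictly longer than this many seconds are
#'   removed (spliced out); shorter runs are linearly interpolated. Default 15.
#' @param jump_bpm Adjacent samples differing by more than this many bpm mark
#'   an unstable stretch. Default 25.
#' @param min_bpm,max_bpm Physiological range; samples outside are replaced by
#'   monotone Hermite interpolation. Defaults 50 and 200.
#' @param segment_length_min Segment length selected for analysis, minutes.
#'   Default 13.
#' @param stable_run_samples Minimum length (samples) of a run with all
#'   adjacent differences <= `jump_bpm` to count as stable. Default 8 (2 s at
#'   4 Hz).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(long_gap_s = 15, jump_bpm = 25,
                              min_bpm = 50, max_bpm = 200,
                              segment_length_min = 13,
                              stable_run_samples = 8L) {
  check_scalar_number(long_gap_s, "long_gap_s")
  check_scalar_number(jump_bpm, "jump_bpm")
  check_scalar_number(min_bpm, "min_bpm")
  check_scalar_number(max_bpm, "max_bpm")
  check_count(stable_run_samples, "stable_run_samples", lower = 2L)
  if (long_gap_s <= 0) abort("`long_gap_s` must be > 0")
  if (jump_bpm <= 0) abort("`jump_bpm` must be > 0")
  if (!(0 < min_bpm && min_bpm < max_bpm))
    abort("need 0 < min_bpm < max_bpm")
  structure(list(long_gap_s = long_gap_s, jump_bpm = jump_bpm,
                 min_bpm = min_bpm, max_bpm = max_bpm,
                 segment_length_min = segment_length_min,
                 stable_run_samples = as.integer(stable_run_samples)),
            class = "preprocess_config")
}

#' Locate dropout (zero-valued) segments
#'
#' @param record An [fhr_record].
#' @return A tibble of maximal zero-runs with half-open sample spans
#'   (`start`, `end`, 1-based start, exclusive end) and `length`, in order.
#' @export
find_missing_segments <- function(record) {
  stopifnot(is_fhr_record(record))
  r <- rle(record$samples == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start = starts[keep], end = ends[keep] + 1L,
         length = r$lengths[keep])
}

#' Remove or interpolate dropout segments
#'
#' Zero-runs strictly longer than `long_gap_s` seconds are spliced out of the
#' signal; shorter interior runs are replaced by linear interpolation between
#' the flanking non-zero samples. Zero-runs touching either end of the record
#' have no flanking anchor and are trimmed.
#'
#' @param record An [fhr_record].
#' @param config A [preprocess_config].
#' @return The gap-free [fhr_record] (possibly shorter).
#' @export
remove_long_gaps <- function(record, config = preprocess_config()) {
  stopifnot(is_fhr_record(record))
  x <- record$samples
  if (all(x == 0)) abort("no valid signal: record is entirely zero")
  gaps <- find_missing_segments(record)
  if (nrow(gaps) == 0) return(record)
  n <- length(x)
  max_keep <- config$long_gap_s * record$fs  # strictly longer is removed
  drop <- rep(FALSE, n)
  for (g in seq_len(nrow(gaps))) {
    s <- gaps$start[g]; e <- gaps$end[g] - 1L; len <- gaps$length[g]
    boundary <- s == 1L || e == n
    if (boundary || len > max_keep) {
      drop[s:e] <- TRUE
    } else {
      x[s:e] <- approx(x = c(s - 1L, e + 1L), y = c(x[s - 1L], x[e + 1L]),
                       xout = s:e)$y
    }
  }
  set_samples(record, x[!drop])
}

# Runs of samples whose internal adjacent differences are all <= jump_bpm.
# Returns a logical vector marking samples that belong to a stable run.
stable_mask <- function(x, jump_bpm, min_run) {
  n <- length(x)
  if (n == 1L) return(TRUE)
  ok <- abs(diff(x)) <= jump_bpm  # ok[i]: the step i -> i+1 is calm
  # segment boundaries at every violent step
  seg_id <- cumsum(c(1L, as.integer(!ok)))
  seg_len <- tabulate(seg_id)
  seg_len[seg_id] >= min_run
}

#' Repair unstable stretches (spiky artifacts)
#'
#' Samples outside any stable run (a run of at least `stable_run_samples`
#' samples whose adjacent differences all stay within `jump_bpm`) are replaced
#' by linear interpolation from the last sample of the preceding stable run to
#' the first sample of the following one. Leading/trailing unstable samples
#' are trimmed. A step that survives (two stable runs at different levels
#' abutting directly, as happens at dropout splice junctions) is bridged by a
#' short linear ramp; in the rare case a ramp cannot bring all differences
#' within `jump_bpm`, the record is flagged via the `unrepairable` attribute.
#'
#' @inheritParams remove_long_gaps
#' @return The stabilised [fhr_record].
#' @export
stabilize <- function(record, config = preprocess_config()) {
  stopifnot(is_fhr_record(record))
  x <- record$samples
  stable <- stable_mask(x, config$jump_bpm, config$stable_run_samples)
  if (!any(stable)) abort("unstable record: no stable run found")
  idx_stable <- which(stable)
  # trim ends that have no stable anchor
  x <- x[idx_stable[1]:idx_stable[length(idx_stable)]]
  stable <- stable[idx_stable[1]:idx_stable[length(idx_stable)]]
  if (!all(stable)) {
    anchors <- which(stable)
    x[!stable] <- approx(x = anchors, y = x[anchors],
                         xout = which(!stable))$y
  }
  # A violent step can survive the run interpolation when two stable runs at
  # different levels abut (e.g. at a dropout splice junction): bridge each
  # remaining step with a short linear ramp, widening the ramp if needed.
  for (pass in 1:5) {
    bad <- which(abs(diff(x)) > config$jump_bpm)
    if (!length(bad)) break
    w <- config$stable_run_samples * pass
    prev_hi <- 0L
    for (p in bad) {
      lo <- max(1L, p - w + 1L); hi <- min(length(x), p + w)
      if (lo <= prev_hi) next  # already covered by the previous ramp
      x[lo:hi] <- approx(x = c(lo, hi), y = x[c(lo, hi)], xout = lo:hi)$y
      prev_hi <- hi
    }
  }
  out <- set_samples(record, x)
  if (any(abs(diff(x)) > config$jump_bpm)) {
    warn("adjacent differences above `jump_bpm` remain; record flagged unrepairable")
    attr(out, "unrepairable") <- TRUE
  }
  out
}

#' Repair physiologically extreme samples
#'
#' Samples outside \[`min_bpm`, `max_bpm`\] are replaced by monotone piecewise
#' cubic Hermite interpolation (`stats::splinefun(method = "monoH.FC")`)
#' through the surrounding in-range samples; monotonicity keeps the fill
#' inside the range of its anchors. Out-of-range runs touching the record
#' ends are trimmed.
#'
#' @inheritParams remove_long_gaps
#' @return The repaired [fhr_record], all samples within range.
#' @export
remove_extremes <- function(record, config = preprocess_config()) {
  stopifnot(is_fhr_record(record))
  x <- record$samples
  inr <- x >= config$min_bpm & x <= config$max_bpm
  if (sum(inr) < 4L) abort("fewer than 4 in-range samples")
  if (all(inr)) return(record)
  first <- which(inr)[1]; last <- which(inr)[sum(inr)]
  x <- x[first:last]; inr <- inr[first:last]
  if (!all(inr)) {
    f <- splinefun(x = which(inr), y = x[inr], method = "monoH.FC")
    x[!inr] <- f(which(!inr))
  }
  set_samples(record, x)
}

#' Full three-step FHR preprocessing
#'
#' Composition `remove_long_gaps()` then `stabilize()` then
#' `remove_extremes()`: dropout handling, jump stabilisation, and range
#' repair, in the order the rules are stated clinically. The output contains
#' no zeros and lies within \[`min_bpm`, `max_bpm`\]; the map is idempotent.
#'
#' @inheritParams remove_long_gaps
#' @return The preprocessed [fhr_record].
#' @export
#' @examples
#' rec <- generate_fhr(synth_config("normal", duration_s = 600, seed = 3))
#' clean <- preprocess_fhr(rec)
#' range(clean$samples)
preprocess_fhr <- function(record, config = preprocess_config()) {
  record |>
    remove_long_gaps(config) |>
    stabilize(config) |>
    remove_extremes(config)
}

#' Select the analysis segment
#'
#' Returns the final `segment_length_min` minutes of the record — the portion
#' closest to delivery, where the pH outcome is measured.
#'
#' @param record A preprocessed [fhr_record].
#' @param segment_length_min Segment length in minutes.
#' @return The trailing segment as an [fhr_record] of exactly
#'   `segment_length_min * 60 * fs` samples.
#' @export
select_segment <- function(record, segment_length_min = 13) {
  stopifnot(is_fhr_record(record))
  need <- as.integer(round(segment_length_min * 60 * record$fs))
  n <- length(record$samples)
  if (n < need)
    abort(sprintf("record too short: %d samples available, %d requested",
                  n, need))
  set_samples(record, record$samples[(n - need + 1L):n])
}
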