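#' Configuration for the synthetic cardiotocography generator
#'
#' Defines the statistical structure of a simulated fetal heart rate trace:
#' a baseline level, band-limited short- and long-term variability,
#' acceleration and deceleration events, and the two artifact kinds that
#' clinical recordings carry (zero-valued dropouts and isolated spikes).
#' The `"pathological"` preset encodes the hypoxia pattern described in the
#' obstetric literature: strongly suppressed short-term (beat-to-beat)
#' variability with preserved-to-prominent slow undulation, rarer
#' accelerations and more frequent decelerations. Relative to the normal
#' preset it divides the short-term variability by 4, raises the long-term
#' variability (5 vs 3.5 bpm), multiplies the deceleration rate by 4 and the
#' acceleration rate by 0.25. The fast-to-slow variability ratio is the key
#' contrast: fixed-neighbour-count recurrence plots are invariant to overall
#' amplitude, so classes that differ only in amplitude would render
#' identically.
#'
#' @param class_label `"normal"` or `"pathological"`; selects the preset the
#'   remaining defaults are drawn from.
#' @param duration_s Record length in seconds.
#' @param fs Sampling frequency in Hz.
#' @param baseline_bpm Baseline heart rate in bpm. `NA` draws it uniformly
#'   from \[120, 150\] (inside the normal 110-160 bpm band) when the record is
#'   generated.
#' @param stv_bpm Short-term variability amplitude (standard deviation, bpm).
#' @param ltv_bpm Long-term variability amplitude (standard deviation, bpm).
#' @param accel_rate,decel_rate Expected acceleration / deceleration events
#'   per hour.
#' @param dropout_rate Zero-run (signal loss) events per hour; run lengths are
#'   exponential with mean 8 s, truncated to \[1, 40\] s.
#' @param spike_rate Isolated spiky artifacts per hour.
#' @param seed Integer seed; every random draw in [generate_fhr()] derives
#'   from it, so identical configurations reproduce identical records.
#'
#' @return A `synth_config` list.
#' @export
#' @examples
#' cfg <- synth_config("pathological", duration_s = 600, seed = 7)
#' cfg$decel_rate
synth_config <- function(class_label = c("normal", "pathological"),
                         duration_s = 1200, fs = 4,
                         baseline_bpm = NA_real_,
                         stv_bpm = NULL, ltv_bpm = NULL,
                         accel_rate = NULL, decel_rate = NULL,
                         dropout_rate = 6, spike_rate = 12,
                         seed = 1L) {
  class_label <- match.arg(class_label)
  check_scalar_number(duration_s, "duration_s")
  check_scalar_number(fs, "fs")
  if (duration_s <= 0) abort("`duration_s` must be > 0")
  if (fs <= 0) abort("`fs` must be > 0")
  patho <- class_label == "pathological"
  stv_bpm <- stv_bpm %||% (if (patho) 2 else 8)
  ltv_bpm <- ltv_bpm %||% (if (patho) 5 else 3.5)
  accel_rate <- accel_rate %||% (if (patho) 2.5 else 10)
  decel_rate <- decel_rate %||% (if (patho) 2 else 0.5)
  for (nm in c("stv_bpm", "ltv_bpm", "accel_rate", "decel_rate",
               "dropout_rate", "spike_rate"))
    check_scalar_number(get(nm), nm, lower = 0)
  if (!is.na(baseline_bpm))
    check_scalar_number(baseline_bpm, "baseline_bpm", lower = 110, upper = 160)
  structure(
    list(class_label = class_label, duration_s = duration_s, fs = fs,
         baseline_bpm = baseline_bpm, stv_bpm = stv_bpm, ltv_bpm = ltv_bpm,
         accel_rate = accel_rate, decel_rate = decel_rate,
         dropout_rate = dropout_rate, spike_rate = spike_rate,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Smooth unit-variance Gaussian noise: white noise convolved with a Gaussian
# kernel of standard deviation `smooth_s` seconds, rescaled to sd 1.
smooth_noise <- function(n, fs, smooth_s) {
  half <- max(1L, ceiling(3 * smooth_s * fs))
  kern <- exp(-0.5 * ((-half:half) / (smooth_s * fs))^2)
  kern <- kern / sum(kern)
  z <- rnorm(n + 2L * half)
  s <- stats::filter(z, kern, sides = 2L)
  s <- s[(half + 1L):(half + n)]
  s / sqrt(sum(kern^2))
}

# Gaussian bump of the given peak amplitude and nominal duration, centred at
# `centre` (sample index), added onto `x`.
add_bump <- function(x, centre, amp, dur_samples) {
  sigma <- dur_samples / 4
  lo <- max(1L, floor(centre - 3 * sigma))
  hi <- min(length(x), ceiling(centre + 3 * sigma))
  if (lo > hi) return(x)
  t <- lo:hi
  x[t] <- x[t] + amp * exp(-0.5 * ((t - centre) / sigma)^2)
  x
}

#' Generate one synthetic FHR record
#'
#' Simulates a fetal heart rate trace as baseline + band-limited Gaussian
#' short- and long-term variability + Gaussian-shaped acceleration bumps
#' (+10-25 bpm, 15-60 s) and deceleration dips (-10-40 bpm, 20-90 s), then
#' overwrites artifact positions (zero dropouts and isolated spikes). The
#' event-free signal is kept inside \[55, 195\] bpm so that preprocessing is
#' the identity on artifact-free records. A plausibility pH is attached:
#' uniform on \[7.20, 7.38\] for the normal preset and \[6.95, 7.12\] for the
#' pathological one, straddling the clinical 7.15 borderline.
#'
#' @param config A [synth_config].
#' @param record_id Identifier for the new record.
#' @return An [fhr_record] with `ph` and `label` set.
#' @export
#' @examples
#' rec <- generate_fhr(synth_config("normal", duration_s = 300, seed = 42))
#' range(rec$samples)
generate_fhr <- function(config, record_id = NULL) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  n <- as.integer(round(config$duration_s * config$fs))
  if (n < 1L) abort("duration and fs must give at least one sample")
  record_id <- record_id %||%
    sprintf("synth_%s_%d", substr(config$class_label, 1, 4), config$seed)

  withr::with_seed(config$seed, {
    base <- if (is.na(config$baseline_bpm)) runif(1, 120, 150)
            else config$baseline_bpm
    x <- rep(base, n)
    if (config$stv_bpm > 0)
      x <- x + config$stv_bpm * smooth_noise(n, config$fs, smooth_s = 0.6)
    if (config$ltv_bpm > 0)
      x <- x + config$ltv_bpm * smooth_noise(n, config$fs, smooth_s = 25)
    # the event-free core stays within the documented +/- 30 bpm band
    x <- pmin(pmax(x, base - 30), base + 30)

    hours <- config$duration_s / 3600
    n_acc <- stats::rpois(1, config$accel_rate * hours)
    if (n_acc > 0) for (i in seq_len(n_acc))
      x <- add_bump(x, runif(1, 1, n), amp = runif(1, 10, 25),
                    dur_samples = runif(1, 15, 60) * config$fs)
    n_dec <- stats::rpois(1, config$decel_rate * hours)
    if (n_dec > 0) for (i in seq_len(n_dec))
      x <- add_bump(x, runif(1, 1, n), amp = -runif(1, 10, 40),
                    dur_samples = runif(1, 20, 90) * config$fs)

    # keep the clean signal strictly inside the physiological band
    x <- pmin(pmax(x, 55), 195)

    # artifacts overwrite the clean signal
    n_spk <- stats::rpois(1, config$spike_rate * hours)
    if (n_spk > 0) {
      at <- sample.int(n, min(n_spk, n))
      x[at] <- pmax(0, x[at] + sample(c(-1, 1), length(at), TRUE) *
                      runif(length(at), 30, 100))
    }
    n_drop <- stats::rpois(1, config$dropout_rate * hours)
    if (n_drop > 0) for (i in seq_len(n_drop)) {
      len <- as.integer(round(min(40, max(1, stats::rexp(1, 1 / 8))) * config$fs))
      start <- sample.int(max(1L, n - len), 1L)
      x[start:min(n, start + len - 1L)] <- 0
    }

    ph <- if (config$class_label == "pathological") runif(1, 6.95, 7.12)
          else runif(1, 7.20, 7.38)
    fhr_record(x, fs = config$fs, record_id = record_id,
               ph = ph, label = config$class_label)
  })
}

#' Generate a balanced labelled cohort
#'
#' Produces `n_per_class` records of each class with per-record seeds derived
#' deterministically from `seed`, mirroring the balanced-cohort design used
#' for intrapartum CTG studies.
#'
#' @param n_per_class Records per class (>= 1).
#' @param config_overrides Named list applied to both class presets (e.g.
#'   `list(duration_s = 900)`).
#' @param seed Master seed.
#' @return A tibble with columns `record_id`, `label`, `ph`, `seed` and a
#'   `record` list-column of [fhr_record] objects.
#' @export
#' @examples
#' cohort <- generate_cohort(2, list(duration_s = 300), seed = 1)
#' cohort$label
generate_cohort <- function(n_per_class, config_overrides = list(), seed = 1L) {
  check_count(n_per_class, "n_per_class")
  rows <- list()
  i <- 0L
  for (cls in c("normal", "pathological")) {
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      rec_seed <- derive_seed(seed, sprintf("%s_%d", cls, j))
      cfg <- do.call(synth_config,
                     c(list(class_label = cls, seed = rec_seed),
                       config_overrides))
      id <- sprintf("synth_%s_%03d", substr(cls, 1, 4), j)
      rec <- generate_fhr(cfg, record_id = id)
      rows[[i]] <- tibble(record_id = id, label = cls, ph = rec$ph,
                          seed = rec_seed, record = list(rec))
    }
  }
  dplyr::bind_rows(rows)
}
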