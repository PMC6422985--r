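#' Label an outcome pH
#'
#' Umbilical-artery pH at or above the threshold is assessed as normal,
#' below it as pathological (fetal hypoxia). The clinical borderline used
#' throughout is 7.15.
#'
#' @param ph Numeric vector of pH values.
#' @param threshold Decision borderline (default 7.15).
#' @return Character vector, `"normal"` or `"pathological"`.
#' @export
#' @examples
#' label_by_ph(c(7.15, 7.03, 7.23))
label_by_ph <- function(ph, threshold = 7.15) {
  if (any(!is.finite(ph))) abort("missing pH: cannot label")
  ifelse(ph >= threshold, "normal", "pathological")
}

#' Balance classes by subsampling the majority
#'
#' Randomly subsamples the majority class without replacement down to the
#' minority size (seeded), mirroring the balanced-cohort design.
#'
#' @param cohort Tibble with a `label` column (e.g. from [generate_cohort()]).
#' @param seed Integer seed.
#' @return The balanced tibble, original row order preserved.
#' @export
balance_classes <- function(cohort, seed = 1L) {
  if (!"label" %in% names(cohort)) abort("`cohort` needs a `label` column")
  tab <- table(cohort$label)
  if (length(tab) < 2) abort("both classes must be present")
  n_min <- min(tab)
  keep <- withr::with_seed(seed, {
    unlist(lapply(names(tab), function(cls) {
      idx <- which(cohort$label == cls)
      if (length(idx) > n_min) sort(sample(idx, n_min)) else idx
    }))
  })
  cohort[sort(keep), ]
}

#' Augmentation grid of recurrence-plot parameters
#'
#' The defaults are the published sweep: m in \{2, 3\}, tau and k each 1..10,
#' i.e. 200 images per record.
#'
#' @param m_values,tau_values,k_values Integer vectors of embedding
#'   dimensions, delays and neighbour counts.
#' @return A tibble of grid cells in lexicographic (m, tau, k) order.
#' @export
augmentation_grid <- function(m_values = c(2L, 3L), tau_values = 1:10,
                              k_values = 1:10) {
  if (!length(m_values) || !length(tau_values) || !length(k_values))
    abort("grid must be non-empty")
  if (any(m_values < 2)) abort("m values must be >= 2")
  if (any(tau_values < 1) || any(k_values < 1))
    abort("tau and k values must be >= 1")
  g <- expand.grid(k = as.integer(sort(k_values)),
                   tau = as.integer(sort(tau_values)),
                   m = as.integer(sort(m_values)))
  tibble(m = g$m, tau = g$tau, k = g$k)
}

#' Render every grid cell of one record
#'
#' Produces one recurrence-plot image per (m, tau, k) grid cell, in
#' deterministic lexicographic order — the parameter-grid augmentation that
#' turns each record into (by default) 200 training images.
#'
#' @param record A preprocessed [fhr_record].
#' @param grid An [augmentation_grid()] tibble.
#' @param size Image side length.
#' @param mode Threshold mode passed to [signal_to_rp()].
#' @return A tibble with columns `record_id`, `label`, `m`, `tau`, `k` and an
#'   `image` list-column.
#' @export
augment_record <- function(record, grid = augmentation_grid(), size = 64,
                           mode = "per-point") {
  stopifnot(is_fhr_record(record))
  L <- length(record$samples)
  for (i in seq_len(nrow(grid))) {
    need <- (grid$m[i] - 1L) * grid$tau[i] + grid$k[i] + 1L
    if (L < need)
      abort(sprintf("record %s too short for grid cell (m=%d, tau=%d, k=%d)",
                    record$record_id, grid$m[i], grid$tau[i], grid$k[i]))
  }
  imgs <- purrr::pmap(grid, function(m, tau, k)
    signal_to_rp(record, m = m, tau = tau, k = k, size = size, mode = mode))
  dplyr::mutate(grid,
                record_id = record$record_id,
                label = record$label %||% NA_character_,
                image = imgs,
                .before = 1)
}

#' Assign images to cross-validation folds
#'
#' Stratified partition into `n_folds` near-equal folds. In `"image"` mode
#' each image is assigned independently (the published protocol: note that
#' augmented images of one record can then appear in both training and test
#' folds, which leaks record identity and flatters the metrics). In
#' `"record"` mode whole records are assigned to folds, so no record
#' contributes to two folds — the honest generalisation estimate.
#'
#' @param labels Character vector of per-image class labels.
#' @param n_folds Number of folds (default 10).
#' @param mode `"image"` or `"record"`.
#' @param record_ids Per-image record identifiers; required in record mode.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..n_folds, one per image, with the
#'   mode in the `mode` attribute.
#' @export
make_folds <- function(labels, n_folds = 10, mode = c("image", "record"),
                       record_ids = NULL, seed = 1L) {
  mode <- match.arg(mode)
  n <- length(labels)
  check_count(n_folds, "n_folds", lower = 2L)
  if (n < n_folds) abort("fewer images than folds")
  fold <- integer(n)
  withr::with_seed(seed, {
    if (mode == "image") {
      for (cls in unique(labels)) {
        idx <- which(labels == cls)
        fold[idx[sample.int(length(idx))]] <-
          rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      if (is.null(record_ids)) abort("record mode needs `record_ids`")
      rec <- unique(data.frame(record_ids, labels))
      if (anyDuplicated(rec$record_ids))
        abort("a record carries two labels")
      rec_fold <- integer(nrow(rec))
      for (cls in unique(rec$labels)) {
        idx <- which(rec$labels == cls)
        rec_fold[idx[sample.int(length(idx))]] <-
          rep_len(seq_len(n_folds), length(idx))
      }
      fold <- rec_fold[match(record_ids, rec$record_ids)]
    }
  })
  structure(fold, mode = mode)
}

#' Build the full augmented image dataset from a cohort
#'
#' Preprocesses every record, selects the trailing analysis segment, renders
#' the whole augmentation grid per record, and stacks the results.
#'
#' @param cohort Tibble with `record` list-column and `label` (e.g. from
#'   [generate_cohort()]).
#' @param grid An [augmentation_grid()].
#' @param segment_length_min Analysis segment length in minutes; `NULL` skips
#'   segment selection (use for records shorter than the segment).
#' @param size Image side length.
#' @param config [preprocess_config()] used for cleaning.
#' @return A tibble with one row per image: `record_id`, `label`, `m`, `tau`,
#'   `k`, `image`.
#' @export
build_image_dataset <- function(cohort, grid = augmentation_grid(),
                                segment_length_min = 13, size = 64,
                                config = preprocess_config()) {
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    rec <- preprocess_fhr(cohort$record[[i]], config)
    if (!is.null(segment_length_min))
      rec <- select_segment(rec, segment_length_min)
    rec$label <- cohort$label[i]
    augment_record(rec, grid, size = size)
  })
  dplyr::bind_rows(rows)
}
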