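#' End-to-end pipeline on a synthetic or on-disk cohort
#'
#' Runs simulate (or load) -> preprocess -> segment -> recurrence-plot
#' augmentation -> folds -> cross-validated training -> report, writing a
#' cohort manifest, an image-dataset manifest and a JSON report under
#' `out_dir`. A single global seed deterministically derives every
#' stage seed, so reruns with the same configuration are identical.
#'
#' @param n_per_class Synthetic records per class (ignored when
#'   `cohort` is supplied).
#' @param cohort Optional existing cohort tibble (`record`, `label`,
#'   `record_id`, `ph` columns); when `NULL` one is generated.
#' @param duration_s Synthetic record duration (seconds).
#' @param grid [augmentation_grid()] for the RP parameter sweep.
#' @param segment_length_min Analysis segment (minutes).
#' @param arch [cnn_architecture()] to train.
#' @param train [train_config()] hyperparameters.
#' @param preprocess [preprocess_config()] thresholds.
#' @param n_folds,fold_mode Cross-validation protocol.
#' @param size Image side length.
#' @param out_dir Output directory; `NULL` skips writing artifacts.
#' @param seed Global seed.
#' @return A list with `cohort`, `dataset`, `report` (a `cv_report`) and
#'   `paths` of written artifacts.
#' @export
run_pipeline <- function(n_per_class = 30, cohort = NULL, duration_s = 1200,
                         grid = augmentation_grid(2, 1:2, c(2, 6)),
                         segment_length_min = 13,
                         arch = cnn_architecture("8"),
                         train = train_config(),
                         preprocess = preprocess_config(),
                         n_folds = 10, fold_mode = "record", size = 64,
                         out_dir = NULL, seed = 1L) {
  # validate everything before any work starts
  stopifnot(inherits(arch, "cnn_architecture"),
            inherits(train, "train_config"),
            inherits(preprocess, "preprocess_config"))
  invisible(arch_shapes(arch))
  if (is.null(cohort)) {
    message(sprintf("simulate: %d records per class", n_per_class))
    cohort <- generate_cohort(n_per_class,
                              list(duration_s = duration_s),
                              seed = derive_seed(seed, "simulate"))
  }
  message(sprintf("preprocess + augment: %d records x %d grid cells",
                  nrow(cohort), nrow(grid)))
  dataset <- build_image_dataset(cohort, grid,
                                 segment_length_min = segment_length_min,
                                 size = size, config = preprocess)
  message(sprintf("dataset: %d images (%s)", nrow(dataset),
                  paste(sprintf("%s=%d", names(table(dataset$label)),
                                table(dataset$label)), collapse = ", ")))
  report <- cross_validate(dataset, folds = n_folds, arch = arch,
                           config = train, fold_mode = fold_mode,
                           seed = derive_seed(seed, "cv"))
  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths$cohort <- file.path(out_dir, "cohort")
    write_cohort(cohort, paths$cohort)
    paths$report <- file.path(out_dir, "cv_report.json")
    write_cv_report(report, paths$report)
  }
  list(cohort = cohort, dataset = dataset, report = report, paths = paths)
}
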