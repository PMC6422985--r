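#' Confusion counts for a binary screen
#'
#' Tallies true/false positives and negatives. Note the convention used
#' throughout: the POSITIVE class is the NORMAL fetus (sensitivity is the
#' detection rate of normal fetuses, specificity that of hypoxic ones) —
#' the opposite of the usual clinical disease-positive convention. Override
#' with `positive`.
#'
#' @param truth,predicted Character vectors of `"normal"`/`"pathological"`
#'   labels, equal length.
#' @param positive Which class counts as positive (default `"normal"`).
#' @return A tibble with columns `tp`, `fp`, `fn`, `tn`.
#' @export
#' @examples
#' confusion(c("normal", "normal", "pathological"),
#'           c("normal", "pathological", "pathological"))
confusion <- function(truth, predicted, positive = "normal") {
  if (length(truth) != length(predicted)) abort("length mismatch")
  lv <- c("normal", "pathological")
  if (!all(truth %in% lv) || !all(predicted %in% lv))
    abort("labels must be \"normal\" or \"pathological\"")
  pos_t <- truth == positive
  pos_p <- predicted == positive
  tibble(tp = sum(pos_t & pos_p), fp = sum(!pos_t & pos_p),
         fn = sum(pos_t & !pos_p), tn = sum(!pos_t & !pos_p))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Acc = (TP+TN)/(TP+FP+FN+TN), Se = TP/(TP+FN), Sp = TN/(FP+TN), reported
#' in percent. Full precision is kept in the `accuracy`/`sensitivity`/
#' `specificity` columns; the `*_2dp` columns are rounded half-up to two
#' decimals as tables conventionally print them. Metrics with a zero
#' denominator are returned as `NA` with a warning.
#'
#' @param cc A one-row [confusion()] tibble (or list with tp, fp, fn, tn).
#' @return A one-row tibble of metrics in percent.
#' @export
#' @examples
#' cls_metrics(tibble::tibble(tp = 2037, fp = 86, fn = 63, tn = 2014))
cls_metrics <- function(cc) {
  tp <- cc$tp; fp <- cc$fp; fn <- cc$fn; tn <- cc$tn
  stopifnot(all(c(tp, fp, fn, tn) >= 0))
  total <- tp + fp + fn + tn
  if (total < 1) abort("empty confusion counts")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s undefined: zero denominator", what))
      return(NA_real_)
    }
    num / den
  }
  acc <- 100 * safe_div(tp + tn, total, "accuracy")
  se <- 100 * safe_div(tp, tp + fn, "sensitivity")
  sp <- 100 * safe_div(tn, fp + tn, "specificity")
  tibble(accuracy = acc, sensitivity = se, specificity = sp,
         accuracy_2dp = round_half_up(acc), sensitivity_2dp = round_half_up(se),
         specificity_2dp = round_half_up(sp))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the empirical ROC traced over all score
#' thresholds; with ties handled by the trapezoid this equals the
#' Mann-Whitney concordance probability P(score_pos > score_neg) + 0.5
#' P(tie).
#'
#' @param scores Numeric scores for the positive (normal) class.
#' @param truth Class labels, both classes present.
#' @param positive Positive class (default `"normal"`).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, truth, positive = "normal") {
  if (length(scores) != length(truth)) abort("length mismatch")
  pos <- truth == positive
  if (!any(pos) || all(pos)) abort("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # cumulative counts at each distinct threshold
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, cumsum(p)[keep] / sum(pos))
  fpr <- c(0, cumsum(!p)[keep] / sum(!pos))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' Bootstrap confidence interval for the AUC
#'
#' Stratified bootstrap (resampling within each class), percentile interval.
#'
#' @inheritParams roc_auc
#' @param n_boot Number of resamples (default 2000).
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return A tibble with `auc`, `lower`, `upper`, `conf`.
#' @export
roc_auc_ci <- function(scores, truth, positive = "normal", n_boot = 2000,
                       conf = 0.95, seed = 1L) {
  pos_idx <- which(truth == positive)
  neg_idx <- which(truth != positive)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      i <- c(sample(pos_idx, replace = TRUE), sample(neg_idx, replace = TRUE))
      roc_auc(scores[i], truth[i], positive)
    }, numeric(1))
  })
  q <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  tibble(auc = roc_auc(scores, truth, positive), lower = q[1], upper = q[2],
         conf = conf)
}

#' Cross-validated training and evaluation
#'
#' For each fold: hold the fold out as the test set, train a fresh network on
#' the remaining images (with an internal stratified train/validation split),
#' and score the held-out fold. Per-fold confusion counts, Acc/Se/Sp/AUC and
#' their across-fold arithmetic means are reported. Fully seeded: fold
#' training seeds derive deterministically from `seed`.
#'
#' @param dataset Tibble with `image` list-column, `label` and `record_id`
#'   columns (e.g. from [build_image_dataset()]).
#' @param folds Integer fold assignment from [make_folds()] (one id per row
#'   of `dataset`), or a fold count to be assigned here.
#' @param arch A [cnn_architecture()].
#' @param config A [train_config()].
#' @param fold_mode Passed to [make_folds()] when `folds` is a count.
#' @param seed Master seed.
#' @return A `cv_report`: list with `folds` (per-fold metric tibble),
#'   `summary` (averaged metrics), `predictions`, and the configuration.
#' @export
cross_validate <- function(dataset, folds = 10, arch = cnn_architecture("8"),
                           config = train_config(),
                           fold_mode = c("image", "record"), seed = 1L) {
  fold_mode <- match.arg(fold_mode)
  need <- c("image", "label", "record_id")
  if (!all(need %in% names(dataset)))
    abort("`dataset` needs columns image, label, record_id")
  if (length(folds) == 1L)
    folds <- make_folds(dataset$label, n_folds = folds, mode = fold_mode,
                        record_ids = dataset$record_id,
                        seed = derive_seed(seed, "folds"))
  if (length(folds) != nrow(dataset)) abort("fold assignment length mismatch")
  x_all <- images_to_batch(dataset$image)
  fold_ids <- sort(unique(folds))
  fold_rows <- vector("list", length(fold_ids))
  preds <- vector("list", length(fold_ids))
  for (fi in seq_along(fold_ids)) {
    f <- fold_ids[fi]
    te <- which(folds == f); tr <- which(folds != f)
    if (length(unique(dataset$label[te])) < 2)
      warn(sprintf("fold %d holds a single class; AUC undefined there", f))
    model <- build_cnn(arch, seed = derive_seed(seed, paste0("init", f)))
    cfg <- config
    cfg$seed <- derive_seed(seed, paste0("train", f))
    model <- train_cnn(model, x_all[, , , tr, drop = FALSE],
                       dataset$label[tr], config = cfg)
    pr <- predict_cnn(model, x_all[, , , te, drop = FALSE])
    pr$truth <- dataset$label[te]
    pr$record_id <- dataset$record_id[te]
    pr$fold <- f
    cc <- confusion(pr$truth, pr$.pred_label)
    mt <- cls_metrics(cc)
    auc <- if (length(unique(pr$truth)) == 2)
      roc_auc(pr$p_normal, pr$truth) else NA_real_
    fold_rows[[fi]] <- dplyr::bind_cols(tibble(fold = f), cc,
                                        mt[, 1:3], tibble(auc = 100 * auc))
    preds[[fi]] <- pr
  }
  folds_tbl <- dplyr::bind_rows(fold_rows)
  summary <- tibble(
    accuracy = mean(folds_tbl$accuracy),
    sensitivity = mean(folds_tbl$sensitivity),
    specificity = mean(folds_tbl$specificity),
    auc = mean(folds_tbl$auc, na.rm = TRUE))
  structure(list(folds = folds_tbl, summary = summary,
                 predictions = dplyr::bind_rows(preds),
                 fold_mode = attr(folds, "mode") %||% fold_mode,
                 arch_pattern = attr(arch, "pattern") %||% "custom",
                 config = config, seed = as.integer(seed)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold (%s-level), architecture %s\n",
              nrow(x$folds), x$fold_mode, x$arch_pattern))
  s <- x$summary
  cat(sprintf("  averaged: Acc %.2f%%  Se %.2f%%  Sp %.2f%%  AUC %.2f%%\n",
              s$accuracy, s$sensitivity, s$specificity, s$auc))
  invisible(x)
}

#' Tidiers for cross-validation reports
#'
#' `tidy()` returns the per-fold metric table; `glance()` the one-row
#' across-fold averages.
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return A tibble.
#' @name cv_report-tidiers
NULL

#' @rdname cv_report-tidiers
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) x$folds

#' @rdname cv_report-tidiers
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble(n_folds = nrow(x$folds), fold_mode = x$fold_mode,
           arch = x$arch_pattern),
    x$summary)
}

#' Write a cross-validation report as JSON
#'
#' @param report A `cv_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  jsonlite::write_json(
    list(fold_mode = report$fold_mode, arch = report$arch_pattern,
         seed = report$seed, config = unclass(report$config),
         folds = report$folds, summary = report$summary),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
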