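test_that("confusion counts treat the normal class as positive", {
  cc <- confusion(rep(c("normal", "pathological"), c(3, 2)),
                  rep(c("normal", "pathological"), c(3, 2)))
  expect_equal(unlist(cc), c(tp = 3, fp = 0, fn = 0, tn = 2))

  flipped <- confusion(rep(c("normal", "pathological"), c(3, 2)),
                       rep(c("pathological", "normal"), c(3, 2)))
  expect_equal(unlist(flipped), c(tp = 0, fp = 2, fn = 3, tn = 0))

  withr::with_seed(13, {
    truth <- sample(c("normal", "pathological"), 20, TRUE)
    pred <- sample(c("normal", "pathological"), 20, TRUE)
    cc2 <- confusion(truth, pred)
    # independent tally
    expect_equal(cc2$tp, sum(truth == "normal" & pred == "normal"))
    expect_equal(cc2$fp, sum(truth == "pathological" & pred == "normal"))
    expect_equal(cc2$fn, sum(truth == "normal" & pred == "pathological"))
    expect_equal(cc2$tn, sum(truth == "pathological" & pred == "pathological"))
  })
  expect_error(confusion("normal", c("normal", "normal")), "length")
  expect_error(confusion("yes", "no"), "labels")
})

test_that("metric identities and degenerate counts behave", {
  n <- 17
  mt <- cls_metrics(tibble::tibble(tp = n, fp = 0, fn = 0, tn = n))
  expect_equal(unlist(mt[, 1:3]),
               c(accuracy = 100, sensitivity = 100, specificity = 100))

  cc <- tibble::tibble(tp = 12, fp = 5, fn = 3, tn = 20)
  mt2 <- cls_metrics(cc)
  total <- 40
  expect_equal(mt2$accuracy * total / 100, cc$tp + cc$tn)
  expect_true(mt2$sensitivity >= 0 && mt2$sensitivity <= 100)
  expect_warning(mt3 <- cls_metrics(tibble::tibble(tp = 0, fp = 0, fn = 0,
                                                   tn = 5)),
                 "sensitivity undefined")
  expect_true(is.na(mt3$sensitivity))
})

test_that("AUC matches trivial cases and the concordance oracle", {
  truth6 <- c("normal", "normal", "normal", "pathological", "pathological",
              "pathological")
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1), truth6), 1.0)
  expect_equal(roc_auc(rep(0.5, 6), truth6), 0.5)

  s6 <- c(0.9, 0.4, 0.6, 0.5, 0.4, 0.2)
  expect_equal(roc_auc(s6, truth6), oracle_auc(s6, truth6))

  withr::with_seed(19, {
    for (rep in 1:10) {
      n <- sample(10:200, 1)
      truth <- sample(c("normal", "pathological"), n, TRUE)
      if (length(unique(truth)) < 2) next
      scores <- round(runif(n), 2)  # coarse grid forces ties
      expect_equal(roc_auc(scores, truth), oracle_auc(scores, truth))
    }
  })
  expect_error(roc_auc(1:3 / 3, rep("normal", 3)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(23, {
    for (rep in 1:5) {
      n <- 80
      truth <- sample(c("normal", "pathological"), n, TRUE)
      scores <- runif(n) + (truth == "normal") * runif(1, 0, 1)
      ours <- roc_auc(scores, truth)
      ref <- as.numeric(pROC::auc(pROC::roc(
        response = truth, predictor = scores, levels = c("pathological",
                                                         "normal"),
        direction = "<", quiet = TRUE)))
      expect_equal(ours, ref, tolerance = 1e-12)
    }
  })
})

test_that("bootstrap AUC interval brackets the point estimate", {
  withr::with_seed(29, {
    truth <- rep(c("normal", "pathological"), each = 40)
    scores <- c(rnorm(40, 1), rnorm(40, 0))
    ci <- roc_auc_ci(scores, truth, n_boot = 200, seed = 5)
    expect_true(ci$lower <= ci$auc && ci$auc <= ci$upper)
    ci2 <- roc_auc_ci(scores, truth, n_boot = 200, seed = 5)
    expect_identical(ci, ci2)
  })
})

test_that("cross-validation reports per-fold and averaged metrics", {
  sep <- separable_images(60, seed = 40)
  ord <- order(sep$labels)  # group images so each record is single-class
  ds <- tibble::tibble(
    image = sep$images[ord], label = sep$labels[ord],
    record_id = rep(sprintf("r%02d", 1:20), each = 3))
  cfg <- train_config(max_epochs = 3, seed = 1)
  rep1 <- cross_validate(ds, folds = 4, arch = cnn_architecture("8"),
                         config = cfg, fold_mode = "record", seed = 77)
  expect_s3_class(rep1, "cv_report")
  expect_equal(nrow(rep1$folds), 4)
  expect_equal(rep1$summary$accuracy, mean(rep1$folds$accuracy))
  expect_equal(rep1$summary$auc, mean(rep1$folds$auc))
  expect_equal(nrow(rep1$predictions), 60)
  # record-level folds never split a record
  split_ok <- tapply(rep1$predictions$fold, rep1$predictions$record_id,
                     function(v) length(unique(v)))
  expect_true(all(split_ok == 1))

  rep2 <- cross_validate(ds, folds = 4, arch = cnn_architecture("8"),
                         config = cfg, fold_mode = "record", seed = 77)
  expect_identical(tidy(rep1), tidy(rep2))

  g <- glance(rep1)
  expect_equal(g$n_folds, 4)
  expect_equal(g$accuracy, rep1$summary$accuracy)
})

test_that("cross-validation reports serialise to JSON deterministically", {
  sep <- separable_images(24, seed = 50)
  ds <- tibble::tibble(image = sep$images, label = sep$labels,
                       record_id = sprintf("r%02d", 1:24))
  cfg <- train_config(max_epochs = 2, seed = 1)
  rep1 <- cross_validate(ds, folds = 3, arch = cnn_architecture("5"),
                         config = cfg, seed = 3)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_cv_report(rep1, p1)
  write_cv_report(rep1, p2)
  expect_identical(readLines(p1), readLines(p2))
  parsed <- jsonlite::read_json(p1)
  expect_length(parsed$folds, 3)
})
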