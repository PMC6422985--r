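test_that("convolution shape arithmetic matches the architecture table", {
  expect_equal(conv_output_size(64, 5, 1, 0), 60L)
  expect_equal(conv_output_size(60, 3, 2, 0), 29L)
  expect_equal(conv_output_size(29, 5, 1, 0), 25L)
  expect_equal(conv_output_size(25, 3, 2, 0), 12L)
  for (n in c(7, 13, 64)) expect_equal(conv_output_size(n, 1, 1, 0), n)
  expect_error(conv_output_size(3, 7, 1, 0), "non-positive")
})

test_that("the default architecture reproduces the published feature maps", {
  arch <- cnn_architecture("8")
  shapes <- arch_shapes(arch)
  kinds <- vapply(arch, `[[`, "", "kind")
  expect_equal(shapes[[1]], c(64, 64, 3))
  expect_equal(shapes[[which(kinds == "conv")[1]]], c(60, 60, 8))
  expect_equal(shapes[[which(kinds == "avgpool")[1]]], c(29, 29, 8))
  expect_equal(shapes[[which(kinds == "conv")[2]]], c(25, 25, 8))
  expect_equal(shapes[[which(kinds == "avgpool")[2]]], c(12, 12, 8))
  expect_equal(shapes[[which(kinds == "fc")[1]]], 144L)
  expect_equal(shapes[[which(kinds == "fc")[2]]], 2L)
  # dropout sits between the two fully connected layers, probability 0.8
  di <- which(kinds == "dropout")
  expect_equal(di, which(kinds == "fc")[1] + 1L)
  expect_equal(arch[[di]]$drop_prob, 0.8)
})

test_that("parameter counts and seeded initialisation are reproducible", {
  arch <- cnn_architecture("8")
  m1 <- build_cnn(arch, seed = 31)
  expect_equal(length(m1$params[[2]]$W) + length(m1$params[[2]]$b),
               5 * 5 * 3 * 8 + 8)  # 608
  m2 <- build_cnn(arch, seed = 31)
  expect_identical(m1$params, m2$params)
  m3 <- build_cnn(arch, seed = 32)
  expect_false(identical(m1$params[[2]]$W, m3$params[[2]]$W))
})

test_that("inconsistent layer chains fail shape validation by layer", {
  bad <- cnn_architecture("I-C-P-C-P-C-P-C-P-F-O")  # feature map shrinks away
  expect_error(arch_shapes(bad), "layer")
  expect_error(build_cnn(bad), "layer")
})

test_that("softmax probabilities are valid for any input batch", {
  m <- build_cnn(cnn_architecture("8"), seed = 1)
  withr::with_seed(2, x <- array(runif(64 * 64 * 3 * 7), c(64, 64, 3, 7)))
  pr <- predict_cnn(m, x)
  expect_equal(nrow(pr), 7)
  expect_equal(pr$p_normal + pr$p_pathological, rep(1, 7), tolerance = 1e-6)
  expect_true(all(pr$.pred_label %in% c("normal", "pathological")))
})

test_that("evaluation mode is deterministic and per-image", {
  sep <- separable_images(24, seed = 4)
  m <- build_cnn(cnn_architecture("8"), seed = 5)
  m <- train_cnn(m, sep$images, sep$labels,
                 config = train_config(max_epochs = 2, seed = 6))
  p1 <- predict_cnn(m, sep$images[1:6])
  p2 <- predict_cnn(m, sep$images[1:6])
  expect_identical(p1, p2)
  # duplicated image gives identical probability rows
  pdup <- predict_cnn(m, sep$images[c(1, 1)])
  expect_equal(pdup$p_normal[1], pdup$p_normal[2])
})

test_that("analytic gradients match numerical differentiation", {
  arch <- cnn_architecture("I-C-P-F-O", input = c(12, 12, 3), n_filters = 2,
                           kernel = 3, pool = 2, pool_stride = 2)
  model <- build_cnn(arch, seed = 5)
  withr::with_seed(2, xs <- array(rnorm(12 * 12 * 3 * 4), c(12, 12, 3, 4)))
  y <- fetalrp:::labels_to_onehot(c("normal", "pathological",
                                    "normal", "pathological"))
  fw <- fetalrp:::cnn_forward(model, xs, training = TRUE)
  gr <- fetalrp:::cnn_backward(model, fw$caches, fw$probs, y)
  loss_at <- function(mod) {
    f <- fetalrp:::cnn_forward(mod, xs, training = TRUE)
    fetalrp:::cnn_loss(mod, f$probs, y, 0)
  }
  withr::with_seed(8, {
    for (li in seq_along(gr)) {
      if (is.null(gr[[li]])) next
      for (nm in names(gr[[li]])) {
        n_par <- length(model$params[[li]][[nm]])
        for (t in sample(seq_len(n_par), min(4, n_par))) {
          eps <- 1e-5
          mp <- model; mp$params[[li]][[nm]][t] <- mp$params[[li]][[nm]][t] + eps
          mm <- model; mm$params[[li]][[nm]][t] <- mm$params[[li]][[nm]][t] - eps
          g_num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
          expect_equal(gr[[li]][[nm]][t], g_num, tolerance = 1e-5)
        }
      }
    }
  })
})

test_that("a gradient step on one sample decreases its loss", {
  arch <- cnn_architecture("I-C-P-F-O", input = c(12, 12, 3), n_filters = 2,
                           kernel = 3, pool = 2, pool_stride = 2)
  y <- fetalrp:::labels_to_onehot("pathological")
  withr::with_seed(3, {
    for (seed in 1:5) {
      model <- build_cnn(arch, seed = seed)
      # give the zero-initialised head a non-trivial starting point
      model$params[[6]]$W[] <- rnorm(length(model$params[[6]]$W), sd = 0.05)
      x1 <- array(rnorm(12 * 12 * 3), c(12, 12, 3, 1))
      fw <- fetalrp:::cnn_forward(model, x1, training = TRUE)
      l0 <- fetalrp:::cnn_loss(model, fw$probs, y, 0)
      gr <- fetalrp:::cnn_backward(model, fw$caches, fw$probs, y)
      for (li in seq_along(gr)) {
        if (is.null(gr[[li]])) next
        for (nm in names(gr[[li]]))
          model$params[[li]][[nm]] <-
            model$params[[li]][[nm]] - 1e-3 * gr[[li]][[nm]]
      }
      fw1 <- fetalrp:::cnn_forward(model, x1, training = TRUE)
      expect_lt(fetalrp:::cnn_loss(model, fw1$probs, y, 0), l0)
    }
  })
})

test_that("training masters a linearly separable image set", {
  sep <- separable_images(200, seed = 10)
  model <- build_cnn(cnn_architecture("8"), seed = 11)
  model <- train_cnn(model, sep$images, sep$labels,
                     config = train_config(seed = 12, val_fraction = 0))
  hist <- tidy(model)
  expect_equal(nrow(hist), 10)
  expect_gte(hist$train_acc[10], 0.95)
  expect_lte(hist$train_loss[10], hist$train_loss[1])
  # the trained model generalises to fresh draws from the same construction
  fresh <- separable_images(40, seed = 13)
  pr <- predict_cnn(model, fresh$images)
  expect_gte(mean(pr$.pred_label == fresh$labels), 0.95)
})

test_that("training is deterministic and rejects single-class sets", {
  sep <- separable_images(30, seed = 20)
  cfg <- train_config(max_epochs = 2, seed = 21)
  m1 <- train_cnn(build_cnn(cnn_architecture("8"), seed = 22),
                  sep$images, sep$labels, config = cfg)
  m2 <- train_cnn(build_cnn(cnn_architecture("8"), seed = 22),
                  sep$images, sep$labels, config = cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(tidy(m1), tidy(m2))

  only_normal <- sep$images[sep$labels == "normal"]
  expect_error(train_cnn(build_cnn(cnn_architecture("8"), seed = 1),
                         only_normal, rep("normal", length(only_normal))),
               "single class")
})

test_that("optimisers other than Adam run and learn", {
  sep <- separable_images(60, seed = 30)
  for (opt in c("sgd", "rmsprop")) {
    m <- build_cnn(cnn_architecture("8"), seed = 31)
    m <- train_cnn(m, sep$images, sep$labels,
                   config = train_config(optimizer = opt, max_epochs = 5,
                                         seed = 32, val_fraction = 0))
    expect_gte(tail(tidy(m)$train_acc, 1), 0.6)
  }
})
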