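#' Output size of a valid convolution or pooling window
#'
#' Standard shape arithmetic: `floor((in_size - kernel + 2 * padding) /
#' stride) + 1`.
#'
#' @param in_size Input spatial size (pixels).
#' @param kernel Square kernel size.
#' @param stride Stride.
#' @param padding Zero padding on each side.
#' @return The output spatial size.
#' @export
#' @examples
#' conv_output_size(64, 5, 1, 0) # 60
#' conv_output_size(60, 3, 2, 0) # 29
conv_output_size <- function(in_size, kernel, stride = 1, padding = 0) {
  in_size <- check_count(in_size, "in_size")
  kernel <- check_count(kernel, "kernel")
  stride <- check_count(stride, "stride")
  padding <- check_count(padding, "padding", lower = 0L)
  out <- floor((in_size - kernel + 2 * padding) / stride) + 1
  if (out < 1) abort("non-positive output size: kernel larger than padded input")
  as.integer(out)
}

layer_spec <- function(kind, ...) c(list(kind = kind), list(...))

#' Convolutional architectures for recurrence-plot classification
#'
#' `cnn_architecture()` builds a layer chain from a compact pattern of main
#' layers: `I` (64 x 64 x 3 image input), `C` (5 x 5 convolution with 8
#' filters, stride 1, no padding, followed by batch normalisation and ReLU),
#' `P` (3 x 3 average pooling, stride 2), `F` (fully connected; intermediate
#' `F`s have 144 units and are separated by dropout 0.8, the final `F` has 2
#' units) and `O` (softmax classification output). The default `"8"` is the
#' 8-main-layer network `I-C-P-C-P-F-F-O` whose feature maps run
#' 64x64x3 -> 60x60x8 -> 29x29x8 -> 25x25x8 -> 12x12x8 -> 144 -> 2; `"5"` is
#' the shallow `I-C-P-F-O` baseline.
#'
#' @param variant `"8"`, `"5"`, or any `I-C-P-...-O` pattern string.
#' @param input Input dimensions `c(height, width, channels)`.
#' @param n_filters,kernel,conv_stride Convolution settings.
#' @param pool,pool_stride Average-pooling settings.
#' @param fc_units Width of intermediate fully connected layers.
#' @param drop_prob Dropout probability between consecutive FC layers.
#' @return A list of layer specs of class `cnn_architecture`.
#' @export
#' @examples
#' arch <- cnn_architecture("8")
#' vapply(arch, `[[`, "", "kind")
cnn_architecture <- function(variant = "8", input = c(64, 64, 3),
                             n_filters = 8, kernel = 5, conv_stride = 1,
                             pool = 3, pool_stride = 2, fc_units = 144,
                             drop_prob = 0.8) {
  pattern <- switch(variant,
                    "8" = "I-C-P-C-P-F-F-O",
                    "5" = "I-C-P-F-O",
                    variant)
  toks <- strsplit(toupper(pattern), "-", fixed = TRUE)[[1]]
  if (toks[1] != "I" || toks[length(toks)] != "O" ||
      !all(toks %in% c("I", "C", "P", "F", "O")))
    abort("pattern must be I-...-O over tokens I, C, P, F, O")
  f_pos <- which(toks == "F")
  if (!length(f_pos)) abort("pattern needs at least one F layer")
  layers <- list(layer_spec("input", size = as.integer(input)))
  for (i in seq_along(toks)[-1]) {
    tk <- toks[i]
    if (tk == "C") {
      layers <- c(layers, list(
        layer_spec("conv", kernel = kernel, n_filters = n_filters,
                   stride = conv_stride, padding = 0L),
        layer_spec("batchnorm"),
        layer_spec("relu")))
    } else if (tk == "P") {
      layers <- c(layers, list(
        layer_spec("avgpool", kernel = pool, stride = pool_stride,
                   padding = 0L)))
    } else if (tk == "F") {
      units <- if (i == max(f_pos)) 2L else as.integer(fc_units)
      layers <- c(layers, list(layer_spec("fc", units = units)))
      if (i < max(f_pos))
        layers <- c(layers, list(layer_spec("dropout", drop_prob = drop_prob)))
    } else if (tk == "O") {
      layers <- c(layers, list(layer_spec("softmax")))
    }
  }
  structure(layers, pattern = pattern, class = "cnn_architecture")
}

#' Propagate feature-map shapes through an architecture
#'
#' @param arch A [cnn_architecture()].
#' @return A list of shapes (c(h, w, c) or a unit count), one per layer;
#'   errors name the first layer whose shapes are inconsistent.
#' @export
arch_shapes <- function(arch) {
  shp <- NULL
  out <- vector("list", length(arch))
  for (i in seq_along(arch)) {
    ly <- arch[[i]]
    shp <- switch(ly$kind,
      input = ly$size,
      conv = {
        if (length(shp) != 3)
          abort(sprintf("layer %d (conv): expected a 3-d feature map", i))
        s <- tryCatch(conv_output_size(shp[1], ly$kernel, ly$stride, ly$padding),
                      error = function(e)
                        abort(sprintf("layer %d (conv): %s", i, conditionMessage(e))))
        c(s, conv_output_size(shp[2], ly$kernel, ly$stride, ly$padding),
          ly$n_filters)
      },
      avgpool = {
        if (length(shp) != 3)
          abort(sprintf("layer %d (avgpool): expected a 3-d feature map", i))
        s <- tryCatch(conv_output_size(shp[1], ly$kernel, ly$stride, ly$padding),
                      error = function(e)
                        abort(sprintf("layer %d (avgpool): %s", i, conditionMessage(e))))
        c(s, conv_output_size(shp[2], ly$kernel, ly$stride, ly$padding), shp[3])
      },
      batchnorm = shp,
      relu = shp,
      fc = ly$units,
      dropout = shp,
      softmax = shp,
      abort(sprintf("layer %d: unknown kind `%s`", i, ly$kind)))
    out[[i]] <- shp
  }
  out
}

#' Training hyperparameters
#'
#' Defaults are the optimised configuration: Adam with learning rate 1e-3,
#' squared-gradient decay 0.6 and epsilon 1e-6, L2 factor 1e-4 on weights,
#' mini-batch 64, 10 epochs. The Adam first-moment decay is not part of that
#' configuration and uses the conventional 0.9; both decays are exposed here.
#'
#' @param learning_rate Step size.
#' @param l2_factor L2 penalty coefficient applied to conv/FC weights.
#' @param batch_size Mini-batch size.
#' @param max_epochs Full passes over the training images.
#' @param optimizer `"adam"`, `"sgd"` or `"rmsprop"`.
#' @param adam_beta1 Adam first-moment decay.
#' @param adam_decay Squared-gradient decay (Adam beta2 / RMSprop rho).
#' @param adam_epsilon Denominator stabiliser.
#' @param sgd_momentum Momentum for SGD.
#' @param val_fraction Fraction of the training images held out for per-epoch
#'   validation when no explicit validation set is given.
#' @param seed Integer seed covering initial shuffling and dropout masks.
#' @param verbose Print per-epoch progress.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, l2_factor = 1e-4,
                         batch_size = 64, max_epochs = 10,
                         optimizer = c("adam", "sgd", "rmsprop"),
                         adam_beta1 = 0.9, adam_decay = 0.6,
                         adam_epsilon = 1e-6, sgd_momentum = 0.8,
                         val_fraction = 0.1, seed = 1L, verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  check_scalar_number(learning_rate, "learning_rate")
  if (learning_rate <= 0) abort("`learning_rate` must be > 0")
  check_count(batch_size, "batch_size")
  check_count(max_epochs, "max_epochs")
  check_scalar_number(l2_factor, "l2_factor", lower = 0)
  structure(list(learning_rate = learning_rate, l2_factor = l2_factor,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), optimizer = optimizer,
                 adam_beta1 = adam_beta1, adam_decay = adam_decay,
                 adam_epsilon = adam_epsilon, sgd_momentum = sgd_momentum,
                 val_fraction = val_fraction, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Build (initialise) a network
#'
#' Seeded scaled-uniform (fan-in) weight initialisation: weights are drawn
#' from U(-sqrt(3/fan_in), sqrt(3/fan_in)) (unit-variance scaling), biases
#' start at zero, batch-norm at identity. Shapes are validated first via
#' [arch_shapes()].
#'
#' @param arch A [cnn_architecture()].
#' @param seed Integer seed for the parameter draw.
#' @return An (untrained) `cnn_model`.
#' @export
build_cnn <- function(arch, seed = 1L) {
  shapes <- arch_shapes(arch)
  params <- withr::with_seed(seed, {
    lapply(seq_along(arch), function(i) {
      ly <- arch[[i]]
      inshp <- if (i > 1) shapes[[i - 1]] else NULL
      if (ly$kind == "conv") {
        cin <- inshp[3]
        fan_in <- ly$kernel^2 * cin
        lim <- sqrt(3 / fan_in)
        list(W = array(runif(ly$kernel^2 * cin * ly$n_filters, -lim, lim),
                       dim = c(ly$kernel, ly$kernel, cin, ly$n_filters)),
             b = numeric(ly$n_filters))
      } else if (ly$kind == "batchnorm") {
        ch <- inshp[3]
        # running stats are zero-debiased at evaluation time (see
        # cnn_forward), so both start at zero
        list(gamma = rep(1, ch), beta = numeric(ch),
             running_mean = numeric(ch), running_var = numeric(ch))
      } else if (ly$kind == "fc") {
        n_in <- prod(inshp)
        # the final (classification) layer starts at zero so that early
        # training is driven by the data, not the random draw
        is_last_fc <- i == max(which(vapply(arch, `[[`, "", "kind") == "fc"))
        lim <- if (is_last_fc) 0 else sqrt(3 / n_in)
        list(W = matrix(runif(ly$units * n_in, -lim, lim), ly$units, n_in),
             b = numeric(ly$units))
      } else NULL
    })
  })
  structure(list(arch = arch, shapes = shapes, params = params,
                 input_mean = NULL, history = NULL, trained = FALSE,
                 seed = as.integer(seed)),
            class = "cnn_model")
}

#' Stack recurrence-plot images into a network input batch
#'
#' Replicates each grayscale image into 3 identical channels (the network's
#' 64 x 64 x 3 input convention) and stacks along the fourth dimension.
#'
#' @param images A list of `rp_image` matrices, or an already-stacked 4-d
#'   array.
#' @return A numeric array of dimension (H, W, 3, N).
#' @export
images_to_batch <- function(images) {
  if (is.array(images) && length(dim(images)) == 4) return(images)
  if (!is.list(images)) abort("`images` must be a list of image matrices")
  h <- nrow(images[[1]]); w <- ncol(images[[1]])
  x <- array(0, dim = c(h, w, 3, length(images)))
  for (i in seq_along(images)) {
    im <- unclass(images[[i]])
    if (!all(dim(im) == c(h, w))) abort("images differ in size")
    x[, , 1, i] <- im; x[, , 2, i] <- im; x[, , 3, i] <- im
  }
  x
}

# Broadcast a per-channel vector over an (H, W, C, N) array.
bcast_ch <- function(v, dims) {
  array(rep(rep(v, each = dims[1] * dims[2]), times = dims[4]), dim = dims)
}

pad_array <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  y <- array(0, dim = c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  y[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , ] <- x
  y
}

# Forward pass. Returns the 2 x N probability matrix and, when `training`,
# the per-layer caches needed by cnn_backward. Dropout masks are drawn from
# the current RNG state.
cnn_forward <- function(model, x, training = FALSE) {
  arch <- model$arch; params <- model$params
  if (isTRUE(model$rate_normalize)) {
    # express intensities relative to each plot's recurrence rate so images
    # built with different neighbour counts k share one scale
    mu_img <- apply(x, 4, mean)
    x <- sweep(x, 4, pmax(mu_img, 1e-8), "/")
  }
  if (!is.null(model$input_mean)) {
    x <- x - c(model$input_mean)
  }
  caches <- vector("list", length(arch))
  for (i in seq_along(arch)) {
    ly <- arch[[i]]; pr <- params[[i]]
    if (ly$kind == "input") {
      d <- dim(x)
      if (!all(d[1:3] == ly$size))
        abort(sprintf("input batch is %s, expected %s",
                      paste(d[1:3], collapse = "x"),
                      paste(ly$size, collapse = "x")))
    } else if (ly$kind == "conv") {
      xp <- pad_array(x, ly$padding)
      caches[[i]] <- list(x = xp)
      x <- cpp_conv_fwd(xp, pr$W, pr$b, ly$stride)
    } else if (ly$kind == "batchnorm") {
      d <- dim(x); ch <- d[3]; eps <- 1e-5
      if (training) {
        m <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = ch)
        mu <- colMeans(m)
        v <- colMeans(m * m) - mu^2
        model$params[[i]]$running_mean <-
          0.9 * pr$running_mean + 0.1 * mu
        model$params[[i]]$running_var <-
          0.9 * pr$running_var + 0.1 * v
      } else {
        t_bn <- model$bn_t %||% 0L
        if (t_bn > 0L) {
          # zero-debiased exponential averages (running stats start at 0)
          corr <- 1 - 0.9^t_bn
          mu <- pr$running_mean / corr
          v <- pr$running_var / corr
        } else {
          mu <- numeric(ch); v <- rep(1, ch)
        }
      }
      invstd <- 1 / sqrt(v + eps)
      xhat <- (x - bcast_ch(mu, d)) * bcast_ch(invstd, d)
      caches[[i]] <- list(xhat = xhat, invstd = invstd)
      x <- xhat * bcast_ch(pr$gamma, d) + bcast_ch(pr$beta, d)
    } else if (ly$kind == "relu") {
      mask <- x > 0
      caches[[i]] <- list(mask = mask)
      x <- x * mask
    } else if (ly$kind == "avgpool") {
      caches[[i]] <- list(insize = dim(x))
      x <- cpp_pool_avg_fwd(x, ly$kernel, ly$stride)
    } else if (ly$kind == "fc") {
      if (is.array(x) && length(dim(x)) == 4) {
        n <- dim(x)[4]
        caches[[i]] <- list(inshape = dim(x))
        x <- matrix(x, ncol = n)
      } else caches[[i]] <- list(inshape = NULL)
      caches[[i]]$x <- x
      x <- pr$W %*% x + pr$b
    } else if (ly$kind == "dropout") {
      if (training && ly$drop_prob > 0) {
        keep <- 1 - ly$drop_prob
        mask <- (matrix(runif(length(x)), nrow(x)) >= ly$drop_prob) / keep
        caches[[i]] <- list(mask = mask)
        x <- x * mask
      }
    } else if (ly$kind == "softmax") {
      x <- sweep(x, 2, apply(x, 2, max))
      e <- exp(x)
      x <- sweep(e, 2, colSums(e), "/")
    }
  }
  list(probs = x, caches = caches, model = model)
}

# Backward pass from the softmax/cross-entropy gradient. `y` is the 2 x N
# one-hot target matrix. Returns per-layer gradients matching model$params.
cnn_backward <- function(model, caches, probs, y) {
  arch <- model$arch; params <- model$params
  n <- ncol(probs)
  grads <- vector("list", length(arch))
  g <- (probs - y) / n  # d(loss)/d(fc2 output), softmax+CE combined
  for (i in rev(seq_along(arch))) {
    ly <- arch[[i]]; pr <- params[[i]]; ca <- caches[[i]]
    if (ly$kind == "softmax" || ly$kind == "input") {
      next
    } else if (ly$kind == "fc") {
      grads[[i]] <- list(W = g %*% t(ca$x), b = rowSums(g))
      g <- t(pr$W) %*% g
      if (!is.null(ca$inshape)) g <- array(g, dim = ca$inshape)
    } else if (ly$kind == "dropout") {
      if (!is.null(ca$mask)) g <- g * ca$mask
    } else if (ly$kind == "avgpool") {
      g <- cpp_pool_avg_bwd(g, ca$insize[1], ca$insize[2], ly$kernel,
                            ly$stride)
    } else if (ly$kind == "relu") {
      g <- g * ca$mask
    } else if (ly$kind == "batchnorm") {
      d <- dim(g); ch <- d[3]; m_count <- d[1] * d[2] * d[4]
      to_ch <- function(a) colSums(matrix(aperm(a, c(1, 2, 4, 3)), ncol = ch))
      dgamma <- to_ch(g * ca$xhat)
      dbeta <- to_ch(g)
      dxhat <- g * bcast_ch(pr$gamma, d)
      s1 <- to_ch(dxhat); s2 <- to_ch(dxhat * ca$xhat)
      g <- (dxhat - bcast_ch(s1 / m_count, d) -
              ca$xhat * bcast_ch(s2 / m_count, d)) *
        bcast_ch(ca$invstd, d)
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
    } else if (ly$kind == "conv") {
      bw <- cpp_conv_bwd(ca$x, pr$W, g, ly$stride)
      grads[[i]] <- list(W = bw$dw, b = bw$db)
      g <- bw$dx
      if (ly$padding > 0) {
        p <- ly$padding; d <- dim(g)
        g <- g[(p + 1):(d[1] - p), (p + 1):(d[2] - p), , , drop = FALSE]
      }
    }
  }
  grads
}

# Cross-entropy (mean over batch) + L2 penalty on conv/FC weights.
cnn_loss <- function(model, probs, y, l2_factor) {
  ce <- -mean(colSums(y * log(pmax(probs, 1e-12))))
  if (l2_factor > 0) {
    w2 <- sum(vapply(seq_along(model$arch), function(i) {
      if (model$arch[[i]]$kind %in% c("conv", "fc"))
        sum(model$params[[i]]$W^2) else 0
    }, numeric(1)))
    ce <- ce + l2_factor / 2 * w2
  }
  ce
}

labels_to_onehot <- function(labels) {
  lv <- c("normal", "pathological")
  if (!all(labels %in% lv))
    abort("labels must be \"normal\" or \"pathological\"")
  y <- matrix(0, 2, length(labels))
  y[cbind(match(labels, lv), seq_along(labels))] <- 1
  y
}

# One optimiser step; state carries per-parameter moments.
optim_step <- function(params, grads, state, cfg, t) {
  for (i in seq_along(params)) {
    if (is.null(grads[[i]])) next
    for (nm in names(grads[[i]])) {
      gr <- grads[[i]][[nm]]
      if (cfg$l2_factor > 0 && nm == "W") gr <- gr + cfg$l2_factor * params[[i]][[nm]]
      key <- paste0(i, ".", nm)
      if (cfg$optimizer == "adam") {
        st <- state[[key]] %||% list(m = gr * 0, v = gr * 0)
        st$m <- cfg$adam_beta1 * st$m + (1 - cfg$adam_beta1) * gr
        st$v <- cfg$adam_decay * st$v + (1 - cfg$adam_decay) * gr^2
        mhat <- st$m / (1 - cfg$adam_beta1^t)
        vhat <- st$v / (1 - cfg$adam_decay^t)
        params[[i]][[nm]] <- params[[i]][[nm]] -
          cfg$learning_rate * mhat / (sqrt(vhat) + cfg$adam_epsilon)
        state[[key]] <- st
      } else if (cfg$optimizer == "rmsprop") {
        st <- state[[key]] %||% list(v = gr * 0)
        st$v <- cfg$adam_decay * st$v + (1 - cfg$adam_decay) * gr^2
        params[[i]][[nm]] <- params[[i]][[nm]] -
          cfg$learning_rate * gr / (sqrt(st$v) + cfg$adam_epsilon)
        state[[key]] <- st
      } else {
        st <- state[[key]] %||% list(m = gr * 0)
        st$m <- cfg$sgd_momentum * st$m + gr
        params[[i]][[nm]] <- params[[i]][[nm]] - cfg$learning_rate * st$m
        state[[key]] <- st
      }
    }
  }
  list(params = params, state = state)
}

#' Train a network
#'
#' Mini-batch stochastic optimisation of the softmax cross-entropy with an L2
#' weight penalty. Dropout and batch-statistics normalisation are active only
#' during training; running batch-norm averages (momentum 0.1) are used at
#' evaluation. Fully deterministic for a fixed `config$seed` (single
#' threaded).
#'
#' @param model An untrained [build_cnn()] model.
#' @param images Training images (list of `rp_image` or (H, W, 3, N) array).
#' @param labels Per-image class labels (`"normal"`/`"pathological"`).
#' @param val_images,val_labels Optional explicit validation set; when
#'   omitted, `val_fraction` of the training images is held out (stratified).
#' @param config A [train_config()].
#' @return The trained `cnn_model`, with a `history` tibble of per-epoch
#'   training/validation loss and accuracy.
#' @export
train_cnn <- function(model, images, labels, val_images = NULL,
                      val_labels = NULL, config = train_config()) {
  stopifnot(inherits(model, "cnn_model"))
  x <- images_to_batch(images)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    abort("training set contains a single class")
  if (dim(x)[4] != length(labels)) abort("images/labels length mismatch")

  withr::with_seed(config$seed, {
    if (is.null(val_images) && config$val_fraction > 0) {
      idx_val <- unlist(lapply(unique(labels), function(cls) {
        idx <- which(labels == cls)
        sample(idx, max(1L, round(config$val_fraction * length(idx))))
      }))
      # never let monitoring starve the optimiser: keep at least one
      # training example of each class
      keep <- setdiff(seq_along(labels), idx_val)
      if (length(keep) >= 2 && length(unique(labels[keep])) == 2) {
        val_images <- x[, , , idx_val, drop = FALSE]
        val_labels <- labels[idx_val]
        x <- x[, , , keep, drop = FALSE]
        labels <- labels[keep]
      }
    } else if (!is.null(val_images)) {
      val_images <- images_to_batch(val_images)
    }
    y <- labels_to_onehot(labels)
    n <- dim(x)[4]
    # recurrence-rate scaling (set before the mean is computed) followed by
    # zero-centre normalisation over the training images
    model$rate_normalize <- TRUE
    mu_img <- apply(x, 4, mean)
    xn <- sweep(x, 4, pmax(mu_img, 1e-8), "/")
    model$input_mean <- apply(xn, c(1, 2, 3), mean)
    rm(xn)
    state <- list()
    t_step <- 0L
    hist <- vector("list", config$max_epochs)
    for (ep in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (b0 in seq(1L, n, by = config$batch_size)) {
        bi <- ord[b0:min(n, b0 + config$batch_size - 1L)]
        xb <- x[, , , bi, drop = FALSE]; yb <- y[, bi, drop = FALSE]
        fw <- cnn_forward(model, xb, training = TRUE)
        model <- fw$model  # refreshed batch-norm running stats
        model$bn_t <- (model$bn_t %||% 0L) + 1L
        loss <- cnn_loss(model, fw$probs, yb, config$l2_factor)
        grads <- cnn_backward(model, fw$caches, fw$probs, yb)
        t_step <- t_step + 1L
        up <- optim_step(model$params, grads, state, config, t_step)
        model$params <- up$params; state <- up$state
        ep_loss <- ep_loss + loss * length(bi)
        ep_correct <- ep_correct +
          sum((apply(fw$probs, 2, which.max) == 1) == (yb[1, ] == 1))
      }
      row <- tibble(epoch = ep, train_loss = ep_loss / n,
                    train_acc = ep_correct / n,
                    val_loss = NA_real_, val_acc = NA_real_)
      if (!is.null(val_images)) {
        vf <- cnn_forward(model, val_images, training = FALSE)
        yv <- labels_to_onehot(val_labels)
        row$val_loss <- cnn_loss(model, vf$probs, yv, config$l2_factor)
        row$val_acc <- mean((apply(vf$probs, 2, which.max) == 1) ==
                              (val_labels == "normal"))
      }
      if (config$verbose)
        message(sprintf("epoch %2d  loss %.4f  acc %.3f  val_acc %s", ep,
                        row$train_loss, row$train_acc,
                        ifelse(is.na(row$val_acc), "-",
                               sprintf("%.3f", row$val_acc))))
      hist[[ep]] <- row
    }
    model$history <- dplyr::bind_rows(hist)
    model$config <- config
    model$trained <- TRUE
    model
  })
}

#' Classify images with a trained network
#'
#' Evaluation mode is deterministic: dropout is disabled and batch
#' normalisation uses running averages. Probability ties go to the normal
#' class.
#'
#' @param model A trained `cnn_model`.
#' @param images List of `rp_image` or (H, W, 3, N) array.
#' @return A tibble with `p_normal`, `p_pathological` and `.pred_label`.
#' @export
predict_cnn <- function(model, images) {
  stopifnot(inherits(model, "cnn_model"))
  x <- images_to_batch(images)
  probs <- cnn_forward(model, x, training = FALSE)$probs
  tibble(p_normal = probs[1, ], p_pathological = probs[2, ],
         .pred_label = ifelse(probs[2, ] > probs[1, ],
                              "pathological", "normal"))
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> %s (%d layers)%s\n",
              attr(x$arch, "pattern") %||% "custom", length(x$arch),
              if (x$trained) ", trained" else ", untrained"))
  invisible(x)
}

#' Tidiers for trained networks
#'
#' `tidy()` returns the per-epoch training history; `glance()` a one-row
#' model summary.
#'
#' @param x A `cnn_model`.
#' @param ... Unused.
#' @return A tibble.
#' @name cnn_model-tidiers
NULL

#' @rdname cnn_model-tidiers
#' @method tidy cnn_model
#' @export
tidy.cnn_model <- function(x, ...) {
  if (is.null(x$history)) abort("model has no training history yet")
  x$history
}

#' @rdname cnn_model-tidiers
#' @method glance cnn_model
#' @export
glance.cnn_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, function(p)
    if (is.null(p)) 0 else sum(lengths(lapply(p, c))), numeric(1)))
  tibble(pattern = attr(x$arch, "pattern") %||% "custom",
         n_layers = length(x$arch), n_parameters = n_par,
         trained = x$trained,
         final_train_acc = if (is.null(x$history)) NA_real_
                           else tail(x$history$train_acc, 1))
}
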