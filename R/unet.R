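# Multi-label 2D U-Net: encoder-decoder with skip connections, zero-padded
# convolutions, batch normalization, PReLU activations, decoder dropout and
# per-channel sigmoid heads. The three output channels (glottis ROI, vocal
# cords, aspiration) are independent because the classes overlap.

#' Network configuration
#'
#' @param base_filters Filters in the first convolutional layer; doubled at
#'   each deeper encoder level.
#' @param depth Number of encoder levels (including the bottleneck); the
#'   deepest stage has `base_filters * 2^(depth - 1)` filters and input
#'   spatial sizes must be divisible by `2^(depth - 1)`.
#' @param dropout_rate Dropout rate applied after each decoder block.
#' @param n_classes Output channels (fixed pipeline order: glottis ROI,
#'   vocal cords, aspiration).
#' @return A `fees_net_config` list.
#' @export
unet_config <- function(base_filters = 32L, depth = 4L, dropout_rate = 0.1,
                        n_classes = 3L) {
  if (base_filters < 1L) abort("`base_filters` must be >= 1.", class = "feesxai_config_error")
  if (depth < 2L) abort("`depth` must be >= 2.", class = "feesxai_config_error")
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort("`dropout_rate` must be in [0, 1).", class = "feesxai_config_error")
  }
  structure(list(base_filters = as.integer(base_filters), depth = as.integer(depth),
                 dropout_rate = dropout_rate, n_classes = as.integer(n_classes)),
            class = "fees_net_config")
}

#' Training configuration
#'
#' Defaults follow the reference recipe: Adam at learning rate 1e-4, batch
#' size 16, validation every 500 iterations, early stopping after 15
#' validations without a mean-Jaccard improvement.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Patches per iteration.
#' @param val_interval Iterations between validation passes.
#' @param patience Validation steps without improvement before stopping.
#' @param max_iterations Safety cap on training iterations.
#' @param seed Seed for sampling, augmentation, dropout and initialization.
#' @return A `fees_train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 16L,
                         val_interval = 500L, patience = 15L,
                         max_iterations = 100000L, seed = NULL) {
  vals <- c(learning_rate, batch_size, val_interval, patience, max_iterations)
  if (any(vals <= 0)) {
    abort("All training-configuration values must be positive.",
          class = "feesxai_config_error")
  }
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 val_interval = as.integer(val_interval),
                 patience = as.integer(patience),
                 max_iterations = as.integer(max_iterations), seed = seed),
            class = "fees_train_config")
}

# filters at encoder level l (1-based)
level_filters <- function(config, l) config$base_filters * 2L^(l - 1L)

conv_init <- function(k, cin, cout) {
  # He initialization for the (k*k*cin) x cout kernel matrix
  matrix(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))), k * k * cin, cout)
}

block_param_names <- function(prefix) {
  as.vector(outer(paste0(prefix, c("_conv1", "_bn1", "_prelu1", "_conv2", "_bn2", "_prelu2")),
                  "", paste0))
}

init_block <- function(params, buffers, prefix, cin, cout) {
  params[[paste0(prefix, "_conv1_W")]] <- conv_init(3, cin, cout)
  params[[paste0(prefix, "_conv1_b")]] <- numeric(cout)
  params[[paste0(prefix, "_bn1_gamma")]] <- rep(1, cout)
  params[[paste0(prefix, "_bn1_beta")]] <- numeric(cout)
  params[[paste0(prefix, "_prelu1_alpha")]] <- rep(0.25, cout)
  params[[paste0(prefix, "_conv2_W")]] <- conv_init(3, cout, cout)
  params[[paste0(prefix, "_conv2_b")]] <- numeric(cout)
  params[[paste0(prefix, "_bn2_gamma")]] <- rep(1, cout)
  params[[paste0(prefix, "_bn2_beta")]] <- numeric(cout)
  params[[paste0(prefix, "_prelu2_alpha")]] <- rep(0.25, cout)
  buffers[[paste0(prefix, "_bn1_mean")]] <- numeric(cout)
  buffers[[paste0(prefix, "_bn1_var")]] <- rep(1, cout)
  buffers[[paste0(prefix, "_bn2_mean")]] <- numeric(cout)
  buffers[[paste0(prefix, "_bn2_var")]] <- rep(1, cout)
  list(params = params, buffers = buffers)
}

#' Build a U-Net model
#'
#' @param config A [unet_config()].
#' @param input_channels Channels of the input image (3 for RGB frames).
#' @param seed Seed for the weight initialization.
#' @return A `fees_unet` object (mutable environment holding parameters,
#'   batch-norm buffers and the configuration).
#' @export
build_unet <- function(config = unet_config(), input_channels = 3L, seed = NULL) {
  stopifnot(inherits(config, "fees_net_config"))
  params <- list(); buffers <- list()
  with_seed(seed, {
    cin <- input_channels
    for (l in seq_len(config$depth - 1L)) {
      st <- init_block(params, buffers, paste0("enc", l), cin, level_filters(config, l))
      params <- st$params; buffers <- st$buffers
      cin <- level_filters(config, l)
    }
    st <- init_block(params, buffers, "bott", cin, level_filters(config, config$depth))
    params <- st$params; buffers <- st$buffers
    for (l in rev(seq_len(config$depth - 1L))) {
      cprev <- if (l == config$depth - 1L) level_filters(config, config$depth)
               else level_filters(config, l + 1L)
      st <- init_block(params, buffers, paste0("dec", l),
                       cprev + level_filters(config, l), level_filters(config, l))
      params <- st$params; buffers <- st$buffers
    }
    params$head_W <- conv_init(1, config$base_filters, config$n_classes)
    params$head_b <- numeric(config$n_classes)
  })
  net <- new.env(parent = emptyenv())
  net$config <- config
  net$input_channels <- as.integer(input_channels)
  net$params <- params
  net$buffers <- buffers
  class(net) <- "fees_unet"
  net
}

#' @export
print.fees_unet <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<fees_unet> base_filters=%d depth=%d classes=%d  %s parameters\n",
              x$config$base_filters, x$config$depth, x$config$n_classes,
              format(np, big.mark = ",")))
  invisible(x)
}

block_forward <- function(net, prefix, x, training) {
  p <- net$params; b <- net$buffers
  c1 <- conv_forward(x, p[[paste0(prefix, "_conv1_W")]], p[[paste0(prefix, "_conv1_b")]], 3L)
  n1 <- bn_forward(c1$y, p[[paste0(prefix, "_bn1_gamma")]], p[[paste0(prefix, "_bn1_beta")]],
                   b[[paste0(prefix, "_bn1_mean")]], b[[paste0(prefix, "_bn1_var")]], training)
  if (training) {
    net$buffers[[paste0(prefix, "_bn1_mean")]] <- n1$rmean
    net$buffers[[paste0(prefix, "_bn1_var")]] <- n1$rvar
  }
  r1 <- prelu_forward(n1$y, p[[paste0(prefix, "_prelu1_alpha")]])
  c2 <- conv_forward(r1$y, p[[paste0(prefix, "_conv2_W")]], p[[paste0(prefix, "_conv2_b")]], 3L)
  n2 <- bn_forward(c2$y, p[[paste0(prefix, "_bn2_gamma")]], p[[paste0(prefix, "_bn2_beta")]],
                   b[[paste0(prefix, "_bn2_mean")]], b[[paste0(prefix, "_bn2_var")]], training)
  if (training) {
    net$buffers[[paste0(prefix, "_bn2_mean")]] <- n2$rmean
    net$buffers[[paste0(prefix, "_bn2_var")]] <- n2$rvar
  }
  r2 <- prelu_forward(n2$y, p[[paste0(prefix, "_prelu2_alpha")]])
  list(y = r2$y, cache = list(c1 = c1$cache, n1 = n1$cache, r1 = r1$cache,
                              c2 = c2$cache, n2 = n2$cache, r2 = r2$cache))
}

block_backward <- function(net, prefix, dy, cache, grads) {
  p <- net$params
  g2 <- prelu_backward(dy, cache$r2)
  grads[[paste0(prefix, "_prelu2_alpha")]] <- g2$dalpha
  gb2 <- bn_backward(g2$dx, cache$n2)
  grads[[paste0(prefix, "_bn2_gamma")]] <- gb2$dgamma
  grads[[paste0(prefix, "_bn2_beta")]] <- gb2$dbeta
  gc2 <- conv_backward(gb2$dx, p[[paste0(prefix, "_conv2_W")]], cache$c2)
  grads[[paste0(prefix, "_conv2_W")]] <- gc2$dW
  grads[[paste0(prefix, "_conv2_b")]] <- gc2$db
  g1 <- prelu_backward(gc2$dx, cache$r1)
  grads[[paste0(prefix, "_prelu1_alpha")]] <- g1$dalpha
  gb1 <- bn_backward(g1$dx, cache$n1)
  grads[[paste0(prefix, "_bn1_gamma")]] <- gb1$dgamma
  grads[[paste0(prefix, "_bn1_beta")]] <- gb1$dbeta
  gc1 <- conv_backward(gb1$dx, p[[paste0(prefix, "_conv1_W")]], cache$c1)
  grads[[paste0(prefix, "_conv1_W")]] <- gc1$dW
  grads[[paste0(prefix, "_conv1_b")]] <- gc1$db
  list(dx = gc1$dx, grads = grads)
}

check_input_size <- function(net, h, w) {
  f <- 2L^(net$config$depth - 1L)
  if (h %% f != 0L || w %% f != 0L) {
    abort(sprintf("Input spatial size %dx%d must be divisible by %d (pad first).",
                  h, w, f), class = "feesxai_size_error")
  }
}

# Full forward pass on a (H, W, C, N) batch. Returns sigmoid probabilities and
# (when caching) everything needed for the backward pass.
unet_forward <- function(net, x, training = FALSE, keep_cache = training) {
  d <- dim(x)
  check_input_size(net, d[1], d[2])
  L <- net$config$depth
  skips <- vector("list", L - 1L)
  caches <- list(enc = vector("list", L - 1L), pool = vector("list", L - 1L),
                 dec = vector("list", L - 1L), drop = vector("list", L - 1L),
                 concat_c1 = integer(L - 1L))
  h <- x
  for (l in seq_len(L - 1L)) {
    bl <- block_forward(net, paste0("enc", l), h, training)
    skips[[l]] <- bl$y
    caches$enc[[l]] <- bl$cache
    mp <- maxpool_forward(bl$y)
    caches$pool[[l]] <- mp$cache
    h <- mp$y
  }
  bl <- block_forward(net, "bott", h, training)
  caches$bott <- bl$cache
  h <- bl$y
  for (l in rev(seq_len(L - 1L))) {
    up <- upsample_forward(h)
    caches$concat_c1[l] <- dim(up)[3]
    h <- concat_channels(up, skips[[l]])
    bl <- block_forward(net, paste0("dec", l), h, training)
    caches$dec[[l]] <- bl$cache
    dr <- dropout_forward(bl$y, net$config$dropout_rate, training)
    caches$drop[l] <- list(dr$cache)
    h <- dr$y
  }
  hc <- conv_forward(h, net$params$head_W, net$params$head_b, 1L)
  caches$head <- hc$cache
  p <- sigmoid(hc$y)
  list(p = p, cache = if (keep_cache) c(caches, list(p = p)) else NULL)
}

# Backward pass from dL/d(logits) = dp * p * (1 - p) already folded in by the
# caller (dlogits). Returns the flat gradient list.
unet_backward <- function(net, cache, dlogits) {
  grads <- list()
  L <- net$config$depth
  gh <- conv_backward(dlogits, net$params$head_W, cache$head)
  grads$head_W <- gh$dW
  grads$head_b <- gh$db
  dy <- gh$dx
  for (l in seq_len(L - 1L)) {
    dy <- dropout_backward(dy, cache$drop[[l]])
    bb <- block_backward(net, paste0("dec", l), dy, cache$dec[[l]], grads)
    grads <- bb$grads
    sp <- split_channels(bb$dx, cache$concat_c1[l])
    dskip <- sp$b
    dy <- upsample_backward(sp$a)
    if (l == L - 1L) {
      bb <- block_backward(net, "bott", dy, cache$bott, grads)
      grads <- bb$grads
      dy <- bb$dx
    }
    # gradient flowing into the encoder side of this level
    attr(dskip, "level") <- l
    grads[[paste0(".skip", l)]] <- dskip
  }
  # encoder backward, deepest first
  for (l in rev(seq_len(L - 1L))) {
    if (l < L - 1L) {
      # dy currently holds gradient w.r.t. pooled output of level l
    }
    dpool <- maxpool_backward(dy, cache$pool[[l]])
    dsum <- dpool + grads[[paste0(".skip", l)]]
    grads[[paste0(".skip", l)]] <- NULL
    bb <- block_backward(net, paste0("enc", l), dsum, cache$enc[[l]], grads)
    grads <- bb$grads
    dy <- bb$dx
  }
  grads
}

#' Soft Dice loss
#'
#' `1 - mean over channels of (2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)`.
#' With `epsilon = 0` a channel that is empty in both prediction and target
#' scores a Dice of 1.
#'
#' @param pred Numeric array of probabilities (H x W, or H x W x C).
#' @param target Binary array of the same shape.
#' @param epsilon Smoothing constant (1 during training; 0 reproduces the
#'   exact evaluation formula).
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred, target, epsilon = 1) {
  target <- target * 1
  if (!identical(dim(pred), dim(target))) {
    abort("`pred` and `target` must share a shape.", class = "feesxai_validation_error")
  }
  if (is.matrix(pred)) { dim(pred) <- c(dim(pred), 1L); dim(target) <- dim(pred) }
  C <- dim(pred)[3]
  d <- numeric(C)
  for (c in seq_len(C)) {
    p <- pred[, , c]; t <- target[, , c]
    num <- 2 * sum(p * t) + epsilon
    den <- sum(p) + sum(t) + epsilon
    d[c] <- if (den == 0) 1 else num / den
  }
  1 - mean(d)
}

# Soft-Dice loss and gradient w.r.t. probabilities for a (H, W, C, N) batch,
# channels pooled over the batch.
dice_loss_grad <- function(p, t, epsilon = 1) {
  d <- dim(p)
  C <- d[3]
  dp <- array(0, d)
  dvals <- numeric(C)
  for (c in seq_len(C)) {
    pc <- p[, , c, , drop = FALSE]; tc <- t[, , c, , drop = FALSE]
    num <- 2 * sum(pc * tc) + epsilon
    den <- sum(pc) + sum(tc) + epsilon
    dvals[c] <- num / den
    dp[, , c, ] <- -(2 * tc * den - num) / den^2 / C
  }
  list(loss = 1 - mean(dvals), dp = dp)
}

#' Trace the early-stopping rule over a validation-score sequence
#'
#' Strict-improvement rule: the best state is the first validation attaining
#' the maximum score seen; training stops once `patience` consecutive
#' validations pass without a strict improvement.
#'
#' @param scores Numeric vector of validation scores in evaluation order.
#' @param patience Allowed number of consecutive non-improving validations.
#' @return List with `best_index` (1-based validation attaining the retained
#'   state), `stop_index` (validation at which training stops, `NA` if the
#'   sequence ends first) and `stopped`.
#' @export
early_stopping_trace <- function(scores, patience = 15L) {
  best <- -Inf; best_index <- NA_integer_; since <- 0L
  stop_index <- NA_integer_
  for (i in seq_along(scores)) {
    if (scores[i] > best) {
      best <- scores[i]; best_index <- i; since <- 0L
    } else {
      since <- since + 1L
      if (since >= patience) { stop_index <- i; break }
    }
  }
  list(best_index = best_index, stop_index = stop_index,
       stopped = !is.na(stop_index))
}

# Pad an (H, W, C) array to spatial multiples of f by edge replication.
pad_to_multiple <- function(x, f) {
  d <- dim(x)
  ph <- (f - d[1] %% f) %% f
  pw <- (f - d[2] %% f) %% f
  if (ph > 0) x <- x[c(seq_len(d[1]), rep(d[1], ph)), , , drop = FALSE]
  if (pw > 0) x <- x[, c(seq_len(d[2]), rep(d[2], pw)), , drop = FALSE]
  x
}

#' Predict per-class probability maps for one frame
#'
#' The frame (already downscaled to working resolution) is padded to the
#' network's size contract, passed through the network in evaluation mode
#' (dropout off, batch-norm running statistics) and cropped back.
#'
#' @param model A trained `fees_unet`, or a plain function
#'   `frame -> probability array` (useful for testing pipelines).
#' @param frame A [fees_frame()] or an H x W x 3 array (0..255 or 0..1).
#' @return A `fees_probmaps`: H x W x 3 array in `[0, 1]`, third dimension
#'   named glottis_roi / vocal_cords / aspiration.
#' @export
predict_frame <- function(model, frame) {
  UseMethod("predict_frame")
}

#' @export
predict_frame.function <- function(model, frame) {
  as_probmaps(model(frame))
}

#' @export
predict_frame.fees_unet <- function(model, frame) {
  px <- if (inherits(frame, "fees_frame")) frame$pixels else frame
  if (max(px) > 1.5) px <- px / 255
  d0 <- dim(px)
  f <- 2L^(model$config$depth - 1L)
  px <- pad_to_multiple(px, f)
  x <- array(px, c(dim(px), 1L))
  p <- unet_forward(model, x, training = FALSE)$p
  maps <- p[seq_len(d0[1]), seq_len(d0[2]), , 1L]
  as_probmaps(maps)
}

as_probmaps <- function(maps) {
  if (length(dim(maps)) != 3L) {
    abort("Probability maps must be an H x W x C array.",
          class = "feesxai_validation_error")
  }
  dimnames(maps) <- list(NULL, NULL, frame_classes[seq_len(dim(maps)[3])])
  structure(maps, class = "fees_probmaps")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Per-class Jaccard of binarized predictions against references over a set of
# frames: per frame pooled pixels, frames where both are empty are skipped for
# that class; frame scores averaged.
validation_jaccard <- function(model, frames, annotations, threshold = 0.5) {
  acc <- matrix(NA_real_, length(frames), 3L)
  for (i in seq_along(frames)) {
    maps <- predict_frame(model, frames[[i]])
    ann <- annotations[[i]]
    for (c in 1:3) {
      pred <- maps[, , c] >= threshold
      ref <- ann[[frame_classes[c]]]
      if (!any(pred) && !any(ref)) next
      acc[i, c] <- jaccard(pred, ref)
    }
  }
  colMeans(acc, na.rm = TRUE)
}

#' Train a U-Net with stratified sampling and Jaccard early stopping
#'
#' Optimizes the soft Dice loss with Adam on stratified patches. Every
#' `val_interval` iterations the model is evaluated on all validation frames
#' (binarized at 0.5): per-class Jaccard scores are averaged into a mean
#' Jaccard, the state with the highest mean Jaccard is retained, and training
#' stops after `patience` validations without improvement (or at
#' `max_iterations`).
#'
#' @param model A `fees_unet` from [build_unet()] (updated in place; the
#'   returned model carries the best validation state).
#' @param dataset A `fees_dataset` (frames + annotations).
#' @param train_ids,val_ids 1-based positions of training / validation frames
#'   within `dataset`.
#' @param scfg A [sampler_config()]; its `patch_size` must satisfy the
#'   network's size contract.
#' @param tcfg A [train_config()].
#' @param augment Apply online augmentation to sampled patches.
#' @param downscale Sample patches at half resolution (the standard pipeline).
#' @param verbose Print validation progress.
#' @return List with `model` (best state) and `history`
#'   (`fees_train_history`).
#' @export
train_unet <- function(model, dataset, train_ids, val_ids,
                       scfg = sampler_config(), tcfg = train_config(),
                       augment = TRUE, downscale = TRUE, verbose = FALSE) {
  stopifnot(inherits(model, "fees_unet"))
  if (length(train_ids) == 0L || length(val_ids) == 0L) {
    abort("Training and validation splits must be non-empty.",
          class = "feesxai_config_error")
  }
  val_frames <- dataset$frames[val_ids]
  val_anns <- dataset$annotations[val_ids]
  if (downscale) {
    val_frames <- lapply(val_frames, downscale_frame)
    val_anns <- lapply(val_anns, downscale_annotation)
  }
  loss_hist <- numeric(0)
  val_hist <- list()
  best <- list(score = -Inf, iteration = NA_integer_, params = NULL, buffers = NULL)
  since_best <- 0L
  adam <- adam_init(model$params)

  with_seed(tcfg$seed, {
    it <- 0L
    repeat {
      it <- it + 1L
      xs <- array(0, c(scfg$patch_size[1], scfg$patch_size[2], 3L, tcfg$batch_size))
      ts <- xs
      for (b in seq_len(tcfg$batch_size)) {
        patch <- sample_patch(dataset, scfg, frame_ids = train_ids,
                              downscale = downscale)
        if (augment) patch <- augment_patch(patch)
        xs[, , , b] <- patch$image
        ts[, , , b] <- patch$target
      }
      fw <- unet_forward(model, xs, training = TRUE)
      lg <- dice_loss_grad(fw$p, ts, epsilon = 1)
      if (!is.finite(lg$loss)) {
        abort(sprintf("Training diverged at iteration %d (non-finite loss).", it),
              class = "feesxai_divergence_error")
      }
      loss_hist[it] <- lg$loss
      dz <- lg$dp * fw$p * (1 - fw$p)
      grads <- unet_backward(model, fw$cache, dz)
      upd <- adam_step(model$params, grads, adam, tcfg$learning_rate)
      model$params <- upd$params
      adam <- upd$state

      if (it %% tcfg$val_interval == 0L) {
        jac <- validation_jaccard(model, val_frames, val_anns)
        mean_j <- mean(jac, na.rm = TRUE)
        val_hist[[length(val_hist) + 1L]] <- tibble(
          iteration = it, jaccard_glottis = jac[1], jaccard_vocal_cords = jac[2],
          jaccard_aspiration = jac[3], mean_jaccard = mean_j)
        if (verbose) {
          message(sprintf("iter %d  loss %.4f  mean Jaccard %.4f", it,
                          lg$loss, mean_j))
        }
        if (is.finite(mean_j) && mean_j > best$score) {
          best$score <- mean_j
          best$iteration <- it
          best$params <- model$params
          best$buffers <- model$buffers
          since_best <- 0L
        } else {
          since_best <- since_best + 1L
        }
        if (since_best >= tcfg$patience) break
      }
      if (it >= tcfg$max_iterations) break
    }
  })

  if (!is.null(best$params)) {
    model$params <- best$params
    model$buffers <- best$buffers
  }
  history <- structure(
    list(loss = tibble(iteration = seq_along(loss_hist), loss = loss_hist),
         validations = dplyr::bind_rows(val_hist),
         best_iteration = best$iteration,
         best_mean_jaccard = if (is.finite(best$score)) best$score else NA_real_),
    class = "fees_train_history")
  list(model = model, history = history)
}

#' @export
print.fees_train_history <- function(x, ...) {
  cat(sprintf("<fees_train_history> %d iterations, %d validations, best at %s (mean Jaccard %.4f)\n",
              nrow(x$loss), nrow(x$validations),
              format(x$best_iteration), x$best_mean_jaccard))
  invisible(x)
}

#' @export
tidy.fees_train_history <- function(x, ...) x$validations

#' @export
glance.fees_train_history <- function(x, ...) {
  tibble(n_iterations = nrow(x$loss), n_validations = nrow(x$validations),
         best_iteration = x$best_iteration,
         best_mean_jaccard = x$best_mean_jaccard,
         final_loss = if (nrow(x$loss)) x$loss$loss[nrow(x$loss)] else NA_real_)
}

#' @export
autoplot.fees_train_history <- function(object, ...) {
  long <- tidyr::pivot_longer(object$validations, -"iteration",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_iteration, linetype = "dashed") +
    ggplot2::labs(x = "iteration", y = "validation Jaccard",
                  title = "Validation scores (dashed: retained model)") +
    ggplot2::theme_minimal()
}

#' Save / load a model checkpoint
#'
#' The parameter state goes to an RDS file with a JSON sidecar describing the
#' network and (optionally) training configuration.
#'
#' @param model A `fees_unet`.
#' @param path Checkpoint path (`.rds`).
#' @param tcfg Optional [train_config()] recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
save_unet <- function(model, path, tcfg = NULL) {
  saveRDS(list(params = model$params, buffers = model$buffers,
               config = unclass(model$config),
               input_channels = model$input_channels), path)
  sidecar <- list(net_config = unclass(model$config))
  if (!is.null(tcfg)) sidecar$train_config <- unclass(tcfg)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  st <- readRDS(path)
  cfg <- do.call(unet_config, st$config)
  net <- build_unet(cfg, input_channels = st$input_channels, seed = 0L)
  net$params <- st$params
  net$buffers <- st$buffers
  net
}
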