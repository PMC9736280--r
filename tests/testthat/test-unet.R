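ns <- asNamespace("feesxai")

test_that("convolution matches a naive direct-convolution oracle", {
  set.seed(21)
  H <- 5; W <- 4; C <- 2; Cout <- 3; k <- 3
  x <- array(rnorm(H * W * C), c(H, W, C, 1))
  Wm <- matrix(rnorm(k * k * C * Cout), k * k * C, Cout)
  b <- rnorm(Cout)
  y <- ns$conv_forward(x, Wm, b, k)$y
  pad <- k %/% 2
  oracle <- array(0, c(H, W, Cout))
  for (co in seq_len(Cout)) for (i in seq_len(H)) for (j in seq_len(W)) {
    s <- b[co]
    for (c in seq_len(C)) for (ki in seq_len(k)) for (kj in seq_len(k)) {
      si <- i + ki - 1 - pad; sj <- j + kj - 1 - pad
      if (si >= 1 && si <= H && sj >= 1 && sj <= W) {
        cc <- (c - 1) * k * k + (kj - 1) * k + ki
        s <- s + x[si, sj, c, 1] * Wm[cc, co]
      }
    }
    oracle[i, j, co] <- s
  }
  expect_equal(y[, , , 1], oracle, tolerance = 1e-12)
})

test_that("every layer's analytic gradient matches finite differences", {
  set.seed(22)
  cfg <- unet_config(base_filters = 2, depth = 2, dropout_rate = 0)
  net <- build_unet(cfg, seed = 42)
  xb <- array(runif(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  tb <- array(rbinom(8 * 8 * 3 * 2, 1, 0.3), c(8, 8, 3, 2))
  lossfn <- function() {
    fw <- ns$unet_forward(net, xb, training = TRUE)
    ns$dice_loss_grad(fw$p, tb, 1)$loss
  }
  fw <- ns$unet_forward(net, xb, training = TRUE)
  lg <- ns$dice_loss_grad(fw$p, tb, 1)
  dz <- lg$dp * fw$p * (1 - fw$p)
  grads <- ns$unet_backward(net, fw$cache, dz)
  eps <- 1e-5
  for (nm in c("enc1_conv1_W", "enc1_conv2_b", "enc1_bn1_gamma",
               "enc1_prelu1_alpha", "bott_conv1_W", "bott_bn2_beta",
               "dec1_conv1_W", "dec1_prelu2_alpha", "head_W", "head_b")) {
    i <- sample(length(net$params[[nm]]), 1)
    p0 <- net$params[[nm]][i]
    net$params[[nm]][i] <- p0 + eps; l1 <- lossfn()
    net$params[[nm]][i] <- p0 - eps; l2 <- lossfn()
    net$params[[nm]][i] <- p0
    num <- (l1 - l2) / (2 * eps)
    expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                 label = sprintf("gradient of %s", nm))
  }
})

test_that("output maps keep input resolution and filters double per level", {
  cfg <- unet_config(base_filters = 32, depth = 4)
  net <- build_unet(cfg, seed = 1)
  # deepest encoder stage: 32 * 2^(4-1) = 256 filters, counted from the
  # actual kernel shapes
  expect_equal(ncol(net$params$bott_conv1_W), 256)
  expect_equal(ncol(net$params$enc1_conv1_W), 32)
  expect_equal(ncol(net$params$enc3_conv2_W), 128)
  # the 352 x 288 working patch maps to 3 channels at the same resolution
  small <- build_unet(unet_config(base_filters = 2, depth = 4), seed = 2)
  x <- array(runif(64 * 48 * 3), c(64, 48, 3, 1))
  p <- ns$unet_forward(small, x, training = FALSE)$p
  expect_identical(dim(p), c(64L, 48L, 3L, 1L))
  expect_true(all(p >= 0 & p <= 1))
  # size contract: reject inputs not divisible by the pooling factor
  bad <- array(0, c(60, 48, 3, 1))
  expect_error(ns$unet_forward(small, bad, training = FALSE),
               class = "feesxai_size_error")
})

test_that("evaluation-mode prediction is deterministic and finite", {
  net <- build_unet(unet_config(base_filters = 4, depth = 3, dropout_rate = 0.5),
                    seed = 3)
  fr <- fees_frame(array(0, c(48, 48, 3)))
  a <- predict_frame(net, fr)
  b <- predict_frame(net, fr)
  expect_identical(unclass(a), unclass(b))
  expect_true(all(is.finite(a)))
  expect_identical(dim(a), c(48L, 48L, 3L))
  # padding path: non-divisible frame sizes are padded and cropped back
  odd <- predict_frame(net, fees_frame(array(10, c(50, 45, 3))))
  expect_identical(dim(odd), c(50L, 45L, 3L))
})

test_that("dice_loss reproduces hand-computed values", {
  t <- matrix(0, 2, 2); t[1, ] <- 1
  p_perfect <- t
  expect_equal(dice_loss(p_perfect, t, epsilon = 0), 0)
  expect_equal(dice_loss(1 - t, t, epsilon = 0), 1)
  # pred [[1,0],[0,0]] vs target [[1,1],[0,0]]: Dice = 2/3, loss = 1/3
  p <- matrix(0, 2, 2); p[1, 1] <- 1
  expect_equal(dice_loss(p, t, epsilon = 0), 1 / 3, tolerance = 1e-12)
  expect_error(dice_loss(matrix(0, 2, 2), matrix(0, 3, 2)),
               class = "feesxai_validation_error")
})

test_that("the early-stopping rule reproduces scripted traces", {
  # improvement at step 2, then 15 non-improving scores: stop at step 17
  scores <- c(0.5, 0.6, rep(0.6, 15))
  tr <- early_stopping_trace(scores, patience = 15)
  expect_true(tr$stopped)
  expect_equal(tr$best_index, 2)
  expect_equal(tr$stop_index, 17)
  # patience 1: strictly increasing for k steps then one decrease
  tr2 <- early_stopping_trace(c(0.1, 0.2, 0.3, 0.4, 0.35), patience = 1)
  expect_equal(tr2$best_index, 4)
  expect_equal(tr2$stop_index, 5)
  # no stop when the sequence keeps improving
  tr3 <- early_stopping_trace(1:5 / 10, patience = 2)
  expect_false(tr3$stopped)
  expect_equal(tr3$best_index, 5)
  # ties do not count as improvement
  tr4 <- early_stopping_trace(c(0.5, 0.5, 0.5), patience = 2)
  expect_equal(tr4$best_index, 1)
  expect_equal(tr4$stop_index, 3)
})

test_that("a tiny net memorizes one batch (loss decreases, Dice rises)", {
  set.seed(30)
  ds <- generate_fees_video(tiny_scene(seed = 31, n_frames = 20,
                                       bolus_event_rate = 8,
                                       visibility_prob = 0.75))
  expect_setequal(dataset_strata(ds),
                  c("negative", "roi_with_aspiration", "roi_without_aspiration"))
  cfg <- sampler_config(patch_size = c(32, 32), batch_size = 2)
  xs <- array(0, c(32, 32, 3, 2)); ts <- xs
  for (b in 1:2) {
    p <- sample_patch(ds, cfg)
    xs[, , , b] <- p$image; ts[, , , b] <- p$target
  }
  net <- build_unet(unet_config(base_filters = 4, depth = 2, dropout_rate = 0),
                    seed = 31)
  adam <- ns$adam_init(net$params)
  losses <- numeric(60)
  for (it in 1:60) {
    fw <- ns$unet_forward(net, xs, training = TRUE)
    lg <- ns$dice_loss_grad(fw$p, ts, 1)
    losses[it] <- lg$loss
    dz <- lg$dp * fw$p * (1 - fw$p)
    grads <- ns$unet_backward(net, fw$cache, dz)
    upd <- ns$adam_step(net$params, grads, adam, 3e-3)
    net$params <- upd$params; adam <- upd$state
  }
  expect_lt(mean(tail(losses, 10)), mean(head(losses, 10)) - 0.05)
  expect_lt(losses[60], losses[1])
})

test_that("training histories are reproducible under a fixed seed", {
  ds <- generate_fees_video(tiny_scene(seed = 31, n_frames = 20,
                                       bolus_event_rate = 8,
                                       visibility_prob = 0.75))
  run <- function() {
    net <- build_unet(unet_config(base_filters = 2, depth = 2, dropout_rate = 0.1),
                      seed = 5)
    train_unet(net, ds, train_ids = 1:15, val_ids = 16:20,
               scfg = sampler_config(patch_size = c(32, 32), batch_size = 2),
               tcfg = train_config(learning_rate = 1e-3, batch_size = 2,
                                   val_interval = 5, patience = 2,
                                   max_iterations = 20, seed = 77))
  }
  a <- run(); b <- run()
  expect_equal(a$history$loss, b$history$loss)
  expect_equal(a$history$validations, b$history$validations)
  expect_equal(a$model$params, b$model$params)
  # the retained state attains the maximum recorded mean Jaccard
  expect_equal(a$history$best_mean_jaccard,
               max(a$history$validations$mean_jaccard))
  g <- glance(a$history)
  expect_true(all(c("best_iteration", "best_mean_jaccard") %in% names(g)))
})

test_that("checkpoints round trip through save/load", {
  net <- build_unet(unet_config(base_filters = 2, depth = 2), seed = 9)
  dir <- withr::local_tempdir()
  save_unet(net, file.path(dir, "ckpt.rds"), tcfg = train_config())
  back <- load_unet(file.path(dir, "ckpt.rds"))
  expect_equal(back$params, net$params)
  expect_equal(back$config, net$config)
  expect_true(file.exists(file.path(dir, "ckpt.rds.json")))
  fr <- fees_frame(array(128, c(16, 16, 3)))
  expect_equal(unclass(predict_frame(back, fr)), unclass(predict_frame(net, fr)))
})
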