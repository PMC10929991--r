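test_that("threshold segmenter handles uniform and simple images", {
  # all air -> all background
  cm <- threshold_segment(matrix(-1000, 32, 32), pixel_spacing = 1)
  expect_true(all(cm$labels == 0L))
  # water ellipse on air -> all tissue inside
  lab_truth <- matrix(0L, 64, 96)
  ell <- ellipse_mask(64, 96, 20, 35)
  hu <- matrix(-1000, 64, 96)
  hu[ell] <- 0
  cm2 <- threshold_segment(hu, pixel_spacing = 1)
  expect_identical(cm2$labels == 2L, ell)
})

test_that("threshold segmenter is an exact oracle on noiseless phantoms", {
  ph <- small_phantom()
  cm <- threshold_segment(ph$slice)
  expect_identical(cm$labels, ph$truth$class_map$labels)
  expect_equal(mean_iou(cm, ph$truth$class_map)$mean_iou, 1)
})

test_that("threshold segmenter is robust to CT-level noise", {
  ph <- small_phantom(noise_sd = 20, seed = 99)
  iou <- mean_iou(threshold_segment(ph$slice), ph$truth$class_map)
  expect_true(all(iou$per_class >= 0.95))
})

test_that("IoU satisfies its identities and counts pixels correctly", {
  ph <- small_phantom(n_pix = 96L, pixel_spacing = 4)
  cm <- ph$truth$class_map
  expect_equal(mean_iou(cm, cm)$per_class,
               c(background = 1, lung = 1, tissue = 1, bone = 1))
  # disjoint single-class squares -> IoU 0 for that class
  a <- matrix(0L, 20, 20); a[1:10, 1:10] <- 2L
  b <- matrix(0L, 20, 20); b[11:20, 11:20] <- 2L
  expect_equal(mean_iou(a, b)$per_class[["tissue"]], 0)
  # 10x10 squares shifted by 5: IoU = 50 / 150
  p <- matrix(0L, 30, 30); p[6:15, 6:15] <- 3L
  q <- matrix(0L, 30, 30); q[11:20, 6:15] <- 3L
  expect_equal(mean_iou(p, q)$per_class[["bone"]], 1 / 3)
  # absent-class convention: no lung/bone anywhere -> IoU 1 each
  expect_equal(mean_iou(a, a)$per_class[["lung"]], 1)
  # symmetry and bounds on noisy segmentations
  ph2 <- small_phantom(noise_sd = 60, seed = 1, n_pix = 128L,
                       pixel_spacing = 3)
  s1 <- threshold_segment(ph2$slice)
  i12 <- mean_iou(s1, ph2$truth$class_map)
  i21 <- mean_iou(ph2$truth$class_map, s1)
  expect_equal(i12$per_class, i21$per_class)
  expect_true(all(i12$per_class >= 0 & i12$per_class <= 1))
  expect_error(mean_iou(a, matrix(0L, 5, 5)), "same shape")
})

test_that("an untrained network respects the shape and simplex contracts", {
  cfg <- segmenter_config(input_size = 32L, channels = c(4L, 6L, 8L, 8L, 8L),
                          seed = 7L)
  model <- build_segmenter(cfg)
  expect_false(model$trained)
  set.seed(1)
  hu <- matrix(stats::rnorm(32 * 32, 0, 300), 32, 32)
  probs <- ssdect:::unet_forward_cpp(ssdect:::normalise_hu(hu), model$weights,
                                     cfg$channels, cfg$n_classes)
  expect_equal(dim(probs), c(4, 32 * 32))
  expect_equal(colSums(probs), rep(1, 32 * 32), tolerance = 1e-5)
  # prediction at a different native resolution yields a valid class map
  cm <- predict_classmap(model, hu, pixel_spacing = c(1.2, 0.8))
  expect_equal(dim(cm$labels), c(32, 32))
  expect_true(all(cm$labels %in% 0:3))
  cm2 <- predict_classmap(model, matrix(0, 48, 48), pixel_spacing = 1)
  expect_equal(dim(cm2$labels), c(48, 48))
  expect_error(segmenter_config(input_size = 40L), "divisible by 16")
})

test_that("analytic gradients match finite differences on a tiny network", {
  set.seed(4)
  S <- 16L
  ch <- c(2L, 3L, 4L, 5L, 6L)
  w <- ssdect:::unet_init_cpp(ch, 4L, 3L)
  x <- matrix(stats::runif(S * S), S, S)
  lab <- sample(0:3, S * S, replace = TRUE)
  cw <- c(1, 0.5, 2, 1.5)          # exercise the weighted loss too
  g <- ssdect:::unet_lossgrad_cpp(x, lab, w, ch, 4L, cw)
  eps <- 1e-6
  for (li in seq(1, length(w), by = 2)) {      # every conv weight matrix
    k <- sample(length(w[[li]]), 2)
    for (kk in k) {
      wp <- w; wp[[li]][kk] <- wp[[li]][kk] + eps
      wm <- w; wm[[li]][kk] <- wm[[li]][kk] - eps
      num <- (ssdect:::unet_lossgrad_cpp(x, lab, wp, ch, 4L, cw)$loss -
                ssdect:::unet_lossgrad_cpp(x, lab, wm, ch, 4L, cw)$loss) /
        (2 * eps)
      ana <- g$dW[[(li + 1) / 2]][kk]
      expect_lt(abs(num - ana) / max(abs(num) + abs(ana), 1e-6), 1e-3)
    }
  }
})

test_that("training is deterministic, learns, and checkpoints round-trip", {
  coh <- tiny_cohort()
  images <- lapply(coh, `[[`, "slice")
  masks <- lapply(coh, function(x) x$truth$class_map)
  cfg <- segmenter_config(input_size = 64L, channels = c(4L, 8L, 8L, 8L, 8L),
                          epochs = 6L, batch_size = 4L, seed = 3L)
  fit1 <- train_segmenter(images, masks, cfg)
  fit2 <- train_segmenter(images, masks, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model$weights, fit2$model$weights)
  expect_equal(nrow(fit1$history), 6)
  # cross-entropy decreases over training
  expect_lt(fit1$history$train_loss[6], fit1$history$train_loss[1])
  # mean IoU improves over the untrained start
  expect_gt(fit1$history$holdout_miou[6], fit1$history$holdout_miou[1])

  dir <- withr::local_tempdir()
  ckpt <- file.path(dir, "model.rds")
  save_checkpoint(fit1$model, ckpt)
  model <- load_checkpoint(ckpt)
  expect_identical(model$weights, fit1$model$weights)
  cm_a <- predict_classmap(model, images[[1]])
  cm_b <- predict_classmap(fit1$model, images[[1]])
  expect_identical(cm_a$labels, cm_b$labels)
})

test_that("degenerate single-class masks drive that class's IoU to 1", {
  coh <- tiny_cohort(n = 10)
  images <- lapply(coh, `[[`, "slice")
  masks <- lapply(images, function(s) {
    tissue_class_map(matrix(2L, nrow(s$hu_pixels), ncol(s$hu_pixels)),
                     s$pixel_spacing)
  })
  cfg <- segmenter_config(input_size = 32L, channels = c(4L, 8L, 8L, 8L, 8L),
                          epochs = 6L, seed = 1L)
  fit <- train_segmenter(images, masks, cfg)
  # with an all-tissue truth, the tissue IoU is the predicted tissue fraction
  tissue_iou <- vapply(images, function(s) {
    mean_iou(predict_classmap(fit$model, s), masks[[1]])$per_class[["tissue"]]
  }, numeric(1))
  expect_true(all(tissue_iou >= 0.97))
  expect_gte(stats::median(tissue_iou), 0.99)
})

test_that("training rejects bad inputs", {
  coh <- tiny_cohort(n = 10)
  images <- lapply(coh, `[[`, "slice")
  masks <- lapply(coh, function(x) x$truth$class_map)
  expect_error(train_segmenter(images[1:5], masks[1:5]), "at least 10")
  masks[[2]] <- tissue_class_map(matrix(0L, 8, 8), 1)
  expect_error(train_segmenter(images, masks), "mismatched shapes")
})
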