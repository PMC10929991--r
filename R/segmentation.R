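#' Threshold-based reference segmenter
#'
#' Deterministic four-class segmentation by Hounsfield-unit thresholds: the
#' body is everything above `body_thr` (hole-filled, largest connected
#' component); within the body, pixels below `lung_thr` are lung, above
#' `bone_thr` bone, and soft tissue otherwise. On noiseless phantoms whose
#' region HU values sit inside these brackets the result equals the
#' generator's ground truth pixel-for-pixel, which makes this segmenter the
#' pipeline's reference standard and fallback when no trained network is
#' available.
#'
#' @param slice A [ct_slice()], or a numeric HU matrix (then
#'   `pixel_spacing` is required).
#' @param body_thr HU threshold separating body from air background.
#' @param lung_thr HU below which body pixels are lung.
#' @param bone_thr HU above which body pixels are bone.
#' @param pixel_spacing Pixel spacing in mm when `slice` is a bare matrix.
#' @return A [tissue_class_map()].
#' @export
threshold_segment <- function(slice, body_thr = -400, lung_thr = -300,
                              bone_thr = 150, pixel_spacing = NULL) {
  if (inherits(slice, "ct_slice")) {
    hu <- slice$hu_pixels
    pixel_spacing <- slice$pixel_spacing
  } else {
    hu <- slice
    if (is.null(pixel_spacing)) stop("pixel_spacing required for a bare matrix")
  }
  lab <- matrix(0L, nrow(hu), ncol(hu))
  body <- hu > body_thr
  if (any(body)) {
    body <- largest_filled_component(body)
    lab[body] <- 2L
    lab[body & hu < lung_thr] <- 1L
    lab[body & hu > bone_thr] <- 3L
  }
  tissue_class_map(lab, pixel_spacing)
}

#' U-Net segmenter configuration
#'
#' @param input_size Square network input size in pixels; must be divisible
#'   by 16 (four 2x2 poolings).
#' @param n_classes Number of output classes (4: background, lung, tissue,
#'   bone).
#' @param encoder_depth Number of residual encoder blocks (fixed at 5).
#' @param channels Feature channels of the five encoder blocks.
#' @param epochs Training epochs.
#' @param holdout_fraction Fraction of image/mask pairs held out for
#'   evaluation, in (0, 1).
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param class_weights `"balanced"` (median-frequency weighting computed
#'   from the training labels, so rare classes such as vertebral bone carry
#'   usable gradient), `"none"` (plain cross-entropy), or a numeric vector
#'   of one weight per class.
#' @param seed Integer seed controlling weight initialisation, the
#'   train/holdout split and shuffling; training is bit-reproducible given
#'   the seed.
#' @return A list of class `segmenter_config`.
#' @export
segmenter_config <- function(input_size = 128L, n_classes = 4L,
                             encoder_depth = 5L,
                             channels = c(8L, 16L, 32L, 64L, 64L),
                             epochs = 30L, holdout_fraction = 0.2,
                             learning_rate = 1e-3, batch_size = 1L,
                             class_weights = "balanced",
                             seed = 1L) {
  input_size <- as.integer(input_size)
  if (input_size %% 16L != 0L) {
    stop("input_size must be divisible by 16")
  }
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop("holdout_fraction must be in (0, 1)")
  }
  if (encoder_depth != 5L) stop("the encoder has a fixed depth of 5 blocks")
  if (length(channels) != 5L) stop("channels must have length 5")
  structure(list(
    input_size = input_size, n_classes = as.integer(n_classes),
    encoder_depth = 5L, channels = as.integer(channels),
    epochs = as.integer(epochs), holdout_fraction = holdout_fraction,
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    class_weights = class_weights,
    seed = as.integer(seed)
  ), class = "segmenter_config")
}

#' Build an (untrained) U-Net segmenter
#'
#' Allocates the network weights (He-normal initialisation, seeded) for a
#' residual-encoder U-Net: five residual blocks in the down-sampling path
#' separated by 2x2 max pooling, a symmetric 2x up-sampling path with skip
#' concatenations, and a 1x1 convolution + softmax head over the four
#' classes.
#'
#' @param config A [segmenter_config()].
#' @return A list of class `unet_model` with `config`, `weights` and a
#'   `trained` flag.
#' @export
build_segmenter <- function(config = segmenter_config()) {
  weights <- unet_init_cpp(config$channels, config$n_classes, config$seed)
  structure(list(config = config, weights = weights, trained = FALSE),
            class = "unet_model")
}

# clip HU to [-1000, 1000] and scale to [0, 1]; a fixed physical window so
# normalisation does not depend on the image at hand
normalise_hu <- function(hu) {
  (pmin(pmax(hu, -1000), 1000) + 1000) / 2000
}

resize_image <- function(m, size, labels = FALSE) {
  if (nrow(m) == size && ncol(m) == size) return(m)
  out <- EBImage::resize(m, w = size, h = size,
                         filter = if (labels) "none" else "bilinear")
  matrix(as.numeric(out), size, size)
}

as_label_matrix <- function(mask) {
  if (inherits(mask, "tissue_class_map")) mask$labels else mask
}

# per-class loss weights: median-frequency balancing over the training
# labels ("balanced"), all-ones ("none"), or a user-supplied vector
class_weight_vector <- function(config, y_train) {
  cw <- config$class_weights
  K <- config$n_classes
  if (is.numeric(cw)) {
    if (length(cw) != K || any(cw < 0)) stop("need one weight >= 0 per class")
    return(as.numeric(cw))
  }
  if (identical(cw, "none")) return(rep(1, K))
  if (!identical(cw, "balanced")) stop("unknown class_weights setting")
  freq <- tabulate(as.integer(y_train) + 1L, nbins = K) / length(y_train)
  present <- freq > 0
  w <- rep(0, K)
  w[present] <- stats::median(freq[present]) / freq[present]
  w
}

#' Train the U-Net segmenter
#'
#' Images are resized to the network input size (bilinear; labels
#' nearest-neighbour), HU-normalised to a fixed [-1000, 1000] window, split
#' into training and holdout sets, and fitted by Adam on per-pixel
#' multi-class cross-entropy. Given the same seed the run is
#' bit-reproducible.
#'
#' @param images List of HU matrices or [ct_slice()] objects (>= 10).
#' @param masks List of [tissue_class_map()]s or label matrices, same
#'   length and per-pair shape as `images`.
#' @param config A [segmenter_config()].
#' @return A list with `model` (trained `unet_model`) and `history` (one
#'   row per epoch: losses and mean IoU on the training and holdout sets).
#' @export
train_segmenter <- function(images, masks, config = segmenter_config()) {
  if (length(images) != length(masks)) {
    stop("images and masks must have the same length")
  }
  if (length(images) < 10) stop("need at least 10 image/mask pairs")
  n <- length(images)
  S <- config$input_size
  X <- array(0, c(S, S, n))
  Y <- matrix(0L, S * S, n)
  for (i in seq_len(n)) {
    hu <- if (inherits(images[[i]], "ct_slice")) images[[i]]$hu_pixels else images[[i]]
    lab <- as_label_matrix(masks[[i]])
    if (!identical(dim(hu), dim(lab))) {
      stop("image and mask ", i, " have mismatched shapes")
    }
    X[, , i] <- normalise_hu(resize_image(hu, S))
    Y[, i] <- as.integer(resize_image(lab, S, labels = TRUE))
  }
  set.seed(config$seed)
  n_hold <- max(1L, round(config$holdout_fraction * n))
  holdout_idx <- sort(sample.int(n, n_hold))
  train_idx <- setdiff(seq_len(n), holdout_idx)
  orders <- lapply(seq_len(config$epochs),
                   function(e) sample.int(length(train_idx)))
  cw <- class_weight_vector(config, Y[, train_idx, drop = FALSE])
  weights <- unet_init_cpp(config$channels, config$n_classes, config$seed)
  fit <- unet_train_cpp(X, Y, weights, config$channels, config$n_classes,
                        config$learning_rate, config$epochs,
                        config$batch_size, train_idx, holdout_idx, orders,
                        cw)
  history <- as.data.frame(fit$history)
  names(history) <- c("train_loss", "holdout_loss", "train_miou",
                      "holdout_miou")
  history$epoch <- seq_len(nrow(history))
  history <- history[, c("epoch", "train_loss", "holdout_loss",
                         "train_miou", "holdout_miou")]
  model <- structure(list(config = config, weights = fit$weights,
                          trained = TRUE,
                          holdout_miou = history$holdout_miou[nrow(history)]),
                     class = "unet_model")
  list(model = model, history = history)
}

#' Predict a tissue class map with a U-Net model
#'
#' Resizes and normalises the image to the network input, takes the argmax
#' of the softmax output and maps labels back to the native resolution by
#' nearest neighbour.
#'
#' @param model A `unet_model` from [build_segmenter()] or
#'   [train_segmenter()].
#' @param slice A [ct_slice()], or an HU matrix plus `pixel_spacing`.
#' @param pixel_spacing Pixel spacing in mm for bare matrices.
#' @return A [tissue_class_map()] at the input's native resolution.
#' @export
predict_classmap <- function(model, slice, pixel_spacing = NULL) {
  if (inherits(slice, "ct_slice")) {
    hu <- slice$hu_pixels
    pixel_spacing <- slice$pixel_spacing
  } else {
    hu <- slice
    if (is.null(pixel_spacing)) stop("pixel_spacing required for a bare matrix")
  }
  S <- model$config$input_size
  x <- normalise_hu(resize_image(hu, S))
  probs <- unet_forward_cpp(x, model$weights, model$config$channels,
                            model$config$n_classes)
  lab_small <- matrix(max.col(t(probs)) - 1L, S, S)
  lab <- resize_to_shape_nn(lab_small, nrow(hu), ncol(hu))
  tissue_class_map(lab, pixel_spacing)
}

# nearest-neighbour resize of a label raster to an arbitrary shape
resize_to_shape_nn <- function(lab, nr, nc) {
  if (nrow(lab) == nr && ncol(lab) == nc) return(lab)
  ri <- pmin(pmax(round((seq_len(nr) - 0.5) * nrow(lab) / nr + 0.5), 1), nrow(lab))
  ci <- pmin(pmax(round((seq_len(nc) - 0.5) * ncol(lab) / nc + 0.5), 1), ncol(lab))
  matrix(as.integer(lab[ri, ci]), nr, nc)
}

#' Per-class and mean intersection-over-union
#'
#' Jaccard index per class; a class absent from both rasters scores 1 by
#' convention (so phantoms lacking, say, bone do not zero the mean), and the
#' mean is the arithmetic mean over the four classes.
#'
#' @param pred,truth [tissue_class_map()]s or label matrices of equal shape.
#' @return A list of class `iou_report` with `per_class` (named numeric,
#'   `background`/`lung`/`tissue`/`bone`) and `mean_iou`.
#' @export
mean_iou <- function(pred, truth) {
  p <- as_label_matrix(pred)
  t_ <- as_label_matrix(truth)
  if (!identical(dim(p), dim(t_))) stop("pred and truth must have the same shape")
  per <- vapply(0:3, function(cl) {
    a <- p == cl
    b <- t_ == cl
    uni <- sum(a | b)
    if (uni == 0) 1 else sum(a & b) / uni
  }, numeric(1))
  names(per) <- class_names
  structure(list(per_class = per, mean_iou = mean(per)), class = "iou_report")
}

#' @export
print.iou_report <- function(x, ...) {
  cat("IoU per class (absent classes score 1):\n")
  for (nm in names(x$per_class)) {
    cat(sprintf("  %-10s %.4f\n", nm, x$per_class[[nm]]))
  }
  cat(sprintf("  mean       %.4f\n", x$mean_iou))
  invisible(x)
}

#' Save / load a U-Net checkpoint
#'
#' The checkpoint is a single RDS file holding the configuration and
#' weights.
#'
#' @param model A `unet_model`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint` invisibly returns `path`; `load_checkpoint`
#'   returns the `unet_model`.
#' @export
save_checkpoint <- function(model, path) {
  if (!inherits(model, "unet_model")) stop("not a unet_model")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "unet_model")) stop("not a unet_model checkpoint")
  model
}
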