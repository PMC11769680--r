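## The multi-task fully convolutional model: construction, normalization,
## augmentation, training, dense inference.

#' Per-tile percentile normalization
#'
#' Maps each channel affinely so that its 3rd percentile goes to 0 and its
#' 99.8th percentile to 1 (values outside that range extend beyond
#' \[0, 1\]). A small epsilon guards constant channels, which are returned
#' as all-zero with a warning.
#'
#' @param image `H x W x C` numeric array (or a single matrix).
#' @param p_low,p_high Percentiles in \[0, 100\] (defaults 3 and 99.8).
#' @return Array of the same shape.
#' @export
normalize_tile <- function(image, p_low = 3, p_high = 99.8) {
  one <- function(ch, nm) {
    q <- quantile(ch, c(p_low, p_high) / 100, na.rm = TRUE, names = FALSE)
    if (q[2] - q[1] <= 0) {
      warning("channel ", nm, " is constant; normalized to 0")
      return(ch * 0)
    }
    (ch - q[1]) / (q[2] - q[1] + 1e-12)
  }
  if (is.matrix(image)) return(one(image, "1"))
  nm <- dimnames(image)[[3]] %||% as.character(seq_len(dim(image)[3]))
  out <- image
  for (i in seq_len(dim(image)[3])) out[, , i] <- one(image[, , i], nm[i])
  out
}

#' Random augmentation of a training patch
#'
#' Geometric operations (horizontal/vertical flips and 90-degree
#' rotations) are applied identically to the input and the label patch;
#' intensity operations are applied to the input only: multiplication by
#' `s1 ~ U(0.6, 2)`, addition of `s2 ~ U(-0.2, 0.2)`, then additive
#' Gaussian noise with standard deviation `noise_sd`.
#'
#' @param input `P x P x C` input patch.
#' @param label `L x L x 6` label patch.
#' @param noise_sd Gaussian noise sd (default 0.1).
#' @param rot Number of 90-degree rotations (0-3); drawn at random if NULL.
#' @param flip Horizontal flip first; drawn at random if NULL.
#' @param s1,s2 Intensity scale/shift; drawn at random if NULL.
#' @return List with transformed `input` and `label`.
#' @export
augment_patch <- function(input, label, noise_sd = 0.1, rot = NULL,
                          flip = NULL, s1 = NULL, s2 = NULL) {
  if (is.null(rot)) rot <- sample(0:3, 1)
  if (is.null(flip)) flip <- runif(1) < 0.5
  if (is.null(s1)) s1 <- runif(1, 0.6, 2)
  if (is.null(s2)) s2 <- runif(1, -0.2, 0.2)
  geo <- function(a) {
    for (ch in seq_len(dim(a)[3])) {
      m <- a[, , ch]
      if (flip) m <- m[, ncol(m):1]
      if (rot > 0) for (r in seq_len(rot)) m <- t(m)[nrow(m):1, ] # 90 ccw
      a[, , ch] <- m
    }
    a
  }
  input <- geo(input) * s1 + s2
  if (noise_sd > 0)
    input <- input + array(rnorm(length(input), 0, noise_sd), dim(input))
  list(input = input, label = geo(label))
}

#' Training configuration
#'
#' Defaults follow the training recipe used throughout the package: Adam
#' with learning rate 1e-3, per-branch mean-squared-error losses weighted
#' 20 (phenotype) to 1 (proximity), 100 epochs, additive input noise of
#' sd 0.1, dropout 0.2 on the fully connected stages, flip/rotation and
#' intensity augmentation. Batch size and batch-norm momentum are package
#' choices.
#'
#' @param learning_rate,epochs,batch_size Optimizer settings.
#' @param loss_weight_proximity,loss_weight_phenotype Branch loss weights.
#' @param dropout Dropout rate on fully connected stages.
#' @param input_noise_sd Gaussian noise added to inputs during training.
#' @param augment Apply geometric/intensity augmentation.
#' @param bn_momentum Running-statistics momentum for batch normalization.
#' @param rng_seed Seed controlling shuffling, augmentation and dropout.
#' @return Named list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, epochs = 100L,
                         batch_size = 128L, loss_weight_proximity = 1,
                         loss_weight_phenotype = 20, dropout = 0.2,
                         input_noise_sd = 0.1, augment = TRUE,
                         bn_momentum = 0.9, rng_seed = 1L) {
  stopifnot(epochs >= 1, loss_weight_proximity > 0,
            loss_weight_phenotype > 0)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 loss_weight_proximity = loss_weight_proximity,
                 loss_weight_phenotype = loss_weight_phenotype,
                 dropout = dropout, input_noise_sd = input_noise_sd,
                 augment = augment, bn_momentum = bn_momentum,
                 rng_seed = as.integer(rng_seed)), class = "train_config")
}

he_init <- function(nout, nin) {
  matrix(rnorm(nout * nin, sd = sqrt(2 / nin)), nrow = nout, ncol = nin)
}

#' Build an untrained multi-task detection model
#'
#' Nine 5x5 valid convolutions in three blocks with ResNet-like skip
#' connections (block 1 uses a 1x1 channel projection on the skip), a
#' 25x25 reduction convolution bringing a 63x63 input to a 3x3 feature
#' map, one shared fully connected stage and two branches of two fully
#' connected stages each, all realized as 1x1 convolutions so the network
#' runs densely over whole tiles with output stride 1. Batch normalization
#' on the convolutional layers (not on the skip projection); He-initialized
#' weights.
#'
#' @param width Channel width of the convolutional blocks.
#' @param fc_width Width of the fully connected stages.
#' @param in_channels Input channels (7: the panel).
#' @param n_markers Pseudomarker outputs (5).
#' @param rng_seed Seed for weight initialization.
#' @return A `multitask_fcn` model object (list with `params`, the shape
#'   configuration, and a `history` slot filled by [train_model()]).
#' @export
build_model <- function(width = 16L, fc_width = 32L, in_channels = 7L,
                        n_markers = 5L, rng_seed = 1L) {
  set.seed(rng_seed)
  W <- width; F_ <- fc_width
  p <- list()
  for (i in 1:9) {
    cin <- if (i == 1) in_channels else W
    p[[paste0("conv", i, "_W")]] <- he_init(W, 25 * cin)
    p[[paste0("conv", i, "_b")]] <- numeric(W)
    p[[paste0("bn", i, "_gamma")]] <- rep(1, W)
    p[[paste0("bn", i, "_beta")]] <- numeric(W)
    p[[paste0("bn", i, "_mean")]] <- numeric(W)
    p[[paste0("bn", i, "_var")]] <- rep(1, W)
  }
  p$red_W <- he_init(F_, 625 * W)
  p$red_b <- numeric(F_)
  p$bnred_gamma <- rep(1, F_); p$bnred_beta <- numeric(F_)
  p$bnred_mean <- numeric(F_); p$bnred_var <- rep(1, F_)
  p$proj_W <- he_init(W, in_channels)
  p$proj_b <- numeric(W)
  p$fc_shared_W <- he_init(F_, F_); p$fc_shared_b <- numeric(F_)
  p$fc_prox1_W <- he_init(F_, F_); p$fc_prox1_b <- numeric(F_)
  p$fc_prox2_W <- he_init(1L, F_); p$fc_prox2_b <- numeric(1)
  p$fc_psi1_W <- he_init(F_, F_); p$fc_psi1_b <- numeric(F_)
  p$fc_psi2_W <- he_init(n_markers, F_); p$fc_psi2_b <- numeric(n_markers)
  structure(list(params = p, width = W, fc_width = F_,
                 in_channels = in_channels, n_markers = n_markers,
                 history = NULL), class = "multitask_fcn")
}

#' Train the model on sampled patches
#'
#' Minimizes `loss_weight_proximity * MSE(proximity branch) +
#' loss_weight_phenotype * MSE(pseudomarker branch)` with Adam over
#' shuffled minibatches. Deterministic for a fixed `cfg$rng_seed`.
#'
#' @param model A `multitask_fcn` from [build_model()].
#' @param patches Patch set from [sample_patches()] (or several
#'   concatenated with [combine_patches()]); must contain at least one
#'   patch.
#' @param cfg A [train_config()].
#' @return The model with updated parameters and a `history` matrix
#'   (per-epoch total loss and per-branch MSEs).
#' @export
train_model <- function(model, patches, cfg = train_config()) {
  stopifnot(inherits(model, "multitask_fcn"))
  n <- dim(patches$input)[4]
  if (is.null(n) || n < 1) stop("need at least one training patch")
  set.seed(cfg$rng_seed)
  res <- .net_train(model$params, patches$input, patches$label,
                    unclass(cfg))
  model$params <- res$params
  model$history <- res$history
  model
}

#' Concatenate patch sets from several tiles
#'
#' @param ... Patch sets from [sample_patches()].
#' @return One combined patch set.
#' @export
combine_patches <- function(...) {
  ps <- list(...)
  if (length(ps) == 1 && is.null(ps[[1]]$input)) ps <- ps[[1]]
  input <- array(unlist(lapply(ps, `[[`, "input")),
                 dim = c(dim(ps[[1]]$input)[1:3],
                         sum(sapply(ps, function(p) dim(p$input)[4]))))
  label <- array(unlist(lapply(ps, `[[`, "label")),
                 dim = c(dim(ps[[1]]$label)[1:3],
                         sum(sapply(ps, function(p) dim(p$label)[4]))))
  list(input = input, label = label,
       centers = do.call(rbind, lapply(ps, `[[`, "centers")))
}

#' Subsample a patch set
#'
#' @param patches A patch set.
#' @param n Number of patches to keep (uniform, without replacement).
#' @param rng_seed Seed.
#' @return The reduced patch set.
#' @export
subsample_patches <- function(patches, n, rng_seed = 1L) {
  total <- dim(patches$input)[4]
  if (n >= total) return(patches)
  set.seed(rng_seed)
  sel <- sample(total, n)
  list(input = patches$input[, , , sel, drop = FALSE],
       label = patches$label[, , , sel, drop = FALSE],
       centers = patches$centers[sel, , drop = FALSE])
}

#' Dense prediction of proximity and pseudomarker maps for a whole tile
#'
#' The fully convolutional structure predicts every pixel in one pass:
#' the tile is mirror-padded by 30 px (half the 61 px receptive field), the
#' network is run with valid convolutions, and each output location keeps
#' the center element of its 3x3 output window, which lines the output up
#' exactly with the input pixels. `aggregate = "mean"` instead averages
#' the overlapping 3x3 estimates, i.e. applies a 3x3 box filter to the
#' dense maps.
#'
#' @param model A trained `multitask_fcn`.
#' @param image `H x W x 7` normalized tile (see [normalize_tile()]); at
#'   least 63x63.
#' @param aggregate `"center"` (default) or `"mean"`.
#' @return List with `proximity` (H x W matrix) and `phenotype` (named
#'   list of 5 H x W matrices, in [phenotyping_markers()] order).
#' @export
predict_tile <- function(model, image, aggregate = c("center", "mean")) {
  stopifnot(inherits(model, "multitask_fcn"))
  aggregate <- match.arg(aggregate)
  d <- dim(image)
  if (length(d) != 3 || d[3] != model$in_channels)
    stop("image must be H x W x ", model$in_channels)
  if (d[1] < 63 || d[2] < 63)
    stop("image smaller than the 63 px receptive field")
  pad <- reflect_pad_stack(image, 30L)
  out <- .net_infer(model$params, pad)
  if (aggregate == "mean") {
    k <- matrix(1 / 9, 3, 3)
    for (i in seq_len(dim(out)[3]))
      out[, , i] <- EBImage::filter2(out[, , i], k, boundary = "replicate")
  }
  markers <- phenotyping_markers()
  phen <- lapply(seq_along(markers), function(i) out[, , 1 + i])
  names(phen) <- markers
  list(proximity = out[, , 1], phenotype = phen)
}

#' Forward pass on a single 63x63 patch
#'
#' Convenience wrapper used in tests: runs dense inference on exactly one
#' receptive field, yielding the canonical 3x3 output window.
#'
#' @param model A `multitask_fcn`.
#' @param patch `63 x 63 x 7` array.
#' @return `3 x 3 x 6` array (channel 1 proximity, 2-6 pseudomarkers).
#' @export
predict_patch <- function(model, patch) {
  stopifnot(all(dim(patch) == c(63, 63, model$in_channels)))
  .net_infer(model$params, patch)
}

#' @export
print.multitask_fcn <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(
    "Multi-task FCN: width %d, fc width %d, %d input channels, %s parameters%s\n",
    x$width, x$fc_width, x$in_channels, format(np, big.mark = ","),
    if (is.null(x$history)) " (untrained)" else
      sprintf("; trained %d epochs (final loss %.4g)", nrow(x$history),
              x$history[nrow(x$history), 1])))
  invisible(x)
}
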