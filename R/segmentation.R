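# U-shaped segmentation network over an EfficientNet-style encoder, trained
# with a combined soft-Dice + binary cross-entropy objective.

#' Soft Dice coefficient
#'
#' \eqn{(2|X \cap Y| + s) / (|X| + |Y| + s)} with the soft generalization:
#' the intersection is the elementwise product and the magnitudes are plain
#' sums, so probabilistic predictions are admitted directly. The default
#' smoothing \code{smooth = 1} stabilizes training gradients and makes two
#' empty masks score 1; pass \code{smooth = 0} for the exact set formula.
#'
#' @param pred probability or binary matrix/array.
#' @param truth binary matrix/array of the same shape.
#' @param smooth additive smoothing in numerator and denominator.
#' @return Dice similarity in \code{[0, 1]}.
#' @export
dice_coefficient <- function(pred, truth, smooth = 1) {
  if (!identical(dim(pred), dim(truth))) stop("shapes differ")
  (2 * sum(pred * truth) + smooth) / (sum(pred) + sum(truth) + smooth)
}

#' Dice loss
#'
#' One minus the soft Dice coefficient; see [dice_coefficient()].
#' @inheritParams dice_coefficient
#' @export
dice_loss <- function(pred, truth, smooth = 1) {
  1 - dice_coefficient(pred, truth, smooth)
}

#' Binary cross-entropy loss
#'
#' \eqn{-(1/N) \sum_i [y_i \log \hat y_i + (1-y_i) \log(1-\hat y_i)]} over
#' all N pixels, with predictions clipped into \eqn{(\epsilon, 1-\epsilon)}
#' before the logarithms.
#'
#' @param pred probabilities.
#' @param truth binary labels, same shape.
#' @param eps clipping constant.
#' @export
bce_loss <- function(pred, truth, eps = 1e-7) {
  if (!identical(dim(pred), dim(truth))) stop("shapes differ")
  p <- pmin(pmax(pred, eps), 1 - eps)
  -mean(truth * log(p) + (1 - truth) * log(1 - p))
}

#' Combined segmentation loss: Dice loss plus binary cross-entropy
#'
#' @inheritParams bce_loss
#' @param dice_weight,bce_weight term weights (default 1:1).
#' @param smooth Dice smoothing constant.
#' @export
combined_loss <- function(pred, truth, dice_weight = 1, bce_weight = 1,
                          smooth = 1) {
  dice_weight * dice_loss(pred, truth, smooth) +
    bce_weight * bce_loss(pred, truth)
}

# Analytic gradient of the combined loss w.r.t. the predicted
# probabilities; fed into the network's reverse sweep during training.
combined_loss_grad <- function(pred, truth, dice_weight = 1, bce_weight = 1,
                               smooth = 1, eps = 1e-7) {
  p <- pmin(pmax(pred, eps), 1 - eps)
  dbce <- ((1 - truth) / (1 - p) - truth / p) / length(p)
  S <- sum(pred) + sum(truth) + smooth
  I2 <- 2 * sum(pred * truth) + smooth
  ddice <- -(2 * truth * S - I2) / S^2
  dice_weight * ddice + bce_weight * dbce
}

#' Segmentation model configuration
#'
#' @param backbone encoder identifier: \code{"tiny"} (a 4-stage plain
#'   convolutional encoder, under 100k parameters, trainable on a CPU) or
#'   one of \code{"efficientnet-b0"} ... \code{"efficientnet-b4"}
#'   (EfficientNet-style encoders built from inverted-bottleneck blocks:
#'   1x1 expansion, depthwise 3x3, 1x1 projection, swish activations,
#'   residual adds).
#' @param input_size input side length in pixels; must be divisible by
#'   \code{2^encoder_depth}.
#' @param encoder_depth number of downsampling stages (skip connections are
#'   tapped at the end of each resolution stage).
#' @param decoder_channels per-stage decoder widths, deepest first;
#'   defaults to the reversed encoder widths.
#' @param pretrained must be FALSE; no pretrained encoder weights ship with
#'   the package.
#' @return An object of class \code{seg_model_config}.
#' @export
seg_model_config <- function(backbone = "efficientnet-b4", input_size = 256L,
                             encoder_depth = 4L, decoder_channels = NULL,
                             pretrained = FALSE) {
  if (isTRUE(pretrained))
    stop("pretrained encoder weights are not available; use pretrained = FALSE")
  input_size <- as.integer(input_size)
  encoder_depth <- as.integer(encoder_depth)
  if (input_size %% 2L^encoder_depth != 0L)
    stop("input_size must be divisible by 2^encoder_depth = ",
         2L^encoder_depth)
  widths <- encoder_widths(backbone, encoder_depth)
  if (is.null(decoder_channels)) decoder_channels <- rev(widths)
  structure(list(backbone = backbone, input_size = input_size,
                 encoder_depth = encoder_depth,
                 encoder_channels = widths,
                 decoder_channels = decoder_channels,
                 pretrained = FALSE),
            class = "seg_model_config")
}

encoder_widths <- function(backbone, depth) {
  base <- switch(backbone,
    "tiny" = c(8L, 16L, 32L, 64L, 64L),
    "efficientnet-b0" = c(16L, 24L, 40L, 80L, 112L),
    "efficientnet-b1" = c(16L, 24L, 40L, 80L, 112L),
    "efficientnet-b2" = c(16L, 24L, 48L, 88L, 120L),
    "efficientnet-b3" = c(24L, 32L, 48L, 96L, 136L),
    "efficientnet-b4" = c(24L, 32L, 56L, 112L, 160L),
    stop("unknown backbone: ", backbone))
  if (depth > length(base)) stop("encoder_depth too large for ", backbone)
  base[seq_len(depth)]
}

# Encoder builders append nodes to `g` and return list(skips, bottom).
append_tiny_encoder <- function(g, x, widths) {
  skips <- integer(0)
  cur <- x
  for (w in widths) {
    cur <- nn_add(g, "relu", nn_add(g, "conv", cur, cout = w, k = 3L))
    cur <- nn_add(g, "relu", nn_add(g, "conv", cur, cout = w, k = 3L))
    skips <- c(skips, cur)
    cur <- nn_add(g, "maxpool", cur, k = 2L, stride = 2L, pad = 0L)
  }
  bottom <- nn_add(g, "relu",
                   nn_add(g, "conv", cur, cout = 2L * widths[length(widths)],
                          k = 3L))
  list(skips = skips, bottom = bottom)
}

# Inverted-bottleneck block: 1x1 expand, depthwise 3x3, 1x1 project, swish
# between; residual add when input and output widths agree.
append_mbconv <- function(g, x, cout, expand = 4L) {
  cin <- g$nodes[[x]]$channels
  mid <- expand * cin
  h <- nn_add(g, "swish", nn_add(g, "conv", x, cout = mid, k = 1L))
  h <- nn_add(g, "swish",
              nn_add(g, "conv", h, cout = mid, k = 3L, groups = mid))
  h <- nn_add(g, "conv", h, cout = cout, k = 1L)
  if (cin == cout) nn_add(g, "add", c(h, x)) else h
}

append_effnet_encoder <- function(g, x, widths) {
  cur <- nn_add(g, "swish",
                nn_add(g, "conv", x, cout = widths[1], k = 3L))
  skips <- integer(0)
  for (w in widths) {
    cur <- append_mbconv(g, cur, w)
    cur <- append_mbconv(g, cur, w)
    skips <- c(skips, cur)
    cur <- nn_add(g, "maxpool", cur, k = 2L, stride = 2L, pad = 0L)
  }
  bottom <- append_mbconv(g, cur, 2L * widths[length(widths)])
  list(skips = skips, bottom = bottom)
}

#' Build a U-shaped segmentation network (Eff-Unet)
#'
#' Assembles the encoder selected by \code{cfg$backbone}, taps a skip
#' connection at the end of every resolution stage, and mirrors it with a
#' decoder of upsample–concatenate–convolve stages; the head is a 1x1
#' convolution with a sigmoid, so the output is a per-pixel nodule
#' probability map of the same spatial size as the input.
#'
#' @param cfg a [seg_model_config()].
#' @param seed integer seed for weight initialization.
#' @return An object of class \code{eff_unet} holding the graph, its
#'   parameters and the configuration.
#' @export
build_eff_unet <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "seg_model_config"))
  g <- nn_graph()
  x <- nn_add(g, "input", size = cfg$input_size, channels = 1L)
  enc <- if (cfg$backbone == "tiny")
    append_tiny_encoder(g, x, cfg$encoder_channels)
  else append_effnet_encoder(g, x, cfg$encoder_channels)
  cur <- enc$bottom
  dec <- cfg$decoder_channels
  for (s in rev(seq_len(cfg$encoder_depth))) {
    cur <- nn_add(g, "upsample2", cur)
    cur <- nn_add(g, "concat", c(cur, enc$skips[s]))
    w <- dec[cfg$encoder_depth - s + 1L]
    cur <- nn_add(g, "relu", nn_add(g, "conv", cur, cout = w, k = 3L))
  }
  nn_add(g, "sigmoid", nn_add(g, "conv", cur, cout = 1L, k = 1L))
  params <- nn_init(g, seed)
  structure(list(graph = g, params = params, cfg = cfg, history = NULL),
            class = "eff_unet")
}

#' @export
print.eff_unet <- function(x, ...) {
  cat("Eff-Unet segmentation network\n")
  cat("  backbone:", x$cfg$backbone, " input:", x$cfg$input_size, "x",
      x$cfg$input_size, " depth:", x$cfg$encoder_depth, "\n")
  cat("  parameters:", nn_count_params(x$params), "\n")
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs; final loss %.4f, training IOU %.3f\n",
                nrow(x$history), x$history$loss[nrow(x$history)],
                x$history$iou[nrow(x$history)]))
  invisible(x)
}

#' Segmentation training configuration
#'
#' Adam at learning rate 0.001 with plateau-triggered halving: when the
#' epoch loss has not improved for \code{lr_patience} epochs the rate is
#' multiplied by \code{lr_factor}, followed by \code{lr_cooldown} epochs
#' during which no further reduction is applied.
#'
#' @param learning_rate initial Adam learning rate.
#' @param lr_factor multiplicative decay on plateau (1 disables decay).
#' @param lr_cooldown epochs to wait after a reduction.
#' @param lr_patience epochs without improvement that trigger a reduction.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param dice_weight,bce_weight loss term weights.
#' @param seed RNG seed for shuffling and dropout.
#' @return An object of class \code{seg_train_config}.
#' @export
seg_train_config <- function(learning_rate = 0.001, lr_factor = 0.5,
                             lr_cooldown = 10L, lr_patience = 10L,
                             epochs = 200L, batch_size = 8L,
                             dice_weight = 1, bce_weight = 1, seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(learning_rate = learning_rate, lr_factor = lr_factor,
                 lr_cooldown = as.integer(lr_cooldown),
                 lr_patience = as.integer(lr_patience),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 dice_weight = dice_weight, bce_weight = bce_weight,
                 seed = as.integer(seed)),
            class = "seg_train_config")
}

# Shared plateau learning-rate schedule (segmentation and classification).
plateau_lr_update <- function(st, loss, factor, patience, cooldown) {
  if (loss < st$best - 1e-8) {
    st$best <- loss
    st$wait <- 0L
  } else st$wait <- st$wait + 1L
  if (st$cool > 0L) {
    st$cool <- st$cool - 1L
  } else if (st$wait >= patience && factor < 1) {
    st$lr <- st$lr * factor
    st$wait <- 0L
    st$cool <- cooldown
  }
  st
}

stack_batch <- function(mats, size) {
  array(unlist(mats, use.names = FALSE), c(size, size, 1L, length(mats)))
}

#' Train the segmentation network
#'
#' Minibatch Adam on the combined Dice + BCE loss, with the plateau
#' learning-rate schedule of [seg_train_config()]. Per-epoch loss, training
#' IOU (at a 0.5 cut on the predicted probabilities) and learning rate are
#' recorded in the returned model's \code{history}.
#'
#' @param model an [build_eff_unet()] model.
#' @param dataset list of records, each with \code{image} (matrix in
#'   \code{[0, 1]}) and \code{mask} (binary matrix; three-valued masks are
#'   collapsed with [binarize_mask_for_segmentation()]).
#' @param cfg a [seg_train_config()].
#' @return The model with updated parameters and a \code{history} data
#'   frame (epoch, loss, iou, lr).
#' @export
train_segmentation <- function(model, dataset, cfg = seg_train_config()) {
  stopifnot(inherits(model, "eff_unet"), inherits(cfg, "seg_train_config"))
  if (!length(dataset)) stop("empty training dataset")
  size <- model$cfg$input_size
  xs <- lapply(dataset, function(d) d$image)
  ys <- lapply(dataset, function(d) {
    m <- d$mask
    if (max(m) > 1) m <- binarize_mask_for_segmentation(m)
    m
  })
  if (!all(vapply(xs, function(x) all(dim(x) == size), TRUE)))
    stop("images do not match configured input size ", size)

  set.seed(cfg$seed)
  params <- model$params
  opt <- adam_init(params)
  lrst <- list(lr = cfg$learning_rate, best = Inf, wait = 0L, cool = 0L)
  hist <- data.frame(epoch = integer(), loss = numeric(), iou = numeric(),
                     lr = numeric())
  n <- length(xs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(n)
    ep_loss <- 0; ep_iou <- 0; nb <- 0L
    for (b0 in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
      xb <- stack_batch(xs[idx], size)
      yb <- stack_batch(ys[idx], size)
      fw <- nn_forward(model$graph, params, xb, train = TRUE)
      p <- fw$out
      loss <- combined_loss(p, yb, cfg$dice_weight, cfg$bce_weight)
      dout <- combined_loss_grad(p, yb, cfg$dice_weight, cfg$bce_weight)
      grads <- nn_backward(model$graph, params, fw$cache, dout)
      upd <- adam_step(params, grads, opt, lrst$lr)
      params <- upd$params; opt <- upd$state
      ep_loss <- ep_loss + loss
      ep_iou <- ep_iou + iou((p >= 0.5) * 1, yb)
      nb <- nb + 1L
    }
    ep_loss <- ep_loss / nb
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss,
                                   iou = ep_iou / nb, lr = lrst$lr))
    lrst <- plateau_lr_update(lrst, ep_loss, cfg$lr_factor,
                              cfg$lr_patience, cfg$lr_cooldown)
  }
  model$params <- params
  model$history <- hist
  model
}

#' Predict a per-pixel nodule probability map
#'
#' @param model a (trained) [build_eff_unet()] model.
#' @param image numeric matrix matching the configured input size.
#' @return Numeric matrix of probabilities in \code{[0, 1]}, same shape as
#'   the input.
#' @export
predict_mask <- function(model, image) UseMethod("predict_mask")

#' @export
predict_mask.function <- function(model, image) model(image)

#' @export
predict_mask.eff_unet <- function(model, image) {
  size <- model$cfg$input_size
  if (!all(dim(image) == size))
    stop("image is not ", size, "x", size)
  x <- array(image, c(size, size, 1L, 1L))
  matrix(nn_forward(model$graph, model$params, x)$out, size, size)
}

#' @export
predict.eff_unet <- function(object, newdata, ...) {
  predict_mask(object, newdata)
}

#' Save or load a model (network weights plus a JSON config sidecar)
#'
#' The weights go into an RDS checkpoint; the configuration is additionally
#' written next to it as \code{<path>.json} so checkpoints remain
#' self-describing.
#'
#' @param model an \code{eff_unet} or \code{cnn_model} object.
#' @param path checkpoint file path (e.g. \code{"seg.rds"}).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(
    list(class = class(model)[1], config = unclass(model$cfg),
         n_params = nn_count_params(model$params),
         trained_epochs = if (is.null(model$history)) 0L
           else nrow(model$history)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
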