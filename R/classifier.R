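# Two-branch benign/malignant classifier. A shallow branch (CNN-1) learns
# low-level shape and edge cues; a deeper Inception-style branch (CNN-2)
# learns higher-level features; CNN-F concatenates the two feature vectors
# into a 256-node fusion layer with a single sigmoid output. In CT the two
# classes barely differ in gray level, so margin morphology carries the
# signal — which is why two feature depths are fused.

#' Classifier model configuration
#'
#' @param input_size input side length in pixels.
#' @param cnn1_widths channel widths of the three conv+max-pool stages of
#'   the shallow branch.
#' @param cnn1_dense sizes of the two fully connected layers after flatten.
#' @param cnn1_dropout dropout rates: after the conv stages and after the
#'   dense layers.
#' @param cnn2_base Inception-style feature extractor: \code{"inception-mini"}
#'   (three mixed blocks) or \code{"tiny"} (two small mixed blocks for CPU
#'   test runs). Each mixed block runs parallel 1x1, 3x3 and
#'   pool-projection paths and concatenates them.
#' @param cnn2_dense width of the fully connected layer after global
#'   average pooling (128, the fusion contract of the deep branch).
#' @param fusion_dense width of the post-concatenation merge layer.
#' @param pretrained must be FALSE; no pretrained base weights ship with
#'   the package.
#' @return An object of class \code{clf_model_config}.
#' @export
clf_model_config <- function(input_size = 256L, cnn1_widths = c(32L, 64L, 128L),
                             cnn1_dense = c(256L, 64L),
                             cnn1_dropout = c(0.25, 0.5),
                             cnn2_base = "inception-mini", cnn2_dense = 128L,
                             fusion_dense = 256L, pretrained = FALSE) {
  if (isTRUE(pretrained))
    stop("pretrained base weights are not available; use pretrained = FALSE")
  if (length(cnn1_widths) != 3L)
    stop("the shallow branch uses exactly 3 conv+pool stages")
  if (!cnn2_base %in% c("inception-mini", "tiny"))
    stop("unknown cnn2_base: ", cnn2_base)
  structure(list(input_size = as.integer(input_size),
                 cnn1_widths = as.integer(cnn1_widths),
                 cnn1_dense = as.integer(cnn1_dense),
                 cnn1_dropout = cnn1_dropout,
                 cnn2_base = cnn2_base, cnn2_dense = as.integer(cnn2_dense),
                 fusion_dense = as.integer(fusion_dense),
                 pretrained = FALSE),
            class = "clf_model_config")
}

#' Tiny classifier configuration for CPU-scale runs
#'
#' @param input_size input side length in pixels.
#' @export
clf_model_config_tiny <- function(input_size = 64L) {
  clf_model_config(input_size = input_size, cnn1_widths = c(8L, 16L, 32L),
                   cnn1_dense = c(32L, 16L), cnn1_dropout = c(0.1, 0.25),
                   cnn2_base = "tiny", fusion_dense = 64L)
}

# Shallow branch: 3 x (conv -> max-pool), dropout, flatten, two dense
# layers with a trailing dropout; returns the feature-node id.
append_cnn1_branch <- function(g, x, cfg) {
  cur <- x
  for (w in cfg$cnn1_widths) {
    cur <- nn_add(g, "relu", nn_add(g, "conv", cur, cout = w, k = 3L))
    cur <- nn_add(g, "maxpool", cur, k = 2L, stride = 2L, pad = 0L)
  }
  cur <- nn_add(g, "dropout", cur, rate = cfg$cnn1_dropout[1])
  cur <- nn_add(g, "flatten", cur)
  cur <- nn_add(g, "relu", nn_add(g, "dense", cur, units = cfg$cnn1_dense[1]))
  cur <- nn_add(g, "relu", nn_add(g, "dense", cur, units = cfg$cnn1_dense[2]))
  nn_add(g, "dropout", cur, rate = cfg$cnn1_dropout[2])
}

# One Inception mixed block: parallel 1x1, (1x1 -> 3x3) and
# (3x3 max-pool stride 1 -> 1x1) paths, channel-concatenated.
append_mixed_block <- function(g, x, p1, p3r, p3, pp) {
  b1 <- nn_add(g, "relu", nn_add(g, "conv", x, cout = p1, k = 1L))
  b3 <- nn_add(g, "relu", nn_add(g, "conv", x, cout = p3r, k = 1L))
  b3 <- nn_add(g, "relu", nn_add(g, "conv", b3, cout = p3, k = 3L))
  bp <- nn_add(g, "maxpool", x, k = 3L, stride = 1L, pad = 1L)
  bp <- nn_add(g, "relu", nn_add(g, "conv", bp, cout = pp, k = 1L))
  nn_add(g, "concat", c(b1, b3, bp))
}

# Deep branch: Inception-style base (stem + mixed blocks with pooling in
# between), global average pooling, dense layer of cfg$cnn2_dense nodes.
append_cnn2_branch <- function(g, x, cfg) {
  if (cfg$cnn2_base == "tiny") {
    stem <- 8L
    blocks <- list(c(4L, 4L, 8L, 4L), c(8L, 8L, 16L, 8L))
  } else {
    stem <- 32L
    blocks <- list(c(16L, 16L, 32L, 16L), c(32L, 32L, 64L, 32L),
                   c(48L, 48L, 96L, 48L))
  }
  cur <- nn_add(g, "relu", nn_add(g, "conv", x, cout = stem, k = 3L))
  cur <- nn_add(g, "maxpool", cur, k = 2L, stride = 2L, pad = 0L)
  for (bl in blocks) {
    cur <- append_mixed_block(g, cur, bl[1], bl[2], bl[3], bl[4])
    cur <- nn_add(g, "maxpool", cur, k = 2L, stride = 2L, pad = 0L)
  }
  cur <- nn_add(g, "gap", cur)
  nn_add(g, "relu", nn_add(g, "dense", cur, units = cfg$cnn2_dense))
}

new_cnn_model <- function(g, cfg, arch, branch_ids, seed) {
  structure(list(graph = g, params = nn_init(g, seed), cfg = cfg,
                 arch = arch, branch_ids = branch_ids, history = NULL),
            class = "cnn_model")
}

#' Build the shallow classification branch (CNN-1)
#'
#' Three conv + max-pool stages (spatial size divided by 8), dropout,
#' flatten, two fully connected layers and a trailing dropout, emitting a
#' feature vector; a 1-unit sigmoid head is attached so the branch is also
#' trainable standalone.
#'
#' @param cfg a [clf_model_config()].
#' @param seed weight-initialization seed.
#' @return An object of class \code{cnn_model} (\code{arch = "cnn1"}).
#' @export
build_cnn1 <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "clf_model_config"))
  g <- nn_graph()
  x <- nn_add(g, "input", size = cfg$input_size, channels = 1L)
  feat <- append_cnn1_branch(g, x, cfg)
  ids <- seq(x + 1L, feat)
  nn_add(g, "sigmoid", nn_add(g, "dense", feat, units = 1L))
  m <- new_cnn_model(g, cfg, "cnn1", ids, seed)
  m$feature_id <- feat
  m
}

#' Build the deep classification branch (CNN-2)
#'
#' An Inception-style base (without any classifier head), global average
#' pooling, then a 128-node fully connected layer emitting the feature
#' vector; a 1-unit sigmoid head makes the branch trainable standalone.
#'
#' @inheritParams build_cnn1
#' @return An object of class \code{cnn_model} (\code{arch = "cnn2"}).
#' @export
build_cnn2 <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "clf_model_config"))
  g <- nn_graph()
  x <- nn_add(g, "input", size = cfg$input_size, channels = 1L)
  feat <- append_cnn2_branch(g, x, cfg)
  ids <- seq(x + 1L, feat)
  nn_add(g, "sigmoid", nn_add(g, "dense", feat, units = 1L))
  m <- new_cnn_model(g, cfg, "cnn2", ids, seed)
  m$feature_id <- feat
  m
}

#' Build the fused classifier (CNN-F)
#'
#' Rebuilds both branches over a single shared input, concatenates their
#' feature vectors, merges through a fully connected layer
#' (\code{cfg$fusion_dense} nodes) and ends in a 1-unit sigmoid output.
#' When trained branch models are supplied their weights are transferred
#' into the fused network.
#'
#' @param cnn1,cnn2 branch models from [build_cnn1()] / [build_cnn2()], or
#'   NULL to initialize the branches fresh.
#' @param cfg a [clf_model_config()]; defaults to \code{cnn1$cfg}.
#' @param seed weight-initialization seed.
#' @return An object of class \code{cnn_model} (\code{arch = "cnnf"}).
#' @export
build_cnnf <- function(cnn1 = NULL, cnn2 = NULL, cfg = NULL, seed = 1L) {
  if (is.null(cfg)) {
    if (is.null(cnn1)) stop("supply cfg or branch models")
    cfg <- cnn1$cfg
  }
  if (!is.null(cnn1) && !is.null(cnn2) &&
      cnn1$cfg$input_size != cnn2$cfg$input_size)
    stop("fusion error: branch input sizes differ")
  g <- nn_graph()
  x <- nn_add(g, "input", size = cfg$input_size, channels = 1L)
  f1 <- append_cnn1_branch(g, x, cfg)
  ids1 <- seq(x + 1L, f1)
  f2 <- append_cnn2_branch(g, x, cfg)
  ids2 <- seq(f1 + 1L, f2)
  cc <- nn_add(g, "concat", c(f1, f2))
  h <- nn_add(g, "relu", nn_add(g, "dense", cc, units = cfg$fusion_dense))
  nn_add(g, "sigmoid", nn_add(g, "dense", h, units = 1L))
  m <- new_cnn_model(g, cfg, "cnnf", c(ids1, ids2), seed)
  m$feature_id <- cc
  # transfer branch weights: node creation order matches the standalone
  # builders, so parameterized nodes pair up one-to-one
  transfer <- function(params, from_model, to_ids) {
    src <- from_model$branch_ids
    for (j in seq_along(src)) {
      if (!is.null(from_model$params[[src[j]]]))
        params[[to_ids[j]]] <- from_model$params[[src[j]]]
    }
    params
  }
  if (!is.null(cnn1)) m$params <- transfer(m$params, cnn1, ids1)
  if (!is.null(cnn2)) m$params <- transfer(m$params, cnn2, ids2)
  m
}

#' @export
print.cnn_model <- function(x, ...) {
  nm <- c(cnn1 = "CNN-1 (shallow branch)", cnn2 = "CNN-2 (Inception-style)",
          cnnf = "CNN-F (fused two-branch classifier)")[x$arch]
  cat(nm, "\n  input:", x$cfg$input_size, "x", x$cfg$input_size,
      " parameters:", nn_count_params(x$params), "\n")
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs; final loss %.4f, accuracy %.3f\n",
                nrow(x$history), x$history$loss[nrow(x$history)],
                x$history$acc[nrow(x$history)]))
  invisible(x)
}

#' Classifier training configuration
#'
#' Weighted binary cross-entropy (benign:malignant weights default 1:3 to
#' counter the class imbalance of clinical series, where benign nodules
#' dominate), Adam at 0.001, and the same plateau learning-rate schedule as
#' the segmentation network.
#'
#' @inheritParams seg_train_config
#' @param class_weight named numeric vector \code{c(benign = ,
#'   malignant = )} of positive per-class loss weights.
#' @return An object of class \code{clf_train_config}.
#' @export
clf_train_config <- function(learning_rate = 0.001, lr_factor = 0.5,
                             lr_cooldown = 10L, lr_patience = 10L,
                             epochs = 200L, batch_size = 16L,
                             class_weight = c(benign = 1, malignant = 3),
                             seed = 1L) {
  if (any(class_weight <= 0)) stop("class weights must be positive")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(learning_rate = learning_rate, lr_factor = lr_factor,
                 lr_cooldown = as.integer(lr_cooldown),
                 lr_patience = as.integer(lr_patience),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 class_weight = class_weight, seed = as.integer(seed)),
            class = "clf_train_config")
}

#' Weighted binary cross-entropy over a batch
#'
#' Mean over samples of the per-sample BCE multiplied by its class weight
#' (benign = label 0, malignant = label 1).
#'
#' @param pred predicted probabilities (vector).
#' @param y binary labels (0 benign, 1 malignant).
#' @param class_weight length-2 weights \code{c(benign, malignant)}.
#' @param eps clipping constant.
#' @export
weighted_bce <- function(pred, y, class_weight = c(1, 3), eps = 1e-7) {
  p <- pmin(pmax(pred, eps), 1 - eps)
  w <- ifelse(y >= 0.5, class_weight[2], class_weight[1])
  mean(w * -(y * log(p) + (1 - y) * log(1 - p)))
}

#' Train a classification network
#'
#' @param model a \code{cnn_model} from [build_cnn1()], [build_cnn2()] or
#'   [build_cnnf()].
#' @param instances list of records, each with \code{x} (numeric matrix, the
#'   masked grayscale nodule canvas) and \code{y} (0 = benign,
#'   1 = malignant; or a \code{"benign"}/\code{"malignant"} string).
#' @param cfg a [clf_train_config()].
#' @return The model with trained parameters and a \code{history} data
#'   frame (epoch, loss, acc, lr).
#' @export
train_classifier <- function(model, instances, cfg = clf_train_config()) {
  stopifnot(inherits(model, "cnn_model"), inherits(cfg, "clf_train_config"))
  if (!length(instances)) stop("empty training set")
  size <- model$cfg$input_size
  xs <- lapply(instances, function(d) d$x)
  ys <- vapply(instances, function(d) {
    if (is.character(d$y)) as.numeric(d$y == "malignant") else as.numeric(d$y)
  }, 0)
  if (length(unique(ys)) < 2)
    warning("single-class training set; the classifier cannot learn a boundary")

  set.seed(cfg$seed)
  params <- model$params
  opt <- adam_init(params)
  lrst <- list(lr = cfg$learning_rate, best = Inf, wait = 0L, cool = 0L)
  cw <- cfg$class_weight
  hist <- data.frame(epoch = integer(), loss = numeric(), acc = numeric(),
                     lr = numeric())
  n <- length(xs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(n)
    ep_loss <- 0; ep_hit <- 0L; nb <- 0L
    for (b0 in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
      xb <- stack_batch(xs[idx], size)
      yb <- ys[idx]
      fw <- nn_forward(model$graph, params, xb, train = TRUE)
      p <- as.numeric(fw$out)
      loss <- weighted_bce(p, yb, cw)
      pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
      w <- ifelse(yb >= 0.5, cw[2], cw[1])
      dout <- matrix(w * ((1 - yb) / (1 - pc) - yb / pc) / length(yb),
                     1, length(yb))
      grads <- nn_backward(model$graph, params, fw$cache, dout)
      upd <- adam_step(params, grads, opt, lrst$lr)
      params <- upd$params; opt <- upd$state
      ep_loss <- ep_loss + loss
      ep_hit <- ep_hit + sum((p >= 0.5) == (yb >= 0.5))
      nb <- nb + 1L
    }
    ep_loss <- ep_loss / nb
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss,
                                   acc = ep_hit / n, lr = lrst$lr))
    lrst <- plateau_lr_update(lrst, ep_loss, cfg$lr_factor,
                              cfg$lr_patience, cfg$lr_cooldown)
  }
  model$params <- params
  model$history <- hist
  model
}

# Forward a batch of images (list of matrices) through a classifier.
# A plain function(image) -> probability is accepted in place of a model,
# which is how reference oracles plug into the pipeline.
clf_predict_prob <- function(model, images) {
  if (is.function(model)) return(vapply(images, model, 0))
  size <- model$cfg$input_size
  x <- stack_batch(images, size)
  as.numeric(nn_forward(model$graph, model$params, x)$out)
}

#' @export
predict.cnn_model <- function(object, newdata, ...) {
  clf_predict_prob(object, list(newdata))
}

#' Predict with four-view test-time augmentation
#'
#' Evaluates the classifier on the original image, its horizontal mirror,
#' its vertical mirror and its 180-degree rotation, and averages the four
#' sigmoid outputs. The 180-degree view is used for "rotation" because it
#' is shape-preserving and needs no interpolation. The decision threshold
#' is 0.5 on the averaged probability.
#'
#' @param model a trained \code{cnn_model}.
#' @param image numeric matrix (masked nodule canvas).
#' @param tta set FALSE to evaluate the original view only.
#' @return An object of class \code{classification_result}: \code{pred_prob}
#'   (mean probability), \code{pred_label}, and \code{tta_views} (the
#'   per-view probabilities).
#' @export
predict_tta <- function(model, image, tta = TRUE) {
  views <- if (tta) list(
    image,
    image[, rev(seq_len(ncol(image))), drop = FALSE],   # horizontal mirror
    image[rev(seq_len(nrow(image))), , drop = FALSE],   # vertical mirror
    image[rev(seq_len(nrow(image))), rev(seq_len(ncol(image))),
          drop = FALSE]                                 # 180-degree rotation
  ) else list(image)
  probs <- clf_predict_prob(model, views)
  p <- mean(probs)
  structure(list(pred_prob = p,
                 pred_label = if (p >= 0.5) "malignant" else "benign",
                 tta_views = probs),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("predicted %s (p = %.3f", x$pred_label, x$pred_prob))
  if (length(x$tta_views) > 1)
    cat("; views:", paste(sprintf("%.3f", x$tta_views), collapse = " "))
  cat(")\n")
  invisible(x)
}
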