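test_that("Dice coefficient matches the set formula on hand-built masks", {
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(dice_coefficient(a, a, smooth = 0), 1)
  expect_equal(dice_coefficient(a, a), 1, tolerance = 0.25)  # smoothed

  b <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_equal(dice_coefficient(a, b, smooth = 0), 0)
  expect_lt(dice_coefficient(a, b), 0.25)

  # 3x3: pred has 4 ones, truth shares 2 of them plus 1 elsewhere
  pred <- matrix(0, 3, 3); pred[c(1, 2, 4, 5)] <- 1
  truth <- matrix(0, 3, 3); truth[c(1, 2, 9)] <- 1
  expect_equal(dice_coefficient(pred, truth, smooth = 0), 4 / 7)
  expect_equal(dice_loss(pred, truth, smooth = 0), 3 / 7)

  # both empty: smoothing defines the result as a perfect match
  z <- matrix(0, 3, 3)
  expect_equal(dice_coefficient(z, z), 1)
  expect_error(dice_coefficient(matrix(0, 2, 2), z), "differ")
})

test_that("BCE matches closed-form hand evaluations", {
  y <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(bce_loss(y, y), 0, tolerance = 1e-5)
  half <- matrix(0.5, 2, 2)
  expect_equal(bce_loss(half, y), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(matrix(0.8), matrix(1)), -log(0.8),
               tolerance = 1e-12)
  expect_gte(bce_loss(matrix(runif(16), 4), matrix(rbinom(16, 1, 0.5), 4)),
             0)
})

test_that("combined loss is the sum of its parts and vanishes at truth", {
  y <- matrix(c(1, 1, 0, 0, 1, 0, 0, 0, 0), 3, 3)
  expect_equal(combined_loss(y, y), dice_loss(y, y) + bce_loss(y, y))
  expect_lt(combined_loss(y, y), 0.2)
  p <- matrix(0.5, 3, 3)
  expect_equal(combined_loss(p, y),
               dice_loss(p, y) + log(2), tolerance = 1e-9)
  expect_gte(combined_loss(p, y), dice_loss(p, y))
  expect_gte(combined_loss(p, y), bce_loss(p, y))
})

test_that("Dice and IOU agree with set oracles and with each other", {
  set.seed(31)
  for (i in 1:200) {
    a <- random_binary_mask(8)
    b <- random_binary_mask(8)
    ov <- brute_overlap(a, b)
    if (ov$union == 0) next
    expect_equal(iou(a, b, smooth = 0),
                 ov$inter / ov$union, tolerance = 1e-12)
    expect_equal(dice_coefficient(a, b, smooth = 0),
                 2 * ov$inter / (ov$nx + ov$ny), tolerance = 1e-12)
    # D = 2J / (1 + J) exactly on binary inputs
    J <- iou(a, b, smooth = 0)
    expect_equal(dice_coefficient(a, b, smooth = 0), 2 * J / (1 + J),
                 tolerance = 1e-12)
  }
  expect_equal(iou(matrix(c(1, 1, 0, 0, 1, 0), 2),
                   matrix(c(1, 0, 1, 0, 1, 1), 2), smooth = 0), 0.4)
})

test_that("the U-shaped network maps an image to a same-size probability map", {
  cfg <- seg_model_config(backbone = "tiny", input_size = 32,
                          encoder_depth = 3)
  m <- build_eff_unet(cfg, seed = 2)
  img <- matrix(runif(32 * 32), 32, 32)
  p <- predict_mask(m, img)
  expect_equal(dim(p), c(32, 32))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(predict_mask(m, matrix(0, 16, 16)), "32")

  # constant input through the untrained net gives a near-constant map
  # (stationary architecture away from the borders)
  pz <- predict_mask(m, matrix(0, 32, 32))
  expect_lt(stats::sd(pz[5:28, 5:28]), 1e-6)

  expect_error(seg_model_config(backbone = "tiny", input_size = 100,
                                encoder_depth = 3), "divisible")
  expect_error(seg_model_config(pretrained = TRUE), "pretrained")
})

test_that("an EfficientNet-style encoder builds and keeps the shape contract", {
  cfg <- seg_model_config(backbone = "efficientnet-b0", input_size = 32,
                          encoder_depth = 3)
  m <- build_eff_unet(cfg, seed = 2)
  p <- predict_mask(m, matrix(runif(32 * 32), 32, 32))
  expect_equal(dim(p), c(32, 32))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("one Adam step on a single batch reduces its combined loss", {
  set.seed(21)
  ph <- make_phantoms(4, 400, n_nodules = 1, radius = c(4, 6))
  m <- build_eff_unet(seg_model_config(backbone = "tiny", input_size = 64,
                                       encoder_depth = 2), seed = 3)
  xb <- ctnodule:::stack_batch(lapply(ph, `[[`, "image"), 64)
  yb <- ctnodule:::stack_batch(
    lapply(ph, function(d) binarize_mask_for_segmentation(d$mask)), 64)
  fw <- ctnodule:::nn_forward(m$graph, m$params, xb)
  l0 <- combined_loss(fw$out, yb)
  dout <- ctnodule:::combined_loss_grad(fw$out, yb)
  grads <- ctnodule:::nn_backward(m$graph, m$params, fw$cache, dout)
  upd <- ctnodule:::adam_step(m$params, grads, ctnodule:::adam_init(m$params),
                              lr = 0.001)
  l1 <- combined_loss(ctnodule:::nn_forward(m$graph, upd$params, xb)$out, yb)
  expect_lt(l1, l0)
})

test_that("training is seeded-deterministic and the LR schedule behaves", {
  ph <- make_phantoms(4, 500, n_nodules = 1, radius = c(4, 6))
  build <- function() build_eff_unet(
    seg_model_config(backbone = "tiny", input_size = 64, encoder_depth = 2),
    seed = 5)
  tc <- seg_train_config(epochs = 3, batch_size = 2, seed = 9)
  h1 <- train_segmentation(build(), ph, tc)$history
  h2 <- train_segmentation(build(), ph, tc)$history
  expect_identical(h1, h2)

  # lr_factor = 1 keeps the learning rate constant
  tc1 <- seg_train_config(epochs = 4, lr_factor = 1.0, lr_patience = 1,
                          seed = 9)
  h <- train_segmentation(build(), ph, tc1)$history
  expect_true(all(h$lr == tc1$learning_rate))

  # the plateau state machine: constant loss triggers halving after
  # `patience` epochs, then holds still through the cooldown window
  st <- list(lr = 0.001, best = Inf, wait = 0L, cool = 0L)
  lrs <- numeric(0)
  for (ep in 1:14) {
    st <- ctnodule:::plateau_lr_update(st, 1.0, factor = 0.5,
                                       patience = 3, cooldown = 10)
    lrs <- c(lrs, st$lr)
  }
  expect_equal(unique(lrs), c(0.001, 0.0005))
  expect_equal(sum(lrs == 0.001), 3)      # patience epochs before the cut
  expect_equal(lrs[4], 0.0005)
  expect_true(all(lrs[5:14] == 0.0005))   # cooldown holds the rate
  expect_error(train_segmentation(build(), list(), tc), "empty")
})
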