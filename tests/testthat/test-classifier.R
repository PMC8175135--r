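tiny_cfg <- clf_model_config_tiny(32L)

test_that("the shallow branch keeps its shape contracts", {
  m <- build_cnn1(tiny_cfg, seed = 2)
  img <- matrix(runif(32 * 32), 32, 32)
  p <- predict(m, img)
  expect_length(p, 1)
  expect_true(p >= 0 && p <= 1)

  # 3 pooling stages divide the spatial size by 8 before flatten
  g <- m$graph
  fl <- Filter(function(nd) nd$op == "flatten", g$nodes)[[1]]
  expect_equal(g$nodes[[fl$inputs[1]]]$size, 32 / 8)
  expect_equal(sum(vapply(g$nodes, function(n) n$op == "maxpool", TRUE)), 3)

  # feature vector has the configured final dense width
  expect_equal(g$nodes[[m$feature_id]]$units,
               tiny_cfg$cnn1_dense[2])
})

test_that("the Inception-style branch emits a 128-length feature vector", {
  m <- build_cnn2(tiny_cfg, seed = 2)
  img <- matrix(runif(32 * 32), 32, 32)
  p <- predict(m, img)
  expect_true(p >= 0 && p <= 1)
  expect_equal(m$graph$nodes[[m$feature_id]]$units, 128)

  # global average pooling emits one value per channel of the base
  g <- m$graph
  gap <- Filter(function(nd) nd$op == "gap", g$nodes)[[1]]
  expect_equal(gap$units, g$nodes[[gap$inputs[1]]]$channels)

  # the mixed blocks concatenate parallel paths
  expect_gte(sum(vapply(g$nodes, function(n) n$op == "concat", TRUE)), 2)
})

test_that("the fused model concatenates both branches into one sigmoid", {
  c1 <- build_cnn1(tiny_cfg, seed = 3)
  c2 <- build_cnn2(tiny_cfg, seed = 4)
  mf <- build_cnnf(c1, c2)
  img <- matrix(runif(32 * 32), 32, 32)
  p <- predict(mf, img)
  expect_true(p >= 0 && p <= 1)

  # concatenated feature length = shallow features + 128
  cc <- mf$graph$nodes[[mf$feature_id]]
  expect_equal(cc$units, tiny_cfg$cnn1_dense[2] + 128)
  # merge layer width
  dn <- Filter(function(nd) nd$op == "dense" &&
                 length(nd$inputs) && nd$inputs[1] == mf$feature_id,
               mf$graph$nodes)[[1]]
  expect_equal(dn$units, tiny_cfg$fusion_dense)

  # branch weights transferred from the standalone models
  expect_identical(mf$params[[mf$branch_ids[1]]],
                   c1$params[[c1$branch_ids[1]]])

  # both branches contribute: zeroing the shallow branch's weights moves
  # the fused output
  mz <- mf
  c1_ids <- mf$branch_ids[seq_along(c1$branch_ids)]
  for (id in c1_ids)
    if (!is.null(mz$params[[id]]))
      mz$params[[id]] <- lapply(mz$params[[id]], function(x) x * 0)
  expect_false(isTRUE(all.equal(predict(mz, img), p)))

  big <- clf_model_config_tiny(64L)
  expect_error(build_cnnf(build_cnn1(big), c2), "input sizes differ")
})

test_that("weighted BCE reduces to the hand-computed weighted mean", {
  p <- c(0.8, 0.3); y <- c(0, 1)
  b <- -log(1 - 0.8)   # benign sample's BCE
  m <- -log(0.3)       # malignant sample's BCE
  expect_equal(weighted_bce(p, y, c(1, 1)),
               mean(c(b, m)), tolerance = 1e-12)    # weight identity
  expect_equal(weighted_bce(p, y, c(1, 3)),
               (1 * b + 3 * m) / 2, tolerance = 1e-12)
  expect_error(clf_train_config(class_weight = c(benign = 0, malignant = 3)),
               "positive")
})

test_that("training a tiny classifier on a separable toy set learns it", {
  # bright squares (malignant) vs dim squares (benign): trivially separable
  set.seed(42)
  recs <- lapply(1:16, function(i) {
    x <- matrix(0, 32, 32)
    lvl <- if (i %% 2) 0.9 else 0.3
    x[10:20, 10:20] <- lvl + rnorm(121, sd = 0.02)
    list(x = pmin(pmax(x, 0), 1), y = as.numeric(i %% 2 == 1))
  })
  m <- build_cnn1(tiny_cfg, seed = 5)
  m <- train_classifier(m, recs,
                        clf_train_config(epochs = 60, batch_size = 8,
                                         class_weight = c(benign = 1,
                                                          malignant = 1),
                                         seed = 5))
  expect_gt(m$history$acc[nrow(m$history)], 0.9)
  expect_lt(m$history$loss[nrow(m$history)], m$history$loss[1])

  expect_warning(
    train_classifier(build_cnn1(tiny_cfg, seed = 1), recs[c(1, 3)],
                     clf_train_config(epochs = 1, seed = 1)),
    "single-class")
  expect_error(train_classifier(m, list(), clf_train_config()), "empty")
})

test_that("TTA averages the four dihedral views", {
  m <- build_cnnf(cfg = tiny_cfg, seed = 7)
  set.seed(7)
  for (i in 1:5) {
    img <- matrix(runif(32 * 32), 32, 32)
    res <- predict_tta(m, img)
    expect_length(res$tta_views, 4)
    expect_equal(res$pred_prob, mean(res$tta_views), tolerance = 1e-12)
    expect_equal(res$pred_label,
                 if (res$pred_prob >= 0.5) "malignant" else "benign")
  }
  # input symmetric under all four views: every view agrees
  sym <- matrix(0, 32, 32); sym[14:19, 14:19] <- 0.8
  res <- predict_tta(m, sym)
  expect_equal(max(res$tta_views) - min(res$tta_views), 0, tolerance = 1e-12)
  # tta = FALSE evaluates the original view only
  res1 <- predict_tta(m, sym, tta = FALSE)
  expect_length(res1$tta_views, 1)
  # a function model plugs in directly: views [0.2 0.4 0.6 0.8] average 0.5
  q <- local({ i <- 0; function(x) { i <<- i + 1; c(0.2, 0.4, 0.6, 0.8)[i] } })
  expect_equal(predict_tta(q, sym)$pred_prob, 0.5)
})
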