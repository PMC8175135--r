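test_that("confusion counts match exhaustive tallies", {
  p <- rep(c("malignant", "benign"), each = 5)
  y <- p
  cc <- confusion(p, y)
  expect_equal(unclass(cc)[c("tp", "tn", "fp", "fn")],
               list(tp = 5L, tn = 5L, fp = 0L, fn = 0L))

  y2 <- c(rep("malignant", 3), rep("benign", 7))
  cc2 <- confusion(rep("benign", 10), y2)
  expect_equal(cc2$fn, 3)
  expect_equal(cc2$tp, 0)

  # explicit 10-item tally
  pred <- c("malignant", "benign", "malignant", "benign", "malignant",
            "benign", "benign", "malignant", "benign", "malignant")
  true <- c("malignant", "malignant", "benign", "benign", "malignant",
            "benign", "malignant", "malignant", "benign", "benign")
  cc3 <- confusion(pred, true)
  tally <- table(pred, true)
  expect_equal(cc3$tp, unname(tally["malignant", "malignant"]))
  expect_equal(cc3$tn, unname(tally["benign", "benign"]))
  expect_equal(cc3$fp, unname(tally["malignant", "benign"]))
  expect_equal(cc3$fn, unname(tally["benign", "malignant"]))
  expect_error(confusion("benign", c("benign", "benign")), "length")
})

test_that("classification metrics follow their formulas and flag zeros", {
  r <- classification_metrics(
    structure(list(tp = 1L, tn = 1L, fp = 0L, fn = 0L),
              class = "confusion_counts"))
  for (nm in c("accuracy", "recall", "precision", "specificity", "f1"))
    expect_equal(r[[nm]], 1)

  r <- classification_metrics(
    structure(list(tp = 3L, tn = 5L, fp = 1L, fn = 1L),
              class = "confusion_counts"))
  expect_equal(r$accuracy, 0.8)
  expect_equal(r$recall, 0.75)
  expect_equal(r$precision, 0.75)
  expect_equal(r$specificity, 5 / 6)
  expect_equal(r$f1, 0.75)
  expect_length(r$flags, 0)

  # no positive predictions: precision undefined, flagged, not zero
  r <- classification_metrics(
    structure(list(tp = 0L, tn = 4L, fp = 0L, fn = 2L),
              class = "confusion_counts"))
  expect_true(is.na(r$precision))
  expect_true("precision" %in% r$flags)
})

test_that("rank-statistic AUC matches exhaustive pair counting", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  a <- roc_auc(c(0.2, 0.8), c(1, 1))
  expect_true(is.na(a))
  expect_true(attr(a, "undefined"))

  set.seed(17)
  for (i in 1:100) {
    n <- sample(4:20, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2)  # rounding forces ties
    expect_equal(roc_auc(s, y), brute_auc(s, y), tolerance = 1e-12)
  }
})

test_that("metrics agree with brute-force tallies on random label vectors", {
  set.seed(23)
  for (i in 1:200) {
    n <- sample(3:20, 1)
    pred <- sample(c("benign", "malignant"), n, TRUE)
    true <- sample(c("benign", "malignant"), n, TRUE)
    cc <- confusion(pred, true)
    tp <- sum(pred == "malignant" & true == "malignant")
    tn <- sum(pred == "benign" & true == "benign")
    fp <- sum(pred == "malignant" & true == "benign")
    fn <- sum(pred == "benign" & true == "malignant")
    expect_equal(unclass(cc)[c("tp", "tn", "fp", "fn")],
                 list(tp = tp, tn = tn, fp = fp, fn = fn))
    expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, n)
    r <- classification_metrics(cc)
    if (!is.na(r$recall) && !is.na(r$specificity)) {
      # accuracy is the prevalence-weighted mean of recall and specificity
      prev <- (tp + fn) / n
      expect_equal(r$accuracy,
                   prev * r$recall + (1 - prev) * r$specificity,
                   tolerance = 1e-12)
    }
  }
})

test_that("segmentation evaluation macro-averages per-image IOU", {
  m1p <- matrix(c(1, 1, 0, 0, 1, 0), 2); m1t <- matrix(c(1, 0, 1, 0, 1, 1), 2)
  m2 <- matrix(c(1, 0, 0, 0), 2)
  expect_equal(evaluate_segmentation(list(m1p, m2), list(m1t, m2)),
               mean(c(0.4, 1)), tolerance = 1e-6)
  expect_equal(evaluate_segmentation(list(m2), list(m2)), 1)
  z <- matrix(0, 2, 2)
  expect_equal(iou(z, z), 1)  # both-empty convention via smoothing
  expect_error(evaluate_segmentation(list(m2), list(m2, m2)), "length")
})
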