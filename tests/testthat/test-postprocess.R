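test_that("probability binarization uses the >= convention at the cut", {
  p <- matrix(c(0.29, 0.30, 0.31), 1, 3)
  expect_equal(as.integer(binarize_prediction(p, 0.3)), c(0L, 1L, 1L))
  expect_true(all(binarize_prediction(matrix(0, 4, 4)) == 0L))
  expect_error(binarize_prediction(p, 0), "threshold")
  expect_error(binarize_prediction(p, 1.2), "threshold")
  expect_error(binarize_prediction(matrix(1.5, 2, 2)), "outside")

  # monotone in the threshold: stricter cuts select a subset
  set.seed(6)
  r <- matrix(runif(400), 20, 20)
  f3 <- binarize_prediction(r, 0.3)
  f5 <- binarize_prediction(r, 0.5)
  expect_true(all(f3[f5 == 1L] == 1L))
})

test_that("noise filtering removes exactly the offending components", {
  m <- matrix(0L, 30, 40)
  m[5, 5] <- 1L                  # 1-px blob: below any sane area floor
  m[10:19, 10:19] <- 1L          # 10x10 square: passes
  m[25, 10:29] <- 1L             # 1x20 line: aspect 20
  m[22:26, 32:37] <- 1L          # 5x6 blob: passes
  out <- filter_noise(m, min_area = 5, max_aspect_ratio = 3)
  expect_equal(out[5, 5], 0L)
  expect_true(all(out[10:19, 10:19] == 1L))
  expect_true(all(out[25, 10:29] == 0L))
  expect_true(all(out[22:26, 32:37] == 1L))
  expect_identical(filter_noise(out, 5, 3), out)  # idempotent
  expect_error(filter_noise(m, min_area = 0), "min_area")

  single <- matrix(0L, 10, 10); single[4, 4] <- 1L
  expect_true(all(filter_noise(single, min_area = 5) == 0L))
})

test_that("instance splitting partitions the mask and orders instances", {
  expect_identical(split_nodules(matrix(0L, 16, 16)), list())

  m <- matrix(0L, 16, 16)
  m[2:5, 2:5] <- 1L
  m[10:13, 8:12] <- 1L
  inst <- split_nodules(m)
  expect_length(inst, 2)
  expect_s3_class(inst[[1]], "nodule_instance")
  # ordered by (row_min, col_min), 0-based half-open bboxes
  expect_equal(unname(inst[[1]]$bbox), c(1L, 1L, 5L, 5L))
  expect_equal(unname(inst[[2]]$bbox), c(9L, 7L, 13L, 12L))
  expect_equal(inst[[1]]$area, 16L)
  expect_equal(inst[[2]]$aspect_ratio, 5 / 4)
  # canvases OR-combine back to the input; areas conserve
  expect_identical(inst[[1]]$canvas | inst[[2]]$canvas, m == 1L)
  expect_equal(sum(vapply(inst, `[[`, 0L, "area")), sum(m))
  # each canvas is a single connected component
  for (i in inst)
    expect_equal(max(label_components(i$canvas)), 1)
})

test_that("a diagonal neck keeps a nodule whole under 8-connectivity", {
  m <- matrix(0L, 10, 10)
  m[2:4, 2:4] <- 1L
  m[5, 5] <- 1L
  m[6:8, 6:8] <- 1L
  expect_length(split_nodules(m), 1)
})

test_that("reference labels follow the mean-pixel rule with midpoint 1.5", {
  m <- matrix(0L, 8, 8); m[3:5, 3:5] <- 1L
  inst <- split_nodules(m)[[1]]
  truth1 <- matrix(0L, 8, 8); truth1[3:5, 3:5] <- 1L
  truth2 <- matrix(0L, 8, 8); truth2[3:5, 3:5] <- 2L
  expect_equal(assign_reference_label(inst, truth1), "benign")
  expect_equal(assign_reference_label(inst, truth2), "malignant")

  # mixed coverage: mean 1.6 (> 1.5) -> malignant; mean 1.4 -> benign
  mixed <- truth1
  vals <- c(rep(2L, 6), rep(1L, 3))  # 9 pixels, mean = 15/9 ~ 1.67
  mixed[3:5, 3:5] <- matrix(vals, 3, 3)
  expect_equal(assign_reference_label(inst, mixed), "malignant")
  mixed[3:5, 3:5] <- matrix(c(rep(2L, 3), rep(1L, 6)), 3, 3)  # mean 1.33
  expect_equal(assign_reference_label(inst, mixed), "benign")

  empty <- inst; empty$canvas <- matrix(0L, 8, 8)
  expect_error(assign_reference_label(empty, truth1), "empty")
})

test_that("the connector recovers planted nodules from truth masks", {
  for (ph in make_phantoms(20, 700)) {
    bin <- binarize_mask_for_segmentation(ph$mask)
    inst <- split_nodules(bin)
    expect_length(inst, length(ph$nodules))
    got <- sort(vapply(inst, assign_reference_label, "", truth = ph$mask))
    want <- sort(vapply(ph$nodules, `[[`, "", "label"))
    expect_equal(got, want)
    # bboxes match the generator's records after ordering
    ord <- order(vapply(ph$nodules, function(n) n$bbox[["row_min"]], 0),
                 vapply(ph$nodules, function(n) n$bbox[["col_min"]], 0))
    for (i in seq_along(inst))
      expect_equal(unname(inst[[i]]$bbox),
                   unname(unlist(ph$nodules[[ord[i]]]$bbox)))
  }
})
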