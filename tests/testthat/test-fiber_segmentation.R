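# fiber_segmentation: feature bank, classifier training/prediction,
# postprocessing, backend contract

test_that("feature stack has the stated layout and degenerate behavior", {
  scales <- c(1, 2, 4, 8, 16)
  fs <- compute_features(matrix(123, 32, 32), scales)
  expect_equal(dim(fs$features)[1], 5 * 6 + 1)
  expect_equal(fs$source_shape, c(32, 32))
  # constant image: Gaussian features equal the constant, all
  # derivative-type features exactly zero
  for (f in seq_along(fs$feature_names)) {
    nm <- fs$feature_names[f]
    if (grepl("^(raw|gaussian)", nm)) {
      expect_equal(max(abs(fs$features[f, , ] - 123)), 0,
                   tolerance = 1e-9, info = nm)
    } else if (!grepl("^dog", nm)) {
      expect_equal(max(abs(fs$features[f, , ])), 0, tolerance = 1e-9,
                   info = nm)
    }
  }
  expect_error(compute_features(array(1, c(2, 2, 2))), NULL)
})

test_that("Gaussian response at an impulse decreases monotonically in sigma", {
  img <- matrix(0, 65, 65)
  img[33, 33] <- 1000
  fs <- compute_features(img, c(1, 2, 4, 8))
  idx <- grep("^gaussian", fs$feature_names)
  peaks <- vapply(idx, function(f) fs$features[f, 33, 33], 1.0)
  expect_true(all(diff(peaks) < 0))
  # closed form: peak of a normalized 2-D Gaussian ~ 1/(2 pi sigma^2)
  expect_equal(peaks, 1000 / (2 * pi * c(1, 2, 4, 8)^2),
               tolerance = 0.05)
})

test_that("features are translation-equivariant on interior crops", {
  set.seed(42)
  img <- matrix(stats::runif(80 * 80, 0, 1000), 80, 80)
  sh <- rbind(img[6:80, ], img[1:5, ])      # shift down by 5
  f1 <- compute_features(img, c(1, 2))
  f2 <- compute_features(sh, c(1, 2))
  # compare deep-interior windows away from border effects
  expect_equal(f1$features[, 21:60, 21:60],
               f2$features[, 16:55, 21:60], tolerance = 1e-8)
})

test_that("classifier trains on strokes, is accurate and deterministic", {
  truth <- fixture_truth(101L)
  ch <- render_image(truth)
  strokes <- punctafiber:::.strokes_from_truth(truth$fiber_mask)
  clf <- train_classifier(list(ch$pgp95), list(strokes), n_trees = 30L)

  # training accuracy > 0.95 on its own labels
  prob <- predict_probability(clf, ch$pgp95)
  pred_fiber <- prob >= 0.5
  labeled <- strokes$fiber | strokes$background
  acc <- mean(pred_fiber[labeled] == strokes$fiber[labeled])
  expect_gt(acc, 0.95)
  expect_true(all(prob >= 0 & prob <= 1))
  # fiber-labeled region votes fiber on average; far background does not
  expect_gt(mean(prob[strokes$fiber]), 0.5)
  expect_lt(mean(prob[strokes$background]), 0.5)

  # determinism: same inputs + seed -> identical predictions
  clf2 <- train_classifier(list(ch$pgp95), list(strokes), n_trees = 30L)
  probe <- render_image(fixture_truth(202L))$pgp95
  expect_identical(predict_probability(clf, probe),
                   predict_probability(clf2, probe))

  # error paths
  empty <- matrix(FALSE, nrow(strokes$fiber), ncol(strokes$fiber))
  expect_error(
    train_classifier(list(ch$pgp95),
                     list(list(fiber = strokes$fiber,
                               background = empty))),
    "class underrepresented")
  expect_error(
    train_classifier(list(ch$pgp95),
                     list(list(fiber = strokes$fiber,
                               background = strokes$fiber))),
    "both classes")
  expect_error(
    train_classifier(list(ch$pgp95),
                     list(list(fiber = matrix(TRUE, 2, 2),
                               background = empty))),
    "shape mismatch")
})

test_that("all-background probe yields mean probability < 0.5", {
  truth <- fixture_truth(103L)
  ch <- render_image(truth)
  strokes <- punctafiber:::.strokes_from_truth(truth$fiber_mask)
  clf <- train_classifier(list(ch$pgp95), list(strokes), n_trees = 30L)
  blank_spec <- synthetic_spec(n_fibers = 0L, n_puncta_on = 0L,
                               n_puncta_off = 0L, seed = 55L)
  blank <- render_image(generate_ground_truth(blank_spec))$pgp95
  expect_lt(mean(predict_probability(clf, blank)), 0.5)
})

test_that("postprocess_mask applies threshold and small-object removal", {
  expect_true(all(postprocess_mask(matrix(0.6, 8, 8), 0.5,
                                   min_object_px = 1L)$pixels))
  # inclusive threshold: probability exactly 0.5 is kept
  expect_true(all(postprocess_mask(matrix(0.5, 8, 8), 0.5,
                                   min_object_px = 1L)$pixels))
  # a 3-pixel component vanishes at min_object_px = 10
  p <- matrix(0, 16, 16)
  p[3, 4:6] <- 1
  expect_false(any(postprocess_mask(p, 0.5, min_object_px = 10L)$pixels))
  expect_equal(sum(postprocess_mask(p, 0.5, min_object_px = 3L)$pixels),
               3)
  expect_error(postprocess_mask(p, 1.5), "\\[0, 1\\]")
})

test_that("segment honors both backend contracts", {
  truth <- fixture_truth(104L)
  ch <- render_image(truth)
  # external-mask backend: pass-through
  res <- segment(ch$pgp95, external_mask_backend(truth$fiber_mask))
  expect_identical(res$mask$pixels, truth$fiber_mask$pixels)
  expect_equal(res$backend_name, "external")
  expect_identical(dim(res$probability), dim(ch$pgp95$pixels))

  # classifier backend: shape + IoU on a high-contrast image
  strokes <- punctafiber:::.strokes_from_truth(truth$fiber_mask)
  clf <- train_classifier(list(ch$pgp95), list(strokes), n_trees = 50L)
  res2 <- segment(ch$pgp95, clf)
  expect_identical(dim(res2$probability), dim(ch$pgp95$pixels))
  expect_gte(iou(res2$mask, truth$fiber_mask), 0.7)

  expect_error(segment(ch$pgp95, "bogus"), "unknown segmentation backend")
})

test_that("classifier round-trips through its single-file serialization", {
  truth <- fixture_truth(105L)
  ch <- render_image(truth)
  strokes <- punctafiber:::.strokes_from_truth(truth$fiber_mask)
  clf <- train_classifier(list(ch$pgp95), list(strokes), n_trees = 10L,
                          scales = c(1, 2))
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_classifier(clf, tmp)
  clf2 <- load_classifier(tmp)
  expect_identical(clf2$feature_config, clf$feature_config)
  expect_identical(predict_probability(clf2, ch$pgp95),
                   predict_probability(clf, ch$pgp95))
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(load_classifier(bad), "not a punctafiber classifier")
})
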