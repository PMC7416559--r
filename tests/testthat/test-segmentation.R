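# Contrast adjustment, feature stacks, trainable classification, thresholds.

test_that("contrast adjustment rescales percentiles to [0, 1]", {
  img <- matrix(seq(0, 1, length.out = 100), 10, 10)
  expect_equal(adjust_contrast(img, 0, 100), img)
  two <- matrix(rep(c(0.4, 0.6), 50), 10, 10)
  stretched <- adjust_contrast(two, 0, 100)
  expect_setequal(unique(as.vector(stretched)), c(0, 1))
  const <- matrix(0.5, 10, 10)
  expect_warning(out <- adjust_contrast(const), "contrast")
  expect_equal(out, const)
  expect_error(adjust_contrast(img, 60, 40), "low_pct")
})

test_that("feature stack has 1 + 3 * scales features and zeroes on flat input", {
  img <- matrix(0.3, 32, 32)
  st <- compute_feature_stack(img, scales = c(1, 2))
  expect_equal(ncol(st), 7)
  expect_equal(nrow(st), 32 * 32)
  # flat image: smoothed = constant, gradient and Hessian exactly 0
  expect_true(all(abs(st[, "gauss_s1"] - 0.3) < 1e-12))
  expect_true(all(st[, "gradmag_s1"] == 0))
  expect_true(all(st[, "hessmax_s2"] == 0))
  expect_error(compute_feature_stack(img, scales = numeric(0)), "scales")
  expect_error(compute_feature_stack(img, scales = c(1, -2)), "positive")
})

make_labels <- function(truth, n_per_class, seed) {
  set.seed(seed)
  lab <- rep(NA_character_, length(truth))
  lab[sample(which(truth), n_per_class)] <- "fiber"
  lab[sample(which(!truth), n_per_class)] <- "background"
  lab
}

test_that("classifier separates a two-intensity image perfectly", {
  img <- matrix(0, 64, 64); img[20:40, ] <- 1
  truth <- img == 1
  st <- compute_feature_stack(img)
  lab <- make_labels(truth, 200, seed = 1)
  clf <- train_pixel_classifier(st, lab, seed = 5)
  pred <- classify_pixels(img, clf)
  expect_equal(pred, truth, ignore_attr = TRUE)
  # all-fiber-intensity image goes entirely to fiber
  allf <- matrix(1, 64, 64)
  expect_true(all(classify_pixels(allf, clf)))
})

test_that("classifier is deterministic and accurate on a noisy scene", {
  sp <- fiber_image_spec(image_size = c(128, 128), n_fibers = 30,
                         blur_sigma = 1, noise_sd = 0.05, seed = 2)
  sc <- generate_fiber_image(sp)
  truth <- sc$ground_truth$true_mask
  st <- compute_feature_stack(sc$image)
  lab <- make_labels(truth, 500, seed = 4)
  clf <- train_pixel_classifier(st, lab, seed = 9)
  pred <- classify_pixels(sc$image, clf)
  held_out <- is.na(lab)
  expect_gt(mean(pred[held_out] == truth[held_out]), 0.9)
  expect_gt(sum(pred & truth) / sum(pred | truth), 0.85)  # IoU
  clf2 <- train_pixel_classifier(st, lab, seed = 9)
  expect_identical(classify_pixels(sc$image, clf2), pred)
})

test_that("training requires both classes", {
  img <- matrix(runif(64), 8, 8)
  st <- compute_feature_stack(img, scales = 1)
  lab <- rep(NA_character_, 64); lab[1:5] <- "fiber"
  expect_error(train_pixel_classifier(st, lab), "background")
})

test_that("threshold segmentation recovers a bimodal mixture", {
  sp <- fiber_image_spec(image_size = c(128, 128), n_fibers = 30,
                         fiber_intensity = 0.8, background_intensity = 0.2,
                         blur_sigma = 0.5, noise_sd = 0.02, seed = 6)
  sc <- generate_fiber_image(sp)
  mask <- threshold_segment(sc$image, "otsu")
  truth <- sc$ground_truth$true_mask
  expect_gt(sum(mask & truth) / sum(mask | truth), 0.95)

  two <- matrix(rep(c(0.4, 0.6), 50), 10, 10)
  expect_equal(threshold_segment(two, "fixed", fixed_value = 0.5),
               two > 0.5, ignore_attr = TRUE)
  inv <- threshold_segment(two, "fixed", fixed_value = 0.5, fibers_bright = FALSE)
  expect_equal(inv, !(two > 0.5), ignore_attr = TRUE)
  expect_error(threshold_segment(matrix(0.5, 8, 8), "otsu"), "fixed")
})

test_that("fiber and background fractions always sum to one", {
  sp <- fiber_image_spec(image_size = c(96, 96), n_fibers = 25, seed = 8)
  sc <- generate_fiber_image(sp)
  mask <- threshold_segment(sc$image, "otsu")
  expect_equal(mean(mask) + mean(!mask), 1)
})

test_that("segmentation quality degrades monotonically with noise", {
  iou <- sapply(c(0.02, 0.10, 0.25), function(ns) {
    sp <- fiber_image_spec(image_size = c(128, 128), n_fibers = 30,
                           blur_sigma = 1, noise_sd = ns, seed = 13)
    sc <- generate_fiber_image(sp)
    mask <- threshold_segment(adjust_contrast(sc$image), "otsu")
    truth <- sc$ground_truth$true_mask
    sum(mask & truth) / sum(mask | truth)
  })
  expect_true(all(diff(iou) < 0))
})

test_that("thresholding after contrast adjustment ignores a constant shift", {
  sp <- fiber_image_spec(image_size = c(96, 96), n_fibers = 20,
                         fiber_intensity = 0.7, background_intensity = 0.2,
                         blur_sigma = 1, noise_sd = 0.03, seed = 21)
  img <- generate_fiber_image(sp)$image
  shifted <- matrix(pmin(1, img + 0.1), nrow(img), ncol(img))
  m1 <- threshold_segment(adjust_contrast(img), "otsu")
  m2 <- threshold_segment(adjust_contrast(shifted), "otsu")
  expect_gt(mean(m1 == m2), 0.99)
})
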