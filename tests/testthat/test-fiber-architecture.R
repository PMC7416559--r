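# Skeletonization, distance transform, diameter estimation.

test_that("a thick bar thins to a single centerline without branch points", {
  m <- matrix(FALSE, 20, 60); m[8:12, 5:55] <- TRUE
  sk <- skeletonize(m, min_component = 0)
  expect_true(all(m[sk$pixels]))                   # skeleton inside the mask
  expect_equal(nrow(sk$branch_points), 0)
  # 1-px wide: every skeleton column holds at most one pixel
  expect_true(all(colSums(sk$pixels) <= 1))
  # topology preserved: one component in, one out
  expect_equal(max(bf_components(sk$pixels, 8L)), 1)
})

test_that("a plus-shaped crossing yields one branch-point cluster", {
  m <- matrix(FALSE, 60, 60); m[28:32, ] <- TRUE; m[, 28:32] <- TRUE
  sk <- skeletonize(m, min_component = 0)
  expect_gt(nrow(sk$branch_points), 0)
  # all branch points fall in one 8-connected cluster at the crossing
  bpm <- matrix(FALSE, 60, 60); bpm[sk$branch_points] <- TRUE
  expect_equal(max(bf_components(bpm, 8L)), 1)
  expect_true(all(abs(sk$branch_points[, "row"] - 30) <= 3))
  expect_true(all(abs(sk$branch_points[, "col"] - 30) <= 3))
})

test_that("degenerate skeleton inputs behave", {
  m <- matrix(FALSE, 12, 12); m[6, 6] <- TRUE
  sk <- skeletonize(m, min_component = 0)
  expect_identical(which(sk$pixels), which(m))
  expect_warning(sk0 <- skeletonize(matrix(FALSE, 8, 8)), "empty")
  expect_equal(sum(sk0$pixels), 0)
  # components below min_component are dropped before thinning
  m2 <- matrix(FALSE, 20, 20); m2[3:4, 3:4] <- TRUE; m2[10:12, 2:18] <- TRUE
  sk2 <- skeletonize(m2, min_component = 10)
  expect_true(all(which(sk2$pixels, arr.ind = TRUE)[, 1] %in% 10:12))
})

test_that("distance transform matches brute force exactly on random masks", {
  set.seed(101)
  for (i in 1:20) {
    nr <- sample(5:40, 1); nc <- sample(5:40, 1)
    m <- matrix(runif(nr * nc) < runif(1, 0.3, 0.8), nr, nc)
    expect_equal(distance_transform(m), bf_distance_transform(m))
  }
})

test_that("distance transform analytic cases", {
  m <- matrix(TRUE, 10, 10); m[1, 1] <- FALSE
  d <- distance_transform(m)
  expect_equal(d[1, 4], 3)
  expect_equal(d[1, 1], 0)
  # bar of thickness 5: centerline sits 3 px from the first background row
  bar <- matrix(FALSE, 20, 20); bar[8:12, ] <- TRUE
  db <- distance_transform(bar)
  expect_equal(unique(db[10, ]), 3)
  expect_true(all(distance_transform(!bar)[bar] == 0))
})

test_that("diameters recover rendered widths within one pixel", {
  for (w in c(3, 5, 9)) {
    sp <- fiber_image_spec(image_size = c(128, 128), n_fibers = 1,
                           diameter_mean = w, diameter_sd = 0,
                           orientation_mu = 0, orientation_kappa = 1e6,
                           blur_sigma = 0, noise_sd = 0, seed = 3)
    m <- generate_fiber_image(sp)$ground_truth$true_mask
    dd <- estimate_fiber_diameters(m, skeletonize(m), distance_transform(m))
    expect_lt(abs(dd$summary$mean - w), 1)
  }
})

test_that("diameter estimates are monotone in the true width", {
  means <- sapply(c(3, 5, 9), function(w) {
    sp <- fiber_image_spec(image_size = c(128, 128), n_fibers = 1,
                           diameter_mean = w, diameter_sd = 0,
                           orientation_mu = 20, orientation_kappa = 1e6,
                           blur_sigma = 0, noise_sd = 0, seed = 3)
    m <- generate_fiber_image(sp)$ground_truth$true_mask
    estimate_fiber_diameters(m, skeletonize(m), distance_transform(m))$summary$mean
  })
  expect_true(all(diff(means) > 0))
})

uncorrected_skeleton <- function(sk) {
  structure(list(pixels = sk$pixels,
                 branch_points = sk$branch_points[0, , drop = FALSE]),
            class = "fiber_skeleton")
}

test_that("intersection correction removes crossing-inflated diameters", {
  # axis-aligned crossings: the EDT at the junction exceeds the fiber
  # radius, so pruning there strictly reduces the bias
  set.seed(88)
  for (i in 1:10) {
    r0 <- sample(20:70, 1); c0 <- sample(20:70, 1)
    m <- matrix(FALSE, 96, 96)
    m[(r0 - 2):(r0 + 2), ] <- TRUE
    m[, (c0 - 2):(c0 + 2)] <- TRUE
    sk <- skeletonize(m)
    expect_gt(nrow(sk$branch_points), 0)
    dm <- distance_transform(m)
    corrected <- estimate_fiber_diameters(m, sk, dm)
    uncorrected <- estimate_fiber_diameters(m, uncorrected_skeleton(sk), dm)
    expect_lt(corrected$summary$n, uncorrected$summary$n)
    expect_lte(abs(corrected$summary$mean - 5),
               abs(uncorrected$summary$mean - 5) + 1e-9)
    expect_lt(abs(corrected$summary$mean - 5), 1)
  }
})

test_that("correction stays within discretization jitter on oblique crossings", {
  # oblique bars carry a small negative discretization bias that pruning
  # cannot remove; the correction must not degrade the estimate beyond it
  set.seed(77)
  for (i in 1:10) {
    sp <- fiber_image_spec(image_size = c(96, 96), n_fibers = 2,
                           diameter_mean = 5, diameter_sd = 0,
                           orientation_kappa = 0, blur_sigma = 0,
                           noise_sd = 0, seed = 1000 + i)
    m <- generate_fiber_image(sp)$ground_truth$true_mask
    sk <- skeletonize(m)
    if (nrow(sk$branch_points) == 0) next   # bars did not cross in frame
    dm <- distance_transform(m)
    corrected <- estimate_fiber_diameters(m, sk, dm)
    uncorrected <- estimate_fiber_diameters(m, uncorrected_skeleton(sk), dm)
    expect_lt(corrected$summary$n, uncorrected$summary$n)
    expect_lte(abs(corrected$summary$mean - 5),
               abs(uncorrected$summary$mean - 5) + 0.15)
    expect_lt(abs(corrected$summary$mean - 5), 1)
  }
})

test_that("calibration converts pixel diameters to nanometers", {
  sp <- fiber_image_spec(image_size = c(96, 96), pixel_size = 20, n_fibers = 1,
                         diameter_mean = 5, diameter_sd = 0,
                         orientation_mu = 0, orientation_kappa = 1e6,
                         blur_sigma = 0, noise_sd = 0, seed = 3)
  m <- generate_fiber_image(sp)$ground_truth$true_mask
  dd <- estimate_fiber_diameters(m, skeletonize(m), distance_transform(m))
  expect_equal(dd$pixels$diameter_nm, dd$pixels$diameter_px * 20)
  expect_equal(stats::median(dd$pixels$diameter_nm), 100)
})

test_that("fiber summaries bin diameters with conserved counts", {
  sp <- fiber_image_spec(image_size = c(96, 96), n_fibers = 8, seed = 15)
  m <- generate_fiber_image(sp)$ground_truth$true_mask
  dd <- estimate_fiber_diameters(m, skeletonize(m), distance_transform(m))
  fs <- fiber_summary(dd, bin_width = 0.5)
  expect_equal(sum(fs$histogram$count), dd$summary$n)
  expect_error(fiber_summary(dd, bin_width = 0), "bin_width")
  # constant distribution occupies a single bin
  dd3 <- dd
  dd3$pixels <- dd$pixels[1:3, ]; dd3$pixels$diameter_px <- c(5, 5, 5)
  dd3$summary <- list(mean = 5, median = 5, sd = 0, n = 3)
  fs3 <- fiber_summary(dd3, bin_width = 1)
  expect_equal(sum(fs3$histogram$count > 0), 1)
})
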