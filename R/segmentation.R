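# Fiber/background pixel classification.
#
# Two routes to a binary fiber mask: a trainable per-pixel classifier (a
# seeded tree ensemble over a multiscale intensity/gradient/Hessian feature
# stack, the standard trainable-segmentation recipe), and a deterministic
# thresholding fallback (Otsu or fixed) for pipelines without annotations.

#' Percentile-based contrast stretch
#'
#' Linearly rescales intensities so that the `low_pct` and `high_pct`
#' percentiles map to 0 and 1, clipping beyond. The defaults (1, 99) are
#' robust to a few saturated pixels.
#'
#' @param image numeric matrix in [0, 1].
#' @param low_pct,high_pct percentiles in [0, 100], low < high.
#' @return rescaled image; a constant image is returned unchanged with a
#'   warning.
#' @export
adjust_contrast <- function(image, low_pct = 1, high_pct = 99) {
  check_image(image)
  check_number(low_pct, "low_pct", min = 0, max = 100)
  check_number(high_pct, "high_pct", min = 0, max = 100)
  if (low_pct >= high_pct) stopf("'low_pct' must be < 'high_pct'")
  q <- stats::quantile(image, c(low_pct, high_pct) / 100, names = FALSE)
  if (q[2] <= q[1]) {
    warnf("image has no contrast to stretch; returned unchanged")
    return(image)
  }
  out <- pmin(1, pmax(0, (image - q[1]) / (q[2] - q[1])))
  attributes(out) <- attributes(image)
  out
}

#' Multiscale per-pixel feature stack
#'
#' For each smoothing scale sigma: Gaussian-smoothed intensity, gradient
#' magnitude of the smoothed image, and the largest (signed) eigenvalue of
#' its Hessian; plus the raw intensity. Feature count = 1 + 3 * |scales|.
#'
#' @param image numeric matrix in [0, 1].
#' @param scales positive smoothing scales in px (default c(1, 2, 4)).
#' @return `feature_stack`: numeric matrix, one row per pixel (column-major
#'   pixel order), with attributes `scales` and `image_dim`.
#' @export
compute_feature_stack <- function(image, scales = c(1, 2, 4)) {
  check_image(image)
  if (length(scales) < 1L) stopf("'scales' must be non-empty")
  if (any(scales <= 0)) stopf("'scales' must all be positive")
  feats <- list(intensity = as.vector(image))
  # differentiate first, then smooth: the operators commute and a constant
  # image then yields exactly-zero gradient and Hessian features
  dx <- central_diff(image, along = "col")
  dy <- central_diff(image, along = "row")
  for (s in scales) {
    sm <- gaussian_smooth(image, s)
    gx <- gaussian_smooth(dx, s)
    gy <- gaussian_smooth(dy, s)
    hxx <- central_diff(gx, along = "col")
    hyy <- central_diff(gy, along = "row")
    hxy <- central_diff(gx, along = "row")
    lam <- ((hxx + hyy) + sqrt((hxx - hyy)^2 + 4 * hxy^2)) / 2
    feats[[sprintf("gauss_s%g", s)]] <- as.vector(sm)
    feats[[sprintf("gradmag_s%g", s)]] <- as.vector(sqrt(gx^2 + gy^2))
    feats[[sprintf("hessmax_s%g", s)]] <- as.vector(lam)
  }
  out <- do.call(cbind, feats)
  structure(out, scales = scales, image_dim = dim(image), class = "feature_stack")
}

# Centered difference with replicated edges (one-sided at the border).
central_diff <- function(m, along = c("row", "col")) {
  along <- match.arg(along)
  n <- if (along == "row") nrow(m) else ncol(m)
  ip <- c(2:n, n); im <- c(1, 1:(n - 1))
  if (along == "row") (m[ip, , drop = FALSE] - m[im, , drop = FALSE]) / 2
  else (m[, ip, drop = FALSE] - m[, im, drop = FALSE]) / 2
}

#' Train a fiber/background pixel classifier
#'
#' Fits a seeded random-forest over sparse pixel annotations. The feature
#' configuration is stored on the classifier so unseen images are featurized
#' identically at prediction time.
#'
#' @param features a [compute_feature_stack()] result.
#' @param labels character/factor vector of length n_pixels with values
#'   "fiber"/"background" and NA for unlabeled pixels, or a logical matrix of
#'   the image shape (TRUE = fiber, NA = unlabeled).
#' @param seed integer seed (training is deterministic given the seed).
#' @param num_trees forest size.
#' @return object of class `pixel_classifier`.
#' @export
train_pixel_classifier <- function(features, labels, seed = 1L, num_trees = 100L) {
  if (!inherits(features, "feature_stack")) stopf("'features' must be a feature_stack")
  seed <- check_count(seed, "seed", min = 0L)
  if (is.matrix(labels)) labels <- ifelse(is.na(labels), NA_character_,
                                          ifelse(labels, "fiber", "background"))
  labels <- as.character(labels)
  if (length(labels) != nrow(features))
    stopf("'labels' must have one entry per pixel (%d)", nrow(features))
  keep <- !is.na(labels)
  present <- unique(labels[keep])
  for (cl in c("fiber", "background"))
    if (!cl %in% present) stopf("no '%s' pixels among the annotations", cl)
  df <- as.data.frame(unclass(features)[keep, , drop = FALSE])
  df$.label <- factor(labels[keep], levels = c("background", "fiber"))
  # ranger draws from both its own seed and the R RNG; pin both so training
  # is a pure function of (features, labels, seed)
  fit <- withr::with_seed(seed,
    ranger::ranger(.label ~ ., data = df, num.trees = num_trees,
                   seed = seed, num.threads = 1L))
  structure(list(model = fit, scales = attr(features, "scales"), seed = seed),
            class = "pixel_classifier")
}

#' Classify every pixel of an image as fiber or background
#'
#' @param image numeric matrix in [0, 1].
#' @param classifier a [train_pixel_classifier()] result.
#' @return logical mask (TRUE = fiber) carrying the image's calibration.
#' @export
classify_pixels <- function(image, classifier) {
  check_image(image)
  if (!inherits(classifier, "pixel_classifier")) stopf("'classifier' must be a pixel_classifier")
  stack <- compute_feature_stack(image, classifier$scales)
  df <- as.data.frame(unclass(stack))
  # ties in the majority vote are broken randomly; pin the seed so a trained
  # classifier always yields the same mask
  pred <- stats::predict(classifier$model, data = df, num.threads = 1L,
                         seed = classifier$seed)$predictions
  mask <- matrix(pred == "fiber", nrow(image), ncol(image))
  set_pixel_size(mask, pixel_size_of(image))
}

#' Threshold-based fiber segmentation
#'
#' Deterministic fallback when no training annotations exist. With
#' `fibers_bright = TRUE` (secondary-electron SEM convention) pixels above the
#' threshold are fiber; the flag inverts the polarity exactly.
#'
#' @param image numeric matrix in [0, 1].
#' @param method "otsu" or "fixed".
#' @param fixed_value threshold in (0, 1) when `method = "fixed"`.
#' @param fibers_bright polarity flag.
#' @return logical mask (TRUE = fiber).
#' @export
threshold_segment <- function(image, method = c("otsu", "fixed"),
                              fixed_value = NULL, fibers_bright = TRUE) {
  check_image(image)
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(fixed_value)) stopf("'fixed_value' is required when method = \"fixed\"")
    check_number(fixed_value, "fixed_value", min = 0, max = 1)
    if (fixed_value <= 0 || fixed_value >= 1) stopf("'fixed_value' must be in (0, 1)")
    thr <- fixed_value
  } else {
    if (diff(range(image)) == 0)
      stopf("constant image: Otsu is undefined; use method = \"fixed\"")
    thr <- EBImage::otsu(EBImage::Image(image), range = c(0, 1))
  }
  mask <- if (fibers_bright) image > thr else image <= thr
  set_pixel_size(mask, pixel_size_of(image))
}
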