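# Internal helpers shared across modules.
#
# Conventions used throughout the package (stated once, used everywhere):
#  * images are numeric matrices indexed [row, col], 1-based, origin top-left;
#  * intensities live in [0, 1]; masks are logical matrices with TRUE = fiber;
#  * angles are degrees in [-90, 90), 0 deg = +x axis (columns increasing),
#    counter-clockwise positive with the y axis pointing up (rows decreasing);
#  * physical calibration is a "pixel_size" attribute in nm/px (NA if unknown).

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (strict_min && x <= min) stopf("'%s' must be > %g (got %g)", name, min, x)
  if (!strict_min && x < min) stopf("'%s' must be >= %g (got %g)", name, min, x)
  if (x > max) stopf("'%s' must be <= %g (got %g)", name, max, x)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stopf("'%s' must be an integer >= %d", name, min)
  as.integer(x)
}

check_image <- function(img, name = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stopf("'%s' must be a numeric matrix", name)
  if (nrow(img) < 2L || ncol(img) < 2L)
    stopf("'%s' must be at least 2x2", name)
  if (anyNA(img) || any(!is.finite(img)))
    stopf("'%s' contains non-finite values", name)
  if (min(img) < 0 || max(img) > 1)
    stopf("'%s' must have intensities in [0, 1]; rescale on load", name)
  invisible(img)
}

check_mask <- function(mask, name = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stopf("'%s' must be a logical matrix (TRUE = fiber)", name)
  if (anyNA(mask)) stopf("'%s' contains NA", name)
  invisible(mask)
}

pixel_size_of <- function(x) {
  ps <- attr(x, "pixel_size")
  if (is.null(ps)) NA_real_ else ps
}

set_pixel_size <- function(x, pixel_size) {
  attr(x, "pixel_size") <- pixel_size
  x
}

#' Fold angles into the axial range [-90, 90)
#'
#' Fiber orientations are undirected (a fiber at 170 deg is the same fiber as
#' one at -10 deg), so all angles in the package live on the half-open axial
#' range.
#'
#' @param a numeric vector of angles in degrees.
#' @return angles folded into [-90, 90).
#' @export
fold_angle <- function(a) ((a + 90) %% 180) - 90

#' Circular mean of axial angles
#'
#' Mean direction on the doubled-angle circle, folded back to [-90, 90).
#' Appropriate for undirected (nematic) orientation data.
#'
#' @param a numeric vector of angles in degrees.
#' @return scalar mean angle in degrees.
#' @export
axial_mean <- function(a) {
  if (length(a) == 0L) stopf("cannot take the mean of zero angles")
  r <- a * pi / 90  # doubled angle in radians
  fold_angle(atan2(mean(sin(r)), mean(cos(r))) * 90 / pi)
}

# Gaussian smoothing with replicate boundary; kernel radius capped so the
# filter fits the image (EBImage::filter2 requires filter <= image).
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- min(ceiling(3 * sigma), floor((min(dim(m)) - 1) / 2))
  if (r < 1L) return(m)
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "Gaussian", sigma = sigma)
  EBImage::imageData(EBImage::filter2(EBImage::Image(m), brush, boundary = "replicate"))
}

# Connected-component labeling with selectable connectivity.
# Returns an integer matrix, 0 = background.
label_components <- function(mask, connectivity = 4L) {
  check_mask(mask)
  if (!connectivity %in% c(4L, 8L)) stopf("'connectivity' must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(lab)
  id <- integer(nr * nc); id[idx] <- seq_along(idx)
  edge_pairs <- function(dr, dc) {
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    ok <- r + dr >= 1L & r + dr <= nr & c + dc >= 1L & c + dc <= nc
    nb <- (c[ok] + dc - 1L) * nr + (r[ok] + dr)
    keep <- mask[nb]
    cbind(id[idx[ok][keep]], id[nb[keep]])
  }
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  edges <- do.call(rbind, lapply(shifts, function(s) edge_pairs(s[1], s[2])))
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L)
    g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}

# Binary dilation with a Euclidean disc of the given pixel radius.
dilate_mask <- function(mask, radius) {
  check_mask(mask)
  radius <- check_count(radius, "radius", min = 0L)
  if (radius == 0L) return(mask)
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  out <- EBImage::imageData(EBImage::dilate(EBImage::Image(mask * 1), brush)) > 0.5
  dim(out) <- dim(mask)
  out
}

# Deterministic per-stage seed derivation; stays below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 9973) %% 2147483629)
}
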