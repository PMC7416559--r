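# Structure-tensor orientation analysis.
#
# The structure tensor is the Gaussian-smoothed outer product of the image
# gradient. Its eigenvalues describe local anisotropy: the dominant
# eigenvector points across the texture (direction of maximal intensity
# variation), so the fiber axis reported here is the perpendicular,
# minimal-variation direction. Coherence (l1 - l2)/(l1 + l2) is 1 for a
# perfectly oriented texture and 0 for isotropic structure; energy l1 + l2
# separates textured pixels from flat background.

#' Per-pixel orientation field from the structure tensor
#'
#' Gradients are centered differences after a 1-px Gaussian pre-smooth;
#' tensor components are smoothed with a Gaussian window of sigma
#' `window_sigma` (default 7 px). The reported angle is the local fiber axis
#' in degrees in [-90, 90) (0 deg = x axis, CCW positive); pixels with zero
#' gradient energy have an undefined (NA) angle.
#'
#' @param image numeric matrix in [0, 1].
#' @param window_sigma tensor-smoothing Gaussian sigma in px.
#' @param presmooth_sigma gradient pre-smoothing sigma in px.
#' @return object of class `orientation_field` with matrices `angle` (deg),
#'   `coherence` in [0, 1], and `energy` (>= 0).
#' @export
structure_tensor_field <- function(image, window_sigma = 7, presmooth_sigma = 1) {
  check_image(image)
  check_number(window_sigma, "window_sigma", min = 0, strict_min = TRUE)
  check_number(presmooth_sigma, "presmooth_sigma", min = 0)
  # differentiate, then presmooth (the operators commute; this order leaves
  # a constant image with exactly zero gradients)
  gx <- gaussian_smooth(central_diff(image, along = "col"), presmooth_sigma)
  gy <- -gaussian_smooth(central_diff(image, along = "row"), presmooth_sigma)  # y up
  jxx <- gaussian_smooth(gx * gx, window_sigma)
  jyy <- gaussian_smooth(gy * gy, window_sigma)
  jxy <- gaussian_smooth(gx * gy, window_sigma)
  energy <- jxx + jyy
  disc <- sqrt((jxx - jyy)^2 + 4 * jxy^2)
  eps <- 1e-12
  coherence <- ifelse(energy > eps, disc / energy, 0)
  # dominant direction (max variation), then +90 deg for the fiber axis
  phi <- 0.5 * atan2(2 * jxy, jxx - jyy) * 180 / pi
  angle <- fold_angle(phi + 90)
  angle[energy <= eps] <- NA_real_
  structure(list(angle = angle, coherence = pmin(coherence, 1), energy = energy),
            class = "orientation_field")
}

#' Sample orientations along dilated fiber centerlines
#'
#' Enlarges the skeleton by `dilation_px` (default 2 px, a disc radius) and
#' reads the orientation field at the dilated-centerline pixels whose tensor
#' energy exceeds a floor (default: the median image energy, which excludes
#' background pixels swept in by the dilation).
#'
#' @param field a [structure_tensor_field()] result.
#' @param skeleton a [skeletonize()] result from the same image/mask pair.
#' @param dilation_px non-negative dilation radius.
#' @param energy_floor numeric floor, or "median" (default).
#' @return numeric vector of sampled angles in degrees.
#' @export
centerline_orientations <- function(field, skeleton, dilation_px = 2L,
                                    energy_floor = "median") {
  if (!inherits(field, "orientation_field")) stopf("'field' must be an orientation_field")
  if (!inherits(skeleton, "fiber_skeleton")) stopf("'skeleton' must be a fiber_skeleton")
  if (!all(dim(field$angle) == dim(skeleton$pixels)))
    stopf("field and skeleton shapes differ; were they derived from the same image?")
  if (!any(skeleton$pixels)) {
    warnf("empty skeleton: no orientations to sample")
    return(numeric(0))
  }
  sel <- dilate_mask(skeleton$pixels, dilation_px)
  floor_val <- if (identical(energy_floor, "median")) stats::median(field$energy)
               else check_number(energy_floor, "energy_floor", min = 0)
  keep <- sel & field$energy > floor_val & !is.na(field$angle)
  field$angle[keep]
}

#' Angular histogram of fiber orientations
#'
#' Normalized probability distribution over [-90, 90); peaks are bins whose
#' weight exceeds both circular neighbors.
#'
#' @param angles numeric vector of angles in degrees (non-empty).
#' @param n_bins number of equal-width bins (default 36, i.e. 5 deg).
#' @return object of class `orientation_distribution`: `bin_edges`,
#'   `bin_centers`, `weights` (summing to 1), `peaks` (bin-center angles).
#' @export
orientation_distribution <- function(angles, n_bins = 36L) {
  if (length(angles) == 0L) stopf("'angles' is empty")
  n_bins <- check_count(n_bins, "n_bins", min = 2L)
  a <- fold_angle(angles)
  edges <- seq(-90, 90, length.out = n_bins + 1L)
  bin <- pmin(findInterval(a, edges, rightmost.closed = FALSE), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  w <- counts / sum(counts)
  nxt <- c(2:n_bins, 1L); prv <- c(n_bins, 1:(n_bins - 1L))
  peaks <- which(w > w[nxt] & w > w[prv])
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  structure(list(bin_edges = edges, bin_centers = centers, weights = w,
                 peaks = centers[peaks], n = length(a)),
            class = "orientation_distribution")
}

#' Nematic order parameter of an angle sample
#'
#' S = |mean of (cos 2t, sin 2t)| over the sampled orientations: 1 for
#' perfectly parallel fibers, 0 for an isotropic network. The doubled angle
#' respects the 180-degree ambiguity of undirected fibers.
#'
#' @param angles numeric vector of angles in degrees (non-empty).
#' @return object of class `alignment_score`: `S` in [0, 1], `n_samples`.
#' @export
alignment_score <- function(angles) {
  if (length(angles) == 0L) stopf("'angles' is empty")
  r <- angles * pi / 90
  s <- sqrt(mean(cos(r))^2 + mean(sin(r))^2)
  structure(list(S = min(1, s), n_samples = length(angles)),
            class = "alignment_score")
}
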