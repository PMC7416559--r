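# Fiber diameter estimation from a binary mask.
#
# The estimator follows the classic centerline/EDT recipe: axially thin the
# fiber mask to 1-px centerlines, take the exact Euclidean distance transform
# of the mask, read the transform along the centerlines, excise centerline
# pixels near fiber intersections (branch points), and convert the remaining
# centerline distances to diameters.

#' Skeletonize a fiber mask by axial thinning
#'
#' Zhang-Suen thinning to 1-px-wide, connectivity-preserving centerlines.
#' Connected fiber components smaller than `min_component` pixels are dropped
#' first (segmentation specks carry no diameter information). Branch points
#' are skeleton pixels whose 8-neighborhood crossing number (count of 0->1
#' transitions in the cyclic neighbor sequence) is >= 3: these are true
#' junctions where centerlines meet. A raw neighbor count would also flag
#' every step of the staircase that a 1-px diagonal centerline necessarily
#' forms, which is why the crossing number is used instead.
#'
#' @param mask logical matrix, TRUE = fiber.
#' @param min_component minimum fiber component area kept (px, default 10).
#' @return object of class `fiber_skeleton`: `pixels` (logical matrix),
#'   `branch_points` (integer matrix of row/col coordinates).
#' @export
skeletonize <- function(mask, min_component = 10L) {
  check_mask(mask)
  min_component <- check_count(min_component, "min_component", min = 0L)
  if (!any(mask)) {
    warnf("empty mask: returning an empty skeleton")
    return(structure(list(pixels = mask & FALSE,
                          branch_points = matrix(integer(), 0, 2,
                                                 dimnames = list(NULL, c("row", "col")))),
                     class = "fiber_skeleton"))
  }
  if (min_component > 1L) {
    lab <- label_components(mask, connectivity = 8L)
    sizes <- tabulate(lab)
    keep <- which(sizes >= min_component)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  skel <- thin_zhang_suen(mask)
  bp <- which(skel & transition_count(skel) >= 3L, arr.ind = TRUE)
  colnames(bp) <- c("row", "col")
  structure(list(pixels = skel, branch_points = bp), class = "fiber_skeleton")
}

# Vectorized Zhang-Suen thinning. Neighbor order p2..p9 = N, NE, E, SE, S,
# SW, W, NW around each pixel (rows grow downward).
thin_zhang_suen <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  shift <- function(x, dr, dc) {
    out <- matrix(FALSE, nrow(x), ncol(x))
    rs <- (1 + max(0, dr)):(nrow(x) + min(0, dr))
    cs <- (1 + max(0, dc)):(ncol(x) + min(0, dc))
    out[rs, cs] <- x[rs - dr, cs - dc]
    out
  }
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- lapply(offs, function(o) shift(p, o[1], o[2]))
      B <- Reduce(`+`, nb)
      cyc <- c(nb, nb[1])
      A <- Reduce(`+`, lapply(1:8, function(k) !cyc[[k]] & cyc[[k + 1]]))
      if (step == 1) {
        c3 <- !(nb[[1]] & nb[[3]] & nb[[5]])  # P2*P4*P6 == 0
        c4 <- !(nb[[3]] & nb[[5]] & nb[[7]])  # P4*P6*P8 == 0
      } else {
        c3 <- !(nb[[1]] & nb[[3]] & nb[[7]])  # P2*P4*P8 == 0
        c4 <- !(nb[[1]] & nb[[5]] & nb[[7]])  # P2*P6*P8 == 0
      }
      del <- p & B >= 2 & B <= 6 & A == 1 & c3 & c4
      if (any(del)) { p[del] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  p[2:(nr + 1L), 2:(nc + 1L)]
}

# 8-neighbor count of TRUE pixels for each pixel.
neighbor_count <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  acc <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    acc <- acc + p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  acc
}

# Per-pixel maximum of the distance transform over the 8-neighborhood,
# restricted to fiber pixels: the EDT ridge value nearest each centerline
# pixel.
ridge_distance <- function(dmap, mask) {
  nr <- nrow(dmap); nc <- ncol(dmap)
  p <- matrix(-Inf, nr + 2L, nc + 2L)
  core <- dmap
  core[!mask] <- -Inf
  p[2:(nr + 1L), 2:(nc + 1L)] <- core
  acc <- core
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    acc <- pmax(acc, p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)])
  }
  acc
}

# Crossing number: 0->1 transitions in the cyclic 8-neighbor sequence
# (N, NE, E, SE, S, SW, W, NW). 1 at line ends, 2 along a line, >= 3 at
# junctions.
transition_count <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  nb <- lapply(offs, function(o)
    p[(2 + o[1]):(nr + 1 + o[1]), (2 + o[2]):(nc + 1 + o[2])])
  cyc <- c(nb, nb[1])
  Reduce(`+`, lapply(1:8, function(k) !cyc[[k]] & cyc[[k + 1]]))
}

#' Exact Euclidean distance transform of a fiber mask
#'
#' Per-pixel Euclidean distance (px) from each fiber pixel to the nearest
#' non-fiber pixel in the image; exactly 0 on non-fiber pixels. Distances are
#' exact (not chamfer approximations). Fiber pixels of a mask with no
#' background at all are at infinite distance.
#'
#' @param mask logical matrix, TRUE = fiber.
#' @return numeric matrix of distances.
#' @export
distance_transform <- function(mask) {
  check_mask(mask)
  if (!any(!mask)) {
    d <- matrix(Inf, nrow(mask), ncol(mask))
    d[!mask] <- 0
    return(d)
  }
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1),
                                           metric = "euclidean"))
  dim(d) <- dim(mask)
  d[!mask] <- 0
  d
}

#' Estimate fiber diameters along centerlines
#'
#' Reads the distance transform along the skeleton, removes centerline pixels
#' lying within the intersection-influence radius of every branch point b
#' (Euclidean distance <= dmap(b); ties removed), and converts centerline
#' distances to diameters as `2 * d - 1`. Two calibration details: (i) the -1
#' accounts for the pixel-count convention of the transform — the centerline
#' of a bar rendered t px thick (t odd) sits (t+1)/2 px from the nearest
#' background pixel center, so plain doubling would overestimate every
#' axis-aligned width by one pixel; (ii) d is read as the maximum of the
#' transform over the centerline pixel's 8-neighborhood (restricted to fiber
#' pixels), because thinning places oblique centerlines on a staircase that
#' is up to half a pixel off the true EDT ridge, which would otherwise bias
#' oblique diameters low. On noiseless axis-aligned bars the estimate equals
#' the rendered width exactly. Centerline pixels whose distance value exceeds
#' their distance to the image border are censored: the fiber is cut by the
#' frame there and its true radius is unknowable, the same reasoning that
#' excludes border-touching pores.
#'
#' @param mask logical fiber mask.
#' @param skeleton a [skeletonize()] result derived from `mask`.
#' @param dmap a [distance_transform()] result derived from `mask`.
#' @return object of class `fiber_diameters`: data.frame `pixels` (row, col,
#'   diameter_px, diameter_nm), `summary` (mean, median, sd, n), counts of
#'   skeleton and retained pixels.
#' @export
estimate_fiber_diameters <- function(mask, skeleton, dmap) {
  check_mask(mask)
  if (!inherits(skeleton, "fiber_skeleton")) stopf("'skeleton' must be a fiber_skeleton")
  if (!all(dim(dmap) == dim(mask))) stopf("'dmap' shape differs from 'mask'")
  if (any(skeleton$pixels & !mask))
    stopf("skeleton has pixels outside the mask; were they derived from the same mask?")
  cl <- which(skeleton$pixels, arr.ind = TRUE)
  keep <- rep(TRUE, nrow(cl))
  bp <- skeleton$branch_points
  if (nrow(bp) > 0L && nrow(cl) > 0L) {
    for (i in seq_len(nrow(bp))) {
      r <- dmap[bp[i, "row"], bp[i, "col"]]
      d2 <- (cl[, 1] - bp[i, "row"])^2 + (cl[, 2] - bp[i, "col"])^2
      keep <- keep & d2 > r^2
    }
  }
  cl <- cl[keep, , drop = FALSE]
  ridge <- ridge_distance(dmap, mask)
  dvals <- ridge[cl]
  # border censoring: where the EDT disc would extend beyond the frame the
  # distance to the nearest pore is unknown (the fiber is cut by the image
  # edge), so those centerline pixels carry no valid diameter
  border_dist <- pmin(cl[, 1], nrow(mask) + 1 - cl[, 1],
                      cl[, 2], ncol(mask) + 1 - cl[, 2])
  ok <- is.finite(dvals) & dvals > 0 & dvals <= border_dist
  cl <- cl[ok, , drop = FALSE]
  diam <- 2 * dvals[ok] - 1
  ps <- pixel_size_of(mask)
  px <- data.frame(row = cl[, 1], col = cl[, 2], diameter_px = diam,
                   diameter_nm = if (is.na(ps)) NA_real_ else diam * ps)
  if (nrow(px) == 0L)
    warnf("intersection correction removed every centerline pixel; empty distribution")
  structure(list(pixels = px,
                 summary = list(mean = if (nrow(px)) mean(diam) else NA_real_,
                                median = if (nrow(px)) stats::median(diam) else NA_real_,
                                sd = if (nrow(px) > 1) stats::sd(diam) else NA_real_,
                                n = nrow(px)),
                 n_skeleton = sum(skeleton$pixels), n_retained = nrow(px),
                 pixel_size = ps),
            class = "fiber_diameters")
}

#' Histogram and summary of a fiber-diameter distribution
#'
#' @param dist a [estimate_fiber_diameters()] result (non-empty).
#' @param bin_width histogram bin width in px (> 0); bins are right-open.
#' @return list with `histogram` (data.frame bin_left, bin_right, count) and
#'   `summary` (mean, median, sd, n); counts sum to n.
#' @export
fiber_summary <- function(dist, bin_width = 1) {
  if (!inherits(dist, "fiber_diameters")) stopf("'dist' must be a fiber_diameters object")
  check_number(bin_width, "bin_width", min = 0, strict_min = TRUE)
  d <- dist$pixels$diameter_px
  if (length(d) == 0L) stopf("empty diameter distribution")
  lo <- floor(min(d) / bin_width) * bin_width
  edges <- seq(lo, max(d) + bin_width, by = bin_width)
  bin <- findInterval(d, edges, rightmost.closed = FALSE)  # right-open bins
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  list(histogram = data.frame(bin_left = edges[-length(edges)],
                              bin_right = edges[-1], count = counts),
       summary = dist$summary)
}
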