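# Cell-shape morphometrics and tumor volume.
#
# Circularity c = 4*pi*A/P^2 equals 1 for a circle and decreases toward 0 for
# elongated or irregular outlines (computed at full machine precision for
# pi). Aspect ratio is the length:width ratio of the minimum-area rotated
# bounding rectangle, a reproducible operationalization of calliper length
# and width. Tumor volume uses the two-radius ellipsoid formula
# V = 4/3 * pi * L * S^2.

#' Circularity of a closed shape
#'
#' @param area shape area (> 0).
#' @param perimeter shape perimeter (> 0).
#' @return c = 4*pi*area/perimeter^2; 1 for a circle.
#' @export
circularity <- function(area, perimeter) {
  check_number(area, "area", min = 0, strict_min = TRUE)
  check_number(perimeter, "perimeter", min = 0, strict_min = TRUE)
  4 * pi * area / perimeter^2
}

#' Aspect ratio (length:width)
#'
#' Arguments are reordered so the result is always >= 1.
#'
#' @param length,width positive extents.
#' @return length/width >= 1.
#' @export
aspect_ratio <- function(length, width) {
  check_number(length, "length", min = 0, strict_min = TRUE)
  check_number(width, "width", min = 0, strict_min = TRUE)
  max(length, width) / min(length, width)
}

#' Measure a cell outline
#'
#' Area by the shoelace formula, perimeter as the closed vertex-chain length,
#' length/width from the minimum-area rotated bounding rectangle, and the
#' derived circularity and aspect ratio.
#'
#' @param outline a `cell_outline` (from [generate_cell_outlines()]) or an
#'   n x 2 matrix/data.frame of vertices (columns x, y), n >= 3,
#'   non-self-intersecting.
#' @return data.frame row of class `cell_shape`: area, perimeter, length,
#'   width, circularity, aspect_ratio.
#' @export
measure_cell <- function(outline) {
  v <- if (inherits(outline, "cell_outline")) outline$vertices else as.matrix(outline)
  if (!is.numeric(v) || ncol(v) != 2L || nrow(v) < 3L)
    stopf("'outline' must have >= 3 vertices with columns (x, y)")
  if (anyNA(v)) stopf("'outline' contains NA vertices")
  if (polygon_self_intersects(v)) stopf("'outline' is self-intersecting")
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  area <- abs(sum(x * yn - xn * y)) / 2
  if (area <= 0) stopf("'outline' has zero area")
  perim <- sum(sqrt((xn - x)^2 + (yn - y)^2))
  lw <- min_area_rect(v)
  out <- data.frame(area = area, perimeter = perim,
                    length = lw[1], width = lw[2],
                    circularity = circularity(area, perim),
                    aspect_ratio = aspect_ratio(lw[1], lw[2]))
  class(out) <- c("cell_shape", "data.frame")
  out
}

# Minimum-area rotated bounding rectangle via rotating calipers over the
# convex hull; returns c(length, width), length >= width.
min_area_rect <- function(v) {
  h <- grDevices::chull(v[, 1], v[, 2])
  hv <- v[h, , drop = FALSE]
  n <- nrow(hv)
  if (n == 1L) stopf("degenerate outline (single point)")
  if (n == 2L) {
    len <- sqrt(sum((hv[2, ] - hv[1, ])^2))
    return(c(len, 0))
  }
  nxt <- c(2:n, 1L)
  ang <- atan2(hv[nxt, 2] - hv[, 2], hv[nxt, 1] - hv[, 1])
  best <- c(Inf, NA, NA)
  for (a in unique(ang %% (pi / 2))) {
    ca <- cos(a); sa <- sin(a)
    px <- hv[, 1] * ca + hv[, 2] * sa
    py <- -hv[, 1] * sa + hv[, 2] * ca
    w <- diff(range(px)); hgt <- diff(range(py))
    if (w * hgt < best[1]) best <- c(w * hgt, w, hgt)
  }
  sort(best[2:3], decreasing = TRUE)
}

# O(n^2) vectorized proper-crossing test between non-adjacent edges.
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  x <- v[, 1]; y <- v[, 2]
  i2 <- c(2:n, 1L)
  cr <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  pairs <- which(outer(seq_len(n), seq_len(n), function(i, j)
    j > i + 1L & !(i == 1L & j == n)), arr.ind = TRUE)
  if (nrow(pairs) == 0L) return(FALSE)
  i <- pairs[, 1]; j <- pairs[, 2]
  d1 <- cr(x[i], y[i], x[i2[i]], y[i2[i]], x[j], y[j])
  d2 <- cr(x[i], y[i], x[i2[i]], y[i2[i]], x[i2[j]], y[i2[j]])
  d3 <- cr(x[j], y[j], x[i2[j]], y[i2[j]], x[i], y[i])
  d4 <- cr(x[j], y[j], x[i2[j]], y[i2[j]], x[i2[i]], y[i2[i]])
  any(d1 * d2 < 0 & d3 * d4 < 0)
}

#' Tumor volume from two calliper radii
#'
#' V = 4/3 * pi * L * S^2 with L the larger and S the smaller radius; inputs
#' given in the wrong order are swapped with a warning.
#'
#' @param L larger radius (mm).
#' @param S smaller radius (mm).
#' @return volume in mm^3.
#' @export
tumor_volume <- function(L, S) {
  check_number(L, "L", min = 0, strict_min = TRUE)
  check_number(S, "S", min = 0, strict_min = TRUE)
  if (S > L) {
    warnf("S > L: radii reordered so L is the larger")
    tmp <- L; L <- S; S <- tmp
  }
  4 / 3 * pi * L * S^2
}

#' Compare shape metrics between groups
#'
#' Two groups: two-sided unpaired t-test (equal-variance by default; set
#' `welch = TRUE` for the unequal-variance form). More than two groups:
#' one-way ANOVA followed by Tukey's HSD post-hoc comparisons.
#'
#' @param ... two or more groups, each a numeric vector or a data.frame of
#'   [measure_cell()] rows (then `metric` selects the column).
#' @param metric column to compare when data.frames are supplied.
#' @param welch use Welch's correction for the two-group test.
#' @return for two groups, a list with `t`, `df`, `p`; for more, a list with
#'   `F`, `df`, `p` and `tukey` (the TukeyHSD table).
#' @export
compare_shape_groups <- function(..., metric = "circularity", welch = FALSE) {
  groups <- list(...)
  if (length(groups) == 1L && is.list(groups[[1]]) && !is.data.frame(groups[[1]]))
    groups <- groups[[1]]
  vals <- lapply(groups, function(g) {
    if (is.data.frame(g)) {
      if (!metric %in% names(g)) stopf("metric '%s' not found in group", metric)
      g[[metric]]
    } else as.numeric(g)
  })
  if (length(vals) < 2L) stopf("need at least two groups")
  ns <- vapply(vals, length, 1L)
  if (any(ns < 2L)) stopf("every group needs n >= 2")
  if (length(vals) == 2L) {
    if (stats::var(vals[[1]]) == 0 && stats::var(vals[[2]]) == 0) {
      if (identical(vals[[1]], vals[[2]]) || mean(vals[[1]]) == mean(vals[[2]]))
        return(list(t = 0, df = sum(ns) - 2, p = 1))
      stopf("both groups are constant; the t statistic is undefined")
    }
    ht <- stats::t.test(vals[[1]], vals[[2]], var.equal = !welch)
    return(list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value))
  }
  df <- data.frame(value = unlist(vals),
                   group = factor(rep(seq_along(vals), ns)))
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  list(F = an[["F value"]][1], df = an[["Df"]],
       p = an[["Pr(>F)"]][1], tukey = stats::TukeyHSD(fit)$group)
}
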