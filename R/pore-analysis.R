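# Pore census and porosity statistics.
#
# Pores are connected clusters of non-fiber pixels fully surrounded by fiber:
# clusters touching any image border are excluded (their true extent is
# unknown), as are clusters below a minimum detectable size (segmentation
# specks). Geometry per pore: area, perimeter, and ellipse-equivalent major/
# minor axis lengths from second central moments. Group comparisons use
# Welch's unequal-variance t-test, appropriate for the uneven pore counts
# that different scaffolds produce.

#' Detect pores in a binary fiber mask
#'
#' @param mask logical matrix, TRUE = fiber; pores are components of !mask.
#' @param min_size minimum retained pore area in px^2 (default 10).
#' @param connectivity 4 (default) or 8 for the background components. The
#'   4/8 pairing with 8-connected fiber is the standard digital-topology
#'   choice.
#' @return data.frame of retained pores with columns `id`, `area`,
#'   `perimeter`, `major_axis`, `minor_axis`, `centroid_row`, `centroid_col`,
#'   `touches_border` (always FALSE for retained pores). Excluded components
#'   are available in `attr(, "excluded")` (id, area, reason) so that pixel
#'   accounting is exact.
#' @export
detect_pores <- function(mask, min_size = 10L, connectivity = 4L) {
  check_mask(mask)
  min_size <- check_count(min_size, "min_size", min = 0L)
  lab <- label_components(!mask, connectivity = as.integer(connectivity))
  n <- max(lab)
  empty <- data.frame(id = integer(), area = numeric(), perimeter = numeric(),
                      major_axis = numeric(), minor_axis = numeric(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      touches_border = logical())
  if (n == 0L) {
    attr(empty, "excluded") <- data.frame(id = integer(), area = numeric(),
                                          reason = character())
    return(empty)
  }
  nr <- nrow(mask); nc <- ncol(mask)
  rows <- list(); exc <- list()
  for (k in seq_len(n)) {
    px <- which(lab == k, arr.ind = TRUE)
    area <- nrow(px)
    border <- any(px[, 1] == 1L | px[, 1] == nr | px[, 2] == 1L | px[, 2] == nc)
    if (border) {
      exc[[length(exc) + 1L]] <- data.frame(id = k, area = area, reason = "border")
    } else if (area < min_size) {
      exc[[length(exc) + 1L]] <- data.frame(id = k, area = area, reason = "min_size")
    } else {
      ax <- moment_axes(px)
      rows[[length(rows) + 1L]] <- data.frame(
        id = k, area = area, perimeter = region_perimeter(lab == k),
        major_axis = ax[1], minor_axis = ax[2],
        centroid_row = mean(px[, 1]), centroid_col = mean(px[, 2]),
        touches_border = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  attr(out, "excluded") <- if (length(exc)) do.call(rbind, exc) else
    data.frame(id = integer(), area = numeric(), reason = character())
  out
}

# Ellipse-equivalent full axis lengths from second central moments, with the
# 1/12 per-pixel variance term so a single pixel has positive extent.
moment_axes <- function(px) {
  r <- px[, 1] - mean(px[, 1]); c <- px[, 2] - mean(px[, 2])
  n <- nrow(px)
  mrr <- sum(r * r) / n + 1 / 12
  mcc <- sum(c * c) / n + 1 / 12
  mrc <- sum(r * c) / n
  tr <- mrr + mcc
  disc <- sqrt((mrr - mcc)^2 + 4 * mrc^2)
  lam <- c((tr + disc) / 2, (tr - disc) / 2)
  4 * sqrt(pmax(lam, 0))
}

# Boundary length of a connected pixel region: count of exposed pixel faces,
# reduced by (2 - sqrt(2)) per right-angle corner so that staircase contours
# approach the length of the underlying smooth outline.
region_perimeter <- function(comp) {
  nr <- nrow(comp); nc <- ncol(comp)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- comp
  core <- p[2:(nr + 1L), 2:(nc + 1L)]
  expN <- core & !p[1:nr, 2:(nc + 1L)]
  expS <- core & !p[3:(nr + 2L), 2:(nc + 1L)]
  expW <- core & !p[2:(nr + 1L), 1:nc]
  expE <- core & !p[2:(nr + 1L), 3:(nc + 2L)]
  faces <- sum(expN) + sum(expS) + sum(expW) + sum(expE)
  corners <- sum(expN & expE) + sum(expE & expS) + sum(expS & expW) + sum(expW & expN)
  faces - (2 - sqrt(2)) * corners
}

#' Summarize porosity from a pore census
#'
#' @param pores a [detect_pores()] result derived from `mask`.
#' @param mask the logical fiber mask the pores came from.
#' @param label optional group label carried on the summary.
#' @return object of class `porosity_summary`: pore count, pore area fraction
#'   (retained pore pixels / total pixels), and mean/median/sd of area,
#'   perimeter and axis lengths (NA when no pores were retained).
#' @export
summarize_porosity <- function(pores, mask, label = NA_character_) {
  check_mask(mask)
  stat3 <- function(x) {
    if (length(x) == 0L) return(list(mean = NA_real_, median = NA_real_, sd = NA_real_))
    list(mean = mean(x), median = stats::median(x),
         sd = if (length(x) > 1) stats::sd(x) else NA_real_)
  }
  structure(list(n_pores = nrow(pores),
                 pore_area_fraction = sum(pores$area) / length(mask),
                 area = stat3(pores$area), perimeter = stat3(pores$perimeter),
                 major_axis = stat3(pores$major_axis),
                 minor_axis = stat3(pores$minor_axis), label = label),
            class = "porosity_summary")
}

#' Welch's unequal-variance two-sample t-test
#'
#' Two-sided unpaired t-test with the Welch-Satterthwaite degrees of freedom,
#' the comparison used for pore populations of unequal size and spread.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return object of class `welch_test`: `t`, `df`, `p`, group means and ns.
#' @export
welch_test <- function(a, b) {
  for (nm in c("a", "b")) {
    x <- get(nm)
    if (length(x) < 2L) stopf("group '%s' needs n >= 2 (got %d)", nm, length(x))
  }
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stopf("groups 'a' and 'b' are both constant; no variability to test")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_a = mean(a), mean_b = mean(b),
                 n_a = length(a), n_b = length(b)),
            class = "welch_test")
}

#' Compare pore geometry between two groups
#'
#' One Welch test per requested metric on the per-pore values, with
#' Bonferroni adjustment across the metrics reported alongside the raw p.
#'
#' @param pores_a,pores_b [detect_pores()] results (or data.frames with the
#'   metric columns); both must be non-empty.
#' @param metrics subset of c("area", "perimeter", "major_axis", "minor_axis").
#' @return data.frame with columns metric, t, df, p_raw, p_adj.
#' @export
compare_pore_groups <- function(pores_a, pores_b,
                                metrics = c("area", "perimeter",
                                            "major_axis", "minor_axis")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (nrow(pores_a) == 0L) stopf("group 'a' has no retained pores")
  if (nrow(pores_b) == 0L) stopf("group 'b' has no retained pores")
  res <- lapply(metrics, function(m) {
    wt <- welch_test(pores_a[[m]], pores_b[[m]])
    data.frame(metric = m, t = wt$t, df = wt$df, p_raw = wt$p)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p_raw, method = "bonferroni")
  out
}
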