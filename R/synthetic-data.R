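# Synthetic-data generators with exact ground truth.
#
# Every downstream stage of the package (segmentation, fiber diameters, pore
# census, orientation, rheology crossover, expression screen, cytokine
# normalization) is validated against scenes produced here, where the truth is
# known by construction. All generators are pure functions of (spec, seed).

#' Specification for a synthetic fibrous micrograph
#'
#' Describes an SEM-like scene of straight, constant-width fibers drawn over a
#' uniform background, then degraded by Gaussian blur and additive noise.
#' Fiber angles follow a von Mises law on the doubled-angle circle, the
#' standard dispersion model for undirected (nematic) orientations:
#' `orientation_kappa = 0` gives an isotropic network, large kappa gives
#' fibers tightly aligned around `orientation_mu`.
#'
#' @param image_size integer pair (rows, cols) in pixels, at least 64x64.
#' @param pixel_size physical calibration in nm/px (NA if unknown).
#' @param n_fibers number of fibers drawn.
#' @param diameter_mean,diameter_sd fiber width distribution (px); widths are
#'   normal, truncated at 1 px.
#' @param orientation_mu mean fiber axis in degrees, in [-90, 90).
#' @param orientation_kappa von Mises concentration on doubled angles; 0 =
#'   uniform (isotropic).
#' @param fiber_intensity,background_intensity intensities in [0, 1]; must
#'   differ.
#' @param blur_sigma Gaussian blur sigma (px) applied after rendering.
#' @param noise_sd additive Gaussian noise sd (intensity units).
#' @param center_margin minimum distance (px) of fiber anchor points from the
#'   image border; 0 (default) places fibers uniformly over the whole frame,
#'   a positive margin keeps calibration fibers crossing the interior.
#' @param seed integer seed; generation is a pure function of the spec.
#' @return object of class `fiber_image_spec`.
#' @export
fiber_image_spec <- function(image_size = c(256L, 256L), pixel_size = NA_real_,
                             n_fibers = 60L, diameter_mean = 5, diameter_sd = 1,
                             orientation_mu = 0, orientation_kappa = 0,
                             fiber_intensity = 0.8, background_intensity = 0.2,
                             blur_sigma = 1, noise_sd = 0.05,
                             center_margin = 0, seed = 1L) {
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  if (length(image_size) != 2L || any(image_size < 64L))
    stopf("'image_size' must be a (rows, cols) pair, each >= 64")
  if (!is.na(pixel_size)) check_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  n_fibers <- check_count(n_fibers, "n_fibers")
  check_number(diameter_mean, "diameter_mean", min = 0, strict_min = TRUE)
  check_number(diameter_sd, "diameter_sd", min = 0)
  check_number(orientation_mu, "orientation_mu", min = -90, max = 90)
  check_number(orientation_kappa, "orientation_kappa", min = 0)
  check_number(fiber_intensity, "fiber_intensity", min = 0, max = 1)
  check_number(background_intensity, "background_intensity", min = 0, max = 1)
  if (fiber_intensity == background_intensity)
    stopf("'fiber_intensity' must differ from 'background_intensity'")
  check_number(blur_sigma, "blur_sigma", min = 0)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(center_margin, "center_margin", min = 0,
               max = floor((min(image_size) - 1) / 2))
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(image_size = as.integer(image_size), pixel_size = pixel_size,
                 n_fibers = n_fibers, diameter_mean = diameter_mean,
                 diameter_sd = diameter_sd, orientation_mu = orientation_mu,
                 orientation_kappa = orientation_kappa,
                 fiber_intensity = fiber_intensity,
                 background_intensity = background_intensity,
                 blur_sigma = blur_sigma, noise_sd = noise_sd,
                 center_margin = center_margin, seed = seed),
            class = "fiber_image_spec")
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` returns uniform angles. Used on
#' the doubled-angle circle to draw undirected fiber orientations.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return numeric vector of angles in (-pi, pi] + mu, radians.
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  n <- check_count(n, "n")
  check_number(kappa, "kappa", min = 0)
  if (kappa == 0) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f))) + mu
        break
      }
    }
  }
  out
}

#' Render a synthetic fibrous micrograph with ground truth
#'
#' Fibers are straight constant-width bars: a pixel belongs to a fiber when
#' the perpendicular distance from its center to the fiber axis is strictly
#' less than half the fiber width, so a width-w bar renders exactly w pixels
#' thick for (almost) every sub-pixel offset. The binary ground-truth mask
#' and per-fiber records are captured before blur and noise are applied.
#'
#' @param spec a [fiber_image_spec()].
#' @return list of class `fiber_scene` with elements `image` (numeric matrix
#'   in [0,1], `pixel_size` attribute), and `ground_truth`: `fibers`
#'   (data.frame with angle_deg, width_px, center/endpoint coordinates),
#'   `true_mask` (logical matrix), `true_porosity` (exact non-fiber pixel
#'   fraction).
#' @export
generate_fiber_image <- function(spec) {
  if (!inherits(spec, "fiber_image_spec")) stopf("'spec' must be a fiber_image_spec")
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  withr::with_seed(spec$seed, {
    theta <- fold_angle(rvonmises(spec$n_fibers, 2 * spec$orientation_mu * pi / 180,
                                  spec$orientation_kappa) * 90 / pi)
    width <- pmax(1, stats::rnorm(spec$n_fibers, spec$diameter_mean, spec$diameter_sd))
    m <- spec$center_margin
    r0 <- stats::runif(spec$n_fibers, 1 + m, nr - m)
    c0 <- stats::runif(spec$n_fibers, 1 + m, nc - m)
    mask <- matrix(FALSE, nr, nc)
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    ends <- matrix(NA_real_, spec$n_fibers, 4,
                   dimnames = list(NULL, c("end1_row", "end1_col", "end2_row", "end2_col")))
    for (i in seq_len(spec$n_fibers)) {
      th <- theta[i] * pi / 180
      # signed perpendicular distance in math coords (x = col, y = -row)
      d <- (cc - c0[i]) * (-sin(th)) + (r0[i] - rr) * cos(th)
      mask <- mask | (abs(d) < width[i] / 2)
      ends[i, ] <- clip_line_to_frame(r0[i], c0[i], th, nr, nc)
    }
    img <- matrix(spec$background_intensity, nr, nc)
    img[mask] <- spec$fiber_intensity
    img <- gaussian_smooth(img, spec$blur_sigma)
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    img <- matrix(pmin(1, pmax(0, img)), nr, nc)
  })
  img <- set_pixel_size(img, spec$pixel_size)
  mask <- set_pixel_size(mask, spec$pixel_size)
  fibers <- data.frame(angle_deg = theta, width_px = width,
                       center_row = r0, center_col = c0, ends)
  structure(list(image = img,
                 ground_truth = list(fibers = fibers, true_mask = mask,
                                     true_porosity = mean(!mask)),
                 spec = spec),
            class = "fiber_scene")
}

# Intersect the infinite line through (r0, c0) at axial angle th (radians,
# math convention) with the image rectangle; returns endpoint coordinates.
clip_line_to_frame <- function(r0, c0, th, nr, nc) {
  u <- c(cos(th), sin(th))            # direction in (x, y) = (col, -row)
  p0 <- c(c0, -r0)
  tmin <- -Inf; tmax <- Inf
  for (k in 1:2) {
    lo <- if (k == 1) 1 else -nr
    hi <- if (k == 1) nc else -1
    if (abs(u[k]) < 1e-12) next
    t1 <- (lo - p0[k]) / u[k]; t2 <- (hi - p0[k]) / u[k]
    tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
  }
  p1 <- p0 + tmin * u; p2 <- p0 + tmax * u
  c(-p1[2], p1[1], -p2[2], p2[1])
}

#' Generate synthetic cell outlines (discretized ellipses)
#'
#' Closed polygons emulating traced cell boundaries, with exact recorded
#' ground truth. Elongation (major/minor axis ratio) is held at
#' `elongation_mean` unless `elongation_sd > 0`; cell size and in-plane
#' rotation vary with the seed. Semi-axes are `r*sqrt(e)` and `r/sqrt(e)` so
#' the drawn area is independent of elongation.
#'
#' @param n_cells number of outlines (>= 1).
#' @param elongation_mean mean major/minor ratio, >= 1.
#' @param seed integer seed.
#' @param elongation_sd dispersion of elongation (truncated at 1).
#' @param radius_mean,radius_sd equivalent-circle radius distribution (px).
#' @param n_vertices polygon discretization (default 720).
#' @return list of `cell_outline` objects, each with `vertices` (n x 2 matrix,
#'   columns x, y) and `truth` (area, major, minor, elongation, angle_deg).
#' @export
generate_cell_outlines <- function(n_cells, elongation_mean = 1, seed = 1L,
                                   elongation_sd = 0, radius_mean = 10,
                                   radius_sd = 0, n_vertices = 720L) {
  n_cells <- check_count(n_cells, "n_cells")
  check_number(elongation_mean, "elongation_mean", min = 1)
  check_number(elongation_sd, "elongation_sd", min = 0)
  check_number(radius_mean, "radius_mean", min = 0, strict_min = TRUE)
  n_vertices <- check_count(n_vertices, "n_vertices", min = 8L)
  seed <- check_count(seed, "seed", min = 0L)
  withr::with_seed(seed, {
    e <- pmax(1, stats::rnorm(n_cells, elongation_mean, elongation_sd))
    r <- pmax(1, stats::rnorm(n_cells, radius_mean, radius_sd))
    phi <- stats::runif(n_cells, -90, 90)
    lapply(seq_len(n_cells), function(i) {
      a <- r[i] * sqrt(e[i]); b <- r[i] / sqrt(e[i])
      t <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
      ph <- phi[i] * pi / 180
      x <- a * cos(t) * cos(ph) - b * sin(t) * sin(ph)
      y <- a * cos(t) * sin(ph) + b * sin(t) * cos(ph)
      structure(list(vertices = cbind(x = x, y = y),
                     truth = list(area = pi * a * b, major = 2 * a, minor = 2 * b,
                                  elongation = e[i], angle_deg = phi[i])),
                class = "cell_outline")
    })
  })
}

#' Specification for a synthetic Maxwell-model frequency sweep
#'
#' A single-mode Maxwell element has storage modulus
#' G'(w) = G w^2 tau^2 / (1 + w^2 tau^2) and loss modulus
#' G''(w) = G w tau / (1 + w^2 tau^2); the two cross exactly at w = 1/tau,
#' which is what the crossover analysis must recover. The default frequency
#' grid spans 0.628-62.8 rad/s, the range swept in decellularized-tumor
#' rheometry.
#'
#' @param modulus_scale plateau modulus G (Pa).
#' @param relaxation_time tau (s).
#' @param noise_sd lognormal multiplicative noise sd (relative; 0.02 = 2%).
#' @param frequency_grid strictly increasing positive frequencies (rad/s).
#' @param seed integer seed (used only when noise_sd > 0).
#' @return object of class `maxwell_spec`.
#' @export
maxwell_spec <- function(modulus_scale = 1000, relaxation_time = 1, noise_sd = 0,
                         frequency_grid = exp(seq(log(0.628), log(62.8),
                                                  length.out = 25L)),
                         seed = 1L) {
  check_number(modulus_scale, "modulus_scale", min = 0, strict_min = TRUE)
  check_number(relaxation_time, "relaxation_time", min = 0, strict_min = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  if (length(frequency_grid) < 1L) stopf("'frequency_grid' must be non-empty")
  if (any(frequency_grid <= 0) || any(diff(frequency_grid) <= 0))
    stopf("'frequency_grid' must be strictly increasing and positive")
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(modulus_scale = modulus_scale, relaxation_time = relaxation_time,
                 noise_sd = noise_sd, frequency_grid = frequency_grid, seed = seed),
            class = "maxwell_spec")
}

#' Generate a Maxwell-model rheology sweep
#'
#' @param spec a [maxwell_spec()].
#' @param label sample label carried on the sweep.
#' @return a `rheology_sweep` data.frame with columns `omega_rad_s`,
#'   `g_storage_pa`, `g_loss_pa`.
#' @export
generate_rheology_sweep <- function(spec, label = "maxwell") {
  if (!inherits(spec, "maxwell_spec")) stopf("'spec' must be a maxwell_spec")
  w <- spec$frequency_grid
  wt <- w * spec$relaxation_time
  gp <- spec$modulus_scale * wt^2 / (1 + wt^2)
  gpp <- spec$modulus_scale * wt / (1 + wt^2)
  if (spec$noise_sd > 0) {
    withr::with_seed(spec$seed, {
      gp <- gp * exp(stats::rnorm(length(w), 0, spec$noise_sd))
      gpp <- gpp * exp(stats::rnorm(length(w), 0, spec$noise_sd))
    })
  }
  rheology_sweep(data.frame(omega_rad_s = w, g_storage_pa = gp, g_loss_pa = gpp),
                 label = label)
}

#' Specification for a synthetic two-condition expression table
#'
#' Emulates a gene-level differential table (knockout vs parental) across RNA
#' biotypes, with planted up- and down-regulated protein-coding genes.
#' Planted up genes have fold change >= `effect_fold` and small raw p; planted
#' down genes mirror them at 1/fold; null genes are lognormal around fold 1
#' with uniform p.
#'
#' @param n_genes total genes.
#' @param biotype_proportions named proportions over the six modeled biotypes,
#'   summing to 1.
#' @param n_up,n_down planted counts (among protein-coding genes).
#' @param effect_fold planted effect size (> 1.5).
#' @param null_fold_sd sd of log fold change for null genes.
#' @param seed integer seed.
#' @return object of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(n_genes = 2000L,
                                biotype_proportions = c(protein_coding = 0.70,
                                                        lincRNA = 0.10, miRNA = 0.05,
                                                        `3prime_overlapping_ncRNA` = 0.02,
                                                        processed_pseudogene = 0.08,
                                                        antisense = 0.05),
                                n_up = 50L, n_down = 50L, effect_fold = 3,
                                null_fold_sd = 0.2, seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  allowed <- c("protein_coding", "lincRNA", "miRNA", "3prime_overlapping_ncRNA",
               "processed_pseudogene", "antisense")
  if (is.null(names(biotype_proportions)) ||
      !all(names(biotype_proportions) %in% allowed))
    stopf("'biotype_proportions' must be named with the six modeled biotypes")
  if (abs(sum(biotype_proportions) - 1) > 1e-9)
    stopf("'biotype_proportions' must sum to 1 (got %.12f)", sum(biotype_proportions))
  n_up <- check_count(n_up, "n_up", min = 0L)
  n_down <- check_count(n_down, "n_down", min = 0L)
  check_number(effect_fold, "effect_fold", min = 1.5, strict_min = TRUE)
  check_number(null_fold_sd, "null_fold_sd", min = 0, strict_min = TRUE)
  seed <- check_count(seed, "seed", min = 0L)
  counts <- apportion_counts(biotype_proportions, n_genes)
  n_pc <- counts["protein_coding"]
  if (is.na(n_pc)) n_pc <- 0L
  if (n_up + n_down > n_pc)
    stopf("planted counts (n_up + n_down = %d) exceed the protein-coding pool (%d)",
          n_up + n_down, n_pc)
  structure(list(n_genes = n_genes, biotype_proportions = biotype_proportions,
                 biotype_counts = counts, n_up = n_up, n_down = n_down,
                 effect_fold = effect_fold, null_fold_sd = null_fold_sd,
                 seed = seed),
            class = "expression_sim_spec")
}

# Largest-remainder apportionment of n among proportions (deterministic).
apportion_counts <- function(props, n) {
  raw <- props * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(counts), names(props))
}

#' Generate a synthetic expression table with planted signal
#'
#' @param spec an [expression_sim_spec()].
#' @return data.frame of class `expression_table` with columns `gene_id`,
#'   `biotype`, `fold_change`, `p_raw`, and ground-truth column `planted`
#'   (one of "up", "down", "none").
#' @export
generate_expression_table <- function(spec) {
  if (!inherits(spec, "expression_sim_spec")) stopf("'spec' must be an expression_sim_spec")
  withr::with_seed(spec$seed, {
    biotype <- sample(rep(names(spec$biotype_counts), spec$biotype_counts))
    n <- spec$n_genes
    pc_idx <- which(biotype == "protein_coding")
    planted_idx <- sample(pc_idx, spec$n_up + spec$n_down)
    up_idx <- planted_idx[seq_len(spec$n_up)]
    down_idx <- setdiff(planted_idx, up_idx)
    fold <- exp(stats::rnorm(n, 0, spec$null_fold_sd))
    fold[up_idx] <- spec$effect_fold * exp(abs(stats::rnorm(spec$n_up, 0, 0.15)))
    fold[down_idx] <- 1 / (spec$effect_fold * exp(abs(stats::rnorm(spec$n_down, 0, 0.15))))
    p_raw <- stats::runif(n)
    p_raw[planted_idx] <- stats::runif(length(planted_idx), 1e-10, 1e-6)
    planted <- rep("none", n)
    planted[up_idx] <- "up"; planted[down_idx] <- "down"
  })
  out <- data.frame(gene_id = sprintf("gene_%05d", seq_len(spec$n_genes)),
                    biotype = biotype, fold_change = fold, p_raw = p_raw,
                    planted = planted, stringsAsFactors = FALSE)
  class(out) <- c("expression_table", "data.frame")
  out
}

#' Generate a synthetic duplicate-spot cytokine array
#'
#' Emulates a membrane cytokine array where each analyte is spotted in
#' duplicate alongside background and positive-reference spots. The recorded
#' `true_level` is the noiseless normalized abundance
#' (mean(duplicates) - background) / reference.
#'
#' @param n_analytes number of analytes (>= 1).
#' @param background background spot intensity.
#' @param reference positive-reference spot intensity (> 0).
#' @param seed integer seed.
#' @param noise_sd per-spot additive noise sd.
#' @param level_max maximum true normalized level drawn (uniform on [0, max]).
#' @return data.frame with columns `analyte`, `spot1`, `spot2`, `background`,
#'   `reference`, `true_level`.
#' @export
generate_cytokine_array <- function(n_analytes, background = 2, reference = 20,
                                    seed = 1L, noise_sd = 0.5, level_max = 1) {
  n_analytes <- check_count(n_analytes, "n_analytes")
  check_number(background, "background")
  check_number(reference, "reference", min = 0, strict_min = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  seed <- check_count(seed, "seed", min = 0L)
  withr::with_seed(seed, {
    lvl <- stats::runif(n_analytes, 0, level_max)
    mu <- background + lvl * reference
    s1 <- mu + stats::rnorm(n_analytes, 0, noise_sd)
    s2 <- mu + stats::rnorm(n_analytes, 0, noise_sd)
  })
  data.frame(analyte = sprintf("cytokine_%03d", seq_len(n_analytes)),
             spot1 = s1, spot2 = s2, background = background,
             reference = reference, true_level = lvl)
}
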