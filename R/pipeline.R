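# End-to-end pipeline: segment -> skeleton/diameters -> pores -> orientation,
# with a provenance manifest, plus the command-line entry point.

#' Pipeline configuration with documented defaults
#'
#' Every parameter defaults to the module-level default documented on the
#' corresponding function. Unknown arguments are rejected.
#'
#' @param input_image path to a TIFF/PNG micrograph, or NULL to simulate a
#'   scene from `simulate`.
#' @param output_dir directory for stage outputs (created if absent).
#' @param pixel_size physical calibration in nm/px (NA if unknown).
#' @param simulate named list of [fiber_image_spec()] arguments used when
#'   `input_image` is NULL.
#' @param contrast_low,contrast_high percentiles for [adjust_contrast()].
#' @param segmentation "otsu" or "fixed" (see [threshold_segment()]).
#' @param fixed_threshold threshold for `segmentation = "fixed"`.
#' @param fibers_bright polarity flag (fibers brighter than background).
#' @param min_fiber_size minimum fiber component kept before thinning (px).
#' @param min_pore_size minimum retained pore area (px^2).
#' @param pore_connectivity 4 or 8.
#' @param orientation_window structure-tensor Gaussian sigma (px).
#' @param dilation_px centerline dilation radius for orientation sampling.
#' @param histogram_bins orientation histogram bins.
#' @param diameter_bin_width diameter histogram bin width (px).
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_image = NULL, output_dir = "ecmarch_out",
                            pixel_size = NA_real_, simulate = list(),
                            contrast_low = 1, contrast_high = 99,
                            segmentation = "otsu", fixed_threshold = NULL,
                            fibers_bright = TRUE, min_fiber_size = 10L,
                            min_pore_size = 10L, pore_connectivity = 4L,
                            orientation_window = 7, dilation_px = 2L,
                            histogram_bins = 36L, diameter_bin_width = 1,
                            seed = 1L) {
  if (!segmentation %in% c("otsu", "fixed"))
    stopf("'segmentation' must be \"otsu\" or \"fixed\"")
  cfg <- list(input_image = input_image, output_dir = output_dir,
              pixel_size = pixel_size, simulate = simulate,
              contrast_low = contrast_low, contrast_high = contrast_high,
              segmentation = segmentation, fixed_threshold = fixed_threshold,
              fibers_bright = isTRUE(fibers_bright),
              min_fiber_size = check_count(min_fiber_size, "min_fiber_size", 0L),
              min_pore_size = check_count(min_pore_size, "min_pore_size", 0L),
              pore_connectivity = as.integer(pore_connectivity),
              orientation_window = check_number(orientation_window,
                                                "orientation_window", 0,
                                                strict_min = TRUE),
              dilation_px = check_count(dilation_px, "dilation_px", 0L),
              histogram_bins = check_count(histogram_bins, "histogram_bins", 2L),
              diameter_bin_width = check_number(diameter_bin_width,
                                                "diameter_bin_width", 0,
                                                strict_min = TRUE),
              seed = check_count(seed, "seed", 0L))
  if (!cfg$pore_connectivity %in% c(4L, 8L))
    stopf("'pore_connectivity' must be 4 or 8")
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full architecture pipeline
#'
#' Stages: load-or-simulate -> contrast adjustment -> segmentation -> fiber
#' skeleton/diameters -> pore census -> orientation/alignment. Each stage
#' writes its outputs under `output_dir` and is recorded in a provenance
#' manifest (package version, configuration and its hash, seed, file list).
#' The manifest carries no timestamps, so identical configurations produce
#' bitwise-identical output trees.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage progress messages.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) stopf("'config' must be a pipeline_config")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  outputs <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    say("[%s] done in %.2fs", name, proc.time()[["elapsed"]] - t0)
    res
  }
  op <- function(...) file.path(config$output_dir, ...)

  img <- stage("input", {
    if (is.null(config$input_image)) {
      spec <- do.call(fiber_image_spec,
                      utils::modifyList(list(seed = derive_seed(config$seed, 1L),
                                             pixel_size = config$pixel_size),
                                        config$simulate))
      scene <- generate_fiber_image(spec)
      write_image(scene$image, op("input.tif"))
      write_image(scene$ground_truth$true_mask, op("true_mask.png"))
      outputs$input <- c("input.tif", "true_mask.png")
      scene$image
    } else {
      outputs$input <- config$input_image
      read_image(config$input_image, pixel_size = config$pixel_size)
    }
  })

  img <- stage("contrast", adjust_contrast(img, config$contrast_low, config$contrast_high))

  mask <- stage("segment", {
    m <- threshold_segment(img, method = config$segmentation,
                           fixed_value = config$fixed_threshold,
                           fibers_bright = config$fibers_bright)
    write_image(m, op("mask.png"))
    outputs$segment <- "mask.png"
    m
  })

  fibers <- stage("fibers", {
    skel <- skeletonize(mask, min_component = config$min_fiber_size)
    dmap <- distance_transform(mask)
    dd <- estimate_fiber_diameters(mask, skel, dmap)
    write_table(dd$pixels, op("diameters.csv"))
    fs <- fiber_summary(dd, bin_width = config$diameter_bin_width)
    write_table(fs$histogram, op("diameter_histogram.csv"))
    jsonlite::write_json(dd$summary, op("diameter_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    outputs$fibers <- c("diameters.csv", "diameter_histogram.csv",
                         "diameter_summary.json")
    list(skeleton = skel, diameters = dd)
  })

  stage("pores", {
    pores <- detect_pores(mask, min_size = config$min_pore_size,
                          connectivity = config$pore_connectivity)
    write_table(pores, op("pores.csv"))
    ps <- summarize_porosity(pores, mask)
    jsonlite::write_json(unclass(ps), op("porosity_summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    outputs$pores <- c("pores.csv", "porosity_summary.json")
    pores
  })

  stage("orientation", {
    field <- structure_tensor_field(img, window_sigma = config$orientation_window)
    angles <- centerline_orientations(field, fibers$skeleton,
                                      dilation_px = config$dilation_px)
    if (length(angles) > 0L) {
      od <- orientation_distribution(angles, n_bins = config$histogram_bins)
      write_table(data.frame(bin_center = od$bin_centers, weight = od$weights),
                  op("orientation_distribution.csv"))
      sc <- alignment_score(angles)
      jsonlite::write_json(list(S = sc$S, n_samples = sc$n_samples,
                                peaks = od$peaks),
                           op("alignment.json"), auto_unbox = TRUE, digits = NA)
      outputs$orientation <- c("orientation_distribution.csv", "alignment.json")
    } else {
      warnf("no orientation samples; skipping distribution outputs")
      outputs$orientation <- character(0)
    }
    NULL
  })

  manifest <- list(package = "ecmarch",
                   version = as.character(utils::packageVersion("ecmarch")),
                   config = unclass(config), config_hash = config_hash(config),
                   seed = config$seed, stages = outputs)
  jsonlite::write_json(manifest, op("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `ecmarch` script (inst/cli/ecmarch). Subcommands:
#' simulate, segment, fibers, pores, orient, morpho, screen, rheology, run.
#' Arguments: `--config <path>` (YAML/JSON) and/or `key=value` overrides;
#' subcommands operating on a single file take `--in <path>` and
#' `--out <dir>`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
ecmarch_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: ecmarch <simulate|segment|fibers|pores|orient|morpho|",
                 "screen|rheology|run> [--config cfg.yaml] [--in path]",
                 "[--out dir] [key=value ...]")
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[1]; rest <- args[-1]
  opt <- list(config = NULL, input = NULL, out = "ecmarch_out", overrides = list())
  i <- 1L
  while (i <= length(rest)) {
    a <- rest[i]
    if (a == "--config") { opt$config <- rest[i + 1L]; i <- i + 2L }
    else if (a == "--in") { opt$input <- rest[i + 1L]; i <- i + 2L }
    else if (a == "--out") { opt$out <- rest[i + 1L]; i <- i + 2L }
    else if (grepl("=", a, fixed = TRUE)) {
      kv <- strsplit(a, "=", fixed = TRUE)[[1]]
      val <- utils::type.convert(paste(kv[-1], collapse = "="), as.is = TRUE)
      path <- strsplit(kv[1], ".", fixed = TRUE)[[1]]  # dotted = nested key
      node <- val
      for (k in rev(seq_along(path)))
        node <- stats::setNames(list(node), path[k])
      opt$overrides <- utils::modifyList(opt$overrides, node)
      i <- i + 1L
    } else stopf("unrecognized argument: %s", a)
  }
  cfg_args <- if (is.null(opt$config)) list() else unclass(read_config(opt$config))
  cfg_args <- utils::modifyList(cfg_args, opt$overrides)
  cfg_args$output_dir <- opt$out
  if (!is.null(opt$input) && cmd %in% c("segment", "run")) cfg_args$input_image <- opt$input
  dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)

  switch(cmd,
    run = run_pipeline(do.call(pipeline_config, cfg_args)),
    simulate = {
      cfg <- do.call(pipeline_config, cfg_args)
      spec <- do.call(fiber_image_spec,
                      utils::modifyList(list(seed = derive_seed(cfg$seed, 1L)),
                                        cfg$simulate))
      scene <- generate_fiber_image(spec)
      write_image(scene$image, file.path(opt$out, "input.tif"))
      write_image(scene$ground_truth$true_mask, file.path(opt$out, "true_mask.png"))
      write_table(scene$ground_truth$fibers, file.path(opt$out, "fibers_truth.csv"))
    },
    segment = {
      cfg <- do.call(pipeline_config, cfg_args)
      img <- adjust_contrast(read_image(opt$input), cfg$contrast_low, cfg$contrast_high)
      write_image(threshold_segment(img, cfg$segmentation, cfg$fixed_threshold,
                                    cfg$fibers_bright),
                  file.path(opt$out, "mask.png"))
    },
    fibers = {
      cfg <- do.call(pipeline_config, cfg_args)
      mask <- read_image(opt$input) > 0.5
      skel <- skeletonize(mask, cfg$min_fiber_size)
      dd <- estimate_fiber_diameters(mask, skel, distance_transform(mask))
      write_table(dd$pixels, file.path(opt$out, "diameters.csv"))
      jsonlite::write_json(dd$summary, file.path(opt$out, "diameter_summary.json"),
                           auto_unbox = TRUE, digits = NA)
    },
    pores = {
      cfg <- do.call(pipeline_config, cfg_args)
      mask <- read_image(opt$input) > 0.5
      pores <- detect_pores(mask, cfg$min_pore_size, cfg$pore_connectivity)
      write_table(pores, file.path(opt$out, "pores.csv"))
      jsonlite::write_json(unclass(summarize_porosity(pores, mask)),
                           file.path(opt$out, "porosity_summary.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
    },
    orient = {
      cfg <- do.call(pipeline_config, cfg_args)
      img <- read_image(opt$input)
      mask <- threshold_segment(adjust_contrast(img, cfg$contrast_low, cfg$contrast_high),
                                cfg$segmentation, cfg$fixed_threshold, cfg$fibers_bright)
      field <- structure_tensor_field(img, cfg$orientation_window)
      angles <- centerline_orientations(field, skeletonize(mask, cfg$min_fiber_size),
                                        cfg$dilation_px)
      od <- orientation_distribution(angles, cfg$histogram_bins)
      write_table(data.frame(bin_center = od$bin_centers, weight = od$weights),
                  file.path(opt$out, "orientation_distribution.csv"))
      sc <- alignment_score(angles)
      jsonlite::write_json(list(S = sc$S, n_samples = sc$n_samples, peaks = od$peaks),
                           file.path(opt$out, "alignment.json"),
                           auto_unbox = TRUE, digits = NA)
    },
    morpho = {
      outlines <- read_cell_outlines(opt$input)
      shapes <- do.call(rbind, lapply(outlines, measure_cell))
      shapes <- cbind(cell_id = names(outlines), shapes)
      write_table(shapes, file.path(opt$out, "cell_shapes.csv"))
    },
    screen = {
      tab <- read_expression_table(opt$input)
      tab <- filter_protein_coding(tab)
      if (!"p_adj" %in% names(tab)) tab$p_adj <- bh_adjust(tab$p_raw)
      res <- classify_fold_changes(tab)
      write_table(res$table, file.path(opt$out, "screen_classified.tsv"))
      jsonlite::write_json(as.list(res$counts), file.path(opt$out, "screen_counts.json"),
                           auto_unbox = TRUE, digits = NA)
    },
    rheology = {
      sweep <- read_rheology_sweep(opt$input)
      rep <- crossover_frequency(sweep)
      jsonlite::write_json(list(crossovers = rep$crossovers, primary = rep$primary,
                                method = rep$method),
                           file.path(opt$out, "crossover.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
    },
    stopf("unknown subcommand '%s'\n%s", cmd, usage))
  invisible(0L)
}
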