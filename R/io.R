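# File I/O: images (TIFF/PNG), tables (CSV/TSV), configuration (YAML/JSON).

#' Read a grayscale image
#'
#' Reads TIFF or PNG (8- or 16-bit), averages channels of multi-channel
#' images, and returns intensities in [0, 1].
#'
#' @param path image file path (.tif/.tiff/.png).
#' @param pixel_size optional physical calibration (nm/px) attached to the
#'   result.
#' @return numeric matrix in [0, 1] with a `pixel_size` attribute.
#' @export
read_image <- function(path, pixel_size = NA_real_) {
  if (!file.exists(path)) stopf("input image not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stopf("unsupported image format '.%s' (use TIFF or PNG)", ext))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img <- matrix(pmin(1, pmax(0, img)), nrow(img), ncol(img))
  set_pixel_size(img, pixel_size)
}

#' Write a grayscale image or mask
#'
#' Masks (logical matrices) are written as 0/255 8-bit rasters; numeric
#' matrices are quantized at the requested bit depth.
#'
#' @param img numeric matrix in [0, 1] or logical mask.
#' @param path output path (.tif/.tiff/.png).
#' @param bits 8 or 16.
#' @return the path, invisibly.
#' @export
write_image <- function(img, path, bits = 16L) {
  if (is.logical(img)) { img <- img * 1; bits <- 8L }
  if (!bits %in% c(8L, 16L)) stopf("'bits' must be 8 or 16")
  img <- matrix(pmin(1, pmax(0, img)), nrow(img), ncol(img))
  levels <- 2^bits - 1
  img <- round(img * levels) / levels
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = as.integer(bits)),
         png = png::writePNG(img, path),
         stopf("unsupported image format '.%s' (use TIFF or PNG)", ext))
  invisible(path)
}

#' Read a delimited table with required columns
#'
#' Delimiter is inferred from the extension (.tsv/.tab = tab, otherwise
#' comma).
#'
#' @param path file path.
#' @param required character vector of required column names.
#' @return data.frame.
#' @export
read_table <- function(path, required = character()) {
  if (!file.exists(path)) stopf("input table not found: %s", path)
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "tab")) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stopf("table %s is missing required column(s): %s", path,
          paste(missing, collapse = ", "))
  df
}

#' Write a delimited table
#'
#' @param df data.frame.
#' @param path output path (.tsv/.tab writes tabs, otherwise commas).
#' @return the path, invisibly.
#' @export
write_table <- function(df, path) {
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "tab")) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a rheology frequency sweep from CSV
#'
#' Expects columns omega_rad_s, g_storage_pa, g_loss_pa.
#'
#' @param path CSV path.
#' @param label sample label.
#' @return a [rheology_sweep()].
#' @export
read_rheology_sweep <- function(path, label = basename(path)) {
  rheology_sweep(read_table(path, c("omega_rad_s", "g_storage_pa", "g_loss_pa")),
                 label = label)
}

#' Read an expression table from CSV/TSV
#'
#' Requires gene_id, biotype, fold_change and at least one of p_raw / p_adj.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_expression_table <- function(path) {
  df <- read_table(path, c("gene_id", "biotype", "fold_change"))
  if (!any(c("p_raw", "p_adj") %in% names(df)))
    stopf("table %s needs a 'p_raw' or 'p_adj' column", path)
  check_expression_table(df)
  df
}

#' Read cell outlines from CSV
#'
#' Long format: one vertex per row with columns cell_id, vertex_index, x, y.
#'
#' @param path CSV path.
#' @return named list of vertex matrices, one per cell.
#' @export
read_cell_outlines <- function(path) {
  df <- read_table(path, c("cell_id", "vertex_index", "x", "y"))
  lapply(split(df, df$cell_id), function(d) {
    d <- d[order(d$vertex_index), ]
    cbind(x = d$x, y = d$y)
  })
}

#' Write cell outlines to CSV
#'
#' @param outlines list of `cell_outline` objects or vertex matrices.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_cell_outlines <- function(outlines, path) {
  rows <- lapply(seq_along(outlines), function(i) {
    v <- if (inherits(outlines[[i]], "cell_outline")) outlines[[i]]$vertices
         else as.matrix(outlines[[i]])
    data.frame(cell_id = i, vertex_index = seq_len(nrow(v)),
               x = v[, 1], y = v[, 2])
  })
  write_table(do.call(rbind, rows), path)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys take the documented defaults of
#' [pipeline_config()].
#'
#' @param path .yaml/.yml or .json file.
#' @return a validated `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path, simplifyVector = TRUE),
                stopf("unsupported config format '.%s' (use YAML or JSON)", ext))
  if (!is.list(cfg)) stopf("config must be a mapping of parameter names to values")
  do.call(pipeline_config, cfg)
}
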