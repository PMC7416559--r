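# Differential expression screen and cytokine-array normalization.
#
# Screening rules for knockout-vs-parental gene tables: drop non-coding
# biotypes, adjust raw p-values for false discovery rate, call genes up at
# fold change strictly above 1.5 and down strictly below 0.5 (both at
# adjusted p < 0.05), and intersect the up/down sets across cell lines.

EXCLUDED_BIOTYPES <- c("lincRNA", "miRNA", "3prime_overlapping_ncRNA",
                       "processed_pseudogene", "antisense")

check_expression_table <- function(table) {
  if (!is.data.frame(table)) stopf("expression table must be a data.frame")
  for (col in c("gene_id", "biotype", "fold_change"))
    if (!col %in% names(table)) stopf("expression table is missing column '%s'", col)
  if (anyDuplicated(table$gene_id)) stopf("'gene_id' values must be unique")
  if (any(table$fold_change <= 0)) stopf("'fold_change' must be positive")
  invisible(table)
}

#' Retain protein-coding transcripts
#'
#' Removes the five non-coding biotypes (lincRNA, miRNA, 3prime overlapping
#' ncRNA, processed pseudogene, antisense). Rows with unrecognized biotypes
#' are retained with a warning.
#'
#' @param table data.frame with columns gene_id, biotype, fold_change, ...
#' @return the filtered table.
#' @export
filter_protein_coding <- function(table) {
  check_expression_table(table)
  known <- c("protein_coding", EXCLUDED_BIOTYPES)
  unknown <- setdiff(unique(table$biotype), known)
  if (length(unknown) > 0L)
    warnf("unrecognized biotype(s) retained: %s", paste(unknown, collapse = ", "))
  table[!table$biotype %in% EXCLUDED_BIOTYPES, , drop = FALSE]
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1.
#'
#' @param p_raw numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_raw) {
  if (length(p_raw) == 0L) return(numeric(0))
  if (anyNA(p_raw) || any(p_raw < 0 | p_raw > 1))
    stopf("'p_raw' must be in [0, 1] with no NA")
  stats::p.adjust(p_raw, method = "BH")
}

#' Classify genes by fold change and adjusted significance
#'
#' Mutually exclusive, exhaustive classes: `excluded_biotype` for the five
#' filtered biotypes; otherwise `up` (fold strictly above `up_threshold` and
#' p_adj < alpha), `down` (fold strictly below `down_threshold` and p_adj <
#' alpha), `unchanged` (significant but between the thresholds), or
#' `not_significant`.
#'
#' @param table data.frame with gene_id, biotype, fold_change and `p_adj`
#'   (see [bh_adjust()]).
#' @param up_threshold,down_threshold fold-change cutoffs (strict).
#' @param alpha adjusted-significance cutoff (strict).
#' @return object of class `screen_result`: the table with a `class` column,
#'   `up_genes`/`down_genes` character vectors, and per-class `counts`.
#' @export
classify_fold_changes <- function(table, up_threshold = 1.5, down_threshold = 0.5,
                                  alpha = 0.05) {
  check_expression_table(table)
  if (!"p_adj" %in% names(table))
    stopf("expression table is missing column 'p_adj'; run bh_adjust() on p_raw first")
  if (any(table$p_adj < 0 | table$p_adj > 1)) stopf("'p_adj' must be in [0, 1]")
  cls <- rep("not_significant", nrow(table))
  sig <- table$p_adj < alpha
  cls[sig] <- "unchanged"
  cls[sig & table$fold_change > up_threshold] <- "up"
  cls[sig & table$fold_change < down_threshold] <- "down"
  cls[table$biotype %in% EXCLUDED_BIOTYPES] <- "excluded_biotype"
  table$class <- cls
  counts <- table(factor(cls, levels = c("up", "down", "unchanged",
                                         "not_significant", "excluded_biotype")))
  structure(list(table = table,
                 up_genes = table$gene_id[cls == "up"],
                 down_genes = table$gene_id[cls == "down"],
                 counts = counts,
                 thresholds = list(up = up_threshold, down = down_threshold,
                                   alpha = alpha)),
            class = "screen_result")
}

#' Genes shared between two screens
#'
#' Intersects up-with-up and down-with-down gene sets across two cell lines.
#'
#' @param result_a,result_b [classify_fold_changes()] results.
#' @return list with `shared_up`, `shared_down` (gene ids) and their counts.
#' @export
shared_gene_sets <- function(result_a, result_b) {
  for (r in list(result_a, result_b))
    if (!inherits(r, "screen_result")) stopf("inputs must be screen_result objects")
  up <- intersect(result_a$up_genes, result_b$up_genes)
  dn <- intersect(result_a$down_genes, result_b$down_genes)
  list(shared_up = up, shared_down = dn,
       n_shared_up = length(up), n_shared_down = length(dn))
}

#' Normalize a duplicate-spot cytokine measurement
#'
#' (mean of the duplicate spots - background) / reference, floored at 0:
#' background exceeding the signal is noise, not negative abundance.
#'
#' @param duplicates numeric vector of the duplicate spot intensities.
#' @param background background spot intensity.
#' @param reference positive-reference spot intensity (> 0).
#' @return normalized level >= 0.
#' @export
normalize_cytokine_spots <- function(duplicates, background, reference) {
  if (!is.numeric(duplicates) || length(duplicates) < 1L || anyNA(duplicates))
    stopf("'duplicates' must be a numeric vector of spot intensities")
  check_number(background, "background")
  check_number(reference, "reference", min = 0, strict_min = TRUE)
  val <- (mean(duplicates) - background) / reference
  if (val < 0) {
    warnf("background exceeds the mean spot signal; level floored at 0")
    val <- 0
  }
  val
}
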