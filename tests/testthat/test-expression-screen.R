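# Biotype filtering, BH adjustment, fold-change classes, intersections,
# cytokine normalization.

test_that("biotype filter keeps protein-coding rows only", {
  tab <- data.frame(gene_id = paste0("g", 1:6),
                    biotype = c("protein_coding", "lincRNA", "miRNA",
                                "3prime_overlapping_ncRNA",
                                "processed_pseudogene", "antisense"),
                    fold_change = rep(1, 6), p_raw = rep(0.5, 6))
  out <- filter_protein_coding(tab)
  expect_equal(out$gene_id, "g1")
  allpc <- tab[1, ]
  expect_identical(filter_protein_coding(allpc), allpc)
  tec <- tab; tec$biotype[2] <- "TEC"
  expect_warning(kept <- filter_protein_coding(tec), "TEC")
  expect_true("TEC" %in% kept$biotype)
  expect_error(filter_protein_coding(data.frame(gene_id = "g", fold_change = 1)),
               "biotype")
})

test_that("BH adjustment matches the hand-computed step-up example", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "p_raw")
})

test_that("BH matches the brute-force oracle on all permutations of 5 p-values", {
  base <- c(0.001, 0.02, 0.049, 0.3, 0.9)
  perms <- list()
  permute <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in permute(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  for (p in permute(base)) expect_equal(bh_adjust(p), bf_bh(p))
})

test_that("fold-change classes follow the strict thresholds", {
  tab <- data.frame(
    gene_id = paste0("g", 1:6),
    biotype = c(rep("protein_coding", 5), "miRNA"),
    fold_change = c(2.0, 1.5, 0.4, 0.4, 1.0, 3.0),
    p_adj = c(0.01, 0.001, 0.2, 0.01, 0.01, 0.001))
  res <- classify_fold_changes(tab)
  expect_equal(res$table$class,
               c("up",               # fold 2.0, p 0.01
                 "unchanged",        # fold exactly 1.5: boundary excluded
                 "not_significant",  # p_adj 0.2
                 "down",             # fold 0.4, p 0.01
                 "unchanged",        # significant but between thresholds
                 "excluded_biotype"))
  expect_equal(sum(res$counts), nrow(tab))   # classes partition the table
  expect_error(classify_fold_changes(tab[, -4]), "p_adj")
})

test_that("planted genes are recovered with high sensitivity and specificity", {
  tab <- generate_expression_table(expression_sim_spec(n_genes = 2000, seed = 5))
  tab <- filter_protein_coding(tab)
  tab$p_adj <- bh_adjust(tab$p_raw)
  res <- classify_fold_changes(tab)
  truth_hit <- tab$planted != "none"
  called <- res$table$class %in% c("up", "down")
  correct <- (tab$planted == "up" & res$table$class == "up") |
             (tab$planted == "down" & res$table$class == "down")
  sens <- sum(correct) / sum(truth_hit)
  spec <- sum(!truth_hit & !called) / sum(!truth_hit)
  expect_gte(sens, 0.95)
  expect_gte(spec, 0.95)
  expect_equal(sum(res$counts), nrow(tab))
})

test_that("shared gene sets intersect up-with-up and down-with-down", {
  mk <- function(up, down) {
    ids <- c(up, down)
    tab <- data.frame(gene_id = ids, biotype = "protein_coding",
                      fold_change = c(rep(2, length(up)), rep(0.3, length(down))),
                      p_adj = 0.01)
    classify_fold_changes(tab)
  }
  a <- mk(c("g1", "g2", "g3"), c("d1", "d2"))
  b <- mk(c("g2", "g3", "g4"), c("d2", "d9"))
  sh <- shared_gene_sets(a, b)
  expect_setequal(sh$shared_up, c("g2", "g3"))
  expect_equal(sh$n_shared_up, 2)
  expect_setequal(sh$shared_down, "d2")
  disj <- shared_gene_sets(mk("x1", "y1"), mk("x2", "y2"))
  expect_equal(disj$n_shared_up, 0)
  sub <- shared_gene_sets(mk(c("g1", "g2"), "d1"), mk(c("g1", "g2", "g3"), "d1"))
  expect_setequal(sub$shared_up, c("g1", "g2"))
})

test_that("cytokine normalization follows the duplicate-spot formula", {
  expect_equal(normalize_cytokine_spots(c(10, 12), 2, 20), 0.45)
  expect_equal(normalize_cytokine_spots(c(2, 2), 2, 20), 0)
  expect_warning(v <- normalize_cytokine_spots(c(1, 1), 5, 20), "floored")
  expect_equal(v, 0)
  expect_error(normalize_cytokine_spots(c(1, 2), 0, 0), "reference")
})
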