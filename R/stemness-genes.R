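# Stemness signature gene selection from single-cell profiles, and the
# AUCell-style per-cell gene-set activity score.

check_profile <- function(profile) {
  needed <- c("cell_id", "stemness", "malignant")
  missing <- setdiff(needed, names(profile))
  if (length(missing)) {
    abort(sprintf("`profile` is missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(profile$stemness)) ||
      any(profile$stemness < 0 | profile$stemness > 1)) {
    abort("`profile$stemness` must be finite and within [0, 1].")
  }
  if (!is.logical(profile$malignant)) {
    abort("`profile$malignant` must be logical.")
  }
  invisible(profile)
}

align_cells <- function(expr, profile) {
  check_expr(expr)
  check_profile(profile)
  common <- intersect(colnames(expr), profile$cell_id)
  if (length(common) < 3) {
    abort("fewer than 3 cells shared between `expr` and `profile`.")
  }
  list(expr = expr[, common, drop = FALSE],
       profile = profile[match(common, profile$cell_id), ])
}

#' Genes correlated with the per-cell stemness score (G1)
#'
#' Pearson correlation between each gene's expression and the stemness
#' score, computed across malignant cells, with two-sided p-values and
#' Benjamini-Hochberg FDR over all testable genes. A gene is selected when
#' `r > r_threshold` and `FDR < fdr_threshold`. Zero-variance genes are
#' untestable (reported with `testable = FALSE`), not errors.
#'
#' @param expr gene x cell expression matrix.
#' @param profile tibble with `cell_id`, `stemness`, `malignant`.
#' @param r_threshold minimum Pearson r (default 0.2).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return Tibble: `gene`, `r`, `p_value`, `fdr`, `testable`, `selected`.
#' @export
correlate_with_stemness <- function(expr, profile,
                                    r_threshold = 0.2,
                                    fdr_threshold = 0.05) {
  al <- align_cells(expr, profile)
  keep <- al$profile$malignant
  if (sum(keep) < 3) abort("fewer than 3 malignant cells for correlation.")
  x <- al$expr[, keep, drop = FALSE]
  s <- al$profile$stemness[keep]
  n <- length(s)
  if (sd(s) == 0) abort("stemness score is constant across malignant cells.")

  gene_sd <- apply(x, 1, sd)
  testable <- gene_sd > 0
  r <- rep(NA_real_, nrow(x))
  r[testable] <- as.vector(cor(t(x[testable, , drop = FALSE]), s))
  # two-sided test via the t transform, df = n - 2 (identical to cor.test)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  p[!testable] <- NA_real_
  fdr <- rep(NA_real_, length(p))
  fdr[testable] <- p.adjust(p[testable], method = "BH")

  tibble::tibble(
    gene = rownames(x),
    r = r, p_value = p, fdr = fdr, testable = testable,
    selected = testable & !is.na(r) & r > r_threshold & fdr < fdr_threshold
  )
}

#' Genes upregulated in malignant cells (G2)
#'
#' Two-sided Wilcoxon rank-sum test of malignant vs non-malignant cells per
#' gene, with log2 fold change `log2((mean_malignant + 1) /
#' (mean_other + 1))` on the linear expression scale and BH FDR. A gene is
#' selected when `lfc > lfc_threshold` and `FDR < fdr_threshold`.
#'
#' @inheritParams correlate_with_stemness
#' @param lfc_threshold minimum log2 fold change (default 0.25).
#' @return Tibble: `gene`, `lfc`, `p_value`, `fdr`, `testable`, `selected`.
#' @export
malignant_upregulated <- function(expr, profile,
                                  lfc_threshold = 0.25,
                                  fdr_threshold = 0.05) {
  al <- align_cells(expr, profile)
  mal <- al$profile$malignant
  if (sum(mal) < 2 || sum(!mal) < 2) {
    abort("need at least 2 malignant and 2 non-malignant cells.")
  }
  x <- al$expr
  m1 <- rowMeans(x[, mal, drop = FALSE])
  m0 <- rowMeans(x[, !mal, drop = FALSE])
  lfc <- unname(log2((m1 + 1) / (m0 + 1)))

  gene_sd <- apply(x, 1, sd)
  testable <- gene_sd > 0
  p <- rep(NA_real_, nrow(x))
  for (i in which(testable)) {
    p[i] <- wilcox.test(x[i, mal], x[i, !mal], exact = FALSE,
                        correct = TRUE)$p.value
  }
  fdr <- rep(NA_real_, length(p))
  fdr[testable] <- p.adjust(p[testable], method = "BH")

  tibble::tibble(
    gene = rownames(x),
    lfc = lfc, p_value = p, fdr = fdr, testable = testable,
    selected = testable & lfc > lfc_threshold & fdr < fdr_threshold
  )
}

#' Intersect the stemness-correlated and malignant-upregulated gene sets
#'
#' @param g1 character vector of stemness-correlated genes, or the tibble
#'   returned by [correlate_with_stemness()].
#' @param g2 character vector of malignant-upregulated genes, or the tibble
#'   returned by [malignant_upregulated()].
#' @return Sorted character vector `g1` intersect `g2`; warns when empty.
#' @export
select_signature_genes <- function(g1, g2) {
  pull_set <- function(x) {
    if (is.data.frame(x)) x$gene[x$selected] else as.character(x)
  }
  out <- sort(intersect(pull_set(g1), pull_set(g2)))
  if (length(out) == 0) warn("signature gene set is empty (G1 and G2 are disjoint).")
  out
}

#' Run the full stemness signature gene selection
#'
#' Convenience wrapper: G1 by [correlate_with_stemness()], G2 by
#' [malignant_upregulated()], signature = G1 intersect G2.
#'
#' @inheritParams correlate_with_stemness
#' @inheritParams malignant_upregulated
#' @return List with `g1_stats`, `g2_stats` (tibbles) and `signature_genes`
#'   (sorted character vector).
#' @export
stemness_signature_genes <- function(expr, profile,
                                     r_threshold = 0.2,
                                     lfc_threshold = 0.25,
                                     fdr_threshold = 0.05) {
  g1 <- correlate_with_stemness(expr, profile, r_threshold, fdr_threshold)
  g2 <- malignant_upregulated(expr, profile, lfc_threshold, fdr_threshold)
  list(g1_stats = g1, g2_stats = g2,
       signature_genes = select_signature_genes(g1, g2))
}

#' AUCell-style per-cell gene-set activity score
#'
#' For each cell, genes are ranked by decreasing expression (ties broken by
#' gene id so scores are deterministic) and the score is the area under the
#' gene-set recovery curve within the top `ceiling(top_fraction * n_genes)`
#' ranks, normalised by the maximum achievable area so scores lie in
#' \[0, 1\]. Depends only on within-cell rankings, hence invariant to any
#' strictly increasing transform of a cell's expression vector.
#'
#' @param expr gene x cell expression matrix.
#' @param gene_set character vector of gene ids.
#' @param top_fraction fraction of top-ranked genes forming the recovery
#'   window (default 0.05).
#' @return Tibble: `cell_id`, `score`.
#' @export
aucell_score <- function(expr, gene_set, top_fraction = 0.05) {
  check_expr(expr)
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction > 1) {
    abort("`top_fraction` must be in (0, 1].")
  }
  set <- intersect(gene_set, rownames(expr))
  if (length(set) == 0) {
    abort("`gene_set` has no genes in common with `expr` (empty intersection).")
  }
  n <- nrow(expr)
  k <- ceiling(top_fraction * n)
  m <- length(set)
  # max area: all m set genes packed into the top ranks
  mm <- min(m, k)
  max_auc <- mm * (mm + 1) / 2 + (k - mm) * mm

  in_set <- rownames(expr) %in% set
  ids <- rownames(expr)
  scores <- vapply(seq_len(ncol(expr)), function(j) {
    ord <- order(-expr[, j], ids)
    hits <- in_set[ord][seq_len(k)]
    sum(cumsum(hits)) / max_auc
  }, numeric(1))
  tibble::tibble(cell_id = colnames(expr), score = scores)
}
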