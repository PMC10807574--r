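# Cross-cohort differential-expression concordance: the reproducibility
# check that the high/low-risk split captures the same biology in
# independent cohorts.

#' Differentially expressed genes between predicted risk groups
#'
#' Per-gene two-sided Wilcoxon rank-sum test of high- vs low-risk samples
#' with BH FDR; direction is the sign of the difference of group means
#' (`"up"` = higher in the high-risk group).
#'
#' @param expr gene x sample expression matrix.
#' @param labels subtype labels: a tibble with `sample_id` and `subtype`
#'   (e.g. from [median_split()]) or a named character vector of
#'   `"high"`/`"low"`.
#' @param fdr_threshold BH FDR cutoff, default 0.05.
#' @return Tibble with the genes passing the threshold: `gene`,
#'   `direction`, `fdr`. Attribute `n_tested`.
#' @export
deg_between_groups <- function(expr, labels, fdr_threshold = 0.05) {
  check_expr(expr)
  if (is.data.frame(labels)) {
    labels <- setNames(labels$subtype, labels$sample_id)
  }
  common <- intersect(colnames(expr), names(labels))
  if (length(common) == 0) abort("`labels` shares no samples with `expr`.")
  expr <- expr[, common, drop = FALSE]
  lab <- labels[common]
  hi <- lab == "high"
  if (sum(hi) < 2 || sum(!hi) < 2) {
    abort("each risk group needs at least 2 samples.")
  }

  m_hi <- rowMeans(expr[, hi, drop = FALSE])
  m_lo <- rowMeans(expr[, !hi, drop = FALSE])
  testable <- apply(expr, 1, sd) > 0
  p <- rep(NA_real_, nrow(expr))
  for (i in which(testable)) {
    p[i] <- wilcox.test(expr[i, hi], expr[i, !hi], exact = FALSE,
                        correct = TRUE)$p.value
  }
  fdr <- rep(NA_real_, length(p))
  fdr[testable] <- p.adjust(p[testable], method = "BH")
  keep <- testable & fdr < fdr_threshold

  out <- tibble::tibble(
    gene = rownames(expr)[keep],
    direction = unname(ifelse(m_hi[keep] >= m_lo[keep], "up", "down")),
    fdr = fdr[keep]
  )
  structure(out, n_tested = sum(testable), class = class(out))
}

#' Concordance of two differential-expression gene lists
#'
#' The concordance score is the fraction of shared genes (present in both
#' lists) whose direction agrees; the concordant count is tested against
#' chance with a one-sided exact binomial test (success probability 0.5),
#' since the claim of interest is an enrichment of agreement.
#'
#' @param a,b DEG tibbles from [deg_between_groups()] (columns `gene`,
#'   `direction`).
#' @return List: `shared` (count), `score` (proportion, `NA` when no genes
#'   are shared), `binom_p`.
#' @export
concordance_score <- function(a, b) {
  j <- dplyr::inner_join(tibble::as_tibble(a)[, c("gene", "direction")],
                         tibble::as_tibble(b)[, c("gene", "direction")],
                         by = "gene", suffix = c("_a", "_b"))
  shared <- nrow(j)
  if (shared == 0) {
    return(list(shared = 0L, score = NA_real_, binom_p = NA_real_))
  }
  conc <- sum(j$direction_a == j$direction_b)
  list(
    shared = as.integer(shared),
    score = conc / shared,
    binom_p = binom.test(conc, shared, 0.5, alternative = "greater")$p.value
  )
}
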