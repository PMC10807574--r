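# Single-sample gene-set enrichment (ssGSEA) and median-split subtyping.

#' Single-sample GSEA enrichment score
#'
#' Implements the single-sample enrichment score from its definition: per
#' sample, genes are ranked by decreasing expression (ties broken by gene
#' id); walking down the ranked list, an empirical CDF of gene-set members
#' weighted by rank magnitude raised to `tau` is accumulated against the
#' unweighted CDF of non-members, and the enrichment score is the sum over
#' list positions of their difference. With `rank_mode = "raw_rank"` the
#' rank magnitude at list position p is `n - p + 1`; `"normalized_rank"`
#' divides by `n` (scores are identical when `tau` is shared, since the
#' normalisation cancels). Scores depend only on within-sample rankings and
#' are therefore invariant to per-sample monotone transforms. No
#' cross-sample normalisation is applied: only within-cohort ordering is
#' consumed downstream (see `normalize`).
#'
#' @param expr gene x sample expression matrix.
#' @param gene_set character vector of gene ids.
#' @param tau non-negative weighting exponent (default 0.25).
#' @param rank_mode `"raw_rank"` (default) or `"normalized_rank"`.
#' @param normalize if `TRUE`, divide scores by the range of the maximum
#'   attainable positive and negative deviations (a cross-sample-free
#'   rescaling kept for compatibility with range-normalised conventions);
#'   default `FALSE`.
#' @return Tibble: `sample_id`, `score`.
#' @export
ssgsea_score <- function(expr, gene_set, tau = 0.25,
                         rank_mode = c("raw_rank", "normalized_rank"),
                         normalize = FALSE) {
  check_expr(expr)
  rank_mode <- match.arg(rank_mode)
  if (!is.numeric(tau) || length(tau) != 1 || tau < 0) {
    abort("`tau` must be a non-negative real.")
  }
  set <- intersect(gene_set, rownames(expr))
  n <- nrow(expr)
  m <- length(set)
  if (m == 0) abort("`gene_set` has no genes in common with `expr`.")
  if (n - m < 2) abort("need at least 2 genes outside `gene_set`.")

  ids <- rownames(expr)
  in_set <- ids %in% set
  rank_mag <- as.numeric(n:1)
  if (rank_mode == "normalized_rank") rank_mag <- rank_mag / n

  scores <- vapply(seq_len(ncol(expr)), function(j) {
    ord <- order(-expr[, j], ids)
    hit <- in_set[ord]
    w <- ifelse(hit, rank_mag^tau, 0)
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!hit) / (n - m)
    sum(p_in - p_out)
  }, numeric(1))

  if (normalize) {
    # extremes: set packed at the very top vs the very bottom of the list
    top <- local({
      hit <- c(rep(TRUE, m), rep(FALSE, n - m))
      w <- ifelse(hit, rank_mag^tau, 0)
      sum(cumsum(w) / sum(w) - cumsum(!hit) / (n - m))
    })
    bottom <- local({
      hit <- c(rep(FALSE, n - m), rep(TRUE, m))
      w <- ifelse(hit, rank_mag^tau, 0)
      sum(cumsum(w) / sum(w) - cumsum(!hit) / (n - m))
    })
    scores <- scores / (top - bottom)
  }
  tibble::tibble(sample_id = colnames(expr), score = scores)
}

#' Median-split subtype assignment
#'
#' Splits each cohort at the median enrichment score: samples strictly
#' above the cohort median are labelled `"high"`, the rest `"low"` (ties at
#' the median go low, a fixed rule required for determinism). The recorded
#' thresholds are per cohort.
#'
#' @param scores tibble with `sample_id` and `score`, as returned by
#'   [ssgsea_score()]; an optional `cohort` column splits within cohorts.
#' @param cohort optional cohort id vector (recycled named or per-row);
#'   overrides a `cohort` column.
#' @return Tibble of class `reosig_subtypes`: `sample_id`, `cohort`,
#'   `score`, `subtype`; attribute `thresholds` is a tibble
#'   (`cohort`, `threshold`).
#' @export
median_split <- function(scores, cohort = NULL) {
  if (!all(c("sample_id", "score") %in% names(scores))) {
    abort("`scores` must have columns `sample_id` and `score`.")
  }
  out <- tibble::as_tibble(scores[, c("sample_id", "score")])
  out$cohort <- if (!is.null(cohort)) {
    rep(cohort, length.out = nrow(out))
  } else if ("cohort" %in% names(scores)) {
    scores[["cohort"]]
  } else {
    rep("cohort1", nrow(out))
  }

  res <- dplyr::group_by(out, .data$cohort)
  res <- dplyr::group_modify(res, function(d, key) {
    if (nrow(d) < 2) {
      abort(sprintf("cohort `%s` has fewer than 2 samples.", key$cohort))
    }
    med <- median(d$score)
    if (all(d$score == d$score[1])) {
      abort(sprintf("cohort `%s` is degenerate: all scores identical.",
                    key$cohort))
    }
    d$subtype <- ifelse(d$score > med, "high", "low")
    d$threshold <- med
    d
  })
  res <- dplyr::ungroup(res)
  thresholds <- dplyr::distinct(res, .data$cohort, .data$threshold)
  res <- dplyr::select(res, "sample_id", "cohort", "score", "subtype")
  structure(res, thresholds = thresholds,
            class = c("reosig_subtypes", class(res)))
}
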