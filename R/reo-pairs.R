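# Within-sample relative expression orderings (REOs): the cumulative
# binomial stable-pair model, reversal-pair detection, and cross-cohort
# intersection. All operations here consume only within-sample orderings,
# so their output is exactly invariant to strictly increasing per-sample
# transforms of the expression matrix.

#' Upper-tail binomial probability for a stable REO pattern
#'
#' For a gene pair observed in `k` informative samples of a subtype, of
#' which `s` show the majority ordering, the stability p-value under the
#' null of no preferred ordering (success probability `pe`) is
#' `P(X >= s) = 1 - sum_{i=0}^{s-1} C(k, i) pe^i (1 - pe)^(k - i)`.
#' Vectorised over `k` and `s`; `s = 0` returns 1.
#'
#' @param k number of informative samples (>= 1).
#' @param s number of samples showing the pattern, `0 <= s <= k`.
#' @param pe null success probability, default 0.5.
#' @return Numeric vector of upper-tail probabilities.
#' @export
#' @examples
#' binomial_reo_p(10, 10)  # 0.5^10
#' binomial_reo_p(1, 1)    # 0.5
binomial_reo_p <- function(k, s, pe = 0.5) {
  if (any(!is.finite(k)) || any(k < 1) || any(k != round(k))) {
    abort("`k` must be a positive integer count.")
  }
  if (any(!is.finite(s)) || any(s < 0) || any(s != round(s))) {
    abort("`s` must be a non-negative integer count.")
  }
  if (any(s > k)) abort("`s` must not exceed `k`.")
  if (!is.numeric(pe) || any(pe <= 0) || any(pe >= 1)) {
    abort("`pe` must lie strictly between 0 and 1.")
  }
  pbinom(s - 1, k, pe, lower.tail = FALSE)
}

canonical_pair_key <- function(gene_a, gene_b) {
  paste(pmin(gene_a, gene_b), pmax(gene_a, gene_b), sep = "\x1f")
}

#' Identify gene pairs with stable REOs in a sample group
#'
#' For each gene pair, counts across the chosen samples how often each
#' ordering holds; a within-sample tie contributes to neither direction and
#' reduces that pair's effective `k`. The majority count `s` is tested with
#' [binomial_reo_p()] and Benjamini-Hochberg adjusted across all tested
#' pairs; pairs with `FDR < fdr_threshold` are retained with their majority
#' direction. Pairs are canonicalised with `gene_a < gene_b`
#' lexicographically, so the result is independent of the gene order of
#' `expr`.
#'
#' @param expr gene x sample expression matrix.
#' @param samples optional character vector of sample ids (or logical mask)
#'   restricting the group; default all columns.
#' @param fdr_threshold BH FDR cutoff, default 0.05.
#' @param candidate_pairs optional tibble with columns `gene_a`, `gene_b`
#'   restricting the scan; default all `choose(G, 2)` pairs.
#' @return Tibble of class `reosig_stable_pairs` with the retained pairs:
#'   `gene_a`, `gene_b` (canonical order), `direction` (`"a_gt_b"` or
#'   `"a_lt_b"`), `k`, `s`, `p_value`, `fdr`. Attribute `n_tested` records
#'   the number of pairs tested.
#' @export
find_stable_pairs <- function(expr, samples = NULL, fdr_threshold = 0.05,
                              candidate_pairs = NULL) {
  check_expr(expr)
  if (!is.null(samples)) {
    expr <- expr[, samples, drop = FALSE]
  }
  if (ncol(expr) < 2) abort("need at least 2 samples in the group.")
  if (nrow(expr) < 2) abort("need at least 2 genes.")

  # canonical gene order makes output independent of input row order
  expr <- expr[order(rownames(expr)), , drop = FALSE]
  g <- rownames(expr)

  if (is.null(candidate_pairs)) {
    n_gt <- matrix(0L, nrow(expr), nrow(expr))
    for (j in seq_len(ncol(expr))) {
      x <- expr[, j]
      n_gt <- n_gt + (outer(x, x, ">"))
    }
    ut <- which(upper.tri(n_gt))
    ia <- row(n_gt)[ut]
    ib <- col(n_gt)[ut]
    cnt_a <- n_gt[ut]          # samples with a > b
    cnt_b <- t(n_gt)[ut]       # samples with b > a
    gene_a <- g[ia]
    gene_b <- g[ib]
  } else {
    if (!all(c("gene_a", "gene_b") %in% names(candidate_pairs))) {
      abort("`candidate_pairs` must have columns `gene_a` and `gene_b`.")
    }
    ga <- pmin(candidate_pairs$gene_a, candidate_pairs$gene_b)
    gb <- pmax(candidate_pairs$gene_a, candidate_pairs$gene_b)
    if (any(ga == gb)) abort("a gene cannot be paired with itself.")
    keep <- ga %in% g & gb %in% g
    ga <- ga[keep]; gb <- gb[keep]
    dup <- duplicated(canonical_pair_key(ga, gb))
    gene_a <- ga[!dup]; gene_b <- gb[!dup]
    A <- expr[gene_a, , drop = FALSE]
    B <- expr[gene_b, , drop = FALSE]
    cnt_a <- rowSums(A > B)
    cnt_b <- rowSums(A < B)
  }

  k <- cnt_a + cnt_b           # ties drop out
  s <- pmax(cnt_a, cnt_b)
  testable <- k >= 1
  p <- rep(NA_real_, length(k))
  p[testable] <- binomial_reo_p(k[testable], s[testable])
  fdr <- rep(NA_real_, length(k))
  fdr[testable] <- p.adjust(p[testable], method = "BH")

  keep <- testable & fdr < fdr_threshold
  out <- tibble::tibble(
    gene_a = gene_a[keep],
    gene_b = gene_b[keep],
    direction = ifelse(cnt_a[keep] >= cnt_b[keep], "a_gt_b", "a_lt_b"),
    k = as.integer(k[keep]),
    s = as.integer(s[keep]),
    p_value = p[keep],
    fdr = fdr[keep]
  )
  structure(out, n_tested = sum(testable),
            class = c("reosig_stable_pairs", class(out)))
}

#' Reversal gene pairs between two subtypes
#'
#' Pairs stable in both subtypes but with opposite orderings. Each reversal
#' is emitted as a directed pair oriented by the high-risk subtype: the
#' ordering `gene_high > gene_low` is the one observed stably in the
#' high-risk group, and a new sample showing it casts a high-risk vote.
#'
#' @param stable_high,stable_low [find_stable_pairs()] results for the
#'   high- and low-risk subtype respectively.
#' @return Tibble: `gene_high`, `gene_low`, plus the per-subtype FDRs
#'   (`fdr_high`, `fdr_low`).
#' @export
reversal_pairs <- function(stable_high, stable_low) {
  j <- dplyr::inner_join(
    tibble::as_tibble(stable_high)[, c("gene_a", "gene_b", "direction", "fdr")],
    tibble::as_tibble(stable_low)[, c("gene_a", "gene_b", "direction", "fdr")],
    by = c("gene_a", "gene_b"), suffix = c("_high", "_low")
  )
  j <- dplyr::filter(j, .data$direction_high != .data$direction_low)
  tibble::tibble(
    gene_high = ifelse(j$direction_high == "a_gt_b", j$gene_a, j$gene_b),
    gene_low  = ifelse(j$direction_high == "a_gt_b", j$gene_b, j$gene_a),
    fdr_high = j$fdr_high,
    fdr_low = j$fdr_low
  )
}

#' Intersect reversal pairs across cohorts
#'
#' Pairs discovered in both cohorts are compared for orientation
#' concordance; only orientation-consistent pairs are passed downstream.
#' The concordant count is tested against chance (success probability 0.5)
#' with a two-sided exact binomial test.
#'
#' @param reversals_1,reversals_2 [reversal_pairs()] results from two
#'   cohorts.
#' @return List: `consistent` (tibble `gene_high`, `gene_low`), `n_shared`,
#'   `concordance` (proportion of shared pairs with identical orientation;
#'   `NA` if none shared), `binom_p`.
#' @export
intersect_cohort_reversals <- function(reversals_1, reversals_2) {
  k1 <- canonical_pair_key(reversals_1$gene_high, reversals_1$gene_low)
  k2 <- canonical_pair_key(reversals_2$gene_high, reversals_2$gene_low)
  shared <- intersect(k1, k2)
  n_shared <- length(shared)
  if (n_shared == 0) {
    return(list(
      consistent = tibble::tibble(gene_high = character(0),
                                  gene_low = character(0)),
      n_shared = 0L, concordance = NA_real_, binom_p = NA_real_
    ))
  }
  i1 <- match(shared, k1)
  i2 <- match(shared, k2)
  concordant <- reversals_1$gene_high[i1] == reversals_2$gene_high[i2]
  n_conc <- sum(concordant)
  list(
    consistent = tibble::tibble(
      gene_high = reversals_1$gene_high[i1][concordant],
      gene_low = reversals_1$gene_low[i1][concordant]
    ),
    n_shared = as.integer(n_shared),
    concordance = n_conc / n_shared,
    binom_p = binom.test(n_conc, n_shared, 0.5,
                         alternative = "two.sided")$p.value
  )
}

# Vote matrix: samples x pairs, TRUE when the sample shows the pair's
# high-risk ordering (gene_high > gene_low), FALSE for the reverse, NA when
# either gene is missing or the two values tie. Accepts a single matrix or
# a named list of cohort matrices (votes merge platform-free).
vote_matrix <- function(expr, pairs) {
  one <- function(m) {
    check_expr(m)
    nsamp <- ncol(m)
    V <- matrix(NA, nsamp, nrow(pairs),
                dimnames = list(colnames(m), NULL))
    hi_in <- pairs$gene_high %in% rownames(m)
    lo_in <- pairs$gene_low %in% rownames(m)
    ok <- hi_in & lo_in
    if (any(ok)) {
      A <- m[pairs$gene_high[ok], , drop = FALSE]
      B <- m[pairs$gene_low[ok], , drop = FALSE]
      v <- t(A > B)
      v[t(A == B)] <- NA
      V[, ok] <- v
    }
    V
  }
  if (is.list(expr) && !is.matrix(expr)) {
    do.call(rbind, lapply(expr, one))
  } else {
    one(expr)
  }
}
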