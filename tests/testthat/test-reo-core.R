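# Stable-REO binomial model, stable-pair discovery, reversal detection.

# exhaustive oracle: P(X >= s) by enumerating all 2^k equally likely
# direction assignments
binom_tail_enum <- function(k, s) {
  grid <- expand.grid(rep(list(0:1), k))
  mean(rowSums(grid) >= s)
}

test_that("binomial REO p-value matches its closed forms", {
  expect_equal(binomial_reo_p(10, 10), 0.5^10, tolerance = 1e-15)
  expect_equal(binomial_reo_p(1, 1), 0.5, tolerance = 1e-15)
  expect_equal(binomial_reo_p(10, 5), 0.623046875, tolerance = 1e-15)
  expect_equal(binomial_reo_p(20, 0), 1)
})

test_that("binomial REO p-value matches exhaustive enumeration (spot checks)", {
  for (k in c(3, 6, 8)) {
    for (s in 0:k) {
      expect_equal(binomial_reo_p(k, s), binom_tail_enum(k, s),
                   tolerance = 1e-12)
    }
  }
})

test_that("binomial REO p-value is monotone and validates input", {
  for (k in c(5, 12, 30)) {
    p <- binomial_reo_p(rep(k, k + 1), 0:k)
    expect_true(all(diff(p) <= 0))
  }
  expect_error(binomial_reo_p(5, 6), "exceed")
  expect_error(binomial_reo_p(0, 0), "positive")
  expect_error(binomial_reo_p(5, 3, pe = 1), "between")
})

test_that("a unanimous pair is retained with the exact binomial p", {
  n <- 20
  expr <- rbind(a = 10 + seq_len(n), b = seq_len(n))
  colnames(expr) <- sprintf("s%03d", seq_len(n))
  res <- find_stable_pairs(expr, fdr_threshold = 0.05)
  expect_equal(nrow(res), 1)
  expect_equal(res$p_value, 0.5^20, tolerance = 1e-15)
  expect_identical(res$direction, "a_gt_b")
  expect_equal(res$k, 20L)
  expect_equal(res$s, 20L)
})

test_that("an evenly split pair is not retained", {
  n <- 20
  expr <- rbind(a = c(2 + seq_len(10), seq_len(10)),
                b = c(seq_len(10), 2 + seq_len(10)))
  colnames(expr) <- sprintf("s%03d", seq_len(n))
  res <- find_stable_pairs(expr, fdr_threshold = 0.05)
  expect_equal(nrow(res), 0)
  expect_equal(binomial_reo_p(20, 10), 0.5880985, tolerance = 1e-6)
})

test_that("within-sample ties reduce the effective sample count", {
  expr <- rbind(a = c(5, 5, 5, 9, 9, 9, 9, 9),
                b = c(5, 5, 5, 1, 1, 1, 1, 1))
  colnames(expr) <- sprintf("s%03d", 1:8)
  res <- find_stable_pairs(expr, fdr_threshold = 1.1)
  expect_equal(res$k, 5L)   # 3 tied samples contribute to neither direction
  expect_equal(res$s, 5L)
  expect_equal(res$p_value, 0.5^5, tolerance = 1e-15)
})

test_that("a gene is never paired with itself", {
  expr <- rand_expr(4, 6)
  expect_error(
    find_stable_pairs(expr, candidate_pairs = tibble::tibble(
      gene_a = "g001", gene_b = "g001")),
    "itself"
  )
})

test_that("stable pairs are identical whatever the gene order of the input", {
  expr <- rand_expr(20, 15, seed = 6)
  res1 <- find_stable_pairs(expr, fdr_threshold = 0.2)
  res2 <- find_stable_pairs(expr[rev(seq_len(nrow(expr))), ],
                            fdr_threshold = 0.2)
  expect_equal(tibble::as_tibble(res1), tibble::as_tibble(res2))
  # candidate-pair route agrees with the all-pairs route
  cand <- tibble::as_tibble(res1)[, c("gene_a", "gene_b")]
  res3 <- find_stable_pairs(expr, fdr_threshold = 1.1, candidate_pairs = cand)
  expect_equal(res3$s, res1$s)
  expect_equal(res3$direction, res1$direction)
})

test_that("stable-pair discovery is invariant to per-sample monotone maps", {
  expr <- rand_expr(25, 20, seed = 13)
  base <- find_stable_pairs(expr, fdr_threshold = 0.2)
  distorted <- apply_monotone_per_sample(expr, seed = 99)
  expect_equal(tibble::as_tibble(find_stable_pairs(distorted, fdr_threshold = 0.2)),
               tibble::as_tibble(base))
})

test_that("reversal pairs require opposite stable directions", {
  hi <- tibble::tibble(gene_a = c("a", "c"), gene_b = c("b", "d"),
                       direction = c("a_gt_b", "a_gt_b"),
                       k = c(10L, 10L), s = c(10L, 10L),
                       p_value = c(1e-3, 1e-3), fdr = c(1e-3, 1e-3))
  lo_flip <- hi; lo_flip$direction <- c("a_lt_b", "a_gt_b")
  out <- reversal_pairs(hi, lo_flip)
  expect_equal(nrow(out), 1)
  expect_identical(out$gene_high, "a")   # high-risk pattern: a > b
  expect_identical(out$gene_low, "b")
  # same directions: no reversal
  expect_equal(nrow(reversal_pairs(hi, hi)), 0)
})

test_that("cross-cohort intersection measures orientation concordance", {
  r1 <- tibble::tibble(gene_high = letters[1:10],
                       gene_low = LETTERS[1:10])
  expect_equal(intersect_cohort_reversals(r1, r1)$concordance, 1)

  flipped <- tibble::tibble(gene_high = r1$gene_low, gene_low = r1$gene_high)
  res <- intersect_cohort_reversals(r1, flipped)
  expect_equal(res$concordance, 0)
  expect_equal(nrow(res$consistent), 0)

  one_off <- r1
  one_off[10, ] <- list(gene_low = r1$gene_high[10],
                        gene_high = r1$gene_low[10])[c("gene_high", "gene_low")]
  res9 <- intersect_cohort_reversals(r1, one_off)
  expect_equal(res9$n_shared, 10L)
  expect_equal(res9$concordance, 0.9)
  expect_equal(res9$binom_p, 0.021484375, tolerance = 1e-12)
  expect_equal(nrow(res9$consistent), 9)
})

test_that("planted reversal pairs are recovered from simulated cohorts", {
  cfg <- synth_config(n_genes = 150, n_cells = 10, n_stem_genes = 20,
                      n_samples_per_cohort = 150, n_cohorts = 1,
                      n_planted_pairs = 25, delta = 1.5, sigma = 0.5,
                      seed = 31)
  sim <- simulate_bulk_cohorts(cfg)
  m <- sim$expr[[1]]
  subtype <- sim$truth$sample_subtype[colnames(m)]
  hi <- find_stable_pairs(m, names(subtype)[subtype == "high"])
  lo <- find_stable_pairs(m, names(subtype)[subtype == "low"])
  rev <- reversal_pairs(hi, lo)
  planted <- paste(sim$truth$planted_pairs$gene_high,
                   sim$truth$planted_pairs$gene_low)
  recovered <- mean(planted %in% paste(rev$gene_high, rev$gene_low))
  expect_gte(recovered, 0.8)
})
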