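# Candidate filtering, forward search, half-voting classification.

# a sample vector realising a given vote pattern over pairs (p1..pk)
vote_expr <- function(votes) {
  genes <- c(rbind(sprintf("h%d", seq_along(votes)),
                   sprintf("l%d", seq_along(votes))))
  vals <- c(rbind(ifelse(votes, 2, 1), ifelse(votes, 1, 2)))
  setNames(vals, genes)
}

test_that("the half-voting rule labels samples as stated", {
  sig4 <- make_signature(sprintf("h%d", 1:4), sprintf("l%d", 1:4))
  # 2 of 4 vote high -> high (at least half)
  expect_identical(
    classify_samples(vote_expr(c(TRUE, TRUE, FALSE, FALSE)), sig4)$label,
    "high"
  )
  # 1 of 4 -> low
  expect_identical(
    classify_samples(vote_expr(c(TRUE, FALSE, FALSE, FALSE)), sig4)$label,
    "low"
  )
  sig47 <- make_signature(sprintf("h%d", 1:47), sprintf("l%d", 1:47))
  expect_identical(
    classify_samples(vote_expr(rep(TRUE, 47)), sig47)$label,
    "high"
  )
})

test_that("missing genes skip the pair; all-missing is unclassifiable", {
  sig <- make_signature(c("h1", "h2"), c("l1", "l2"))
  x <- vote_expr(c(TRUE, TRUE))[1:2]   # only pair 1 measured
  res <- classify_samples(x, sig)
  expect_equal(res$votes_total, 1L)
  expect_identical(res$label, "high")
  res0 <- classify_samples(setNames(c(1, 2), c("zz1", "zz2")), sig)
  expect_equal(res0$votes_total, 0L)
  expect_true(is.na(res0$label))
})

test_that("a tied pair casts no vote", {
  sig <- make_signature(c("h1", "h2"), c("l1", "l2"))
  x <- c(h1 = 5, l1 = 5, h2 = 1, l2 = 2)
  res <- classify_samples(x, sig)
  expect_equal(res$votes_total, 1L)
  expect_identical(res$label, "low")
})

test_that("classification is a pure function of the single sample", {
  set.seed(41)
  expr <- rand_expr(30, 25, seed = 41)
  sig <- make_signature(rownames(expr)[1:6], rownames(expr)[7:12])
  base <- classify_samples(expr, sig)
  target <- base[base$sample_id == "s010", ]
  # subset
  sub <- classify_samples(expr[, c("s010", "s001"), drop = FALSE], sig)
  expect_equal(sub[sub$sample_id == "s010", ], target)
  # permute columns
  perm <- classify_samples(expr[, sample(colnames(expr))], sig)
  expect_equal(perm[perm$sample_id == "s010", ], target)
  # augment with new samples
  extra <- rand_expr(30, 5, seed = 99)
  colnames(extra) <- sprintf("x%02d", 1:5)
  aug <- classify_samples(cbind(expr, extra), sig)
  expect_equal(aug[aug$sample_id == "s010", ], target)
})

test_that("labels survive monotone distortion and gene-order permutation", {
  expr <- rand_expr(40, 15, seed = 8)
  sig <- make_signature(rownames(expr)[1:5], rownames(expr)[21:25])
  base <- classify_samples(expr, sig)
  expect_equal(classify_samples(apply_monotone_per_sample(expr, 3), sig), base)
  expect_equal(classify_samples(expr[sample(nrow(expr)), ], sig), base)
  # and the labels match an independent per-sample enumeration
  expect_identical(base$label,
                   halfvote_bruteforce(expr, sig$pairs$gene_high,
                                       sig$pairs$gene_low))
})

# training data where pair votes are planted against survival
make_training <- function(n = 40, n_pairs = 6, frac_info = 1 / 3, seed = 2) {
  set.seed(seed)
  risk <- rep(c(1, 0), each = n / 2)
  genes <- c(rbind(sprintf("h%d", 1:n_pairs), sprintf("l%d", 1:n_pairs)))
  expr <- matrix(0, length(genes), n,
                 dimnames = list(genes, sprintf("s%03d", 1:n)))
  n_info <- ceiling(n_pairs * frac_info)
  for (p in 1:n_pairs) {
    informative <- p <= n_info
    votes <- if (informative) {
      # tracks risk with a little noise
      as.logical(ifelse(runif(n) < 0.85, risk, 1 - risk))
    } else {
      runif(n) < 0.5
    }
    expr[sprintf("h%d", p), ] <- ifelse(votes, 2, 1) + runif(n, 0, 0.01)
    expr[sprintf("l%d", p), ] <- ifelse(votes, 1, 2) + runif(n, 0, 0.01)
  }
  rate <- 0.05 * exp(log(4) * risk)
  t_event <- rexp(n, rate)
  t_cens <- runif(n, 0, 60)
  rec <- tibble::tibble(
    sample_id = colnames(expr),
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    surgery_only = TRUE
  )
  pairs <- tibble::tibble(gene_high = sprintf("h%d", 1:n_pairs),
                          gene_low = sprintf("l%d", 1:n_pairs))
  list(expr = expr, records = rec, pairs = pairs, risk = risk,
       n_informative = n_info)
}

test_that("prognostic filtering keeps informative pairs and ranks deterministically", {
  tr <- make_training(n = 80, n_pairs = 9, seed = 3)
  cand <- filter_prognostic_pairs(tr$pairs, tr$expr, tr$records)
  expect_true(all(sprintf("h%d", 1:tr$n_informative) %in% cand$gene_high))
  expect_gt(cand$c_index[1], 0.6)
  expect_true(all(cand$c_index[cand$gene_high %in%
                                 sprintf("h%d", 1:tr$n_informative)] > 0.55))
  expect_true(all(diff(cand$c_index) <= 1e-12))
  # deterministic: identical call, identical ordering
  cand2 <- filter_prognostic_pairs(tr$pairs, tr$expr, tr$records)
  expect_equal(tibble::as_tibble(cand), tibble::as_tibble(cand2))
})

test_that("pairs unrelated to survival are dropped by the Cox filter", {
  set.seed(10)
  tr <- make_training(n = 80, n_pairs = 8, frac_info = 1 / 8, seed = 10)
  cand <- filter_prognostic_pairs(tr$pairs, tr$expr, tr$records,
                                  fdr_threshold = 0.05)
  expect_false(any(sprintf("h%d", 2:8) %in% cand$gene_high))
})

test_that("an empty candidate set is an explicit status, not an error", {
  tr <- make_training(n = 40, n_pairs = 4, frac_info = 0.01, seed = 6)
  # permuted survival: no pair is prognostic
  tr$records$time <- sample(tr$records$time)
  expect_message(
    cand <- filter_prognostic_pairs(tr$pairs, tr$expr, tr$records,
                                    fdr_threshold = 1e-6),
    "no_candidates"
  )
  expect_equal(nrow(cand), 0)
  expect_identical(attr(cand, "status"), "no_candidates")
})

test_that("a single perfectly separating candidate gives C-index 1", {
  expr <- matrix(c(2, 1, 2, 1, 1, 2, 1, 2), 2, 4,
                 dimnames = list(c("hA", "lA"), sprintf("s%d", 1:4)))
  rec <- tibble::tibble(
    sample_id = sprintf("s%d", 1:4),
    time = c(1, 1, 10, 10),
    event = c(1, 1, 0, 0)
  )
  cand <- tibble::tibble(gene_high = "hA", gene_low = "lA",
                         estimate = 1, hazard_ratio = exp(1),
                         p_value = 0.01, fdr = 0.01, c_index = 1)
  sig <- forward_search(cand, expr, rec)
  expect_equal(nrow(sig$pairs), 1)
  expect_equal(sig$c_index, 1)
})

test_that("forward search is bounded by the exhaustive-subset optimum", {
  tr <- make_training(n = 30, n_pairs = 8, frac_info = 0.5, seed = 12)
  cand <- filter_prognostic_pairs(tr$pairs, tr$expr, tr$records,
                                  fdr_threshold = 0.999)
  expect_lte(nrow(cand), 8)
  expect_gte(nrow(cand), 1)
  sig <- forward_search(cand, tr$expr, tr$records)

  # independent exhaustive search over all subsets of the candidates,
  # labelling by brute-force half vote and scoring by brute-force C
  best_subset_ci <- -Inf
  single_ci <- numeric(nrow(cand))
  for (mask in 1:(2^nrow(cand) - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(nrow(cand)) - 1)) > 0)
    lab <- halfvote_bruteforce(tr$expr, cand$gene_high[sel],
                               cand$gene_low[sel])
    ci <- cindex_bruteforce(tr$records$time, tr$records$event,
                            as.numeric(lab == "high"))
    if (length(sel) == 1) single_ci[sel] <- ci
    best_subset_ci <- max(best_subset_ci, ci)
  }
  expect_gte(sig$c_index, max(single_ci) - 1e-12)
  expect_lte(sig$c_index, best_subset_ci + 1e-12)
  # acceptance path strictly increases
  expect_true(all(diff(sig$path$c_index) > 0))
})

test_that("forward search is deterministic and noise pairs cannot lower it", {
  tr <- make_training(n = 60, n_pairs = 8, frac_info = 1 / 4, seed = 21)
  cand <- filter_prognostic_pairs(tr$pairs, tr$expr, tr$records,
                                  fdr_threshold = 0.999)
  s1 <- forward_search(cand, tr$expr, tr$records)
  s2 <- forward_search(cand, tr$expr, tr$records)
  expect_equal(s1$pairs, s2$pairs)
  expect_equal(s1$c_index, s2$c_index)
  expect_gte(s1$c_index, cand$c_index[1] - 1e-12)
})

test_that("evaluation reproduces the stored training C-index and is REO-robust", {
  tr <- make_training(n = 60, n_pairs = 6, seed = 33)
  sig <- build_signature(tr$pairs, tr$expr, tr$records)
  expect_s3_class(sig, "reosig_signature")
  ev <- evaluate_signature(sig, tr$expr, tr$records)
  expect_equal(ev$c_index, sig$c_index)

  distorted <- apply_monotone_per_sample(tr$expr, seed = 5)
  ev2 <- evaluate_signature(sig, distorted, tr$records)
  expect_equal(ev2$classification, ev$classification)
  expect_equal(ev2$logrank_p, ev$logrank_p)
  expect_equal(ev2$c_index, ev$c_index)
})

test_that("signatures round-trip losslessly through JSON", {
  tr <- make_training(n = 60, n_pairs = 6, seed = 33)
  sig <- build_signature(tr$pairs, tr$expr, tr$records)
  expect_s3_class(sig, "reosig_signature")
  tmp <- tempfile(fileext = ".json")
  write_signature(sig, tmp)
  back <- read_signature(tmp)
  expect_equal(back$pairs, sig$pairs)
  expect_equal(back$c_index, sig$c_index)
  expect_identical(back$vote_rule, sig$vote_rule)
  expect_equal(back$path, sig$path)
  # TSV mirror exists alongside
  expect_true(file.exists(sub("\\.json$", ".tsv", tmp)))
  # and classifications agree
  expect_equal(classify_samples(tr$expr, back), classify_samples(tr$expr, sig))
})

test_that("glance and tidy summarise a signature", {
  tr <- make_training(n = 40, n_pairs = 5, seed = 50)
  sig <- build_signature(tr$pairs, tr$expr, tr$records)
  g <- glance(sig)
  expect_equal(g$n_pairs, nrow(sig$pairs))
  expect_equal(tidy(sig), sig$path)
})
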