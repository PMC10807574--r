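# Shared fixture builders: all data is generated in code at test time.

# random gene x sample matrix with ids
rand_expr <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  matrix(runif(n_genes * n_samples, 1, 100), n_genes, n_samples,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n_samples))))
}

# independent strictly increasing map per sample: x -> a * x^b + c on x > 0
apply_monotone_per_sample <- function(m, seed = 1) {
  set.seed(seed)
  for (j in seq_len(ncol(m))) {
    a <- runif(1, 0.2, 5); b <- runif(1, 0.5, 2); cc <- runif(1, 0, 10)
    m[, j] <- a * m[, j]^b + cc
  }
  m
}

# random censored survival records
rand_records <- function(n, seed = 1, rate = 0.1, censor_max = 15) {
  set.seed(seed)
  t_event <- rexp(n, rate)
  t_cens <- runif(n, 0, censor_max)
  tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(n)),
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens)
  )
}

# independent O(n^2) enumeration of Harrell's C: comparable ordered pair
# (i, j) iff t_i < t_j and subject i had the event; tied scores 0.5
cindex_bruteforce <- function(time, event, risk) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (time[i] < time[j] && event[i] == 1) {
        den <- den + 1
        if (risk[i] > risk[j]) num <- num + 1
        else if (risk[i] == risk[j]) num <- num + 0.5
      }
    }
  }
  if (den == 0) NA_real_ else num / den
}

# minimal signature object for classifier tests
make_signature <- function(gene_high, gene_low) {
  structure(
    list(
      pairs = tibble::tibble(gene_high = gene_high, gene_low = gene_low),
      vote_rule = "high if votes_high >= votes_total / 2",
      c_index = NA_real_,
      path = tibble::tibble(step = integer(0), gene_high = character(0),
                            gene_low = character(0), c_index = numeric(0)),
      provenance = list()
    ),
    class = "reosig_signature"
  )
}

# test-local half-vote labelling straight from an expression matrix
halfvote_bruteforce <- function(expr, gene_high, gene_low) {
  vapply(seq_len(ncol(expr)), function(j) {
    nh <- 0; nt <- 0
    for (p in seq_along(gene_high)) {
      if (!(gene_high[p] %in% rownames(expr)) ||
          !(gene_low[p] %in% rownames(expr))) next
      a <- expr[gene_high[p], j]; b <- expr[gene_low[p], j]
      if (a == b) next
      nt <- nt + 1
      if (a > b) nh <- nh + 1
    }
    if (nt == 0) NA_character_ else if (nh >= nt / 2) "high" else "low"
  }, character(1))
}
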