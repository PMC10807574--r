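# Prognostic gene-pair signature: candidate filtering by univariate Cox,
# C-index ranking, half-voting forward search, and per-sample
# classification. A sample's label is a pure function of its own
# expression vector and the signature.

#' Filter reversal pairs to prognostic candidates and rank by C-index
#'
#' Restricts to surgery-only samples when requested, fits a univariate Cox
#' model per pair on the binary high-risk vote, BH-adjusts the Wald
#' p-values across pairs, retains pairs with `FDR < fdr_threshold`,
#' computes each retained pair's Harrell C-index, and sorts candidates in
#' descending C-index order (ties broken by smaller Cox p-value, then
#' lexicographic pair id).
#'
#' @param pairs tibble with `gene_high`, `gene_low` (directed reversal
#'   pairs, e.g. from [intersect_cohort_reversals()]`$consistent`).
#' @param expr gene x sample matrix, or a named list of cohort matrices
#'   (votes are computed within each matrix and pooled, so cohorts never
#'   mix on the expression scale).
#' @param records tibble with `sample_id`, `time`, `event`, optionally
#'   `surgery_only`.
#' @param fdr_threshold BH FDR cutoff for the Cox filter, default 0.05.
#' @param surgery_only if `TRUE` (default) and the column is present,
#'   candidates are assessed on surgery-only samples.
#' @return Tibble of class `reosig_candidates`: `gene_high`, `gene_low`,
#'   `estimate`, `hazard_ratio`, `p_value`, `fdr`, `c_index`, sorted as
#'   described. Attributes: `n_input`, `n_tested`, `status` (`"ok"` or
#'   `"no_candidates"`).
#' @export
filter_prognostic_pairs <- function(pairs, expr, records,
                                    fdr_threshold = 0.05,
                                    surgery_only = TRUE) {
  check_records(records)
  if (!all(c("gene_high", "gene_low") %in% names(pairs))) {
    abort("`pairs` must have columns `gene_high` and `gene_low`.")
  }
  pairs <- tibble::as_tibble(pairs)
  V <- vote_matrix(expr, pairs)
  idx <- match(records$sample_id, rownames(V))
  if (anyNA(idx)) abort("`records` contains samples absent from `expr`.")
  V <- V[idx, , drop = FALSE]

  if (isTRUE(surgery_only) && "surgery_only" %in% names(records)) {
    keep <- records$surgery_only
    records <- records[keep, , drop = FALSE]
    V <- V[keep, , drop = FALSE]
  }
  if (nrow(records) < 2 || sum(records$event) < 1) {
    abort("too few samples or events after filtering for candidate assessment.")
  }
  eng <- cindex_engine(records$time, records$event)

  n_pairs <- nrow(pairs)
  est <- p <- ci <- rep(NA_real_, n_pairs)
  for (i in seq_len(n_pairs)) {
    v <- as.numeric(V[, i])
    ok <- !is.na(v)
    if (sum(ok) < 2 || length(unique(v[ok])) < 2 ||
        sum(records$event[ok]) < 1) next
    d <- data.frame(time = records$time[ok], event = records$event[ok], v = v[ok])
    fit <- suppressWarnings(
      survival::coxph(survival::Surv(time, event) ~ v, data = d,
                      ties = "efron")
    )
    b <- unname(stats::coef(fit))
    se <- sqrt(stats::vcov(fit)[1, 1])
    est[i] <- b
    p[i] <- 2 * stats::pnorm(-abs(b / se))
    if (all(ok)) {
      ci[i] <- eng(v)
    } else {
      m <- outer(ok, ok, "&")
      vv <- v; vv[!ok] <- -Inf   # masked out by `m`, value irrelevant
      ci[i] <- eng(vv, mask = m)
    }
  }

  tested <- !is.na(p)
  fdr <- rep(NA_real_, n_pairs)
  fdr[tested] <- p.adjust(p[tested], method = "BH")
  keep <- tested & fdr < fdr_threshold & !is.na(ci)

  out <- tibble::tibble(
    gene_high = pairs$gene_high[keep],
    gene_low = pairs$gene_low[keep],
    estimate = est[keep],
    hazard_ratio = exp(est[keep]),
    p_value = p[keep],
    fdr = fdr[keep],
    c_index = ci[keep]
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$c_index), .data$p_value,
                        .data$gene_high, .data$gene_low)
  status <- if (nrow(out) == 0) "no_candidates" else "ok"
  if (status == "no_candidates" && n_pairs > 0) {
    inform("no reversal pair passed the prognostic filter (status: no_candidates).")
  }
  structure(out, n_input = n_pairs, n_tested = sum(tested), status = status,
            class = c("reosig_candidates", class(out)))
}

half_vote_labels <- function(V) {
  votes_total <- unname(rowSums(!is.na(V)))
  votes_high <- unname(rowSums(V, na.rm = TRUE))
  label <- ifelse(votes_total == 0, NA_character_,
                  ifelse(votes_high >= votes_total / 2, "high", "low"))
  tibble::tibble(
    sample_id = rownames(V) %||% as.character(seq_len(nrow(V))),
    votes_high = as.integer(votes_high),
    votes_total = as.integer(votes_total),
    vote_fraction = ifelse(votes_total == 0, NA_real_,
                           votes_high / votes_total),
    label = label
  )
}

#' Forward search for the optimal gene-pair signature
#'
#' Greedy single-pass search over the ranked candidates: the signature is
#' initialised with the top-ranked pair; each subsequent candidate is
#' tentatively added, training samples are re-labelled by the half-voting
#' rule, and the candidate is kept iff the training C-index (computed on
#' the binary high/low label) strictly increases (by more than 1e-9).
#'
#' @param candidates ranked candidate tibble from
#'   [filter_prognostic_pairs()].
#' @param expr training expression matrix or named list of cohort matrices.
#' @param records training tibble with `sample_id`, `time`, `event`.
#' @return Object of class `reosig_signature`: `pairs` (tibble `gene_high`,
#'   `gene_low`), `vote_rule`, `c_index` (training), `path` (tibble of the
#'   accepted steps with the C-index sequence), `provenance` list.
#' @export
forward_search <- function(candidates, expr, records) {
  check_records(records)
  if (nrow(candidates) < 1) abort("need at least one candidate pair.")
  pairs <- tibble::tibble(gene_high = candidates$gene_high,
                          gene_low = candidates$gene_low)
  V <- vote_matrix(expr, pairs)
  idx <- match(records$sample_id, rownames(V))
  if (anyNA(idx)) abort("`records` contains samples absent from `expr`.")
  V <- V[idx, , drop = FALSE]
  eng <- cindex_engine(records$time, records$event)

  set_ci <- function(sel) {
    lab <- half_vote_labels(V[, sel, drop = FALSE])
    risk <- as.numeric(lab$label == "high")
    ok <- !is.na(risk)
    if (!all(ok)) {
      m <- outer(ok, ok, "&")
      risk[!ok] <- -Inf
      eng(risk, mask = m)
    } else {
      eng(risk)
    }
  }

  selected <- 1L
  best <- set_ci(selected)
  if (is.na(best)) abort("no comparable sample pairs in the training records.")
  path_idx <- 1L
  path_ci <- best
  for (j in seq_len(nrow(pairs))[-1]) {
    cand_ci <- set_ci(c(selected, j))
    if (!is.na(cand_ci) && cand_ci > best + 1e-9) {
      selected <- c(selected, j)
      best <- cand_ci
      path_idx <- c(path_idx, j)
      path_ci <- c(path_ci, cand_ci)
    }
  }

  structure(
    list(
      pairs = pairs[selected, ],
      vote_rule = "high if votes_high >= votes_total / 2",
      c_index = best,
      path = tibble::tibble(
        step = seq_along(path_idx),
        gene_high = pairs$gene_high[path_idx],
        gene_low = pairs$gene_low[path_idx],
        c_index = path_ci
      ),
      provenance = list(
        n_candidates = nrow(candidates),
        n_training_samples = nrow(records),
        n_training_events = sum(records$event)
      )
    ),
    class = "reosig_signature"
  )
}

#' Build a signature from reversal pairs in one call
#'
#' Runs [filter_prognostic_pairs()] then [forward_search()].
#'
#' @inheritParams filter_prognostic_pairs
#' @return A `reosig_signature` (see [forward_search()]), or `NULL` with a
#'   message when no candidate survives the prognostic filter.
#' @export
build_signature <- function(pairs, expr, records, fdr_threshold = 0.05,
                            surgery_only = TRUE) {
  cand <- filter_prognostic_pairs(pairs, expr, records,
                                  fdr_threshold = fdr_threshold,
                                  surgery_only = surgery_only)
  if (nrow(cand) == 0) return(NULL)
  sig <- forward_search(cand, expr, records)
  sig$provenance$fdr_threshold <- fdr_threshold
  sig$provenance$surgery_only <- surgery_only
  sig
}

#' Classify samples individually by the half-voting rule
#'
#' Each sample is labelled from its own expression vector alone: every
#' signature pair with both genes present and untied casts a vote
#' (high-risk iff `gene_high > gene_low` within the sample), and the
#' sample is `"high"` iff at least half of the usable pairs vote high.
#' Pairs with a missing gene or a tied value are skipped, reducing
#' `votes_total`; a sample with no usable pair is unclassifiable
#' (`label = NA`), which is distinct from `"low"`.
#'
#' @param expr gene x sample matrix, a named list of matrices, or a single
#'   named numeric vector (one sample).
#' @param signature a `reosig_signature`.
#' @return Tibble: `sample_id`, `votes_high`, `votes_total`,
#'   `vote_fraction`, `label`.
#' @export
classify_samples <- function(expr, signature) {
  if (!inherits(signature, "reosig_signature")) {
    abort("`signature` must be a `reosig_signature` object.")
  }
  if (is.numeric(expr) && !is.matrix(expr)) {
    if (is.null(names(expr))) abort("a single-sample vector must be named by gene.")
    expr <- matrix(expr, ncol = 1, dimnames = list(names(expr), "sample1"))
  }
  V <- vote_matrix(expr, signature$pairs)
  half_vote_labels(V)
}

#' Evaluate a signature on a cohort
#'
#' Classifies every sample individually, then reports Kaplan-Meier curves,
#' the log-rank test between predicted groups, the Harrell C-index of the
#' binary label, and univariate (plus optional multivariate) Cox fits.
#'
#' @param signature a `reosig_signature`.
#' @param expr gene x sample matrix or named list of cohort matrices.
#' @param records tibble with `sample_id`, `time`, `event`, and any
#'   covariate columns named in `covariates`.
#' @param covariates optional character vector of clinical covariate
#'   columns for a multivariate Cox fit alongside the signature label.
#' @return List of class `reosig_evaluation`: `classification` tibble,
#'   `km` (`reosig_km`), `logrank_p`, `c_index`, `cox_uni`, `cox_multi`
#'   (NULL unless `covariates` given), `n_unclassifiable`.
#' @export
evaluate_signature <- function(signature, expr, records, covariates = NULL) {
  check_records(records)
  cls <- classify_samples(expr, signature)
  d <- dplyr::inner_join(records, cls, by = "sample_id")
  usable <- !is.na(d$label)
  du <- d[usable, , drop = FALSE]
  if (nrow(du) < 2) abort("fewer than 2 classifiable samples.")

  km <- if (length(unique(du$label)) >= 2) km_curve(du, du$label) else NULL
  ci <- c_index(du, as.numeric(du$label == "high"))
  du$risk_label <- as.numeric(du$label == "high")
  cox_uni <- if (length(unique(du$label)) >= 2) {
    cox_fit(du, "risk_label")
  } else {
    NULL
  }
  cox_multi <- if (!is.null(covariates)) {
    cox_fit(du, c("risk_label", covariates))
  } else {
    NULL
  }
  structure(
    list(
      classification = cls,
      km = km,
      logrank_p = if (is.null(km)) NA_real_ else km$p_value,
      c_index = ci,
      cox_uni = cox_uni,
      cox_multi = cox_multi,
      n_unclassifiable = sum(is.na(cls$label))
    ),
    class = "reosig_evaluation"
  )
}

#' @export
print.reosig_signature <- function(x, ...) {
  cat(sprintf("REO gene-pair signature: %d pairs, training C-index %.3f\n",
              nrow(x$pairs), x$c_index))
  cat(sprintf("Vote rule: %s\n", x$vote_rule))
  print(head(x$pairs, 10))
  if (nrow(x$pairs) > 10) cat(sprintf("... and %d more pairs\n", nrow(x$pairs) - 10))
  invisible(x)
}

#' @export
tidy.reosig_signature <- function(x, ...) x$path

#' @export
glance.reosig_signature <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$pairs),
    c_index = x$c_index,
    n_candidates = x$provenance$n_candidates %||% NA_integer_,
    n_training_samples = x$provenance$n_training_samples %||% NA_integer_
  )
}

#' Write a signature to JSON (with a flat TSV mirror)
#'
#' The JSON carries the pair list, the vote rule, the training C-index and
#' provenance; the TSV mirror holds the `gene_high`/`gene_low` columns.
#' Round-trips losslessly through [read_signature()].
#'
#' @param signature a `reosig_signature`.
#' @param path JSON output path; the TSV mirror is written alongside with
#'   extension `.tsv` unless `tsv_path` is given.
#' @param tsv_path optional explicit TSV path (`NA` to skip).
#' @return `path`, invisibly.
#' @export
write_signature <- function(signature, path, tsv_path = NULL) {
  obj <- list(
    pairs = as.data.frame(signature$pairs),
    vote_rule = signature$vote_rule,
    c_index = signature$c_index,
    path = as.data.frame(signature$path),
    provenance = signature$provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (is.null(tsv_path)) tsv_path <- sub("\\.json$", ".tsv", path)
  if (!is.na(tsv_path)) {
    readr::write_tsv(signature$pairs, tsv_path)
  }
  invisible(path)
}

#' Read a signature written by [write_signature()]
#'
#' @param path JSON path.
#' @return A `reosig_signature`.
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      pairs = tibble::as_tibble(obj$pairs),
      vote_rule = obj$vote_rule,
      c_index = obj$c_index,
      path = tibble::as_tibble(obj$path),
      provenance = obj$provenance
    ),
    class = "reosig_signature"
  )
}
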