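# Synthetic single-cell and bulk cohort generators with planted ground truth.

#' Configuration for the synthetic data generators
#'
#' Builds and validates the parameter set shared by [simulate_single_cell()]
#' and [simulate_bulk_cohorts()]. Defaults describe the study conditions the
#' package is validated under: a modest single-cell experiment with 50 genes
#' tracking a latent stemness score, and two bulk cohorts of 150 samples with
#' a two-subtype structure, 60 planted reversal gene pairs separated by
#' `delta = 3 * sigma` on the log2 scale, a subtype hazard ratio of 2.5, and
#' per-sample monotone batch distortion.
#'
#' Expression is generated on a log2-like scale (gene baselines uniform on
#' 2..8, Gaussian noise `sigma`, floored at 0) and exponentiated for output,
#' so emitted values are linear-scale and positive; within-sample orderings
#' are identical in either space. A seeded jitter below 1e-9 breaks exact
#' ties so relative orderings are well defined.
#'
#' @param n_genes number of genes (shared universe across outputs).
#' @param n_cells number of cells in the single-cell simulation.
#' @param frac_malignant proportion of malignant cells, in (0, 1).
#' @param n_stem_genes number of planted stemness genes.
#' @param stem_effect slope (log2 units) of stem-gene expression on the
#'   latent stemness score; malignant cells additionally gain
#'   `stem_effect / 2` on stem genes.
#' @param n_cohorts number of bulk cohorts.
#' @param n_samples_per_cohort samples per bulk cohort.
#' @param n_planted_pairs number of planted reversal gene pairs.
#' @param delta log2-expression gap between the members of a planted pair
#'   (sign flips between subtypes).
#' @param stem_bulk_effect log2 elevation of the planted stem-gene set in
#'   high-risk bulk samples — the latent subtype structure the enrichment
#'   subtyping recovers. Default `NULL` means "equal to `delta`"; set 0 for
#'   a subtype-signal-free null cohort.
#' @param sigma Gaussian noise sd on the log2 scale.
#' @param subtype_prevalence probability a bulk sample is high-risk.
#' @param hazard_ratio hazard ratio of high- vs low-risk samples.
#' @param baseline_scale mean survival time (same unit as `censor_max`,
#'   nominally months) of low-risk samples under the exponential model.
#' @param censor_max upper bound of the uniform censoring distribution.
#' @param batch_mode one of `"monotone_per_sample"` (REO-preserving strictly
#'   increasing map per sample), `"genewise_shift"` (REO-perturbing
#'   per-cohort per-gene log2 offset), `"both"`, `"none"`.
#' @param frac_surgery_only probability a sample is flagged surgery-only.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#'
#' @return A validated list of class `reosig_config`.
#' @export
#' @examples
#' cfg <- synth_config(n_genes = 100, n_cells = 60, n_samples_per_cohort = 40,
#'                     n_planted_pairs = 10, seed = 7)
#' names(cfg)
synth_config <- function(n_genes = 1000,
                         n_cells = 200,
                         frac_malignant = 0.5,
                         n_stem_genes = 50,
                         stem_effect = 2,
                         n_cohorts = 2,
                         n_samples_per_cohort = 150,
                         n_planted_pairs = 60,
                         delta = 1.5,
                         stem_bulk_effect = NULL,
                         sigma = 0.5,
                         subtype_prevalence = 0.5,
                         hazard_ratio = 2.5,
                         baseline_scale = 60,
                         censor_max = 180,
                         batch_mode = c("monotone_per_sample",
                                        "genewise_shift", "both", "none"),
                         frac_surgery_only = 0.7,
                         seed = 1L) {
  modes <- c("monotone_per_sample", "genewise_shift", "both", "none")
  if (!identical(batch_mode, modes) &&
      (!is.character(batch_mode) || length(batch_mode) != 1 ||
       !batch_mode %in% modes)) {
    abort(sprintf("config field `batch_mode` must be one of: %s.",
                  paste(modes, collapse = ", ")))
  }
  batch_mode <- match.arg(batch_mode)
  cfg <- list(
    n_genes = n_genes, n_cells = n_cells, frac_malignant = frac_malignant,
    n_stem_genes = n_stem_genes, stem_effect = stem_effect,
    n_cohorts = n_cohorts, n_samples_per_cohort = n_samples_per_cohort,
    n_planted_pairs = n_planted_pairs, delta = delta,
    stem_bulk_effect = stem_bulk_effect %||% delta, sigma = sigma,
    subtype_prevalence = subtype_prevalence, hazard_ratio = hazard_ratio,
    baseline_scale = baseline_scale, censor_max = censor_max,
    batch_mode = batch_mode, frac_surgery_only = frac_surgery_only,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "reosig_config")
}

# every validation error names the offending field
validate_synth_config <- function(cfg) {
  is_count <- function(x) length(x) == 1 && is.finite(x) && x == round(x)
  count_pos <- function(field, min = 1) {
    x <- cfg[[field]]
    if (!is_count(x) || x < min) {
      abort(sprintf("config field `%s` must be an integer >= %d.", field, min))
    }
  }
  prop_open <- function(field) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0 || x >= 1) {
      abort(sprintf("config field `%s` must be a proportion in (0, 1).", field))
    }
  }
  pos_real <- function(field) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
      abort(sprintf("config field `%s` must be a positive real.", field))
    }
  }
  count_pos("n_genes", 2); count_pos("n_cells"); count_pos("n_stem_genes", 0)
  count_pos("n_cohorts"); count_pos("n_samples_per_cohort", 2)
  count_pos("n_planted_pairs", 0)
  prop_open("frac_malignant"); prop_open("subtype_prevalence")
  prop_open("frac_surgery_only")
  if (!is.numeric(cfg$stem_effect) || length(cfg$stem_effect) != 1 ||
      !is.finite(cfg$stem_effect) || cfg$stem_effect < 0) {
    abort("config field `stem_effect` must be a non-negative real.")
  }
  if (!is.numeric(cfg$stem_bulk_effect) || length(cfg$stem_bulk_effect) != 1 ||
      !is.finite(cfg$stem_bulk_effect) || cfg$stem_bulk_effect < 0) {
    abort("config field `stem_bulk_effect` must be a non-negative real.")
  }
  pos_real("delta"); pos_real("sigma"); pos_real("hazard_ratio")
  pos_real("baseline_scale"); pos_real("censor_max")
  if (cfg$n_stem_genes > cfg$n_genes) {
    abort("config field `n_stem_genes` must not exceed `n_genes`.")
  }
  if (2 * cfg$n_planted_pairs > cfg$n_genes) {
    abort("config field `n_planted_pairs`: 2 * n_planted_pairs must not exceed `n_genes`.")
  }
  if (cfg$n_stem_genes + 2 * cfg$n_planted_pairs > cfg$n_genes) {
    abort("config field `n_planted_pairs`: stem genes and pair genes must fit disjointly in `n_genes`.")
  }
  if (!is_count(cfg$seed)) abort("config field `seed` must be an integer.")
  invisible(cfg)
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))

# seeded jitter < 1e-9 breaking exact ties on the linear scale
tie_jitter <- function(x) x + runif(length(x), 0, 1e-9)

#' Simulate single-cell expression with a latent stemness gradient
#'
#' Generates a gene x cell matrix in which the planted stem genes increase
#' linearly (log2 scale, slope `stem_effect`) with a per-cell latent
#' stemness score and carry an extra `stem_effect / 2` in malignant cells;
#' all other genes are independent of both. The stemness score stands in
#' for a per-cell differentiation-potential estimate such as CytoTRACE.
#'
#' @param config a [synth_config()] object.
#' @return A list with `expr` (gene x cell linear-scale matrix), `profile`
#'   (tibble: `cell_id`, `stemness`, `malignant`), and `truth` (list with
#'   `stem_genes`).
#' @export
simulate_single_cell <- function(config) {
  validate_synth_config(config)
  set.seed(config$seed)
  g <- gene_ids(config$n_genes)
  cells <- sprintf("c%05d", seq_len(config$n_cells))
  stem_genes <- g[seq_len(config$n_stem_genes)]

  malignant <- runif(config$n_cells) < config$frac_malignant
  stemness <- runif(config$n_cells)
  base <- runif(config$n_genes, 2, 8)

  logx <- matrix(base, config$n_genes, config$n_cells) +
    matrix(rnorm(config$n_genes * config$n_cells, 0, config$sigma),
           config$n_genes, config$n_cells)
  is_stem <- seq_len(config$n_genes) <= config$n_stem_genes
  if (any(is_stem)) {
    effect <- outer(rep(config$stem_effect, sum(is_stem)),
                    stemness + 0.5 * malignant)
    logx[is_stem, ] <- logx[is_stem, ] + effect
  }
  logx <- pmax(logx, 0)
  expr <- matrix(tie_jitter(2^logx), config$n_genes, config$n_cells,
                 dimnames = list(g, cells))

  list(
    expr = expr,
    profile = tibble::tibble(cell_id = cells, stemness = stemness,
                             malignant = malignant),
    truth = list(stem_genes = stem_genes)
  )
}

#' Simulate bulk cohorts with planted subtypes, reversal pairs and survival
#'
#' Each sample is assigned a latent high/low-risk subtype with probability
#' `subtype_prevalence`. For every planted pair (a, b), the log2 mean of a
#' exceeds b by `delta` in high-risk samples and b exceeds a by `delta` in
#' low-risk samples (symmetric about a shared baseline). The planted stem
#' genes are elevated by `delta` in high-risk samples, giving the gene-set
#' enrichment subtyping a recoverable signal. Survival is exponential with
#' the hazard multiplied by `hazard_ratio` in high-risk samples; censoring
#' is uniform on (0, `censor_max`). Batch distortion follows `batch_mode`:
#' the monotone map x -> a * x^b + c (a, b > 0, c >= 0 drawn per sample) is
#' strictly increasing and thus REO-preserving, while the gene-wise shift
#' adds a per-cohort per-gene log2 offset and perturbs orderings.
#'
#' The planted structure (pair identities, gene baselines) is drawn from
#' `config$seed` alone, while sample-level draws use `cohort_seed`; calling
#' again with a different `cohort_seed` therefore yields independent
#' held-out cohorts that share the same ground truth and gene universe but
#' carry their own samples and batch distortions.
#'
#' @param config a [synth_config()] object.
#' @param cohort_seed seed for the sample-level draws (subtypes, noise,
#'   survival, batch); defaults to `config$seed + 1`.
#' @return A list with `expr` (named list of gene x sample matrices, one per
#'   cohort), `clinical` (tibble: `sample_id`, `cohort`, `os_time`,
#'   `os_event`, `surgery_only`, `subtype_truth`), and `truth` (list with
#'   `planted_pairs` tibble (`gene_high`, `gene_low`), `stem_genes`,
#'   `sample_subtype`).
#' @export
simulate_bulk_cohorts <- function(config, cohort_seed = NULL) {
  validate_synth_config(config)
  set.seed(config$seed)
  g <- gene_ids(config$n_genes)
  stem_idx <- seq_len(config$n_stem_genes)

  # pair genes drawn after the stem block so the two plants stay disjoint
  pool <- setdiff(seq_len(config$n_genes), stem_idx)
  pair_idx <- if (config$n_planted_pairs > 0) {
    matrix(sample(pool, 2 * config$n_planted_pairs), ncol = 2)
  } else {
    matrix(integer(0), ncol = 2)
  }
  planted_pairs <- tibble::tibble(
    gene_high = g[pair_idx[, 1]] %||% character(0),
    gene_low  = g[pair_idx[, 2]] %||% character(0)
  )

  base <- runif(config$n_genes, 2, 8)
  if (nrow(pair_idx)) {
    centre <- runif(nrow(pair_idx), 3, 7)
    base[pair_idx[, 1]] <- centre
    base[pair_idx[, 2]] <- centre
  }

  set.seed(as.integer(cohort_seed %||% (config$seed + 1L)))
  expr_list <- list()
  clin_list <- list()
  for (co in seq_len(config$n_cohorts)) {
    cohort_id <- sprintf("cohort%d", co)
    n <- config$n_samples_per_cohort
    ids <- sprintf("%s_s%04d", cohort_id, seq_len(n))
    high <- runif(n) < config$subtype_prevalence

    logx <- matrix(base, config$n_genes, n) +
      matrix(rnorm(config$n_genes * n, 0, config$sigma), config$n_genes, n)
    # stem-set elevation in high-risk samples
    if (length(stem_idx) && config$stem_bulk_effect > 0) {
      logx[stem_idx, high] <- logx[stem_idx, high] + config$stem_bulk_effect
    }
    # reversal plant: +delta/2 vs -delta/2, flipped between subtypes
    if (nrow(pair_idx)) {
      half <- config$delta / 2
      logx[pair_idx[, 1], high]  <- logx[pair_idx[, 1], high]  + half
      logx[pair_idx[, 2], high]  <- logx[pair_idx[, 2], high]  - half
      logx[pair_idx[, 1], !high] <- logx[pair_idx[, 1], !high] - half
      logx[pair_idx[, 2], !high] <- logx[pair_idx[, 2], !high] + half
    }
    if (config$batch_mode %in% c("genewise_shift", "both")) {
      logx <- logx + rnorm(config$n_genes, 0, 1)
    }
    logx <- pmax(logx, 0)
    x <- 2^logx
    if (config$batch_mode %in% c("monotone_per_sample", "both")) {
      a <- runif(n, 0.5, 2); b <- runif(n, 0.8, 1.25); cc <- runif(n, 0, 0.5)
      for (j in seq_len(n)) x[, j] <- a[j] * x[, j]^b[j] + cc[j]
    }
    x[] <- tie_jitter(x)
    dimnames(x) <- list(g, ids)
    expr_list[[cohort_id]] <- x

    rate <- (1 / config$baseline_scale) *
      ifelse(high, config$hazard_ratio, 1)
    t_event <- rexp(n, rate)
    t_cens <- runif(n, 0, config$censor_max)
    clin_list[[cohort_id]] <- tibble::tibble(
      sample_id = ids,
      cohort = cohort_id,
      os_time = pmin(t_event, t_cens),
      os_event = as.integer(t_event <= t_cens),
      surgery_only = runif(n) < config$frac_surgery_only,
      subtype_truth = ifelse(high, "high", "low")
    )
  }

  clinical <- dplyr::bind_rows(clin_list)
  list(
    expr = expr_list,
    clinical = clinical,
    truth = list(
      planted_pairs = planted_pairs,
      stem_genes = g[stem_idx],
      sample_subtype = setNames(clinical$subtype_truth, clinical$sample_id)
    )
  )
}
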