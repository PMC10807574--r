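# Config-driven end-to-end pipeline: stemness genes -> enrichment subtyping
# -> stable pairs -> reversal pairs -> prognostic candidates -> forward
# search -> evaluation, with a manifest of per-stage counts and file hashes.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    simulate = NULL,          # a synth_config(); otherwise supply paths
    sc_expr = NULL, sc_meta = NULL,
    bulk_expr = NULL,         # named list of cohort TSV paths
    clinical = NULL,
    r_threshold = 0.2,
    lfc_threshold = 0.25,
    fdr_genes = 0.05,
    tau = 0.25,
    top_fraction = 0.05,
    fdr_pairs = 0.05,
    fdr_candidates = 0.05,
    surgery_only = TRUE,
    run_concordance = TRUE,
    out_dir = NULL
  )
}

#' Assemble and validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list; unknown fields are rejected
#' and thresholds are validated before any stage runs.
#'
#' @param config YAML path or named list overriding the defaults (see
#'   Details in [run_reo_pipeline()]).
#' @return Validated config list of class `reosig_pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  base <- default_pipeline_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) {
    abort(sprintf("unknown config field(s): %s.", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(base, config)
  for (f in c("fdr_genes", "fdr_pairs", "fdr_candidates")) {
    x <- cfg[[f]]
    if (!is.numeric(x) || length(x) != 1 || x <= 0 || x >= 1) {
      abort(sprintf("config field `%s` must lie in (0, 1).", f))
    }
  }
  if (!is.numeric(cfg$r_threshold) || cfg$r_threshold < -1 || cfg$r_threshold > 1) {
    abort("config field `r_threshold` must lie in [-1, 1].")
  }
  if (!is.numeric(cfg$lfc_threshold) || cfg$lfc_threshold < 0) {
    abort("config field `lfc_threshold` must be non-negative.")
  }
  if (!is.numeric(cfg$tau) || cfg$tau < 0) {
    abort("config field `tau` must be non-negative.")
  }
  if (!is.numeric(cfg$top_fraction) || cfg$top_fraction <= 0 || cfg$top_fraction > 1) {
    abort("config field `top_fraction` must lie in (0, 1].")
  }
  if (!is.null(cfg$simulate) && !inherits(cfg$simulate, "reosig_config")) {
    cfg$simulate <- do.call(synth_config, cfg$simulate)
  }
  structure(cfg, class = c("reosig_pipeline_config", "list"))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage `%s` failed: %s", stage,
                  conditionMessage(e)))
  })
}

#' Run the full REO signature pipeline
#'
#' Executes, in order: stemness signature gene selection on the single-cell
#' input; ssGSEA scoring and median-split subtyping of every bulk cohort;
#' stable-pair discovery per subtype; reversal-pair detection per cohort;
#' cross-cohort intersection; prognostic candidate filtering on pooled
#' (optionally surgery-only) samples; forward search; training evaluation;
#' and, optionally, cross-cohort DEG concordance. Inputs are either
#' simulated in-memory (`config$simulate` = a [synth_config()]) or read
#' from the configured TSV paths. When `out_dir` is set, derived tables
#' are written there and their MD5 hashes recorded in the manifest.
#'
#' @param config a [pipeline_config()], a named list, or a YAML path.
#' @return Object of class `reosig_manifest`: `seed`, `thresholds`,
#'   `stages` (named list of per-stage input/output counts), `files`
#'   (named MD5 vector), and `results` (signature genes, subtypes,
#'   reversal pairs, candidates, `signature`, training `evaluation`,
#'   concordance).
#' @export
run_reo_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "reosig_pipeline_config")) config else pipeline_config(config)
  stages <- list()
  results <- list()

  inputs <- with_stage("load_inputs", {
    if (!is.null(cfg$simulate)) {
      sc <- simulate_single_cell(cfg$simulate)
      bulk <- simulate_bulk_cohorts(cfg$simulate)
      clin <- bulk$clinical
      clin$time <- clin$os_time
      clin$event <- clin$os_event
      list(sc_expr = sc$expr, sc_meta = sc$profile,
           bulk_expr = bulk$expr, clinical = clin,
           truth = list(sc = sc$truth, bulk = bulk$truth))
    } else {
      if (is.null(cfg$sc_expr) || is.null(cfg$sc_meta) ||
          is.null(cfg$bulk_expr) || is.null(cfg$clinical)) {
        abort("supply either `simulate` or all of sc_expr/sc_meta/bulk_expr/clinical.")
      }
      meta <- readr::read_tsv(cfg$sc_meta, show_col_types = FALSE, progress = FALSE)
      meta$malignant <- as.logical(meta$malignant)
      list(
        sc_expr = read_expression_tsv(cfg$sc_expr),
        sc_meta = meta,
        bulk_expr = lapply(cfg$bulk_expr, read_expression_tsv),
        clinical = read_clinical_tsv(cfg$clinical),
        truth = NULL
      )
    }
  })
  cohorts <- names(inputs$bulk_expr)
  stages$load_inputs <- list(
    n_sc_genes = nrow(inputs$sc_expr), n_cells = ncol(inputs$sc_expr),
    n_cohorts = length(cohorts),
    n_bulk_samples = sum(vapply(inputs$bulk_expr, ncol, integer(1)))
  )

  sel <- with_stage("stemness_genes", {
    stemness_signature_genes(inputs$sc_expr, inputs$sc_meta,
                             r_threshold = cfg$r_threshold,
                             lfc_threshold = cfg$lfc_threshold,
                             fdr_threshold = cfg$fdr_genes)
  })
  stages$stemness_genes <- list(
    n_g1 = sum(sel$g1_stats$selected),
    n_g2 = sum(sel$g2_stats$selected),
    n_signature_genes = length(sel$signature_genes)
  )
  results$signature_genes <- sel$signature_genes
  results$gene_stats <- sel[c("g1_stats", "g2_stats")]

  subtypes <- with_stage("enrichment_subtyping", {
    purrr::map(inputs$bulk_expr, function(m) {
      sc <- ssgsea_score(m, sel$signature_genes, tau = cfg$tau)
      median_split(sc)
    })
  })
  stages$enrichment_subtyping <- purrr::imap(subtypes, function(st, co) {
    list(n_high = sum(st$subtype == "high"), n_low = sum(st$subtype == "low"))
  })
  results$subtypes <- subtypes

  # gene universe: genes present in every cohort
  universe <- Reduce(intersect, lapply(inputs$bulk_expr, rownames))
  reversals <- with_stage("reversal_pairs", {
    purrr::imap(inputs$bulk_expr, function(m, co) {
      st <- subtypes[[co]]
      m <- m[universe, , drop = FALSE]
      hi <- find_stable_pairs(m, st$sample_id[st$subtype == "high"],
                              fdr_threshold = cfg$fdr_pairs)
      lo <- find_stable_pairs(m, st$sample_id[st$subtype == "low"],
                              fdr_threshold = cfg$fdr_pairs)
      list(stable_high = hi, stable_low = lo,
           reversals = reversal_pairs(hi, lo))
    })
  })
  stages$reversal_pairs <- purrr::imap(reversals, function(r, co) {
    list(n_stable_high = nrow(r$stable_high),
         n_stable_low = nrow(r$stable_low),
         n_reversal = nrow(r$reversals))
  })

  consistent <- with_stage("cross_cohort", {
    if (length(cohorts) >= 2) {
      acc <- reversals[[1]]$reversals
      consensus <- list(consistent = acc, n_shared = nrow(acc),
                        concordance = NA_real_, binom_p = NA_real_)
      for (co in cohorts[-1]) {
        consensus <- intersect_cohort_reversals(consensus$consistent,
                                                reversals[[co]]$reversals)
      }
      consensus
    } else {
      r <- reversals[[1]]$reversals
      list(consistent = r[, c("gene_high", "gene_low")],
           n_shared = nrow(r), concordance = NA_real_, binom_p = NA_real_)
    }
  })
  stages$cross_cohort <- list(
    n_shared = consistent$n_shared,
    concordance = consistent$concordance,
    n_consistent = nrow(consistent$consistent)
  )
  results$reversal_pairs <- consistent$consistent
  results$reversal_concordance <- consistent[c("n_shared", "concordance", "binom_p")]

  clinical <- inputs$clinical
  candidates <- with_stage("candidate_filter", {
    filter_prognostic_pairs(consistent$consistent, inputs$bulk_expr, clinical,
                            fdr_threshold = cfg$fdr_candidates,
                            surgery_only = cfg$surgery_only)
  })
  n_cand_samples <- if (isTRUE(cfg$surgery_only) &&
                        "surgery_only" %in% names(clinical)) {
    sum(clinical$surgery_only)
  } else {
    nrow(clinical)
  }
  stages$candidate_filter <- list(
    n_in = attr(candidates, "n_input"),
    n_tested = attr(candidates, "n_tested"),
    n_out = nrow(candidates),
    n_samples = n_cand_samples,
    status = attr(candidates, "status")
  )
  results$candidates <- candidates

  signature <- with_stage("forward_search", {
    if (nrow(candidates) == 0) NULL else {
      forward_search(candidates, inputs$bulk_expr, clinical)
    }
  })
  stages$forward_search <- list(
    n_pairs = if (is.null(signature)) 0L else nrow(signature$pairs),
    c_index = if (is.null(signature)) NA_real_ else signature$c_index
  )
  results$signature <- signature

  evaluation <- with_stage("evaluation", {
    if (is.null(signature)) NULL else {
      evaluate_signature(signature, inputs$bulk_expr, clinical)
    }
  })
  stages$evaluation <- list(
    logrank_p = if (is.null(evaluation)) NA_real_ else evaluation$logrank_p,
    c_index = if (is.null(evaluation)) NA_real_ else evaluation$c_index
  )
  results$evaluation <- evaluation

  if (isTRUE(cfg$run_concordance) && length(cohorts) >= 2) {
    conc <- with_stage("deg_concordance", {
      degs <- purrr::imap(inputs$bulk_expr, function(m, co) {
        deg_between_groups(m, subtypes[[co]], fdr_threshold = cfg$fdr_genes)
      })
      list(degs = degs,
           concordance = concordance_score(degs[[1]], degs[[2]]))
    })
    stages$deg_concordance <- c(
      list(n_deg = vapply(conc$degs, nrow, integer(1))),
      conc$concordance
    )
    results$deg_concordance <- conc
  }

  files <- character(0)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(cfg$out_dir, f)
    readr::write_tsv(sel$g1_stats, p("g1_stats.tsv"))
    readr::write_tsv(sel$g2_stats, p("g2_stats.tsv"))
    write_gmt(sel$signature_genes, p("signature_genes.gmt"),
              name = "stemness_signature")
    readr::write_tsv(dplyr::bind_rows(subtypes), p("subtypes.tsv"))
    readr::write_tsv(results$reversal_pairs, p("reversal_pairs.tsv"))
    readr::write_tsv(tibble::as_tibble(candidates), p("candidates.tsv"))
    if (!is.null(signature)) {
      write_signature(signature, p("signature.json"))
    }
    out_files <- list.files(cfg$out_dir, full.names = TRUE)
    files <- tools::md5sum(out_files)
    names(files) <- basename(out_files)
  }

  manifest <- structure(
    list(
      seed = if (!is.null(cfg$simulate)) cfg$simulate$seed else cfg$seed,
      thresholds = cfg[c("r_threshold", "lfc_threshold", "fdr_genes", "tau",
                         "top_fraction", "fdr_pairs", "fdr_candidates",
                         "surgery_only")],
      stages = stages,
      files = as.list(files),
      results = results,
      truth = inputs$truth
    ),
    class = "reosig_manifest"
  )
  if (!is.null(cfg$out_dir)) {
    m <- manifest
    m$results <- NULL
    m$truth <- NULL
    jsonlite::write_json(unclass(m), file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  manifest
}

#' @export
print.reosig_manifest <- function(x, ...) {
  cat("REO signature pipeline manifest (seed", x$seed, ")\n")
  for (nm in names(x$stages)) {
    flat <- unlist(x$stages[[nm]])
    vals <- vapply(flat, function(v) {
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num)) as.character(v) else format(signif(num, 4))
    }, character(1))
    cat(sprintf("  %-22s %s\n", nm,
                paste(names(vals), vals, sep = "=", collapse = ", ")))
  }
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes the bulk expression TSVs, the clinical TSV, the planted-truth
#' JSON and the planted stem-gene set as GMT; for a single-cell simulation
#' also the cell metadata TSV.
#'
#' @param sim result of [simulate_single_cell()] or
#'   [simulate_bulk_cohorts()].
#' @param dir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if (is.matrix(sim$expr)) {
    paths["expr"] <- write_expression_tsv(sim$expr, file.path(dir, "sc_expr.tsv"))
    readr::write_tsv(sim$profile, file.path(dir, "sc_meta.tsv"))
    paths["meta"] <- file.path(dir, "sc_meta.tsv")
  } else {
    for (co in names(sim$expr)) {
      f <- file.path(dir, sprintf("expr_%s.tsv", co))
      paths[paste0("expr_", co)] <- write_expression_tsv(sim$expr[[co]], f)
    }
    paths["clinical"] <- write_clinical_tsv(sim$clinical,
                                            file.path(dir, "clinical.tsv"))
  }
  truth_path <- file.path(dir, "truth.json")
  truth <- sim$truth
  if (!is.null(truth$planted_pairs)) {
    truth$planted_pairs <- as.data.frame(truth$planted_pairs)
  }
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths["truth"] <- truth_path
  if (!is.null(sim$truth$stem_genes)) {
    paths["gmt"] <- write_gmt(sim$truth$stem_genes,
                              file.path(dir, "stem_genes.gmt"),
                              name = "planted_stem_genes")
  }
  invisible(paths)
}
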