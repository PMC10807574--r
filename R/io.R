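# Plain-text readers/writers: expression TSV (genes x samples), clinical
# TSV, GMT gene sets, truth JSON.

#' Read a gene x sample expression matrix from TSV
#'
#' First column holds gene ids; remaining columns are samples.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  genes <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  check_expr(m)
}

#' Write a gene x sample expression matrix to TSV
#'
#' @param expr numeric matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  check_expr(expr)
  d <- tibble::as_tibble(expr, rownames = "gene_id")
  readr::write_tsv(d, path)
  invisible(path)
}

#' Read a clinical table from TSV
#'
#' Expects at least `sample_id`, `os_time`, `os_event`; returns the survival
#' columns renamed to `time`/`event` alongside everything else.
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_clinical_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("sample_id", "os_time", "os_event")
  missing <- setdiff(needed, names(d))
  if (length(missing)) {
    abort(sprintf("clinical table is missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  d$time <- d$os_time
  d$event <- d$os_event
  d
}

#' Write a clinical table to TSV
#'
#' @param clinical tibble with at least `sample_id`, `os_time`, `os_event`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical_tsv <- function(clinical, path) {
  readr::write_tsv(clinical, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (tab-separated: set name, description, genes...).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) abort("malformed GMT line: fewer than 3 fields.")
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors (or a single character
#'   vector, written under `name`).
#' @param path output path.
#' @param name set name used when `sets` is a bare vector.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, name = "gene_set") {
  if (!is.list(sets)) sets <- setNames(list(sets), name)
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
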