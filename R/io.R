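# Tab-delimited readers and writers for every table the pipeline
# consumes or emits.  All files are UTF-8 TSV with a header row.

read_tsv_checked <- function(path, what) {
  if (!file.exists(path)) stop_param(sprintf("%s file not found: '%s'.", what, path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop_param(sprintf("malformed %s file '%s' at line %d: %s.",
                       what, path, probs$row[1] + 1, probs$expected[1]))
  }
  df
}

parse_numeric_column <- function(x, col, path, ids) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    stop_param(sprintf(
      "non-numeric value '%s' in file '%s', column '%s', row %d (gene '%s').",
      x[bad[1]], path, col, bad[1] + 1, ids[bad[1]]
    ))
  }
  out
}

#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a header row, gene ids in the first column and one integer
#' column per sample.  Duplicate gene ids, negative counts and
#' non-integer cells are rejected with the offending gene/sample named.
#'
#' @param path Path to a tab-delimited counts file.
#' @return A counts tibble (gene_id + numeric sample columns).
#' @export
read_count_matrix <- function(path) {
  df <- read_tsv_checked(path, "counts")
  if (ncol(df) < 2) stop_param(sprintf("counts file '%s' has no sample columns.", path))
  ids <- df[[1]]
  for (j in seq(2, ncol(df))) {
    df[[j]] <- parse_numeric_column(df[[j]], names(df)[j], path, ids)
  }
  names(df)[1] <- "gene_id"
  m <- count_matrix(df)          # duplicates, negatives, missing values
  check_integer_counts(m)
  df
}

#' Read a sample design table from TSV
#'
#' Columns `sample_id`, `genotype`, `group` (sensitive/tolerant),
#' `replicate` and optionally `alias`.
#'
#' @param path Path to a tab-delimited design file.
#' @return A validated design tibble.
#' @export
read_design <- function(path) {
  df <- read_tsv_checked(path, "design")
  check_design(df)
}

#' Read a gene-length table from TSV
#'
#' Columns `gene_id` and `length_bp`.
#'
#' @param path Path to a tab-delimited gene table.
#' @return A tibble `(gene_id, length_bp)`.
#' @export
read_gene_lengths <- function(path) {
  df <- read_tsv_checked(path, "gene length")
  if (!all(c("gene_id", "length_bp") %in% names(df))) {
    stop_param(sprintf("file '%s' must have columns gene_id and length_bp.", path))
  }
  df$length_bp <- parse_numeric_column(df$length_bp, "length_bp", path, df$gene_id)
  tibble::as_tibble(df)
}

#' Read a flat term-to-gene annotation table from TSV
#'
#' Columns `gene_id`, `term_id` and optionally `term_name`; used for both
#' GO-term and pathway annotations.  The annotated universe is the set of
#' distinct gene ids in the file.
#'
#' @param path Path to a tab-delimited annotation file.
#' @return An annotation tibble with a `universe` attribute.
#' @export
read_annotation <- function(path) {
  df <- read_tsv_checked(path, "annotation")
  if (!all(c("gene_id", "term_id") %in% names(df))) {
    stop_param(sprintf("file '%s' must have columns gene_id and term_id.", path))
  }
  out <- tibble::as_tibble(df)
  attr(out, "universe") <- unique(out$gene_id)
  out
}

#' Read a qPCR threshold-cycle table from TSV
#'
#' Columns `gene_id`, `genotype`, `replicate`, `ct`.
#'
#' @param path Path to a tab-delimited CT file.
#' @param control_gene Optional control gene id to attach to the table.
#' @return A CT tibble.
#' @export
read_ct_table <- function(path, control_gene = NULL) {
  df <- read_tsv_checked(path, "qPCR CT")
  req <- c("gene_id", "genotype", "replicate", "ct")
  if (!all(req %in% names(df))) {
    stop_param(sprintf("file '%s' must have columns %s.", path,
                       paste(req, collapse = ", ")))
  }
  df$ct <- parse_numeric_column(df$ct, "ct", path, df$gene_id)
  out <- tibble::as_tibble(df)
  if (!is.null(control_gene)) attr(out, "control_gene") <- control_gene
  out
}

#' Write a table as TSV
#'
#' Plain tab-delimited writer used for every pipeline output.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}

#' Write a simulation to a directory of TSV files
#'
#' Emits `counts.tsv`, `design.tsv`, `genes.tsv` and `truth.tsv`,
#' re-readable by the package's own readers.
#'
#' @param sim An `ndeg_sim` object from [simulate_counts()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "ndeg_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(sim$counts, file.path(dir, "counts.tsv"))
  write_table(sim$design, file.path(dir, "design.tsv"))
  write_table(sim$genes, file.path(dir, "genes.tsv"))
  write_table(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
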