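#' TMM scaling factors
#'
#' Trimmed-mean-of-M-values normalization for between-sample scaling of
#' RNA-seq counts.  For each sample against a reference sample, gene-wise
#' log ratios `M = log2((y_k/N_k)/(y_r/N_r))` and average log abundances
#' `A` are computed over genes with nonzero counts in both libraries,
#' doubly trimmed (by `trim_m` on M, `trim_a` on A, each side), and the
#' scaling factor is two to the precision-weighted mean of the retained M
#' values, with weights from the delta-method (asymptotic binomial)
#' variance of M.  Factors are rescaled to have geometric mean one.
#'
#' Genes with zero counts in every sample carry no information and are
#' dropped before factor computation (their ids are recorded in the
#' `dropped_genes` attribute).  The reference sample is the one whose
#' library-size-standardized upper-quartile count (over its nonzero genes)
#' is closest to the mean across samples.
#'
#' @param counts Counts tibble: gene ids in column 1, one numeric column
#'   per sample.
#' @param trim_m Two-sided trim fraction on the log ratios M.
#' @param trim_a Two-sided trim fraction on the average log abundances A.
#' @param weighted Use precision weights (default); `FALSE` takes the
#'   unweighted trimmed mean, for sensitivity checks.
#' @param ref_sample Optional sample id to force as reference.
#'
#' @return A tibble `(sample_id, lib_size, tmm_factor, effective_size)`
#'   with `effective_size = lib_size * tmm_factor`, and attributes
#'   `reference` and `dropped_genes`.
#' @export
#' @examples
#' counts <- tibble::tibble(gene_id = paste0("g", 1:4),
#'                          a = c(10, 20, 30, 40), b = c(20, 40, 60, 80))
#' tmm_factors(counts)$tmm_factor  # proportional libraries: both 1
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05,
                        weighted = TRUE, ref_sample = NULL) {
  m <- count_matrix(counts)
  if (ncol(m) < 2) stop_param("TMM normalization needs at least two samples.")
  keep <- rowSums(m) > 0
  dropped <- rownames(m)[!keep]
  m <- m[keep, , drop = FALSE]
  lib <- colSums(m)
  if (any(lib == 0)) {
    stop_param(sprintf("sample '%s' has no nonzero counts.",
                       colnames(m)[which(lib == 0)[1]]))
  }
  uq <- vapply(seq_len(ncol(m)), function(k) {
    x <- m[, k]
    quantile(x[x > 0], 0.75, names = FALSE) / lib[k]
  }, numeric(1))
  r <- if (is.null(ref_sample)) {
    which.min(abs(uq - mean(uq)))
  } else {
    ri <- match(ref_sample, colnames(m))
    if (is.na(ri)) stop_param(sprintf("`ref_sample` '%s' not found.", ref_sample))
    ri
  }
  log_f <- vapply(seq_len(ncol(m)), function(k) {
    if (k == r) return(0)
    trimmed_mean_m(m[, k], m[, r], lib[k], lib[r], trim_m, trim_a, weighted,
                   sample = colnames(m)[k], ref = colnames(m)[r])
  }, numeric(1))
  f <- 2^log_f
  f <- f / geo_mean(f)
  out <- tibble::tibble(
    sample_id = colnames(m),
    lib_size = unname(lib),
    tmm_factor = unname(f),
    effective_size = unname(lib * f)
  )
  attr(out, "reference") <- colnames(m)[r]
  attr(out, "dropped_genes") <- dropped
  out
}

# Doubly trimmed, precision-weighted mean log ratio of one sample against
# the reference, over genes nonzero in both.
trimmed_mean_m <- function(y, yr, n, nr, trim_m, trim_a, weighted, sample, ref) {
  both <- y > 0 & yr > 0
  if (!any(both)) {
    stop_param(sprintf(
      "sample '%s' shares no nonzero genes with reference sample '%s'.",
      sample, ref
    ))
  }
  y <- y[both]
  yr <- yr[both]
  M <- log2((y / n) / (yr / nr))
  A <- 0.5 * log2((y / n) * (yr / nr))
  ng <- length(M)
  lo_m <- floor(ng * trim_m) + 1
  hi_m <- ng + 1 - lo_m
  lo_a <- floor(ng * trim_a) + 1
  hi_a <- ng + 1 - lo_a
  rk_m <- rank(M)
  rk_a <- rank(A)
  keep <- rk_m >= lo_m & rk_m <= hi_m & rk_a >= lo_a & rk_a <= hi_a
  if (!any(keep)) return(0)
  if (weighted) {
    v <- (n - y) / (n * y) + (nr - yr) / (nr * yr)
    sum(M[keep] / v[keep]) / sum(1 / v[keep])
  } else {
    mean(M[keep])
  }
}

#' Reads per kilobase per million (RPKM)
#'
#' `RPKM_gk = 1e9 * y_gk / (N_k * length_g)` with `N_k` the column total.
#'
#' @param counts Counts tibble (gene ids in column 1).
#' @param gene_lengths Data frame `(gene_id, length_bp)`; every gene in
#'   `counts` must have a positive length.
#' @return A tibble of the same shape as `counts` holding RPKM values,
#'   with attribute `value_kind = "rpkm"`.
#' @export
rpkm <- function(counts, gene_lengths) {
  m <- count_matrix(counts)
  if (!is.data.frame(gene_lengths) ||
      !all(c("gene_id", "length_bp") %in% names(gene_lengths))) {
    stop_param("`gene_lengths` must have columns `gene_id` and `length_bp`.")
  }
  len <- gene_lengths$length_bp[match(rownames(m), gene_lengths$gene_id)]
  bad <- is.na(len) | len <= 0
  if (any(bad)) {
    stop_param(sprintf("missing or non-positive length for gene(s): %s.",
                       paste(head(rownames(m)[bad], 5), collapse = ", ")))
  }
  n <- colSums(m)
  if (any(n == 0)) {
    stop_param(sprintf("sample '%s' has zero total count; RPKM undefined.",
                       colnames(m)[which(n == 0)[1]]))
  }
  vals <- 1e9 * sweep(sweep(m, 2, n, "/"), 1, len, "/")
  out <- tibble::as_tibble(cbind(tibble::tibble(gene_id = rownames(m)),
                                 tibble::as_tibble(vals)))
  attr(out, "value_kind") <- "rpkm"
  out
}

#' Log2 transform of an expression matrix
#'
#' `log2(x + pseudocount)`; the pseudocount keeps zero RPKM values finite.
#'
#' @param expr RPKM tibble from [rpkm()].
#' @param pseudocount Positive offset added before taking logs.
#' @return Tibble of log2 values, `value_kind = "log2rpkm"`, with the
#'   pseudocount recorded in attribute `pseudocount`.
#' @export
log_transform <- function(expr, pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 ||
      is.na(pseudocount) || pseudocount <= 0) {
    stop_param("`pseudocount` must be a single positive number.",
               field = "pseudocount")
  }
  kind <- attr(expr, "value_kind")
  if (!identical(kind, "rpkm")) {
    stop_param("`expr` must be an RPKM matrix (value_kind 'rpkm').")
  }
  out <- expr
  for (j in seq(2, ncol(out))) out[[j]] <- log2(out[[j]] + pseudocount)
  attr(out, "value_kind") <- "log2rpkm"
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Average replicate columns into genotype profiles
#'
#' Arithmetic mean of each genotype's replicate columns, one output column
#' per genotype, used for reporting genotype-level expression.
#'
#' @param expr Expression tibble (gene ids in column 1, sample columns).
#' @param design Sample design mapping every expression column to a
#'   genotype.
#' @return Tibble with one column per genotype,
#'   `value_kind = "genotype_mean_log2"`.
#' @export
average_replicates <- function(expr, design) {
  design <- check_design(design)
  samples <- names(expr)[-1]
  unassigned <- setdiff(samples, design$sample_id)
  if (length(unassigned) > 0) {
    stop_param(sprintf("expression columns not present in `design`: %s.",
                       paste(unassigned, collapse = ", ")))
  }
  genotypes <- unique(design$genotype)
  means <- lapply(genotypes, function(g) {
    cols <- design$sample_id[design$genotype == g]
    cols <- intersect(cols, samples)
    if (length(cols) == 0) {
      stop_param(sprintf("genotype '%s' has no columns in `expr`.", g))
    }
    rowMeans(as.matrix(expr[, cols, drop = FALSE]))
  })
  out <- tibble::as_tibble(
    c(stats::setNames(list(expr[[1]]), names(expr)[1]),
      stats::setNames(means, genotypes))
  )
  attr(out, "value_kind") <- "genotype_mean_log2"
  out
}
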