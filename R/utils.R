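# Internal validation and coercion helpers shared across the pipeline.

stop_param <- function(message, field = NULL) {
  abort(message, class = "ndeg_parameter_error", field = field)
}

geo_mean <- function(x) exp(mean(log(x)))

# Coerce a counts tibble (gene ids in column 1, one numeric column per
# sample) to a numeric matrix with gene ids as rownames.
count_matrix <- function(counts, what = "counts") {
  if (!is.data.frame(counts) || ncol(counts) < 2) {
    stop_param(sprintf(
      "`%s` must be a data frame with a gene-id column followed by at least one sample column.",
      what
    ))
  }
  ids <- as.character(counts[[1]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop_param(sprintf(
      "duplicated gene ids in `%s`: %s", what,
      paste(head(dup, 5), collapse = ", ")
    ))
  }
  m <- as.matrix(counts[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_param(sprintf("`%s` sample columns must be numeric.", what))
  if (anyNA(m)) stop_param(sprintf("`%s` contains missing values.", what))
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop_param(sprintf(
      "negative count at gene '%s', sample '%s'.",
      ids[bad[1]], colnames(m)[bad[2]]
    ))
  }
  if (any(!is.finite(m))) stop_param(sprintf("`%s` contains non-finite values.", what))
  rownames(m) <- ids
  m
}

# Raw read counts must be integers; normalized pseudo-counts need not be.
check_integer_counts <- function(m, what = "counts") {
  off <- abs(m - round(m)) > 1e-8
  if (any(off)) {
    bad <- which(off, arr.ind = TRUE)[1, ]
    gene <- rownames(m)[bad[1]] %||% as.character(bad[1])
    sample <- colnames(m)[bad[2]] %||% as.character(bad[2])
    stop_param(sprintf(
      "non-integer count (%g) in `%s` at gene '%s', sample '%s'.",
      m[bad[1], bad[2]], what, gene, sample
    ))
  }
  invisible(m)
}

check_design <- function(design) {
  req <- c("sample_id", "genotype", "group", "replicate")
  if (!is.data.frame(design)) stop_param("`design` must be a data frame.")
  miss <- setdiff(req, names(design))
  if (length(miss) > 0) {
    stop_param(sprintf("`design` is missing columns: %s.", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(design$sample_id)) stop_param("`design` has duplicated sample ids.")
  bad <- setdiff(unique(design$group), c("sensitive", "tolerant"))
  if (length(bad) > 0) {
    stop_param(sprintf(
      "`design$group` must be 'sensitive' or 'tolerant'; found: %s.",
      paste(bad, collapse = ", ")
    ))
  }
  one_group <- tapply(design$group, design$genotype, function(g) length(unique(g)) == 1L)
  if (!all(one_group)) {
    stop_param("each genotype must belong to exactly one group in `design`.")
  }
  tibble::as_tibble(design)
}

# Display label for a genotype: its numeric alias when the design carries
# one (the 1-7 library numbering), otherwise the genotype name itself.
genotype_label <- function(design, genotype) {
  if ("alias" %in% names(design)) {
    al <- design$alias[match(genotype, design$genotype)]
    if (!anyNA(al)) return(as.character(al))
  }
  as.character(genotype)
}

# Matrix of replicate columns for one genotype, in design order.
as_rep_matrix <- function(x, what = "counts") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!is.numeric(x)) stop_param(sprintf("`%s` must be numeric.", what))
  if (any(x < 0)) stop_param(sprintf("`%s` must be non-negative.", what))
  x
}
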