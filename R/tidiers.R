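# broom-style tidy()/glance() methods for the package's result objects.

#' Tidy a pairwise comparison result
#'
#' @param x An `ndeg_comparison` from [run_comparison()].
#' @param ... Unused.
#' @return The per-gene tibble with a leading `comparison` column.
#' @method tidy ndeg_comparison
#' @export
tidy.ndeg_comparison <- function(x, ...) {
  out <- tibble::as_tibble(x)
  tibble::add_column(out, comparison = attr(x, "comparison"), .before = 1)
}

#' One-row summary of a pairwise comparison
#'
#' @inheritParams tidy.ndeg_comparison
#' @return A one-row tibble: comparison label, dispersion, gene counts
#'   and the number of significant DEGs.
#' @method glance ndeg_comparison
#' @export
glance.ndeg_comparison <- function(x, ...) {
  tibble::tibble(
    comparison = attr(x, "comparison"),
    phi = attr(x, "phi"),
    n_genes = nrow(x),
    n_tested = sum(x$tested),
    n_significant = sum(x$significant)
  )
}

#' Tidy a consensus result
#'
#' @param x An `ndeg_consensus` from [build_consensus()].
#' @param ... Unused.
#' @return The per-gene records tibble.
#' @method tidy ndeg_consensus
#' @export
tidy.ndeg_consensus <- function(x, ...) x$records

#' One-row summary of a consensus result
#'
#' @inheritParams tidy.ndeg_consensus
#' @return A one-row tibble with the size of the common list, its
#'   direction partition and the number of background-excluded genes.
#' @method glance ndeg_consensus
#' @export
glance.ndeg_consensus <- function(x, ...) {
  d <- x$common$direction
  tibble::tibble(
    n_min = x$n_min,
    n_comparisons = length(x$comparisons),
    n_common = nrow(x$common),
    n_sensitive_abundant = sum(d == "sensitive_abundant"),
    n_tolerant_abundant = sum(d == "tolerant_abundant"),
    n_mixed = sum(d == "mixed"),
    n_excluded = sum(x$records$excluded)
  )
}

#' One-row summary of an enrichment result
#'
#' @param x An `ndeg_enrichment` from [enrich()].
#' @param ... Unused.
#' @return A one-row tibble with term counts and the alpha used.
#' @method glance ndeg_enrichment
#' @export
glance.ndeg_enrichment <- function(x, ...) {
  tibble::tibble(
    n_terms = nrow(x),
    n_enriched = sum(x$enriched),
    alpha = attr(x, "alpha")
  )
}

#' Tidy a qPCR/RNA-seq concordance result
#'
#' @param x An `ndeg_concordance` from [compare_to_rnaseq()].
#' @param ... Unused.
#' @return The per-gene tibble.
#' @method tidy ndeg_concordance
#' @export
tidy.ndeg_concordance <- function(x, ...) x$per_gene

#' One-row summary of a concordance result
#'
#' @inheritParams tidy.ndeg_concordance
#' @return A one-row tibble: number of genes, sign concordance, Spearman
#'   rank correlation.
#' @method glance ndeg_concordance
#' @export
glance.ndeg_concordance <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$per_gene),
    sign_concordance = x$concordance,
    rank_correlation = x$rank_correlation
  )
}
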