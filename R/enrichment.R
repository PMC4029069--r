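#' Hypergeometric upper-tail p-value for gene-set over-representation
#'
#' For an annotated universe of `N` genes of which `M` belong to a term,
#' and `n` DEGs of which `m` fall in the term, the enrichment p-value is
#' the probability of observing at least `m` term members in a draw of
#' `n` genes:
#' `P = 1 - sum_{i=0}^{m-1} C(M,i) C(N-M, n-i) / C(N,n) = P(X >= m)`.
#' Evaluated via the hypergeometric distribution function, which works in
#' log space internally, so large universes are handled without overflow.
#'
#' @param N Annotated universe size.
#' @param M Genes mapped to the term.
#' @param n DEGs within the universe.
#' @param m DEGs within the term.  All four may be vectors.
#' @return Numeric vector of upper-tail probabilities in `[0, 1]`.
#' @export
#' @examples
#' hypergeometric_pvalue(10, 5, 4, 4)  # 5/210
#' hypergeometric_pvalue(6, 3, 3, 3)   # 1/20
hypergeometric_pvalue <- function(N, M, n, m) {
  sizes <- vapply(list(N, M, n, m), length, integer(1))
  len <- max(sizes)
  if (!all(sizes %in% c(1L, len))) {
    stop_param("`N`, `M`, `n`, `m` must have length 1 or a common length.")
  }
  quad <- tibble::tibble(N = N, M = M, n = n, m = m)
  ok <- with(quad, is.finite(N) & is.finite(M) & is.finite(n) & is.finite(m) &
               N >= 0 & M >= 0 & n >= 0 & m >= 0 &
               M <= N & n <= N & m <= pmin(M, n))
  if (!all(ok)) {
    bad <- quad[which(!ok)[1], ]
    stop_param(sprintf(
      "invalid hypergeometric quadruple (N=%s, M=%s, n=%s, m=%s); need 0 <= m <= min(M, n) and M, n <= N.",
      bad$N, bad$M, bad$n, bad$m
    ))
  }
  phyper(quad$m - 1, quad$M, quad$N - quad$M, quad$n, lower.tail = FALSE)
}

#' Gene-set over-representation analysis of a DEG list
#'
#' Tests each annotated term for over-representation of the DEG list via
#' the hypergeometric upper tail.  Following the convention of defining
#' `n` as the DEGs within the annotated universe, DEGs without annotation
#' are dropped (with a warning).  Terms containing no DEG (`m = 0`,
#' necessarily `p = 1`) are omitted from the output.  The `enriched` flag
#' uses the raw p-value at level `alpha` with no multiplicity correction;
#' a BH-adjusted column `p_bh` is reported alongside for reference but
#' does not drive the flag.
#'
#' @param deg_genes Character vector of DEG ids.
#' @param annotation Flat term-to-gene table with columns `term_id`,
#'   `term_name` (optional) and `gene_id`, e.g. from [make_annotation()]
#'   or [read_annotation()].  The universe is its `universe` attribute
#'   when present, otherwise all annotated genes.
#' @param alpha Significance level for the `enriched` flag.
#'
#' @return A tibble of class `ndeg_enrichment`, one row per term with at
#'   least one DEG: `term_id`, `term_name`, `N`, `M`, `n`, `m`, `p`,
#'   `p_bh`, `enriched`, sorted by increasing `p`.
#' @export
enrich <- function(deg_genes, annotation, alpha = 0.05) {
  if (!is.data.frame(annotation) || nrow(annotation) == 0) {
    stop_param("`annotation` must be a non-empty term-to-gene table.")
  }
  if (!all(c("term_id", "gene_id") %in% names(annotation))) {
    stop_param("`annotation` needs columns `term_id` and `gene_id`.")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1) {
    stop_param("`alpha` must be a single value in (0, 1].", field = "alpha")
  }
  universe <- attr(annotation, "universe") %||% unique(annotation$gene_id)
  deg_genes <- unique(deg_genes)
  outside <- setdiff(deg_genes, universe)
  if (length(outside) > 0) {
    warn(sprintf("%d DEG(s) outside the annotated universe were dropped.",
                 length(outside)))
  }
  degs <- intersect(deg_genes, universe)
  if (length(degs) == 0) {
    warn("no DEGs fall inside the annotated universe.")
  }
  N <- length(universe)
  n <- length(degs)
  ann <- annotation[annotation$gene_id %in% universe, ]
  per_term <- dplyr::summarise(
    dplyr::group_by(ann, .data$term_id),
    term_name = if ("term_name" %in% names(ann)) .data$term_name[1] else .data$term_id[1],
    M = dplyr::n_distinct(.data$gene_id),
    m = length(intersect(unique(.data$gene_id), degs)),
    .groups = "drop"
  )
  per_term <- per_term[per_term$m >= 1, ]
  if (nrow(per_term) == 0) {
    out <- tibble::tibble(term_id = character(), term_name = character(),
                          N = integer(), M = integer(), n = integer(),
                          m = integer(), p = numeric(), p_bh = numeric(),
                          enriched = logical())
    class(out) <- c("ndeg_enrichment", class(out))
    return(out)
  }
  p <- hypergeometric_pvalue(N, per_term$M, n, per_term$m)
  out <- tibble::tibble(
    term_id = per_term$term_id,
    term_name = per_term$term_name,
    N = N, M = per_term$M, n = n, m = per_term$m,
    p = p,
    p_bh = bh_adjust(p),
    enriched = p <= alpha
  )
  out <- dplyr::arrange(out, .data$p, .data$term_id)
  attr(out, "alpha") <- alpha
  attr(out, "n_dropped_degs") <- length(outside)
  class(out) <- c("ndeg_enrichment", class(out))
  out
}
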