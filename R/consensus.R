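#' Enumerate the comparison grid for a design
#'
#' Builds the full set of pairwise comparisons implied by a two-group
#' design: every sensitive genotype against every tolerant genotype
#' (`cross`; 3 sensitive x 4 tolerant gives 12), plus all unordered
#' within-group pairs used to flag genotype-background expression
#' differences (`within_tolerant`, `within_sensitive`).  Ordering follows
#' the input order of genotypes; cross labels are
#' `sensitive/tolerant` (numeric aliases when the design carries them).
#'
#' @param design Sample design (`sample_id`, `genotype`, `group`,
#'   `replicate`, optional `alias`).
#' @return A tibble `(type, genotype_a, genotype_b, label)` where `type`
#'   is `"cross"`, `"within_tolerant"` or `"within_sensitive"`.
#' @export
#' @examples
#' sim <- simulate_counts(sim_params(n_genes = 50, seed = 1))
#' table(enumerate_comparisons(sim$design)$type)
enumerate_comparisons <- function(design) {
  design <- check_design(design)
  gt <- dplyr::distinct(design, .data$genotype, .data$group)
  sens <- gt$genotype[gt$group == "sensitive"]
  tol <- gt$genotype[gt$group == "tolerant"]
  if (length(sens) == 0) stop_param("design has no sensitive genotypes.")
  if (length(tol) == 0) stop_param("design has no tolerant genotypes.")
  cross <- purrr::map_dfr(sens, function(s) {
    tibble::tibble(type = "cross", genotype_a = s, genotype_b = tol)
  })
  within_pairs <- function(g, type) {
    if (length(g) < 2) {
      return(tibble::tibble(type = character(), genotype_a = character(),
                            genotype_b = character()))
    }
    pr <- combn(g, 2)
    tibble::tibble(type = type, genotype_a = pr[1, ], genotype_b = pr[2, ])
  }
  out <- dplyr::bind_rows(
    cross,
    within_pairs(tol, "within_tolerant"),
    within_pairs(sens, "within_sensitive")
  )
  out$label <- paste(genotype_label(design, out$genotype_a),
                     genotype_label(design, out$genotype_b), sep = "/")
  out
}

#' Run every comparison in a comparison grid
#'
#' Applies [run_comparison()] to each row of the grid from
#' [enumerate_comparisons()], reusing identical test settings for cross-
#' and within-group pairs.
#'
#' @inheritParams run_comparison
#' @param comparisons Comparison grid; defaults to the full grid for the
#'   design.
#' @param ... Passed on to [run_comparison()].
#' @return A named list of `ndeg_comparison` tibbles (names are the
#'   comparison labels), each with a `type` attribute.
#' @export
run_comparisons <- function(counts, design,
                            comparisons = enumerate_comparisons(design), ...) {
  res <- purrr::pmap(
    list(comparisons$genotype_a, comparisons$genotype_b, comparisons$type),
    function(a, b, type) {
      r <- run_comparison(counts, design, a, b, ...)
      attr(r, "type") <- type
      r
    }
  )
  names(res) <- comparisons$label
  res
}

# Align a list of comparison results on a common gene universe; errors
# list the symmetric difference when universes disagree.
align_results <- function(results) {
  if (length(results) == 0) stop_param("no comparison results supplied.")
  genes <- results[[1]]$gene_id
  for (i in seq_along(results)) {
    gi <- results[[i]]$gene_id
    if (!setequal(gi, genes) || length(gi) != length(genes)) {
      diff <- c(setdiff(genes, gi), setdiff(gi, genes))
      stop_param(sprintf(
        "comparison results do not share a gene universe; differing genes: %s.",
        paste(head(unique(diff), 10), collapse = ", ")
      ))
    }
  }
  lapply(results, function(r) r[match(genes, r$gene_id), ])
}

#' Per-gene membership count over a set of comparisons
#'
#' Counts, for every gene, the number of comparisons in which it was
#' called significantly differentially expressed -- the `n` of the
#' consensus procedure (0 to 12 over the full cross-group grid).
#'
#' @param results List of comparison result tibbles sharing one gene
#'   universe (each with `gene_id` and `significant`).
#' @return A tibble `(gene_id, membership_n)`.
#' @export
membership_counts <- function(results) {
  results <- align_results(results)
  sig <- vapply(results, function(r) r$significant, logical(nrow(results[[1]])))
  if (is.null(dim(sig))) sig <- matrix(sig, nrow = 1)
  tibble::tibble(
    gene_id = results[[1]]$gene_id,
    membership_n = as.integer(rowSums(sig))
  )
}

#' Flag genotype-background genes from within-group comparisons
#'
#' A gene differentially expressed among genotypes of the same response
#' group reflects genotype background rather than stress tolerance.
#' Genes significant in at least `tolerant_min` of the within-tolerant
#' pairs (default 5 of the 6 pairs among 4 tolerant genotypes) or at
#' least `sensitive_min` of the within-sensitive pairs (default 2 of the
#' 3 pairs among 3 sensitive genotypes) are marked for exclusion from the
#' consensus list.
#'
#' @param within_tolerant_results,within_sensitive_results Lists of
#'   comparison results for the within-group pairs (either may be empty).
#' @param tolerant_min,sensitive_min Exclusion thresholds; each must be
#'   at least 1 and no larger than the corresponding number of pairs.
#' @return A tibble `(gene_id, within_tolerant_hits,
#'   within_sensitive_hits, excluded, reason)` where `reason` is
#'   `"tolerant_background"`, `"sensitive_background"`, both joined by
#'   `";"`, or `"none"`.
#' @export
within_group_exclusion <- function(within_tolerant_results,
                                   within_sensitive_results,
                                   tolerant_min = 5, sensitive_min = 2) {
  check_min <- function(x, n_pairs, field) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != round(x)) {
      stop_param(sprintf("`%s` must be a single integer >= 1.", field),
                 field = field)
    }
    if (n_pairs > 0 && x > n_pairs) {
      stop_param(sprintf("`%s` (%d) exceeds the number of pairs (%d).",
                         field, x, n_pairs), field = field)
    }
    as.integer(x)
  }
  nt <- length(within_tolerant_results)
  ns <- length(within_sensitive_results)
  tolerant_min <- check_min(tolerant_min, nt, "tolerant_min")
  sensitive_min <- check_min(sensitive_min, ns, "sensitive_min")
  if (nt == 0 && ns == 0) {
    return(tibble::tibble(gene_id = character(),
                          within_tolerant_hits = integer(),
                          within_sensitive_hits = integer(),
                          excluded = logical(), reason = character()))
  }
  all_results <- c(within_tolerant_results, within_sensitive_results)
  aligned <- align_results(all_results)
  genes <- aligned[[1]]$gene_id
  hits <- function(res_idx) {
    if (length(res_idx) == 0) return(rep(0L, length(genes)))
    membership_counts(aligned[res_idx])$membership_n
  }
  th <- hits(seq_len(nt))
  sh <- hits(nt + seq_len(ns))
  tol_bg <- nt > 0 & th >= tolerant_min
  sens_bg <- ns > 0 & sh >= sensitive_min
  reason <- dplyr::case_when(
    tol_bg & sens_bg ~ "tolerant_background;sensitive_background",
    tol_bg ~ "tolerant_background",
    sens_bg ~ "sensitive_background",
    TRUE ~ "none"
  )
  tibble::tibble(
    gene_id = genes,
    within_tolerant_hits = th,
    within_sensitive_hits = sh,
    excluded = tol_bg | sens_bg,
    reason = reason
  )
}

#' Build the consensus (common-DEG) list
#'
#' The central inference step: count per-gene membership over the
#' cross-group comparisons, drop genes flagged as genotype background by
#' the within-group exclusion, keep genes significant in at least `n_min`
#' comparisons, and partition survivors by direction.  Direction requires
#' strict sign unanimity among the significant cells: all positive log
#' fold changes give `sensitive_abundant`, all negative
#' `tolerant_abundant`, any disagreement `mixed` (such genes stay in the
#' common list but belong to neither abundance class).
#'
#' @param cross_results Named list of cross-group comparison results
#'   (sensitive as fold-change numerator).
#' @param exclusions Exclusion tibble from [within_group_exclusion()], or
#'   `NULL` for no exclusion.
#' @param n_min Minimal membership count for the common list (1 to the
#'   number of cross comparisons).
#'
#' @return An object of class `ndeg_consensus`: a list with
#'   * `records`: per-gene tibble (`gene_id`, `membership_n`,
#'     `direction`, within-group hit counts, `excluded`, `reason`,
#'     `in_common`),
#'   * `common`: the records of common DEGs, ordered by decreasing
#'     membership,
#'   * `histogram`: tibble `(n, genes_at_n, genes_at_least_n)` for
#'     `n = 1..` number of comparisons,
#'   * `log_fc`, `significant`: per-comparison matrices as tibbles,
#'   * `comparisons`, `n_min`.
#' @export
build_consensus <- function(cross_results, exclusions = NULL, n_min = 6) {
  k <- length(cross_results)
  if (!is.numeric(n_min) || length(n_min) != 1 || is.na(n_min) ||
      n_min < 1 || n_min > k || n_min != round(n_min)) {
    stop_param(sprintf("`n_min` must be an integer in [1, %d].", k),
               field = "n_min")
  }
  aligned <- align_results(cross_results)
  genes <- aligned[[1]]$gene_id
  labels <- names(cross_results) %||%
    vapply(cross_results, function(r) attr(r, "comparison") %||% "?", character(1))
  lfc <- vapply(aligned, function(r) r$log_fc, numeric(length(genes)))
  sig <- vapply(aligned, function(r) r$significant, logical(length(genes)))
  if (is.null(dim(lfc))) {
    lfc <- matrix(lfc, nrow = 1)
    sig <- matrix(sig, nrow = 1)
  }
  colnames(lfc) <- colnames(sig) <- labels
  membership <- as.integer(rowSums(sig))
  pos_n <- rowSums(sig & lfc > 0)
  neg_n <- rowSums(sig & lfc < 0)
  direction <- dplyr::case_when(
    membership == 0 ~ NA_character_,
    pos_n == membership ~ "sensitive_abundant",
    neg_n == membership ~ "tolerant_abundant",
    TRUE ~ "mixed"
  )
  if (is.null(exclusions)) {
    excluded <- rep(FALSE, length(genes))
    reason <- rep("none", length(genes))
    th <- sh <- rep(0L, length(genes))
  } else {
    idx <- match(genes, exclusions$gene_id)
    excluded <- !is.na(idx) & exclusions$excluded[idx]
    reason <- ifelse(is.na(idx), "none", exclusions$reason[idx])
    th <- ifelse(is.na(idx), 0L, exclusions$within_tolerant_hits[idx])
    sh <- ifelse(is.na(idx), 0L, exclusions$within_sensitive_hits[idx])
  }
  records <- tibble::tibble(
    gene_id = genes,
    membership_n = membership,
    direction = direction,
    within_tolerant_hits = as.integer(th),
    within_sensitive_hits = as.integer(sh),
    excluded = excluded,
    reason = reason,
    in_common = membership >= n_min & !excluded
  )
  histogram <- tibble::tibble(
    n = seq_len(k),
    genes_at_n = vapply(seq_len(k), function(n) sum(membership == n), integer(1)),
    genes_at_least_n = vapply(seq_len(k), function(n) sum(membership >= n), integer(1))
  )
  common <- dplyr::arrange(records[records$in_common, ],
                           dplyr::desc(.data$membership_n), .data$gene_id)
  structure(
    list(
      records = records,
      common = common,
      histogram = histogram,
      log_fc = tibble::as_tibble(cbind(tibble::tibble(gene_id = genes),
                                       tibble::as_tibble(lfc))),
      significant = tibble::as_tibble(cbind(tibble::tibble(gene_id = genes),
                                            tibble::as_tibble(sig))),
      comparisons = labels,
      n_min = n_min
    ),
    class = "ndeg_consensus"
  )
}

#' @export
print.ndeg_consensus <- function(x, ...) {
  tab <- table(factor(x$common$direction,
                      levels = c("sensitive_abundant", "tolerant_abundant", "mixed")))
  cat(sprintf(
    "Consensus over %d comparisons (n >= %d): %d common DEGs\n",
    length(x$comparisons), x$n_min, nrow(x$common)
  ))
  cat(sprintf(
    "  sensitive-abundant: %d, tolerant-abundant: %d, mixed: %d; excluded as background: %d\n",
    tab[1], tab[2], tab[3], sum(x$records$excluded)
  ))
  invisible(x)
}

#' Format a consensus result as a publication-style table
#'
#' One row per gene, one column per cross comparison; significant cells
#' print the log2 fold change to one decimal and non-significant cells
#' print a marker (`"ns"` by default, `"**"` as an alternative dialect).
#'
#' @param x An `ndeg_consensus` object.
#' @param marker Non-significant cell marker.
#' @param which `"common"` (default) or `"all"` genes.
#' @return A tibble with character fold-change columns.
#' @export
format_consensus_table <- function(x, marker = c("ns", "**"), which = c("common", "all")) {
  marker <- match.arg(marker)
  which <- match.arg(which)
  stopifnot(inherits(x, "ndeg_consensus"))
  genes <- if (which == "common") x$common$gene_id else x$records$gene_id
  idx <- match(genes, x$log_fc$gene_id)
  cells <- purrr::map(x$comparisons, function(lab) {
    ifelse(x$significant[[lab]][idx],
           formatC(x$log_fc[[lab]][idx], format = "f", digits = 1),
           marker)
  })
  names(cells) <- x$comparisons
  ridx <- match(genes, x$records$gene_id)
  tibble::as_tibble(c(
    list(gene_id = genes,
         membership_n = x$records$membership_n[ridx],
         direction = x$records$direction[ridx]),
    cells
  ))
}
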