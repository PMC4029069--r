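#' Comparative 2^-ddCT relative quantification
#'
#' Quantifies a gene's expression in a test genotype relative to a
#' reference genotype, each normalized to a control (reference) gene:
#' `dCT = mean CT(gene) - mean CT(control)` per genotype,
#' `ddCT = dCT(test) - dCT(reference)`, relative quantity
#' `RQ = 2^-ddCT`.  Replicates (biological and technical alike) are
#' averaged in CT space before differencing; the standard error of RQ is
#' propagated from the replicate variances of the four CT means by the
#' delta method.
#'
#' @param ct_table Tibble `(gene_id, genotype, replicate, ct)`, e.g. from
#'   [simulate_ct_table()] or [read_ct_table()].
#' @param gene_id Target gene.
#' @param test_genotype,reference_genotype Genotypes compared; swapping
#'   them inverts RQ exactly.
#' @param control_gene Control gene id; defaults to the table's
#'   `control_gene` attribute.
#'
#' @return A one-row tibble: `gene_id`, `test_genotype`,
#'   `reference_genotype`, `delta_delta_ct`, `rq`, `log2_rq` (`= -ddCT`),
#'   `se_rq`.
#' @export
delta_delta_ct <- function(ct_table, gene_id, test_genotype,
                           reference_genotype, control_gene = NULL) {
  control_gene <- control_gene %||% attr(ct_table, "control_gene")
  if (is.null(control_gene)) {
    stop_param("`control_gene` is required (none attached to `ct_table`).")
  }
  req <- c("gene_id", "genotype", "ct")
  if (!is.data.frame(ct_table) || !all(req %in% names(ct_table))) {
    stop_param("`ct_table` must have columns gene_id, genotype, ct.")
  }
  if (any(!is.finite(ct_table$ct))) stop_param("CT values must be finite.")
  if (any(ct_table$ct < 10 | ct_table$ct > 40)) {
    warn("some CT values fall outside the typical 10-40 cycle range.")
  }
  ct_mean <- function(g, geno) {
    x <- ct_table$ct[ct_table$gene_id == g & ct_table$genotype == geno]
    if (length(x) == 0) {
      msg <- if (g == control_gene) {
        sprintf("control gene '%s' has no CT rows for genotype '%s'.", g, geno)
      } else {
        sprintf("gene '%s' has no CT rows for genotype '%s'.", g, geno)
      }
      stop_param(msg)
    }
    c(mean = mean(x), var_of_mean = if (length(x) > 1) stats::var(x) / length(x) else 0)
  }
  gt <- ct_mean(gene_id, test_genotype)
  gr <- ct_mean(gene_id, reference_genotype)
  ct <- ct_mean(control_gene, test_genotype)
  cr <- ct_mean(control_gene, reference_genotype)
  dct_test <- gt["mean"] - ct["mean"]
  dct_ref <- gr["mean"] - cr["mean"]
  ddct <- unname(dct_test - dct_ref)
  se_ddct <- sqrt(sum(gt["var_of_mean"], gr["var_of_mean"],
                      ct["var_of_mean"], cr["var_of_mean"]))
  rq <- 2^(-ddct)
  tibble::tibble(
    gene_id = gene_id,
    test_genotype = test_genotype,
    reference_genotype = reference_genotype,
    delta_delta_ct = ddct,
    rq = rq,
    log2_rq = -ddct,
    se_rq = log(2) * rq * se_ddct
  )
}

#' Quantify several genes against one reference genotype
#'
#' Convenience wrapper applying [delta_delta_ct()] to every non-control
#' gene in a CT table for one test/reference genotype pair.
#'
#' @inheritParams delta_delta_ct
#' @param genes Genes to quantify; defaults to all non-control genes.
#' @return A tibble with one row per gene.
#' @export
qpcr_report <- function(ct_table, test_genotype, reference_genotype,
                        control_gene = NULL, genes = NULL) {
  control_gene <- control_gene %||% attr(ct_table, "control_gene")
  genes <- genes %||% setdiff(unique(ct_table$gene_id), control_gene)
  purrr::map_dfr(genes, function(g) {
    delta_delta_ct(ct_table, g, test_genotype, reference_genotype, control_gene)
  })
}

#' Concordance between qPCR and RNA-seq fold changes
#'
#' Per-gene sign agreement and rank correlation between qPCR log2
#' relative quantities and RNA-seq log2 fold changes.  Both inputs must
#' share the `log2(sensitive/tolerant)` orientation: compute the qPCR RQ
#' with the sensitive genotype as test and the tolerant genotype as
#' reference, matching the fold-change convention of [run_comparison()].
#'
#' @param qpcr Data frame with columns `gene_id` and `log2_rq` (e.g. from
#'   [qpcr_report()]).
#' @param rnaseq Data frame with columns `gene_id` and `log_fc` (e.g. a
#'   comparison result or consensus records joined to fold changes).
#' @return An object of class `ndeg_concordance`: list with `per_gene`
#'   (gene_id, log2_rq, log_fc, sign_concordant), `concordance` (fraction
#'   of genes with agreeing non-zero signs) and `rank_correlation`
#'   (Spearman).
#' @export
compare_to_rnaseq <- function(qpcr, rnaseq) {
  if (!all(c("gene_id", "log2_rq") %in% names(qpcr))) {
    stop_param("`qpcr` must have columns `gene_id` and `log2_rq`.")
  }
  if (!all(c("gene_id", "log_fc") %in% names(rnaseq))) {
    stop_param("`rnaseq` must have columns `gene_id` and `log_fc`.")
  }
  shared <- intersect(qpcr$gene_id, rnaseq$gene_id)
  if (length(shared) == 0) {
    stop_param("no genes shared between the qPCR and RNA-seq inputs.")
  }
  per_gene <- tibble::tibble(
    gene_id = shared,
    log2_rq = qpcr$log2_rq[match(shared, qpcr$gene_id)],
    log_fc = rnaseq$log_fc[match(shared, rnaseq$gene_id)]
  )
  per_gene$sign_concordant <- sign(per_gene$log2_rq) == sign(per_gene$log_fc)
  nonzero <- per_gene$log2_rq != 0 | per_gene$log_fc != 0
  concordance <- if (any(nonzero)) mean(per_gene$sign_concordant[nonzero]) else 1
  rho <- if (length(shared) > 1) {
    cor(per_gene$log2_rq, per_gene$log_fc, method = "spearman")
  } else {
    NA_real_
  }
  structure(
    list(per_gene = per_gene, concordance = concordance,
         rank_correlation = rho),
    class = "ndeg_concordance"
  )
}

#' @export
print.ndeg_concordance <- function(x, ...) {
  cat(sprintf(
    "qPCR / RNA-seq concordance over %d genes: sign agreement %.2f, Spearman rho %.2f\n",
    nrow(x$per_gene), x$concordance, x$rank_correlation
  ))
  invisible(x)
}
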