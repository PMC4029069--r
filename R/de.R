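# Negative-binomial testing for a two-genotype comparison: common
# dispersion by conditional maximum likelihood on library-size-equalized
# pseudo-counts, a conditional exact test on group sums, and fold changes
# with the sensitive/tolerant sign convention.

# Rescale replicate counts to a common (geometric-mean) library size.
# Continuous values are kept for the likelihood; group sums are rounded
# only where the exact conditional distribution is evaluated.
equalize_counts <- function(ya, yb, ea, eb) {
  common <- geo_mean(c(ea, eb))
  list(
    a = sweep(ya, 2, common / ea, "*"),
    b = sweep(yb, 2, common / eb, "*")
  )
}

# Conditional NB log-likelihood of the replicates in one group given
# their per-gene total, summed over genes; terms free of phi are dropped.
cond_log_lik <- function(y, phi) {
  r <- 1 / phi
  n <- ncol(y)
  z <- rowSums(y)
  sum(rowSums(lgamma(y + r)) - n * lgamma(r) + lgamma(n * r) - lgamma(z + n * r))
}

check_effective_sizes <- function(e, y, field) {
  e <- e %||% colSums(y)
  if (!is.numeric(e) || length(e) != ncol(y) || any(!is.finite(e)) || any(e <= 0)) {
    stop_param(sprintf(
      "`%s` must be %d positive finite values.", field, ncol(y)
    ), field = field)
  }
  e
}

#' Estimate a common negative-binomial dispersion for one comparison
#'
#' Maximizes the summed conditional NB log-likelihood of the replicate
#' counts given their per-gene group totals, after rescaling every
#' library to the geometric-mean effective size.  The conditional
#' likelihood is free of the per-gene means, so a single dispersion `phi`
#' (`variance = mu + phi * mu^2`) is estimated by bounded one-dimensional
#' search over `[1e-6, 10]`.
#'
#' @param counts_a,counts_b Numeric matrices (genes x replicates) for the
#'   two genotypes; rows must align.
#' @param effective_sizes_a,effective_sizes_b Effective library sizes
#'   (library size times TMM factor); default column totals.
#' @param interval Search interval for `phi`.
#'
#' @return A list of class `ndeg_dispersion` with elements `phi`,
#'   `method` (`"conditional_ml"`) and `n_genes_used`.
#' @export
estimate_common_dispersion <- function(counts_a, counts_b,
                                       effective_sizes_a = NULL,
                                       effective_sizes_b = NULL,
                                       interval = c(1e-6, 10)) {
  ya <- as_rep_matrix(counts_a, "counts_a")
  yb <- as_rep_matrix(counts_b, "counts_b")
  if (nrow(ya) != nrow(yb)) stop_param("`counts_a` and `counts_b` must have the same genes.")
  if (ncol(ya) < 2 || ncol(yb) < 2) {
    stop_param("each genotype needs at least 2 replicates to estimate dispersion.")
  }
  if (sum(ya) + sum(yb) == 0) stop_param("all genes have zero total count.")
  ea <- check_effective_sizes(effective_sizes_a, ya, "effective_sizes_a")
  eb <- check_effective_sizes(effective_sizes_b, yb, "effective_sizes_b")
  z <- equalize_counts(ya, yb, ea, eb)
  nonzero <- rowSums(z$a) + rowSums(z$b) > 0
  if (!any(nonzero)) stop_param("all genes have zero total count.")
  if (sum(nonzero) < 50) {
    warn(sprintf(
      "only %d genes with nonzero totals; the common dispersion estimate may be unstable.",
      sum(nonzero)
    ))
  }
  za <- z$a[nonzero, , drop = FALSE]
  zb <- z$b[nonzero, , drop = FALSE]
  ll <- function(phi) cond_log_lik(za, phi) + cond_log_lik(zb, phi)
  opt <- optimize(ll, interval = interval, maximum = TRUE, tol = 1e-6)
  if (!is.finite(opt$objective)) {
    stop_param(sprintf(
      "dispersion estimation did not converge (objective %g at phi %g).",
      opt$objective, opt$maximum
    ))
  }
  phi <- opt$maximum
  # optimize() never returns an endpoint; prefer the boundary when the
  # likelihood is monotone towards it (Poisson-like data).
  if (ll(interval[1]) >= opt$objective) phi <- interval[1]
  if (ll(interval[2]) >= opt$objective) phi <- interval[2]
  structure(
    list(phi = phi, method = "conditional_ml", n_genes_used = sum(nonzero)),
    class = "ndeg_dispersion"
  )
}

#' @export
print.ndeg_dispersion <- function(x, ...) {
  cat(sprintf("Common NB dispersion: phi = %.4g (%s, %d genes)\n",
              x$phi, x$method, x$n_genes_used))
  invisible(x)
}

# Two-sided conditional exact p-value for one gene, from the rounded
# group sums `sa` and `sb` on the equalized scale.  Conditional on the
# total, the group-A sum follows the convolution-ratio NB distribution
# (negative hypergeometric); at phi = 0 it reduces to a binomial.
exact_nb_p1 <- function(sa, sb, na, nb, phi) {
  t <- sa + sb
  if (t == 0) return(1)
  # canonical group order makes swap symmetry exact in floating point
  if (sa > sb || (sa == sb && na > nb)) {
    tmp <- sa; sa <- sb; sb <- tmp
    tmp <- na; na <- nb; nb <- tmp
  }
  if (phi == 0) {
    pr <- na / (na + nb)
    lower <- pbinom(sa, t, pr)
    upper <- pbinom(sa - 1, t, pr, lower.tail = FALSE)
  } else {
    r <- 1 / phi
    mu <- t / (na + nb)
    y <- 0:t
    lp <- dnbinom(y, size = na * r, mu = na * mu, log = TRUE) +
      dnbinom(t - y, size = nb * r, mu = nb * mu, log = TRUE)
    lp <- lp - max(lp)
    pr_y <- exp(lp)
    pr_y <- pr_y / sum(pr_y)
    lower <- sum(pr_y[y <= sa])
    upper <- sum(pr_y[y >= sa])
  }
  min(2 * min(lower, upper), 1)
}

#' Conditional negative-binomial exact test
#'
#' Per-gene two-sided exact test of equal expression between two groups of
#' replicate libraries.  Counts are first rescaled to a common library
#' size (pseudo-counts); conditional on a gene's rounded total, the
#' group-A sum follows the distribution obtained by convolving NB
#' replicates within each group, which is free of the unknown mean.  The
#' two-sided p-value doubles the smaller tail (each tail includes the
#' observed outcome) and is capped at 1, so `p` is always in `(0, 1]`.
#' At `phi = 0` the conditional distribution is binomial (Poisson limit).
#'
#' @param counts_a,counts_b Non-negative integer matrices (genes x
#'   replicates), or vectors for a single gene.
#' @param effective_sizes_a,effective_sizes_b Effective library sizes;
#'   default column totals.
#' @param phi Common NB dispersion, a single value >= 0.
#'
#' @return Numeric vector of p-values, one per gene.
#' @export
#' @examples
#' # symmetric split of the total with equal sizes: p = 1
#' exact_nb_test(matrix(10, 1, 4), matrix(10, 1, 4),
#'               rep(1e6, 4), rep(1e6, 4), phi = 0.1)
exact_nb_test <- function(counts_a, counts_b,
                          effective_sizes_a = NULL, effective_sizes_b = NULL,
                          phi) {
  if (!is.numeric(phi) || length(phi) != 1 || is.na(phi) || phi < 0) {
    stop_param("`phi` must be a single number >= 0.", field = "phi")
  }
  ya <- as_rep_matrix(counts_a, "counts_a")
  yb <- as_rep_matrix(counts_b, "counts_b")
  if (nrow(ya) != nrow(yb)) stop_param("`counts_a` and `counts_b` must have the same genes.")
  check_integer_counts(ya, "counts_a")
  check_integer_counts(yb, "counts_b")
  ea <- check_effective_sizes(effective_sizes_a, ya, "effective_sizes_a")
  eb <- check_effective_sizes(effective_sizes_b, yb, "effective_sizes_b")
  z <- equalize_counts(ya, yb, ea, eb)
  sa <- round(rowSums(z$a))
  sb <- round(rowSums(z$b))
  na <- ncol(ya)
  nb <- ncol(yb)
  vapply(seq_along(sa), function(g) exact_nb_p1(sa[g], sb[g], na, nb, phi),
         numeric(1))
}

#' Log2 fold change between two genotypes
#'
#' `log2` of the ratio of prior-augmented mean normalized counts, group A
#' over group B.  With the cross-group convention the sensitive genotype
#' is group A, giving `log2(sensitive/tolerant)`.  The prior count keeps
#' fold changes finite when one group has no reads; two all-zero groups
#' give 0.
#'
#' @inheritParams exact_nb_test
#' @param prior_count Positive prior added to each group's mean
#'   normalized count.
#' @return Numeric vector of log2 fold changes.
#' @export
nb_log_fc <- function(counts_a, counts_b,
                      effective_sizes_a = NULL, effective_sizes_b = NULL,
                      prior_count = 0.125) {
  if (!is.numeric(prior_count) || length(prior_count) != 1 || prior_count <= 0) {
    stop_param("`prior_count` must be a single positive number.",
               field = "prior_count")
  }
  ya <- as_rep_matrix(counts_a, "counts_a")
  yb <- as_rep_matrix(counts_b, "counts_b")
  if (nrow(ya) != nrow(yb)) stop_param("`counts_a` and `counts_b` must have the same genes.")
  ea <- check_effective_sizes(effective_sizes_a, ya, "effective_sizes_a")
  eb <- check_effective_sizes(effective_sizes_b, yb, "effective_sizes_b")
  z <- equalize_counts(ya, yb, ea, eb)
  ma <- rowMeans(z$a)
  mb <- rowMeans(z$b)
  log2((ma + prior_count) / (mb + prior_count))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: sort ascending, take running minima of
#' `m * p_(j) / j` from the largest rank down, cap at 1, restore the
#' original order.  Wraps [stats::p.adjust()] after validating the input.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop_param("`p` must be numeric values in [0, 1] with no missing values.")
  }
  p.adjust(p, method = "BH")
}

#' Differential expression between two genotypes
#'
#' Runs the full per-pair analysis on the two genotypes' columns: TMM
#' normalization restricted to this pair, common-dispersion estimation,
#' the conditional NB exact test per gene, BH-FDR adjustment within the
#' comparison, and the significance call
#' `|log2FC| >= lfc_threshold AND FDR < fdr_threshold`.  Genotype A is
#' the fold-change numerator; for cross-group comparisons pass the
#' sensitive genotype as `genotype_a` so that
#' `log_fc = log2(sensitive/tolerant)`.
#'
#' Genes whose total count across the two genotypes falls below
#' `min_total` are reported with `p_value = fdr = 1`, marked
#' `tested = FALSE`, and left out of the BH denominator so they do not
#' dilute the FDR.
#'
#' @param counts Counts tibble (gene ids in column 1).
#' @param design Sample design (`sample_id`, `genotype`, `group`,
#'   `replicate`, optional `alias` used in the comparison label).
#' @param genotype_a,genotype_b Genotypes to compare; A is the numerator.
#' @param lfc_threshold Absolute log2-fold-change cutoff (ties count as
#'   significant).
#' @param fdr_threshold FDR cutoff (strict).
#' @param prior_count Prior for [nb_log_fc()].
#' @param min_total Minimal-expression filter on the pair-wise total count.
#' @param phi Optional fixed dispersion; estimated when `NULL`.
#' @param trim_m,trim_a TMM trim fractions.
#'
#' @return A tibble of class `ndeg_comparison` with columns `gene_id`,
#'   `log_fc`, `p_value`, `fdr`, `significant`, `tested` and attributes
#'   `comparison` (label such as `"1/3"`), `genotype_a`, `genotype_b`,
#'   `phi`, `norm_factors` and `thresholds`.
#' @seealso [run_comparisons()] for the whole comparison grid.
#' @export
run_comparison <- function(counts, design, genotype_a, genotype_b,
                           lfc_threshold = 1, fdr_threshold = 0.001,
                           prior_count = 0.125, min_total = 5, phi = NULL,
                           trim_m = 0.30, trim_a = 0.05) {
  design <- check_design(design)
  available <- unique(design$genotype)
  for (g in c(genotype_a, genotype_b)) {
    if (!g %in% available) {
      stop_param(sprintf("unknown genotype '%s'; available: %s.",
                         g, paste(available, collapse = ", ")))
    }
  }
  sa <- design$sample_id[design$genotype == genotype_a]
  sb <- design$sample_id[design$genotype == genotype_b]
  if (length(sa) < 2 || length(sb) < 2) {
    stop_param("both genotypes need at least 2 replicate samples.")
  }
  missing_cols <- setdiff(c(sa, sb), names(counts))
  if (length(missing_cols) > 0) {
    stop_param(sprintf("samples missing from `counts`: %s.",
                       paste(missing_cols, collapse = ", ")))
  }
  sub <- counts[, c(names(counts)[1], sa, sb)]
  m <- count_matrix(sub)
  check_integer_counts(m)
  nf <- tmm_factors(sub, trim_m = trim_m, trim_a = trim_a)
  eff <- setNames(nf$effective_size, nf$sample_id)
  ya <- m[, sa, drop = FALSE]
  yb <- m[, sb, drop = FALSE]
  tested <- rowSums(m) >= min_total
  if (is.null(phi)) {
    phi <- estimate_common_dispersion(ya[tested, , drop = FALSE],
                                      yb[tested, , drop = FALSE],
                                      eff[sa], eff[sb])$phi
  }
  p <- rep(1, nrow(m))
  p[tested] <- exact_nb_test(ya[tested, , drop = FALSE],
                             yb[tested, , drop = FALSE],
                             eff[sa], eff[sb], phi)
  fdr <- rep(1, nrow(m))
  fdr[tested] <- bh_adjust(p[tested])
  lfc <- unname(nb_log_fc(ya, yb, eff[sa], eff[sb], prior_count))
  out <- tibble::tibble(
    gene_id = rownames(m),
    log_fc = lfc,
    p_value = p,
    fdr = fdr,
    significant = abs(lfc) >= lfc_threshold & fdr < fdr_threshold,
    tested = tested
  )
  label <- paste(genotype_label(design, genotype_a),
                 genotype_label(design, genotype_b), sep = "/")
  attr(out, "comparison") <- label
  attr(out, "genotype_a") <- genotype_a
  attr(out, "genotype_b") <- genotype_b
  attr(out, "phi") <- phi
  attr(out, "norm_factors") <- nf
  attr(out, "thresholds") <- c(lfc = lfc_threshold, fdr = fdr_threshold)
  class(out) <- c("ndeg_comparison", class(out))
  out
}
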