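# Shared fixtures and independent oracles, all built in code.

# Two-genotype null design (4 vs 4 replicates).
two_group_design <- function(n_rep = 4) {
  tibble::tibble(
    sample_id = paste0(rep(c("A", "B"), each = n_rep), ".", rep(seq_len(n_rep), 2)),
    genotype = rep(c("A", "B"), each = n_rep),
    group = rep(c("sensitive", "tolerant"), each = n_rep),
    replicate = rep(seq_len(n_rep), 2)
  )
}

# Null NB counts for two genotypes: log2-normal abundances, uniform
# library sizes, common dispersion phi, no differential expression.
null_two_group_counts <- function(n_genes, seed, phi = 0.1, n_rep = 4,
                                  lib_range = c(5e5, 1e6),
                                  abundance = c(4, 2)) {
  set.seed(seed)
  design <- two_group_design(n_rep)
  p <- 2^rnorm(n_genes, abundance[1], abundance[2])
  p <- p / sum(p)
  lib <- round(runif(nrow(design), lib_range[1], lib_range[2]))
  mu <- p %o% lib
  cnt <- if (phi > 0) {
    matrix(rnbinom(n_genes * nrow(design), mu = mu, size = 1 / phi),
           n_genes, nrow(design))
  } else {
    matrix(rpois(n_genes * nrow(design), mu), n_genes, nrow(design))
  }
  colnames(cnt) <- design$sample_id
  counts <- tibble::as_tibble(cbind(
    tibble::tibble(gene_id = sprintf("G%05d", seq_len(n_genes))),
    tibble::as_tibble(cnt)
  ))
  list(counts = counts, design = design)
}

# Minimal fake comparison result for consensus-level tests.
fake_comparison <- function(gene_id, log_fc, significant, label) {
  out <- tibble::tibble(
    gene_id = gene_id,
    log_fc = log_fc,
    p_value = ifelse(significant, 1e-6, 0.5),
    fdr = ifelse(significant, 1e-4, 0.9),
    significant = significant,
    tested = TRUE
  )
  attr(out, "comparison") <- label
  out
}

cross_labels <- c("1/3", "1/4", "1/5", "1/6", "2/3", "2/4", "2/5", "2/6",
                  "7/3", "7/4", "7/5", "7/6")

# Published-style fold-change rows (NA = non-significant cell) for three
# genes with known membership counts 5, 9 and 6.
fixture_rows <- function() {
  list(
    "Sb06g031460" = c(NA, 4.1, 5.3, 6, -4, NA, NA, NA, -2.6, NA, NA, NA),
    "Sb07g004700" = c(3.9, 5.0, 8.4, 3.4, 3.1, 4.2, 7.5, 2.6, NA, NA, 6.8, NA),
    "Sb01g038720" = c(-7.0, -7.7, NA, -6.7, -7.0, -7.6, NA, -6.7, NA, NA, NA, NA)
  )
}

# The fixture rows as a list of 12 fake comparison results.
fixture_results <- function() {
  rows <- fixture_rows()
  genes <- names(rows)
  mat <- do.call(rbind, rows)
  res <- lapply(seq_along(cross_labels), function(j) {
    sig <- !is.na(mat[, j])
    fake_comparison(genes, ifelse(sig, mat[, j], 0), sig, cross_labels[j])
  })
  names(res) <- cross_labels
  res
}

# Independent oracle: conditional binomial tail p-value (Poisson limit of
# the exact NB test at equal library sizes), from explicit binomial pmf.
binom_tail_oracle <- function(sa, t, na, nb) {
  pr <- na / (na + nb)
  y <- 0:t
  pmf <- choose(t, y) * pr^y * (1 - pr)^(t - y)
  lower <- sum(pmf[y <= sa])
  upper <- sum(pmf[y >= sa])
  min(2 * min(lower, upper), 1)
}

# Independent oracle: hypergeometric upper tail by exhaustive enumeration
# of all C(N, n) draws.
hyper_enum_oracle <- function(N, M, n, m) {
  if (n == 0) return(as.numeric(m == 0))
  draws <- combn(N, n)
  cnt <- colSums(matrix(draws <= M, nrow = n))
  mean(cnt >= m)
}

# Independent oracle: BH step-up adjustment from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, m * p[o] / seq_len(m))
  for (i in rev(seq_len(m - 1))) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- adj
  out
}
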