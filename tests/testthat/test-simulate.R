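test_that("simulation is reproducible and validates its parameters", {
  p <- sim_params(n_genes = 150, library_size_range = c(5e4, 1e5),
                  n_tolerance_degs_up_tolerant = 10,
                  n_tolerance_degs_up_sensitive = 10,
                  n_background_degs = 20, seed = 11)
  s1 <- simulate_counts(p)
  s2 <- simulate_counts(p)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$design, s2$design)

  s3 <- simulate_counts(sim_params(n_genes = 150,
                                   library_size_range = c(5e4, 1e5),
                                   n_tolerance_degs_up_tolerant = 10,
                                   n_tolerance_degs_up_sensitive = 10,
                                   n_background_degs = 20, seed = 12))
  expect_false(identical(s1$counts, s3$counts))

  expect_error(sim_params(n_replicates = 1), class = "ndeg_parameter_error")
  expect_error(sim_params(n_replicates = 1), "n_replicates")
  expect_error(sim_params(dispersion = -0.1), "dispersion")
  expect_error(
    sim_params(n_genes = 100, n_background_degs = 90,
               n_tolerance_degs_up_tolerant = 20),
    "n_genes"
  )
  one_tol <- data.frame(
    genotype = c("a", "b", "c"),
    group = c("sensitive", "sensitive", "tolerant")
  )
  expect_error(sim_params(genotypes = one_tol), "at least 2")
})

test_that("simulated counts have the requested NB moments", {
  many_reps <- sim_params(
    n_genes = 1000,
    genotypes = data.frame(genotype = c("s1", "s2", "t1", "t2"),
                           group = c("sensitive", "sensitive",
                                     "tolerant", "tolerant")),
    n_replicates = 40,
    dispersion = 0,
    library_size_range = c(8e5, 8e5),
    n_tolerance_degs_up_tolerant = 0, n_tolerance_degs_up_sensitive = 0,
    n_background_degs = 0,
    seed = 21
  )
  sim <- simulate_counts(many_reps)
  m <- as.matrix(sim$counts[, sim$design$sample_id[sim$design$genotype == "s1"]])
  mu_hat <- rowMeans(m)
  v_hat <- apply(m, 1, var)
  keep <- mu_hat > 5
  # Poisson limit: variance/mean ratio centered at 1
  expect_gt(mean(v_hat[keep] / mu_hat[keep]), 0.9)
  expect_lt(mean(v_hat[keep] / mu_hat[keep]), 1.1)

  nb <- simulate_counts(sim_params(
    n_genes = 1000,
    genotypes = data.frame(genotype = c("s1", "s2", "t1", "t2"),
                           group = c("sensitive", "sensitive",
                                     "tolerant", "tolerant")),
    n_replicates = 60,
    dispersion = 0.2,
    library_size_range = c(8e5, 8e5),
    n_tolerance_degs_up_tolerant = 0, n_tolerance_degs_up_sensitive = 0,
    n_background_degs = 0,
    seed = 22
  ))
  m <- as.matrix(nb$counts[, nb$design$sample_id[nb$design$genotype == "s1"]])
  mu_hat <- rowMeans(m)
  v_hat <- apply(m, 1, var)
  keep <- mu_hat > 50
  phi_hat <- (v_hat[keep] - mu_hat[keep]) / mu_hat[keep]^2
  expect_gt(mean(phi_hat), 0.15)
  expect_lt(mean(phi_hat), 0.25)
})

test_that("planted effects appear in raw group means at the stated size", {
  p <- sim_params(
    n_genes = 300,
    mean_log2_expression = c(4, 0),       # equal abundance: mu = L / n_genes
    library_size_range = c(1.5e5, 1.5e5), # baseline mean ~500 per sample
    n_tolerance_degs_up_tolerant = 20,
    n_tolerance_degs_up_sensitive = 0,
    n_background_degs = 0,
    planted_log2fc = 2,
    seed = 31
  )
  sim <- simulate_counts(p)
  up_tol <- sim$truth$gene_id[sim$truth$class == "tolerance_up_tolerant"]
  m <- as.matrix(sim$counts[, -1])
  rownames(m) <- sim$counts$gene_id
  tol_cols <- sim$design$sample_id[sim$design$group == "tolerant"]
  sens_cols <- sim$design$sample_id[sim$design$group == "sensitive"]
  ratio <- log2(rowMeans(m[up_tol, tol_cols]) / rowMeans(m[up_tol, sens_cols]))
  expect_lt(max(abs(ratio - 2)), 0.6)
  expect_lt(abs(mean(ratio) - 2), 0.15)
  # orientation bookkeeping: sensitive/tolerant log2 FC is -2 for these genes
  expect_true(all(sim$truth$true_log2fc[sim$truth$gene_id %in% up_tol] == -2))
})

test_that("synthetic annotation reflects the requested enrichment strength", {
  sim <- simulate_counts(sim_params(n_genes = 400,
                                    library_size_range = c(5e4, 1e5),
                                    n_tolerance_degs_up_tolerant = 40,
                                    n_tolerance_degs_up_sensitive = 40,
                                    n_background_degs = 40, seed = 41))
  truth <- sim$truth
  planted <- truth$gene_id[truth$class != "null"]

  # full strength: enriched terms consist only of planted genes
  ann1 <- make_annotation(truth, n_terms = 20, enrichment_strength = 1, seed = 1)
  for (tid in attr(ann1, "enriched_terms")) {
    expect_true(all(ann1$gene_id[ann1$term_id == tid] %in% planted))
  }

  # determinism
  expect_identical(
    make_annotation(truth, n_terms = 20, enrichment_strength = 0.5, seed = 9),
    make_annotation(truth, n_terms = 20, enrichment_strength = 0.5, seed = 9)
  )

  # zero strength: membership independent of class (chi-square, many seeds)
  pvals <- vapply(1:30, function(s) {
    ann <- make_annotation(truth, n_terms = 20, enrichment_strength = 0, seed = s)
    in_term <- truth$gene_id %in% ann$gene_id
    is_planted <- truth$class != "null"
    suppressWarnings(stats::chisq.test(table(in_term, is_planted))$p.value)
  }, numeric(1))
  expect_lte(mean(pvals < 0.01), 0.1)

  expect_warning(empty <- make_annotation(truth, n_terms = 0), "empty annotation")
  expect_equal(nrow(empty), 0)
  expect_error(make_annotation(truth, enrichment_strength = 1.5),
               "enrichment_strength")
})

test_that("simulated CT tables encode planted effects in cycles", {
  sim <- simulate_counts(sim_params(n_genes = 200,
                                    library_size_range = c(5e4, 1e5),
                                    n_tolerance_degs_up_tolerant = 20,
                                    n_tolerance_degs_up_sensitive = 20,
                                    n_background_degs = 20,
                                    planted_log2fc = 2, seed = 51))
  truth <- sim$truth
  up_tol <- truth$gene_id[truth$class == "tolerance_up_tolerant"][1]
  null_g <- truth$gene_id[truth$class == "null"][1]
  ctrl <- truth$gene_id[truth$class == "null"][2]

  ct <- simulate_ct_table(truth, sim$design, c(up_tol, null_g), ctrl,
                          ct_noise_sd = 0, seed = 1)
  # control CT constant; target shifted down 2 cycles in tolerant genotypes
  expect_equal(unique(ct$ct[ct$gene_id == ctrl]), 25)
  rq <- delta_delta_ct(ct, up_tol, test_genotype = "SanChiSan",
                       reference_genotype = "CK60")
  expect_equal(rq$rq, 4)
  expect_equal(rq$delta_delta_ct, -2)
  rq0 <- delta_delta_ct(ct, null_g, "SanChiSan", "CK60")
  expect_equal(rq0$delta_delta_ct, 0)
  expect_equal(rq0$rq, 1)

  # a planted gene cannot serve as the control
  expect_error(
    simulate_ct_table(truth, sim$design, null_g, up_tol, seed = 1),
    "planted effect"
  )

  # determinism
  expect_identical(
    simulate_ct_table(truth, sim$design, up_tol, ctrl, seed = 3),
    simulate_ct_table(truth, sim$design, up_tol, ctrl, seed = 3)
  )
})

test_that("noisy CT tables recover planted fold changes within half a log2 unit", {
  sim <- simulate_counts(sim_params(n_genes = 200,
                                    library_size_range = c(5e4, 1e5),
                                    n_tolerance_degs_up_tolerant = 20,
                                    n_tolerance_degs_up_sensitive = 20,
                                    n_background_degs = 20,
                                    planted_log2fc = 2, seed = 61))
  truth <- sim$truth
  gene <- truth$gene_id[truth$class == "tolerance_up_tolerant"][1]
  ctrl <- truth$gene_id[truth$class == "null"][1]
  rec <- vapply(1:100, function(s) {
    ct <- simulate_ct_table(truth, sim$design, gene, ctrl,
                            ct_noise_sd = 0.2, seed = s)
    delta_delta_ct(ct, gene, "SanChiSan", "CK60")$log2_rq
  }, numeric(1))
  expect_lt(abs(mean(rec) - 2), 0.5)
  expect_gte(mean(abs(rec - 2) <= 0.5), 0.9)
})
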