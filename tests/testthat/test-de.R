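test_that("common dispersion is recovered from simulated counts", {
  # Poisson data: estimate collapses to the lower boundary
  sim <- null_two_group_counts(2000, seed = 91, phi = 0,
                               lib_range = c(2e5, 3e5))
  m <- as.matrix(sim$counts[, -1])
  est <- estimate_common_dispersion(m[, 1:4], m[, 5:8])
  expect_lte(est$phi, 0.02)
  expect_equal(est$method, "conditional_ml")

  # phi = 0.1 data: estimates concentrate around the truth across seeds
  phis <- vapply(1:20, function(s) {
    sim <- null_two_group_counts(2000, seed = 100 + s, phi = 0.1,
                                 lib_range = c(2e5, 3e5))
    m <- as.matrix(sim$counts[, -1])
    estimate_common_dispersion(m[, 1:4], m[, 5:8])$phi
  }, numeric(1))
  expect_true(all(phis >= 0.07 & phis <= 0.13))

  # all-zero genes carry no conditional information
  m2 <- rbind(m, matrix(0, 50, 8))
  est2 <- estimate_common_dispersion(m2[, 1:4], m2[, 5:8])
  expect_equal(est2$phi, est$phi, tolerance = 1e-6)

  expect_error(
    estimate_common_dispersion(matrix(0, 5, 4), matrix(0, 5, 4)),
    "zero total"
  )
})

test_that("common dispersion agrees with the edgeR qCML estimate", {
  skip_if_not_installed("edgeR")
  sim <- null_two_group_counts(2000, seed = 131, phi = 0.15,
                               lib_range = c(2e5, 3e5))
  m <- as.matrix(sim$counts[, -1])
  ours <- estimate_common_dispersion(m[, 1:4], m[, 5:8])$phi
  d <- edgeR::DGEList(counts = m, group = rep(c("A", "B"), each = 4))
  d <- edgeR::estimateCommonDisp(d)
  expect_equal(ours, d$common.dispersion, tolerance = 0.25 * d$common.dispersion)
})

test_that("exact NB test matches structural cases and the binomial oracle", {
  eq <- rep(1e6, 4)
  # symmetric split with equal sizes: the doubled tail caps at 1
  p <- exact_nb_test(matrix(10, 1, 4), matrix(10, 1, 4), eq, eq, phi = 0.1)
  expect_equal(p, 1)

  # group swap symmetry
  set.seed(7)
  ya <- matrix(rnbinom(50 * 4, mu = 30, size = 10), 50, 4)
  yb <- matrix(rnbinom(50 * 4, mu = 60, size = 10), 50, 4)
  p_ab <- exact_nb_test(ya, yb, eq, eq, phi = 0.1)
  p_ba <- exact_nb_test(yb, ya, eq, eq, phi = 0.1)
  expect_equal(p_ab, p_ba)
  expect_true(all(p_ab > 0 & p_ab <= 1))

  # Poisson limit: spot-check the conditional binomial oracle (full
  # enumeration over all totals <= 50 runs in the acceptance suite)
  for (t in c(1, 7, 20, 30)) {
    for (sa in 0:t) {
      got <- exact_nb_test(matrix(c(sa, 0, 0, 0), 1, 4),
                           matrix(c(t - sa, 0, 0, 0), 1, 4),
                           eq, eq, phi = 0)
      expect_equal(got, binom_tail_oracle(sa, t, 4, 4), tolerance = 1e-10)
    }
  }

  # the NB path converges to the binomial limit as phi -> 0
  p_small <- exact_nb_test(matrix(c(12, 0, 0), 1, 3),
                           matrix(c(30, 0, 0, 0), 1, 4),
                           rep(1e6, 3), rep(1e6, 4), phi = 1e-9)
  expect_equal(p_small, binom_tail_oracle(12, 42, 3, 4), tolerance = 1e-6)

  expect_error(exact_nb_test(matrix(1.5, 1, 4), matrix(1, 1, 4), eq, eq, 0.1),
               "non-integer")
  expect_error(exact_nb_test(matrix(1, 1, 4), matrix(1, 1, 4), eq, eq, -1),
               "phi")
})

test_that("log fold changes follow the prior-augmented ratio", {
  eq <- rep(1e6, 4)
  expect_equal(nb_log_fc(matrix(40, 1, 4), matrix(40, 1, 4), eq, eq), 0)
  # sensitive mean 4x tolerant at large counts: prior is negligible
  lfc <- nb_log_fc(matrix(4000, 1, 4), matrix(1000, 1, 4), eq, eq)
  expect_equal(lfc, 2, tolerance = 1e-3)
  # both groups all zero: equal priors give zero
  expect_equal(nb_log_fc(matrix(0, 1, 4), matrix(0, 1, 4), eq, eq), 0)
  expect_error(nb_log_fc(matrix(1, 1, 4), matrix(1, 1, 4), eq, eq,
                         prior_count = 0), "prior_count")
})

test_that("BH adjustment reproduces the step-up definition", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(5)
  for (i in 1:5) {
    p <- runif(97)
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("null comparisons are calibrated at the nominal level", {
  fracs <- vapply(1:3, function(s) {
    sim <- null_two_group_counts(2000, seed = 140 + s, phi = 0.1,
                                 lib_range = c(2e5, 4e5))
    cmp <- run_comparison(sim$counts, sim$design, "A", "B")
    mean(cmp$p_value[cmp$tested] < 0.05)
  }, numeric(1))
  expect_true(all(fracs >= 0.03 & fracs <= 0.07))
})

test_that("strong planted effects are detected with high power", {
  hits <- vapply(1:10, function(s) {
    set.seed(160 + s)
    ng <- 1000
    n_pl <- 100
    design <- two_group_design()
    mu_a <- rep(200, ng)
    mu_b <- rep(200, ng)
    planted <- seq_len(n_pl)
    sgn <- rep(c(1, -1), length.out = n_pl)
    mu_b[planted] <- 200 * 2^(3 * sgn)        # |log2 FC| = 3
    cnt <- cbind(
      matrix(rnbinom(ng * 4, mu = mu_a, size = 10), ng, 4),
      matrix(rnbinom(ng * 4, mu = mu_b, size = 10), ng, 4)
    )
    colnames(cnt) <- design$sample_id
    counts <- tibble::as_tibble(cbind(
      tibble::tibble(gene_id = sprintf("G%04d", seq_len(ng))),
      tibble::as_tibble(cnt)
    ))
    cmp <- run_comparison(counts, design, "A", "B")
    mean(cmp$significant[planted])
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})

test_that("comparing a genotype against its own split replicates finds nothing", {
  sim <- null_two_group_counts(2000, seed = 171, phi = 0.1, n_rep = 4,
                               lib_range = c(2e5, 4e5))
  # relabel B's replicates as a second 'genotype' drawn from the same model
  cmp <- run_comparison(sim$counts, sim$design, "A", "B")
  expect_lte(sum(cmp$significant), 2)
})

test_that("the significance flag is exactly the threshold conjunction", {
  sim <- null_two_group_counts(500, seed = 181, phi = 0.1,
                               lib_range = c(5e4, 1e5))
  cmp <- run_comparison(sim$counts, sim$design, "A", "B",
                        lfc_threshold = 1, fdr_threshold = 0.001)
  expect_identical(cmp$significant, abs(cmp$log_fc) >= 1 & cmp$fdr < 0.001)
  expect_true(all(cmp$fdr >= cmp$p_value))
  expect_true(all(cmp$p_value > 0 & cmp$p_value <= 1))
  # untested (low-count) genes are reported at p = fdr = 1
  expect_true(all(cmp$p_value[!cmp$tested] == 1))

  expect_error(run_comparison(sim$counts, sim$design, "A", "Z"),
               "available: A, B")
})
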