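test_that("the comparison grid is the sensitive-by-tolerant cross product", {
  sim_design <- simulate_counts(sim_params(n_genes = 20,
                                           library_size_range = c(1e4, 2e4),
                                           n_tolerance_degs_up_tolerant = 2,
                                           n_tolerance_degs_up_sensitive = 2,
                                           n_background_degs = 2,
                                           seed = 1))$design
  grid <- enumerate_comparisons(sim_design)
  expect_equal(sum(grid$type == "cross"), 12)          # 3 sensitive x 4 tolerant
  expect_equal(sum(grid$type == "within_tolerant"), 6) # C(4, 2)
  expect_equal(sum(grid$type == "within_sensitive"), 3)
  expect_false(anyDuplicated(grid$label) > 0)
  # cross labels use the numeric aliases, sensitive first
  expect_equal(grid$label[grid$type == "cross"][1:4],
               c("1/3", "1/4", "1/5", "1/6"))

  # one genotype per group: a single cross pair, no within pairs
  mini <- tibble::tibble(
    sample_id = c("s.1", "s.2", "t.1", "t.2"),
    genotype = c("s", "s", "t", "t"),
    group = c("sensitive", "sensitive", "tolerant", "tolerant"),
    replicate = c(1, 2, 1, 2)
  )
  g2 <- enumerate_comparisons(mini)
  expect_equal(g2$type, "cross")
  expect_equal(g2$label, "s/t")

  no_tol <- mini[1:2, ]
  expect_error(enumerate_comparisons(no_tol), "tolerant")
})

test_that("membership counts reproduce transcribed published rows", {
  res <- fixture_results()
  mc <- membership_counts(res)
  expect_equal(mc$membership_n[mc$gene_id == "Sb06g031460"], 5L)
  expect_equal(mc$membership_n[mc$gene_id == "Sb07g004700"], 9L)
  expect_equal(mc$membership_n[mc$gene_id == "Sb01g038720"], 6L)

  # all-ns gene has membership zero
  res0 <- lapply(cross_labels, function(l) {
    fake_comparison("gX", 0, FALSE, l)
  })
  expect_equal(membership_counts(res0)$membership_n, 0L)

  # mismatched universes are rejected with the differing genes listed
  bad <- res
  bad[[1]] <- fake_comparison(c("Sb06g031460", "Sb07g004700", "OTHER"),
                              c(0, 0, 0), rep(FALSE, 3), "1/3")
  expect_error(membership_counts(bad), "OTHER")
})

test_that("within-group exclusion applies the at-least thresholds", {
  genes <- paste0("g", 1:4)
  # g1: 0 within hits; g2: 5 of 6 tolerant; g3: 1 of 3 sensitive;
  # g4: 5 tolerant and 2 sensitive (both reasons)
  wt <- lapply(1:6, function(j) {
    fake_comparison(genes, c(0, 2, 0, -2), c(FALSE, j <= 5, FALSE, j <= 5),
                    paste0("t", j))
  })
  ws <- lapply(1:3, function(j) {
    fake_comparison(genes, c(0, 0, 1.5, 2), c(FALSE, FALSE, j <= 1, j <= 2),
                    paste0("s", j))
  })
  ex <- within_group_exclusion(wt, ws)
  expect_equal(ex$excluded, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(ex$reason[2], "tolerant_background")
  expect_equal(ex$reason[3], "none")
  expect_equal(ex$reason[4], "tolerant_background;sensitive_background")
  expect_equal(ex$within_tolerant_hits, c(0L, 5L, 0L, 5L))
  expect_equal(ex$within_sensitive_hits, c(0L, 0L, 1L, 2L))

  expect_error(within_group_exclusion(wt, ws, tolerant_min = 7),
               "exceeds the number of pairs")
  expect_error(within_group_exclusion(wt, ws, sensitive_min = 0),
               "sensitive_min")
})

test_that("consensus classifies the transcribed rows correctly", {
  cons <- build_consensus(fixture_results(), exclusions = NULL, n_min = 6)
  rec <- cons$records
  # LHT1-style row: six negative cells -> in the common list, tolerant-abundant
  lht1 <- rec[rec$gene_id == "Sb01g038720", ]
  expect_equal(lht1$membership_n, 6L)
  expect_equal(lht1$direction, "tolerant_abundant")
  expect_true(lht1$in_common)
  # GS-2-style row: sign conflict among its five significant cells
  gs2 <- rec[rec$gene_id == "Sb06g031460", ]
  expect_equal(gs2$direction, "mixed")
  expect_false(gs2$in_common)  # membership 5 < 6
  # chalcone-synthase-style row: nine positive cells
  chs <- rec[rec$gene_id == "Sb07g004700", ]
  expect_equal(chs$direction, "sensitive_abundant")
  expect_true(chs$in_common)

  ft <- format_consensus_table(cons, marker = "ns")
  expect_equal(ft[["1/3"]][ft$gene_id == "Sb01g038720"], "-7.0")
  expect_equal(ft[["1/5"]][ft$gene_id == "Sb01g038720"], "ns")
  ft2 <- format_consensus_table(cons, marker = "**")
  expect_equal(ft2[["1/5"]][ft2$gene_id == "Sb01g038720"], "**")
})

test_that("consensus equals a brute-force oracle on random small cases", {
  set.seed(201)
  for (rep in 1:5) {
    ng <- 15
    genes <- sprintf("g%02d", seq_len(ng))
    sig <- matrix(runif(ng * 12) < 0.4, ng, 12)
    lfc <- matrix(round(runif(ng * 12, -5, 5), 1), ng, 12)
    lfc[lfc == 0] <- 1.5
    th <- sample(0:6, ng, replace = TRUE)
    sh <- sample(0:3, ng, replace = TRUE)
    excl_tbl <- tibble::tibble(
      gene_id = genes,
      within_tolerant_hits = th,
      within_sensitive_hits = sh,
      excluded = th >= 5 | sh >= 2,
      reason = dplyr::case_when(
        th >= 5 & sh >= 2 ~ "tolerant_background;sensitive_background",
        th >= 5 ~ "tolerant_background",
        sh >= 2 ~ "sensitive_background",
        TRUE ~ "none"
      )
    )
    res <- lapply(1:12, function(j) {
      fake_comparison(genes, lfc[, j], sig[, j], cross_labels[j])
    })
    names(res) <- cross_labels
    n_min <- sample(3:8, 1)
    cons <- build_consensus(res, excl_tbl, n_min = n_min)

    # exhaustive reconstruction, one gene at a time
    for (i in seq_len(ng)) {
      n_i <- sum(sig[i, ])
      excl_i <- th[i] >= 5 || sh[i] >= 2
      expect_equal(cons$records$membership_n[i], n_i)
      expect_equal(cons$records$in_common[i], n_i >= n_min && !excl_i)
      if (n_i > 0) {
        s <- sign(lfc[i, sig[i, ]])
        dir_i <- if (all(s > 0)) "sensitive_abundant"
                 else if (all(s < 0)) "tolerant_abundant"
                 else "mixed"
        expect_equal(cons$records$direction[i], dir_i)
      } else {
        expect_true(is.na(cons$records$direction[i]))
      }
    }

    # partition: the three direction classes cover the common list exactly
    expect_equal(
      sum(cons$common$direction %in%
            c("sensitive_abundant", "tolerant_abundant", "mixed")),
      nrow(cons$common)
    )

    # monotonicity in n_min and in the exclusion thresholds
    if (n_min < 12) {
      tighter <- build_consensus(res, excl_tbl, n_min = n_min + 1)
      expect_true(all(tighter$common$gene_id %in% cons$common$gene_id))
    }
    looser_excl <- excl_tbl
    looser_excl$excluded <- th >= 6 | sh >= 3
    looser <- build_consensus(res, looser_excl, n_min = n_min)
    expect_true(all(cons$common$gene_id %in% looser$common$gene_id))

    # histogram accounting is self-consistent
    expect_equal(cons$histogram$genes_at_least_n,
                 rev(cumsum(rev(cons$histogram$genes_at_n))))
  }
  expect_error(build_consensus(fixture_results(), NULL, n_min = 13), "n_min")
})
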