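test_that("PR2 coordinates follow the third-position tallies", {
  # equal third-position use of A, T, G, C -> plot centre
  centre <- pr2_point(make_counts(TTA = 1, TTT = 1, TTG = 1, TTC = 1))
  expect_equal(unname(centre), c(0.5, 0.5))

  # all T and all C third bases -> lower-left corner
  corner <- pr2_point(make_counts(TTT = 3, TTC = 2))
  expect_equal(unname(corner), c(0, 0))

  # A3=1, T3=3, G3=3, C3=1 -> (0.75, 0.25)
  p <- pr2_point(make_counts(AAA = 1, AAT = 3, AAG = 3, AAC = 1))
  expect_equal(unname(p), c(0.75, 0.25))

  # Met/Trp/stops are excluded; only-excluded input is flagged NA
  expect_equal(pr2_point(make_counts(AAA = 1, AAT = 3, AAG = 3, AAC = 1,
                                     ATG = 50, TGG = 50, TAA = 9)),
               p)
  expect_true(all(is.na(pr2_point(make_counts(ATG = 5, TGG = 3)))))

  # permutation invariance: counting is order-free by construction
  s1 <- paste0("ATG", "AAT", "AAG", "TAA")
  s2 <- paste0("ATG", "AAG", "AAT", "TAA")
  expect_equal(pr2_point(count_codons(s1)), pr2_point(count_codons(s2)))
})

test_that("neutrality regression handles the canonical edge cases", {
  d <- data.frame(gc3 = c(20, 30, 40, 50), gc12 = c(20, 30, 40, 50))
  fit <- neutrality_fit(d)
  expect_equal(fit$slope, 1)
  expect_equal(fit$r, 1)
  expect_equal(fit$mutation_pct, 100)
  expect_equal(fit$mutation_pct + fit$selection_pct, 100)

  flat <- neutrality_fit(data.frame(gc3 = c(20, 30, 40, 50),
                                    gc12 = rep(41, 4)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r, 0)

  expect_error(neutrality_fit(data.frame(gc3 = rep(30, 5),
                                         gc12 = rnorm(5, 40))),
               "variance")
  expect_error(neutrality_fit(data.frame(gc3 = c(1, 2), gc12 = c(1, 2))),
               "3 genes")
})

test_that("neutrality regression recovers a planted slope", {
  rec <- generate_neutrality_set(b = 0.4, noise_sd = 0.02, n = 120L,
                                 seed = 11L)
  idx <- gene_indices(rec)
  fit <- neutrality_fit(idx)
  expect_lt(abs(fit$slope - 0.4), 3 * fit$se_slope)
})

test_that("expression datasets are ENC-ranked, disjoint and deterministic", {
  g <- data.frame(gene = sprintf("g%02d", 1:10), enc = c(35, 60, 42, 25,
                                                         55, 48, 31, 58,
                                                         44, 52))
  s <- select_expression_datasets(g, fraction = 0.1)
  expect_equal(s$high, "g04")  # min ENC
  expect_equal(s$low, "g02")   # max ENC
  expect_length(intersect(s$high, s$low), 0)

  # ties broken lexicographically by gene id
  tied <- data.frame(gene = c("b", "a", "c", "d"), enc = c(30, 30, 50, 50))
  s2 <- select_expression_datasets(tied, fraction = 0.25)
  expect_equal(s2$high, "a")
  expect_equal(s2$low, "d")

  s3 <- select_expression_datasets(tied, fraction = 0.5)
  expect_equal(sort(s3$high), c("a", "b"))
  expect_equal(sort(s3$low), c("c", "d"))

  expect_error(select_expression_datasets(tied[1:3, ], fraction = 0.5),
               "too few")
  expect_error(select_expression_datasets(g, fraction = 0.6), "fraction")
})

test_that("optimal codons require RSCU_high > 1 and a delta above threshold", {
  hi <- make_counts(GCT = 45, GCA = 25, GCC = 20, GCG = 10,
                    TTT = 9, TTC = 11)
  lo <- make_counts(GCT = 40, GCA = 30, GCC = 20, GCG = 10,
                    TTT = 11, TTC = 9)
  res <- optimal_codons(hi, lo)
  # GCT: rscu_high 1.8, rscu_low 1.6 -> delta 0.2 -> optimal
  expect_equal(res$delta_rscu[["GCT"]], 0.2)
  expect_true("GCT" %in% res$optimal)
  # TTT: delta 0.9-1.1 < 0 and rscu_high 0.9 < 1 -> not optimal
  expect_false("TTT" %in% res$optimal)
  # TTC: rscu_high 1.1 > 1, delta 1.1-0.9 = 0.2 -> optimal
  expect_true("TTC" %in% res$optimal)

  # identical sets -> no optimal codons
  expect_length(optimal_codons(hi, hi)$optimal, 0)

  # raising the threshold never enlarges the set
  set.seed(4)
  for (i in 1:10) {
    a <- random_counts(); b <- random_counts()
    o1 <- optimal_codons(a, b, threshold = 0.05)$optimal
    o2 <- optimal_codons(a, b, threshold = 0.2)$optimal
    expect_true(all(o2 %in% o1))
  }
})

test_that("the ENC-plot table pairs observed and expected values", {
  rec <- generate_cds_set(n_genes = 10L, seed = 19L)
  idx <- gene_indices(rec)
  ep <- enc_plot_table(idx)
  expect_equal(names(ep), c("gene", "gc3s", "enc", "expected_enc"))
  expect_equal(ep$expected_enc, enc_expected(idx$gc3s / 100))
})
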