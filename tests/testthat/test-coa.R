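test_that("the RSCU matrix has 59 codon columns and drops empty rows", {
  rec <- generate_cds_set(n_genes = 3L, seed = 2L)
  m <- build_rscu_matrix(rec)
  expect_equal(dim(m), c(3L, 59L))
  expect_equal(colnames(m), degenerate_codons())
  expect_false(any(c("ATG", "TGG", "TAA", "TAG", "TGA") %in% colnames(m)))
  expect_equal(rownames(m), rec$id)

  # a gene using only Phe codons: 1.0 at TTT and TTC, 0 elsewhere
  counts <- list(phe = make_counts(TTT = 1, TTC = 1),
                 mix = make_counts(GCT = 2, GCA = 1, TTA = 1, TTT = 1))
  m2 <- build_rscu_matrix(counts, min_families = 1L)
  expect_equal(unname(m2["phe", c("TTT", "TTC")]), c(1, 1))
  expect_equal(sum(m2["phe", ]), 2)

  # near-empty rows are dropped with a warning under the default threshold
  expect_warning(m3 <- build_rscu_matrix(counts), "fewer than 3")
  expect_equal(rownames(m3), "mix")
})

test_that("CA degenerate cases behave as the chi-square geometry dictates", {
  # identical rows: no deviation from independence
  m <- matrix(rep(c(4, 2, 1, 3), each = 5), nrow = 5)
  res <- correspondence_analysis(m)
  expect_equal(res$total_inertia, 0, tolerance = 1e-12)
  expect_true(all(abs(res$row_coords) < 1e-8))

  # perfect association in a 2x2 table: one axis carries everything
  res2 <- correspondence_analysis(diag(c(10, 10)))
  expect_equal(res2$n_axes, 1L)
  expect_equal(res2$inertia_fraction, 1)
})

test_that("CA matches the brute-force eigendecomposition oracle", {
  set.seed(1234)
  for (i in 1:5) {
    m <- matrix(rpois(200, 6) + 1, nrow = 20, ncol = 10)
    res <- correspondence_analysis(m, n_axes = 4L)
    ora <- ca_oracle(m, n_axes = 4L)
    expect_equal(res$inertia_fraction, ora$inertia_fraction[1:4],
                 tolerance = 1e-10)
    expect_equal(res$row_coords,
                 align_signs(ora$coords[, 1:4], res$row_coords),
                 tolerance = 1e-10, ignore_attr = TRUE)
    # total inertia equals Pearson chi-square / grand total
    chi <- suppressWarnings(stats::chisq.test(m)$statistic)
    expect_equal(res$total_inertia, unname(chi) / sum(m),
                 tolerance = 1e-8)
    # inertia fractions are non-increasing
    expect_true(all(diff(res$inertia_fraction) <= 1e-12))
  }
})

test_that("CA agrees with MASS::corresp on singular values", {
  skip_if_not_installed("MASS")
  set.seed(9)
  m <- matrix(rpois(120, 5) + 1, nrow = 12, ncol = 10)
  res <- correspondence_analysis(m, n_axes = 3L)
  mc <- MASS::corresp(m, nf = 3)
  expect_equal(res$singular_values, unname(mc$cor), tolerance = 1e-8)
})

test_that("oracle equality persists under row rescaling", {
  set.seed(77)
  m <- matrix(rpois(200, 6) + 1, nrow = 20, ncol = 10)
  m[3, ] <- m[3, ] * 5
  res <- correspondence_analysis(m, n_axes = 3L)
  ora <- ca_oracle(m, n_axes = 3L)
  expect_equal(res$inertia_fraction, ora$inertia_fraction[1:3],
               tolerance = 1e-10)
  expect_equal(res$row_coords,
               align_signs(ora$coords[, 1:3], res$row_coords),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("axis orientation is deterministic", {
  set.seed(5)
  m <- matrix(rpois(80, 7) + 1, nrow = 8, ncol = 10)
  r1 <- correspondence_analysis(m)
  r2 <- correspondence_analysis(m)
  expect_identical(r1$row_coords, r2$row_coords)
  # first nonzero column loading of each axis is positive
  for (k in seq_len(r1$n_axes)) {
    nz <- which(abs(r1$col_coords[, k]) > 1e-10)
    expect_gt(r1$col_coords[nz[1], k], 0)
  }
})

test_that("axis-index correlations report r, p and significance marks", {
  rec <- generate_cds_set(n_genes = 30L, seed = 64L)
  idx <- gene_indices(rec)
  res <- correspondence_analysis(build_rscu_matrix(rec))

  # an index equal to the axis-1 coordinate correlates perfectly
  idx$fake <- res$row_coords[match(idx$gene, rownames(res$row_coords)), 1]
  tab <- axis_index_correlations(res, idx, index_cols = c("fake", "enc"))
  r_fake <- tab$r[tab$index == "fake" & tab$axis == 1]
  expect_equal(r_fake, 1, tolerance = 1e-10)
  expect_equal(tab$mark[tab$index == "fake" & tab$axis == 1], "**")

  # a constant index is flagged, not an error
  idx$const <- 1
  tab2 <- axis_index_correlations(res, idx, index_cols = "const")
  expect_true(all(tab2$mark == "undefined"))
  expect_true(all(is.na(tab2$r)))

  # independent noise stays weakly correlated in almost all replicates
  n <- nrow(res$row_coords)
  hits <- 0L
  set.seed(314)
  for (i in 1:100) {
    r <- suppressWarnings(stats::cor(stats::rnorm(n),
                                     res$row_coords[, 1]))
    if (abs(r) < 0.3) hits <- hits + 1L
  }
  expect_gte(hits, 85L)  # |r| < 0.3 expected in ~90% of draws at n = 30
})
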