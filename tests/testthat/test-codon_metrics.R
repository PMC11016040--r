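test_that("codon counting tallies in-frame triplets and concatenates", {
  cc <- count_codons("ATGAAATAA")
  expect_equal(sum(cc), 3L)
  expect_equal(unname(cc[c("ATG", "AAA", "TAA")]), c(1L, 1L, 1L))
  expect_equal(attr(cc, "n_codons"), 3L)
  expect_equal(attr(cc, "scope"), "gene")

  two <- count_codons(c("ATGTAA", "ATGTAA"))
  expect_equal(unname(two[c("ATG", "TAA")]), c(2L, 2L))
  expect_equal(attr(two, "scope"), "species")

  leu <- count_codons("ATGTTATTGTAA")
  expect_equal(unname(leu[c("ATG", "TTA", "TTG", "TAA")]), rep(1L, 4))

  expect_error(count_codons("ATGA"), "multiple of 3")
  expect_error(count_codons("ATGNNNTAA"), "non-ACGT")

  # additivity: list input equals the sum of per-gene tables
  rec <- generate_cds_set(n_genes = 5L, seed = 3L)
  total <- count_codons(rec)
  per_gene <- Reduce(`+`, lapply(rec$sequence, count_codons))
  expect_equal(as.integer(total), as.integer(per_gene[names(total)]),
               ignore_attr = TRUE)
})

test_that("positional GC content follows its definitions", {
  gc <- gc_by_position(make_counts(GGG = 1, AAA = 1))
  expect_equal(unname(gc[c("gc1", "gc2", "gc3", "gc_mean", "gc12")]),
               rep(50, 5))

  # all codons excluded from GC3s -> NaN flag
  met_only <- gc_by_position(make_counts(ATG = 5))
  expect_true(is.nan(met_only[["gc3s"]]))
  expect_equal(met_only[["gc3"]], 100)  # ATG third base is G

  expect_error(gc_by_position(zero_counts()), "empty")

  # invariants on a random table
  set.seed(11)
  g <- gc_by_position(random_counts())
  expect_equal(g[["gc_mean"]], mean(g[c("gc1", "gc2", "gc3")]))
  expect_equal(g[["gc12"]], mean(g[c("gc1", "gc2")]))
  expect_true(all(g >= 0 & g <= 100))
})

test_that("GC of a concatenation is the count-weighted combination", {
  set.seed(21)
  a <- random_counts(); b <- random_counts()
  ga <- gc_by_position(a); gb <- gc_by_position(b)
  gab <- gc_by_position(a + b)
  na <- sum(a); nb <- sum(b)
  for (k in c("gc1", "gc2", "gc3"))
    expect_equal(gab[[k]], (na * ga[[k]] + nb * gb[[k]]) / (na + nb))
})

test_that("RSCU and RFSC match their definitions and the naive oracle", {
  # Leu family 5/1/1/1/1/1: RSCU(TTA) = 5/10 * 6 = 3, RFSC = 0.5
  cc <- make_counts(TTA = 5, TTG = 1, CTT = 1, CTC = 1, CTA = 1, CTG = 1)
  tab <- rscu_rfsc(cc)
  expect_equal(tab$rscu[tab$codon == "TTA"], 3)
  expect_equal(tab$rfsc[tab$codon == "TTA"], 0.5)
  expect_false(all(tab$observed_family))
  expect_equal(tab$rscu[tab$codon == "GGG"], 0)  # unobserved family

  # uniform usage: every observed degenerate codon has RSCU 1
  uni <- rscu_rfsc(count_codons(uniform_usage_gene(3L)$sequence))
  deg <- uni[uni$codon %in% degenerate_codons(), ]
  expect_equal(deg$rscu, rep(1, 59))

  # family sums + oracle equality on random tables
  set.seed(99)
  for (i in 1:50) {
    cc <- random_counts(lambda = 3)
    if (sum(cc) == 0) next
    tab <- rscu_rfsc(cc)
    sums <- tapply(tab$rfsc, tab$amino_acid, sum)
    nsum <- tapply(tab$rscu, tab$amino_acid, sum)
    size <- tapply(tab$family_size, tab$amino_acid, unique)
    obs <- tapply(tab$observed_family, tab$amino_acid, unique)
    expect_equal(as.numeric(sums[obs]), rep(1, sum(obs)))
    expect_equal(as.numeric(nsum[obs]), as.numeric(size[obs]))
    oracle <- naive_rscu_oracle(cc)
    expect_equal(stats::setNames(tab$rscu, tab$codon), oracle$rscu)
    expect_equal(stats::setNames(tab$rfsc, tab$codon), oracle$rfsc)
  }
})

test_that("RSCU is invariant to scaling family counts", {
  cc <- make_counts(TTA = 5, TTG = 1, CTT = 2, GCT = 4, GCA = 2)
  t1 <- rscu_rfsc(cc)
  t2 <- rscu_rfsc(cc * 7L)
  expect_equal(t1$rscu, t2$rscu)
  expect_equal(t1$rfsc, t2$rfsc)
})

test_that("HF classification applies both thresholds", {
  # two-codon family: 0.7 > 0.6 -> TTT is HF; TTC (0.3 < 0.75) is not
  hf <- classify_hf_codons(rscu_rfsc(make_counts(TTT = 7, TTC = 3)))
  expect_true("TTT" %in% hf)
  expect_false("TTC" %in% hf)

  # four-codon family 0.40/0.30/0.20/0.10; threshold 1.5/4 = 0.375
  hf4 <- classify_hf_codons(rscu_rfsc(
    make_counts(GCT = 40, GCA = 30, GCC = 20, GCG = 10)))
  expect_true("GCT" %in% hf4)
  expect_false(any(c("GCA", "GCC", "GCG") %in% hf4))

  # observed single-codon families always qualify; unobserved never
  hfm <- classify_hf_codons(rscu_rfsc(make_counts(ATG = 2, TTT = 1)))
  expect_true("ATG" %in% hfm)
  expect_false("TGG" %in% hfm)

  # the multiplier is exposed
  strict <- classify_hf_codons(rscu_rfsc(make_counts(GCT = 40, GCA = 30,
                                                     GCC = 20, GCG = 10)),
                               multiplier = 1.7)
  expect_false("GCT" %in% strict)
})

test_that("amino-acid totals exclude stop codons", {
  expect_equal(amino_acid_count(make_counts(ATG = 1, AAA = 1, TAA = 1)), 2L)
  expect_equal(amino_acid_count(make_counts(TAA = 3)), 0L)
  row <- composition_row("sp", 10L, 8L,
                         make_counts(ATG = 1, AAA = 1, GGG = 2, TAA = 1))
  expect_equal(row$l_aa, 4L)
  expect_equal(row$cds_before, 10L)
  expect_equal(row$gc3, 60)  # 3 of 5 third bases are G/C
})
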