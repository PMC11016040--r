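test_that("Kazusa tables parse, validate and round-trip", {
  tab <- per_thousand_frequencies(count_codons(
    generate_cds_set(n_genes = 10L, seed = 50L)), "host")
  tab$freq <- round(tab$freq, 1)  # writer precision
  path <- withr::local_tempfile(fileext = ".txt")
  write_kazusa_table(tab, path)
  back <- parse_kazusa_table(path, organism = "host")
  expect_equal(back$freq, tab$freq)
  expect_equal(back$organism, "host")
})

test_that("Kazusa parsing errors name the problem codon", {
  tab <- per_thousand_frequencies(count_codons(
    generate_cds_set(n_genes = 5L, seed = 51L)), "x")
  path <- withr::local_tempfile(fileext = ".txt")
  write_kazusa_table(tab, path)
  lines <- readLines(path)

  # remove one codon -> error naming it
  crippled <- sub("GCU [0-9.]+\\(\\s*[0-9]+\\)\\s*", "", lines)
  expect_error(parse_kazusa_table(crippled), "GCT")

  # duplicate entry -> error
  dup <- c(lines, "GCU 10.0(  1000)")
  expect_error(parse_kazusa_table(dup), "duplicate")

  expect_error(parse_kazusa_table("no codons here"), "no Kazusa")
})

test_that("RNA codons map to DNA and frequencies land per thousand", {
  # hand-built full table: TTT gets 26.1, the rest share the remainder
  vals <- stats::setNames(rep((1000 - 26.1) / 63, 64), all_codons())
  vals[["TTT"]] <- 26.1
  entries <- sprintf("%s %.4f(%6d)", chartr("T", "U", all_codons()),
                     vals, as.integer(round(vals * 100)))
  tab <- parse_kazusa_table(entries, organism = "toy")
  expect_equal(unname(tab$freq[["TTT"]]), 26.1)
  expect_equal(sum(tab$freq), 1000, tolerance = 0.5)
})

test_that("per-thousand frequencies normalise exactly", {
  f <- per_thousand_frequencies(make_counts(ATG = 1, TAA = 1))
  expect_equal(unname(f$freq[["ATG"]]), 500)
  expect_equal(sum(f$freq), 1000)

  f2 <- per_thousand_frequencies(make_counts(AAA = 3, TTT = 1))
  expect_equal(unname(f2$freq[["AAA"]]), 750)

  expect_error(per_thousand_frequencies(zero_counts()), "empty")
})

test_that("ratio bands count divergent and similar codons correctly", {
  uniform <- per_thousand_frequencies(
    stats::setNames(rep(1L, 64), all_codons()), "m")
  host <- uniform
  cmp0 <- compare_frequencies(host, uniform)
  expect_equal(cmp0$n_divergent, 0L)
  expect_equal(cmp0$n_similar, 64L)

  # boundary: ratios of exactly 2 and 0.5 are divergent (inclusive);
  # doubling AAA at GGG's expense keeps the totals equal so the realised
  # ratios are exactly 2.0 and 0.5
  h3 <- uniform; h3$freq[["AAA"]] <- 2; h3$freq[["GGG"]] <- 0
  cmp2 <- compare_frequencies(h3, uniform)
  expect_true("AAA" %in% cmp2$divergent_codons)   # ratio exactly 2.0
  expect_true("GGG" %in% cmp2$divergent_codons)   # ratio 0 <= 0.5
  half <- uniform; half$freq[["AAA"]] <- 0.5; half$freq[["GGG"]] <- 1.5
  expect_true("AAA" %in%
                compare_frequencies(half, uniform)$divergent_codons)

  # planted ratios 2.5 and 0.4, rest untouched
  h3 <- uniform
  h3$freq[["AAA"]] <- h3$freq[["AAA"]] * 2.5
  h3$freq[["TTT"]] <- h3$freq[["TTT"]] * 0.4
  cmp3 <- compare_frequencies(h3, uniform)
  expect_equal(cmp3$n_divergent, 2L)
  expect_equal(cmp3$n_similar, 62L)
  expect_equal(cmp3$divergent_codons, c("AAA", "TTT"))

  # counts always partition the 64 codons
  expect_equal(cmp3$n_divergent + cmp3$n_similar +
                 length(cmp3$undefined_codons), 64L)

  # model zeros are undefined, not divergent
  m0 <- uniform; m0$freq[["GGG"]] <- 0
  cmp4 <- compare_frequencies(h3, m0)
  expect_equal(cmp4$undefined_codons, "GGG")
  expect_equal(cmp4$n_divergent + cmp4$n_similar, 63L)
})

test_that("band counts are reciprocal-symmetric and scale-invariant", {
  set.seed(8)
  for (i in 1:10) {
    a <- per_thousand_frequencies(random_counts() + 1L, "a")
    b <- per_thousand_frequencies(random_counts() + 1L, "b")
    ab <- compare_frequencies(a, b)
    ba <- compare_frequencies(b, a)
    expect_equal(ab$n_divergent, ba$n_divergent)
    expect_equal(ab$n_similar, ba$n_similar)

    a_scaled <- a; a_scaled$freq <- a$freq * 3.7
    expect_equal(compare_frequencies(a_scaled, b)$n_divergent,
                 ab$n_divergent)
  }
})

test_that("the shipped synthetic model tables are valid Kazusa files", {
  dir <- system.file("extdata", "kazusa", package = "chlorocub")
  files <- list.files(dir, pattern = "_synthetic\\.txt$", full.names = TRUE)
  expect_length(files, 4L)
  for (f in files) {
    tab <- parse_kazusa_table(f)
    expect_s3_class(tab, "frequency_table")
    expect_equal(sum(tab$freq), 1000, tolerance = 0.5)
  }
})
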