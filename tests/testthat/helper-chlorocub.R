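# Shared fixtures and independent oracles.

zero_counts <- function() stats::setNames(integer(64), all_codons())

# Build a 64-codon count vector from named entries.
make_counts <- function(...) {
  v <- c(...)
  cc <- zero_counts()
  cc[names(v)] <- as.integer(v)
  cc
}

# One codon observed per synonymous sense family (18 degenerate families
# plus Met and Trp), each `n` times: the analytic ENC = 20 case.
one_per_family_counts <- function(n = 10L) {
  picks <- c("TTT", "ATT", "GTT", "CCT", "ACT", "GCT", "TAT", "CAT",
             "CAA", "AAT", "AAA", "GAT", "GAA", "TGT", "CGT", "GGT",
             "TCT", "CTT")  # one per degenerate family (Ser = TCT only)
  cc <- zero_counts()
  cc[picks] <- n
  cc
}

# Random count table over the 64 codons (possibly sparse).
random_counts <- function(lambda = 8) {
  cc <- zero_counts()
  cc[] <- stats::rpois(64, lambda)
  cc
}

# Naive per-codon RSCU/RFSC oracle built straight from the genetic code,
# independent of the package's family bookkeeping.
naive_rscu_oracle <- function(counts) {
  code <- Biostrings::GENETIC_CODE
  rscu <- rfsc <- stats::setNames(numeric(64), names(counts))
  for (cod in names(counts)) {
    syn <- names(code)[code == code[[cod]]]
    tot <- sum(counts[syn])
    if (tot > 0) {
      rfsc[cod] <- counts[[cod]] / tot
      rscu[cod] <- rfsc[cod] * length(syn)
    }
  }
  list(rscu = rscu, rfsc = rfsc)
}

# Brute-force correspondence analysis through an eigendecomposition of the
# standardized-residual cross-product (independent of svd()).
ca_oracle <- function(m, n_axes = 4L) {
  total <- sum(m)
  m <- m[, colSums(m) > 0, drop = FALSE]
  p <- m / total
  r <- rowSums(p); cc <- colSums(p)
  e <- outer(r, cc)
  s <- (p - e) / sqrt(e)
  dec <- eigen(s %*% t(s), symmetric = TRUE)
  lambda <- pmax(dec$values, 0)
  keep <- lambda > 1e-12
  coords <- diag(1 / sqrt(r)) %*% dec$vectors %*% diag(sqrt(lambda))
  k <- min(n_axes, sum(keep))
  list(inertia = lambda[seq_len(k)],
       inertia_fraction = lambda[seq_len(k)] / sum(lambda[keep]),
       total_inertia = sum(lambda[keep]),
       coords = coords[, seq_len(k), drop = FALSE])
}

# Align oracle axis signs to an implementation's row coordinates.
align_signs <- function(oracle_coords, impl_coords) {
  for (k in seq_len(ncol(oracle_coords))) {
    if (sum(oracle_coords[, k] * impl_coords[, k]) < 0)
      oracle_coords[, k] <- -oracle_coords[, k]
  }
  oracle_coords
}

# Minimal GenBank entry around a genome string and CDS feature locations.
genbank_text <- function(genome, locations, genes = NULL,
                         organism = "Testus plantus") {
  if (is.null(genes)) genes <- sprintf("g%d", seq_along(locations))
  feats <- unlist(mapply(function(loc, g) {
    c(sprintf("     CDS             %s", loc),
      sprintf("                     /gene=\"%s\"", g))
  }, locations, genes, SIMPLIFY = FALSE))
  chunks <- substring(tolower(genome),
                      seq(1, nchar(genome), 60),
                      pmin(seq(60, nchar(genome) + 59, 60), nchar(genome)))
  origin <- sprintf("%9d %s", seq(1, nchar(genome), 60),
                    vapply(chunks, function(x)
                      paste(substring(x, seq(1, nchar(x), 10),
                                      pmin(seq(10, nchar(x) + 9, 10),
                                           nchar(x))),
                            collapse = " "), character(1)))
  c(sprintf("LOCUS       TESTCHL %20d bp    DNA     circular PLN 01-JAN-2024",
            nchar(genome)),
    "DEFINITION  synthetic test entry.",
    sprintf("  ORGANISM  %s", organism),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(genome)),
    feats,
    "ORIGIN",
    origin,
    "//")
}

write_genbank <- function(genome, locations, genes = NULL, ...) {
  path <- withr::local_tempfile(fileext = ".gb",
                                .local_envir = parent.frame())
  writeLines(genbank_text(genome, locations, genes, ...), path)
  path
}

# A long valid CDS: ATG + n_mid copies of `mid` + stop.
valid_cds <- function(n_mid = 98L, mid = "AAA", stop_codon = "TAA") {
  paste0("ATG", strrep(mid, n_mid), stop_codon)
}

# Path to the real-accession GenBank files (present only after
# scripts/fetch_accessions.R has been run with network access).
accession_file <- function(acc) {
  p <- system.file("extdata", "accessions", paste0(acc, ".gb"),
                   package = "chlorocub")
  if (nzchar(p)) p else file.path("inst", "extdata", "accessions",
                                  paste0(acc, ".gb"))
}
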