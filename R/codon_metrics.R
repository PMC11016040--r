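#' Count codons in one gene or a concatenated gene set
#'
#' Tallies the in-frame, non-overlapping triplets of one or more coding
#' sequences into a 64-codon count table. A vector of sequences (or a
#' multi-row CDS-record data.frame) yields the concatenated, species-scope
#' table; a single sequence yields a gene-scope table.
#'
#' @param x A CDS-record data.frame, or a character vector of in-frame
#'   nucleotide sequences.
#' @return Named integer vector over all 64 codons (alphabetical,
#'   zero-filled), with attributes `n_codons` (sum) and `scope`
#'   (`"gene"` or `"species"`).
#' @export
#' @examples
#' count_codons("ATGAAATAA")
count_codons <- function(x) {
  seqs <- if (is_cds_records(x)) x$sequence else as.character(x)
  if (any(nchar(seqs) %% 3L != 0L))
    stop("sequence length not a multiple of 3")
  counts <- stats::setNames(integer(64), all_codons())
  total_triplets <- sum(nchar(seqs)) %/% 3L
  if (length(seqs) && total_triplets > 0L) {
    freq <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(seqs), width = 3, step = 3)
    tal <- colSums(freq)
    counts[names(tal)] <- as.integer(tal)
    if (sum(counts) != total_triplets)
      stop("sequences contain non-ACGT codons; filter before counting")
  }
  structure(counts, n_codons = sum(counts),
            scope = if (length(seqs) > 1L) "species" else "gene")
}

.check_counts <- function(counts) {
  if (!is.numeric(counts) || length(counts) != 64L ||
      !all(all_codons() %in% names(counts)))
    stop("expected a named 64-codon count vector (see count_codons())")
  counts[all_codons()]
}

#' Positional GC content of a codon count table
#'
#' GC1/GC2/GC3 are the percentages of G or C at the first, second and third
#' codon positions over all codons in the table; GC12 is the mean of GC1 and
#' GC2 and `gc_mean` the mean of all three. GC3s is the third-position G+C
#' percentage restricted to codons of degenerate sense families, i.e.
#' excluding ATG (Met), TGG (Trp) and the three stop codons.
#'
#' @param counts 64-codon count vector from [count_codons()].
#' @return Named numeric vector `gc1`, `gc2`, `gc3`, `gc_mean`, `gc12`,
#'   `gc3s`, all percentages in [0, 100]. `gc3s` is `NaN` when every codon
#'   in the table is excluded from its definition.
#' @export
gc_by_position <- function(counts) {
  counts <- .check_counts(counts)
  n <- sum(counts)
  if (n == 0) stop("empty codon count table")
  codons <- names(counts)
  gc_at <- function(pos, keep = rep(TRUE, 64L)) {
    is_gc <- substr(codons, pos, pos) %in% c("G", "C")
    denom <- sum(counts[keep])
    if (denom == 0) return(NaN)
    100 * sum(counts[is_gc & keep]) / denom
  }
  gc1 <- gc_at(1L); gc2 <- gc_at(2L); gc3 <- gc_at(3L)
  eligible <- codons %in% degenerate_codons()
  c(gc1 = gc1, gc2 = gc2, gc3 = gc3,
    gc_mean = (gc1 + gc2 + gc3) / 3, gc12 = (gc1 + gc2) / 2,
    gc3s = gc_at(3L, eligible))
}

#' Relative synonymous codon usage and relative synonymous frequency
#'
#' For codon j of amino-acid family i with counts X_ij, family total
#' sum_j X_ij and family size n_i (1-6; the three stop codons form one
#' family of size 3):
#' RFSC = X_ij / sum_j X_ij (a codon's share of its family, summing to 1),
#' RSCU = RFSC * n_i (observed over expected-under-uniform use; 1 =
#' unbiased). Families with zero total count get RSCU = RFSC = 0 and are
#' flagged unobserved.
#'
#' @param counts 64-codon count vector from [count_codons()].
#' @return data.frame with one row per codon: `codon`, `amino_acid`,
#'   `family_size`, `count`, `rfsc`, `rscu`, `observed_family` (logical).
#' @export
#' @examples
#' rscu_rfsc(count_codons("ATGTTATTGTAA"))
rscu_rfsc <- function(counts) {
  counts <- .check_counts(counts)
  if (sum(counts) == 0) stop("empty codon count table")
  tab <- codon_table()
  fam_tot <- tapply(counts[tab$codon], tab$amino_acid, sum)[tab$amino_acid]
  observed <- fam_tot > 0
  rfsc <- ifelse(observed, counts[tab$codon] / fam_tot, 0)
  data.frame(codon = tab$codon, amino_acid = tab$amino_acid,
             family_size = tab$family_size,
             count = as.integer(counts[tab$codon]),
             rfsc = unname(rfsc),
             rscu = unname(rfsc * tab$family_size),
             observed_family = unname(observed),
             stringsAsFactors = FALSE)
}

#' Classify high-frequency (HF) codons
#'
#' A codon is HF when its RFSC exceeds `cutoff` (default 0.6) or exceeds
#' its family's average frequency 1/n_i by more than half of that average,
#' i.e. RFSC > `multiplier`/n_i with `multiplier` = 1.5. Single-codon
#' families (ATG, TGG) therefore qualify whenever observed. Unobserved
#' families are excluded.
#'
#' @param table RSCU table from [rscu_rfsc()].
#' @param cutoff Absolute RFSC cutoff.
#' @param multiplier Multiple of the family-average frequency to exceed.
#' @return Character vector of HF codons (alphabetical).
#' @export
classify_hf_codons <- function(table, cutoff = 0.6, multiplier = 1.5) {
  stopifnot(is.data.frame(table), all(c("rfsc", "family_size") %in%
                                        names(table)))
  hf <- table$observed_family &
    (table$rfsc > cutoff | table$rfsc > multiplier / table$family_size)
  sort(table$codon[hf])
}

#' Total amino acids encoded by a count table
#'
#' The number of sense codons, i.e. total codons minus stop codons — the
#' length in amino acids of the encoded proteins.
#'
#' @param counts 64-codon count vector.
#' @return Integer count.
#' @export
amino_acid_count <- function(counts) {
  counts <- .check_counts(counts)
  as.integer(sum(counts) - sum(counts[c("TAA", "TAG", "TGA")]))
}

#' Per-species composition summary row
#'
#' Mirrors the usual genome-table layout: CDS numbers before/after
#' filtering, total amino acids and positional GC percentages (2 decimals).
#'
#' @param species Species label.
#' @param n_before,n_after CDS counts before and after filtering.
#' @param counts Species-scope codon counts of the filtered set.
#' @return One-row data.frame.
#' @export
composition_row <- function(species, n_before, n_after, counts) {
  gc <- gc_by_position(counts)
  data.frame(species = species, cds_before = n_before, cds_after = n_after,
             l_aa = amino_acid_count(counts),
             gc1 = round(gc[["gc1"]], 2), gc2 = round(gc[["gc2"]], 2),
             gc3 = round(gc[["gc3"]], 2),
             gc_mean = round(gc[["gc_mean"]], 2),
             stringsAsFactors = FALSE)
}
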