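#' Family homozygosity (Wright's F-hat)
#'
#' For a synonymous family with total count n and within-family frequencies
#' p_j, the estimated homozygosity is F-hat = (n * sum(p_j^2) - 1)/(n - 1).
#' Undefined (NA) when n < 2.
#'
#' @param family_counts Integer vector of codon counts within one family.
#' @return F-hat, or NA when the family count is below 2.
#' @export
#' @examples
#' family_homozygosity(c(TTT = 3, TTC = 1))  # 0.5
family_homozygosity <- function(family_counts) {
  n <- sum(family_counts)
  if (n < 2) return(NA_real_)
  p <- family_counts / n
  (n * sum(p^2) - 1) / (n - 1)
}

#' Effective number of codons (ENC)
#'
#' Wright's estimator of codon-usage evenness for a single gene, ranging
#' from 20 (exactly one codon used per family) to 61 (uniform synonymous
#' usage). Per observed family, homozygosity F-hat is estimated (see
#' [family_homozygosity()]); F-hat values are averaged within degeneracy
#' classes k in {2, 3, 4, 6} and ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6.
#'
#' Conventions: families with count < 2 and F-hat values <= 0 are dropped
#' from their class average; a missing 3-fold class (Ile unobserved) is
#' imputed by harmonic interpolation between the 2- and 4-fold class means
#' (1/F3 = (1/F2 + 1/F4)/2); a gene missing an entire 2-, 4- or 6-fold
#' class yields NA. The estimate is capped at 61 (sampling noise pushes the
#' raw sum above the theoretical maximum).
#'
#' @param counts Gene-scope 64-codon count vector.
#' @param cap Upper cap (default 61).
#' @return ENC value in [20, 61], or NA when undefined.
#' @export
enc <- function(counts, cap = 61) {
  counts <- .check_counts(counts)
  tab <- codon_table()
  sense <- tab[tab$amino_acid != "*" & tab$family_size > 1L, ]
  fams <- split(sense$codon, sense$amino_acid)
  fam_size <- vapply(fams, length, integer(1))
  f_hat <- vapply(fams, function(cod) family_homozygosity(counts[cod]),
                  numeric(1))
  usable <- !is.na(f_hat) & f_hat > 0
  class_mean <- vapply(c(2, 3, 4, 6), function(k) {
    vals <- f_hat[usable & fam_size == k]
    if (length(vals) == 0L) NA_real_ else mean(vals)
  }, numeric(1))
  names(class_mean) <- c("F2", "F3", "F4", "F6")
  if (is.na(class_mean["F3"]) &&
      !is.na(class_mean["F2"]) && !is.na(class_mean["F4"]))
    class_mean["F3"] <- 2 / (1 / class_mean["F2"] + 1 / class_mean["F4"])
  if (anyNA(class_mean)) return(NA_real_)
  raw <- 2 + 9 / class_mean[["F2"]] + 1 / class_mean[["F3"]] +
    5 / class_mean[["F4"]] + 3 / class_mean[["F6"]]
  min(raw, cap)
}

#' Expected ENC under third-position composition bias alone
#'
#' The mutation-only reference curve of the ENC-plot:
#' ENC = 2 + S + 29/(S^2 + (1 - S)^2), with S the GC3s fraction.
#'
#' @param gc3s GC3s as a fraction in [0, 1] (vectorised).
#' @return Expected ENC.
#' @export
#' @examples
#' enc_expected(0.5)  # 60.5
enc_expected <- function(gc3s) {
  if (any(is.na(gc3s)) || any(gc3s < 0 | gc3s > 1))
    stop("gc3s must lie in [0, 1]")
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' Relative adaptiveness weights for CAI
#'
#' Sharp & Li weights from a reference (putatively highly expressed) codon
#' count table: within each synonymous family, w_j = X_j / max_j' X_j'.
#' Zero counts are smoothed to 0.5 before division so rare codons keep a
#' positive weight. Met, Trp and stop codons are excluded.
#'
#' @param reference Species- or set-scope 64-codon count vector of the
#'   reference gene set.
#' @return Named numeric vector of weights in (0, 1] over the 59 degenerate
#'   sense codons.
#' @export
cai_weights <- function(reference) {
  reference <- .check_counts(reference)
  if (sum(reference) == 0) stop("empty reference count table")
  tab <- codon_table()
  keep <- tab[tab$codon %in% degenerate_codons(), ]
  w <- numeric(0)
  for (fam in split(keep$codon, keep$amino_acid)) {
    x <- reference[fam]
    x[x == 0] <- 0.5
    w <- c(w, x / max(x))
  }
  w[degenerate_codons()]
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean of the relative adaptiveness weights over a gene's
#' codons, excluding Met, Trp and stop codons (whose weights are
#' uninformative).
#'
#' @param x A single CDS sequence (character), one-row CDS-record
#'   data.frame, or a gene-scope 64-codon count vector.
#' @param weights Weights from [cai_weights()].
#' @return CAI in (0, 1].
#' @export
cai <- function(x, weights) {
  counts <- if (is.numeric(x) && length(x) == 64L) .check_counts(x)
            else count_codons(x)
  eligible <- counts[degenerate_codons()]
  n <- sum(eligible)
  if (n == 0) stop("gene has no codons eligible for CAI")
  w <- weights[degenerate_codons()]
  if (any(is.na(w) | w <= 0)) stop("invalid CAI weights")
  exp(sum(eligible * log(w)) / n)
}

#' Per-gene index table
#'
#' Computes, for every record, the positional GC composition, ENC, CAI
#' (weights from `reference`, or from the lowest-ENC `reference_fraction`
#' of the genes themselves when `reference` is NULL), amino-acid length and
#' PR2 coordinates — the substrate of the ENC-, PR2- and neutrality plots
#' and of the correspondence-analysis correlations.
#'
#' @param records Filtered CDS-record data.frame.
#' @param reference Optional 64-codon reference count table for CAI.
#' @param reference_fraction Fraction of lowest-ENC genes used to build the
#'   CAI reference when `reference` is NULL (default 0.1).
#' @return data.frame with columns `gene`, `gc1`, `gc2`, `gc3`, `gc_mean`,
#'   `gc12`, `gc3s`, `enc`, `cai`, `l_aa`, `pr2_x`, `pr2_y`.
#' @export
gene_indices <- function(records, reference = NULL,
                         reference_fraction = 0.1) {
  stopifnot(is_cds_records(records), nrow(records) > 0)
  counts_list <- lapply(records$sequence, count_codons)
  gc <- t(vapply(counts_list, gc_by_position, numeric(6)))
  enc_v <- vapply(counts_list, enc, numeric(1))
  pr2 <- t(vapply(counts_list, pr2_point, numeric(2)))
  if (is.null(reference)) {
    ok <- which(!is.na(enc_v))
    split <- select_expression_datasets(
      data.frame(gene = records$id[ok], enc = enc_v[ok],
                 stringsAsFactors = FALSE),
      fraction = reference_fraction)
    ref_rows <- ok[records$id[ok] %in% split$high]
    reference <- count_codons(records[ref_rows, , drop = FALSE])
  }
  w <- cai_weights(reference)
  cai_v <- vapply(counts_list, cai, numeric(1), weights = w)
  data.frame(gene = records$id, gc[, c("gc1", "gc2", "gc3", "gc_mean",
                                       "gc12", "gc3s")],
             enc = enc_v, cai = cai_v,
             l_aa = vapply(counts_list, amino_acid_count, integer(1)),
             pr2_x = pr2[, 1], pr2_y = pr2[, 2],
             stringsAsFactors = FALSE, row.names = NULL)
}
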