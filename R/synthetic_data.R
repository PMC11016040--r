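#' Generate a synthetic CDS set with controlled codon-usage structure
#'
#' Emulates a chloroplast-like gene set: every gene starts with ATG, ends
#' with a stop codon, contains no internal stop, and has length >= 300 nt
#' and a multiple of 3 — so generated sets pass [filter_cds()] by
#' construction. Within-family codon preferences are drawn per gene from a
#' symmetric Dirichlet: small `concentration` gives sharp (selection-like)
#' preferences, large values approach uniform usage. Third-position G+C is
#' tilted toward a per-gene GC3 target drawn around `gc3_target`
#' (mutation-pressure-like composition bias). Setting `gc3_target = NULL`
#' disables the tilt; `concentration = Inf` gives uniform pre-tilt
#' preferences, i.e. a mutation-only set.
#'
#' Defaults mirror the study conditions of legume chloroplast genomes:
#' about 48 CDS per genome, lengths 300-2400 nt, AT-rich third positions
#' (GC3 around 27%).
#'
#' @param n_genes Number of genes (default 48).
#' @param length_range Min/max gene length in nt; lengths are sampled
#'   uniformly over the multiples of 3 in this range.
#' @param concentration Symmetric Dirichlet concentration for within-family
#'   preferences (default 1; `Inf` = uniform).
#' @param gc3_target Global third-position GC target as a fraction
#'   (default 0.27), or NULL for no tilt.
#' @param gc3_sd Between-gene SD of the per-gene GC3 target (default 0.02).
#' @param seed Integer seed; generation is bit-reproducible.
#' @param species Species label on the records.
#' @param aa_freq Amino-acid sampling frequencies for the internal codons:
#'   a named numeric vector over the 20 one-letter codes (normalised
#'   internally). The default is a plastid-like protein composition, rich
#'   in Leu/Ile/Ser/Phe, which puts first- and second-position GC in the
#'   range seen in chloroplast genes (GC1 around 45%, GC2 around 38%).
#'   `NULL` draws amino acids in proportion to family size (uniform over
#'   sense codons).
#' @return CDS-record data.frame with `source = "synthetic"`.
#' @export
generate_cds_set <- function(n_genes = 48L, length_range = c(300L, 2400L),
                             concentration = 1, gc3_target = 0.27,
                             gc3_sd = 0.02, seed = 1L,
                             species = "synthetic",
                             aa_freq = plastid_aa_frequencies()) {
  stopifnot(n_genes >= 1L, length_range[1] >= 300L,
            length_range[2] >= length_range[1], concentration > 0)
  if (!is.null(gc3_target) && (gc3_target < 0 || gc3_target > 1))
    stop("gc3_target must lie in [0, 1]")
  tab <- codon_table()
  sense <- tab[tab$amino_acid != "*", ]
  fams <- split(sense$codon, sense$amino_acid)
  aa_names <- names(fams)
  if (is.null(aa_freq)) {
    aa_prob <- vapply(fams, length, integer(1)) / nrow(sense)
  } else {
    if (!all(aa_names %in% names(aa_freq)))
      stop("aa_freq must name all 20 amino acids")
    aa_prob <- aa_freq[aa_names] / sum(aa_freq[aa_names])
  }
  stops <- c("TAA", "TAG", "TGA")
  with_seed(seed, {
    lengths <- 3L * sample(seq(length_range[1] %/% 3L,
                               length_range[2] %/% 3L), n_genes,
                           replace = TRUE)
    seqs <- character(n_genes)
    for (g in seq_len(n_genes)) {
      g_target <- if (is.null(gc3_target)) NULL else
        min(max(stats::rnorm(1, gc3_target, gc3_sd), 0.02), 0.98)
      prefs <- lapply(fams, function(cod) {
        k <- length(cod)
        p <- if (is.infinite(concentration)) rep(1 / k, k)
             else { x <- stats::rgamma(k, shape = concentration); x / sum(x) }
        stats::setNames(p, cod)
      })
      if (!is.null(g_target)) prefs <- .tilt_gc3(prefs, aa_prob, g_target)
      n_internal <- lengths[g] %/% 3L - 2L
      aa_seq <- sample(aa_names, n_internal, replace = TRUE, prob = aa_prob)
      codons <- vapply(aa_seq, function(a) {
        p <- prefs[[a]]
        sample(names(p), 1L, prob = p)
      }, character(1))
      seqs[g] <- paste0("ATG", paste(codons, collapse = ""),
                        sample(stops, 1L))
    }
    cds_records(sprintf("%s_g%03d", species, seq_len(n_genes)), seqs,
                species, "synthetic")
  })
}

#' Plastid-like amino-acid usage frequencies
#'
#' A typical amino-acid composition of chloroplast-encoded proteins
#' (hydrophobic membrane proteins dominate: Leu, Ile, Ser and Phe are
#' frequent, Cys and His rare). Used as the default sampling profile of
#' [generate_cds_set()] so synthetic genes land near the positional GC
#' composition of real chloroplast CDS.
#'
#' @return Named numeric vector over the 20 one-letter amino-acid codes,
#'   summing to 1.
#' @export
plastid_aa_frequencies <- function() {
  f <- c(L = 0.105, I = 0.084, S = 0.078, G = 0.070, F = 0.066,
         A = 0.065, V = 0.060, T = 0.055, E = 0.053, R = 0.050,
         N = 0.048, K = 0.047, P = 0.045, D = 0.042, Q = 0.040,
         Y = 0.034, M = 0.025, H = 0.022, W = 0.020, C = 0.011)
  f / sum(f)
}

# Exponentially tilt within-family preferences so the expected
# third-position G+C over a gene's codons (amino acids drawn with
# probability aa_prob) equals `target`. The tilt factor tau multiplies the
# preference of every G/C-ending codon; it is solved on the log scale.
.tilt_gc3 <- function(prefs, aa_prob, target) {
  is_gc <- lapply(prefs, function(p)
    substr(names(p), 3L, 3L) %in% c("G", "C"))
  expected_gc3 <- function(log_tau) {
    tau <- exp(log_tau)
    sum(vapply(seq_along(prefs), function(i) {
      p <- prefs[[i]] * ifelse(is_gc[[i]], tau, 1)
      aa_prob[[names(prefs)[i]]] * sum(p[is_gc[[i]]]) / sum(p)
    }, numeric(1)))
  }
  lo <- -25; hi <- 25
  f_lo <- expected_gc3(lo) - target
  f_hi <- expected_gc3(hi) - target
  log_tau <- if (f_lo >= 0) lo else if (f_hi <= 0) hi else
    stats::uniroot(function(x) expected_gc3(x) - target, c(lo, hi),
                   tol = 1e-9)$root
  tau <- exp(log_tau)
  lapply(seq_along(prefs), function(i) {
    p <- prefs[[i]] * ifelse(is_gc[[i]], tau, 1)
    p / sum(p)
  }) |> stats::setNames(names(prefs))
}

#' Generate genes with a planted GC12-GC3 relationship
#'
#' Builds a gene set whose per-gene (GC3, GC12) pairs follow
#' GC12 = a + b * GC3 + eps with eps ~ Normal(0, noise_sd), realised by
#' sampling position-specific base compositions: first and second codon
#' positions at the gene's GC12 target, third position at its GC3 target
#' (G/C and A/T split evenly within each class). Stop codons arising
#' internally are resampled; genes start with ATG and end with a random
#' stop, so the set passes [filter_cds()]. Used to validate
#' [neutrality_fit()] by parameter recovery.
#'
#' @param b Planted slope in [0, 1] (fraction scale).
#' @param noise_sd SD of the Gaussian noise on GC12 (fraction scale).
#' @param n Number of genes.
#' @param seed Integer seed.
#' @param gc3_range Range the per-gene GC3 targets are drawn from.
#' @param intercept Intercept a; default centres GC12 at 0.41 over the GC3
#'   range, matching chloroplast-like composition.
#' @param length_range Gene length range in nt.
#' @return CDS-record data.frame with `source = "synthetic"`.
#' @export
generate_neutrality_set <- function(b, noise_sd = 0.02, n = 200L,
                                    seed = 1L, gc3_range = c(0.15, 0.45),
                                    intercept = NULL,
                                    length_range = c(600L, 1800L)) {
  stopifnot(b >= 0, b <= 1, noise_sd >= 0, n >= 3L)
  if (is.null(intercept)) intercept <- 0.41 - b * mean(gc3_range)
  stops <- c("TAA", "TAG", "TGA")
  with_seed(seed, {
    lengths <- 3L * sample(seq(length_range[1] %/% 3L,
                               length_range[2] %/% 3L), n, replace = TRUE)
    gc3_target <- stats::runif(n, gc3_range[1], gc3_range[2])
    eps <- stats::rnorm(n, 0, noise_sd)
    base_probs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2,
                                 G = gc / 2, T = (1 - gc) / 2)
    seqs <- character(n)
    for (g in seq_len(n)) {
      n_internal <- lengths[g] %/% 3L - 2L
      # third positions first: the planted line is conditioned on the
      # realised GC3, so finite-length sampling noise does not attenuate
      # the recovered slope
      p3 <- base_probs(gc3_target[g])
      third <- sample(names(p3), n_internal, TRUE, p3)
      gc3_real <- mean(third %in% c("C", "G"))
      gc12 <- min(max(intercept + b * gc3_real + eps[g], 0.02), 0.95)
      p12 <- base_probs(gc12)
      first <- sample(names(p12), n_internal, TRUE, p12)
      second <- sample(names(p12), n_internal, TRUE, p12)
      codons <- paste0(first, second, third)
      # resample only positions 1-2 of stop codons: the realised third-
      # position composition is preserved exactly
      repeat {
        bad <- which(codons %in% stops)
        if (length(bad) == 0L) break
        codons[bad] <- paste0(sample(names(p12), length(bad), TRUE, p12),
                              sample(names(p12), length(bad), TRUE, p12),
                              third[bad])
      }
      seqs[g] <- paste0("ATG", paste(codons, collapse = ""),
                        sample(stops, 1L))
    }
    cds_records(sprintf("neut_g%03d", seq_len(n)), seqs,
                "synthetic_neutrality", "synthetic")
  })
}

#' A gene with exactly uniform synonymous codon usage
#'
#' Contains every sense codon exactly `n_per_codon` times (codon order
#' shuffled by `seed`), preceded by an ATG start and followed by a TAA
#' stop. Uniform usage is the analytic upper limit of codon-usage evenness,
#' so [enc()] of this gene is exactly 61.
#'
#' @param n_per_codon Repetitions of each sense codon (>= 1; >= 2 also
#'   satisfies the 300-nt filter).
#' @param seed Shuffle seed.
#' @return One-row CDS-record data.frame.
#' @export
uniform_usage_gene <- function(n_per_codon = 5L, seed = 1L) {
  stopifnot(n_per_codon >= 1L)
  codons <- rep(sense_codons(), n_per_codon)
  with_seed(seed, {
    codons <- sample(codons)
    cds_records("uniform_usage",
                paste0("ATG", paste(codons, collapse = ""), "TAA"),
                "synthetic_uniform", "synthetic")
  })
}
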