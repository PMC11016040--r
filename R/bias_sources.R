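#' Parity rule 2 (PR2) coordinates of a gene
#'
#' Third-position base composition over the degenerate sense codons (Met,
#' Trp and stops excluded): x = G3/(G3 + C3) and y = A3/(A3 + T3). Under
#' mutation pressure alone the point sits at the plot centre (0.5, 0.5)
#' where A = T and G = C; systematic displacement indicates selection or
#' strand-asymmetric effects.
#'
#' @param counts Gene-scope 64-codon count vector.
#' @return Named numeric vector `pr2_x`, `pr2_y` in [0, 1]; a coordinate is
#'   NA when its denominator is zero.
#' @export
#' @examples
#' pr2_point(count_codons(paste0("ATG", "AAT", "AAT", "AAG", "TAA")))
pr2_point <- function(counts) {
  counts <- .check_counts(counts)
  eligible <- names(counts) %in% degenerate_codons()
  third <- substr(names(counts), 3L, 3L)
  tal <- vapply(c("A", "C", "G", "T"),
                function(b) sum(counts[eligible & third == b]), numeric(1))
  x <- if (tal[["G"]] + tal[["C"]] > 0)
    tal[["G"]] / (tal[["G"]] + tal[["C"]]) else NA_real_
  y <- if (tal[["A"]] + tal[["T"]] > 0)
    tal[["A"]] / (tal[["A"]] + tal[["T"]]) else NA_real_
  c(pr2_x = x, pr2_y = y)
}

#' Neutrality-plot regression of GC12 on GC3
#'
#' Ordinary least squares of per-gene GC12 on GC3 (percent scale; the slope
#' is scale-invariant). A slope near 1 with significant correlation
#' indicates mutation-pressure-dominated composition; a slope near 0
#' indicates selection/constraint. The slope is read as the proportion of
#' the codon-usage pattern attributable to mutation pressure
#' (`mutation_pct` = 100 x slope), the remainder to selection.
#'
#' @param genes data.frame with numeric columns `gc12` and `gc3` (one row
#'   per gene), e.g. from [gene_indices()].
#' @return List of class `neutrality_fit`: `slope`, `intercept`, `r`
#'   (Pearson), `p_value`, `n_genes`, `se_slope`, `mutation_pct`,
#'   `selection_pct`.
#' @export
neutrality_fit <- function(genes) {
  stopifnot(is.data.frame(genes), all(c("gc12", "gc3") %in% names(genes)))
  ok <- stats::complete.cases(genes[, c("gc12", "gc3")])
  d <- genes[ok, , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 genes with defined GC12 and GC3")
  if (stats::var(d$gc3) == 0) stop("GC3 has zero variance; slope undefined")
  fit <- stats::lm(gc12 ~ gc3, data = d)
  slope <- unname(stats::coef(fit)[2])
  # summary() warns on exact fits (slope-1 diagonal test case); the SE is
  # still the right degenerate value (0)
  fit_summary <- suppressWarnings(summary(fit))
  if (stats::var(d$gc12) == 0) {
    r <- 0; p <- 1
  } else {
    ct <- stats::cor.test(d$gc3, d$gc12)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r = r, p_value = p, n_genes = nrow(d),
                 se_slope = unname(fit_summary$coefficients[2, 2]),
                 mutation_pct = 100 * slope,
                 selection_pct = 100 * (1 - slope)),
            class = "neutrality_fit")
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf("Neutrality plot fit (n = %d genes):\n", x$n_genes))
  cat(sprintf("  GC12 = %.4f + %.4f x GC3   (r = %.3f, p = %.3g)\n",
              x$intercept, x$slope, x$r, x$p_value))
  cat(sprintf("  mutation pressure %.2f%%, selection/other %.2f%%\n",
              x$mutation_pct, x$selection_pct))
  invisible(x)
}

#' ENC-ranked high- and low-expression gene sets
#'
#' Ranks genes by ENC (ascending; low ENC = strong bias = putatively high
#' expression) and returns the lowest-ENC `fraction` as the high-expression
#' set and the highest-ENC `fraction` as the low-expression set. Ties are
#' broken by gene id (lexicographic) so the sets are deterministic.
#'
#' @param genes data.frame with columns `gene` and `enc`.
#' @param fraction Fraction in (0, 0.5] per extreme (default 0.1; set size
#'   is `ceiling(fraction * N)`).
#' @return List with character vectors `high` and `low` (disjoint).
#' @export
select_expression_datasets <- function(genes, fraction = 0.1) {
  stopifnot(is.data.frame(genes), all(c("gene", "enc") %in% names(genes)))
  if (fraction <= 0 || fraction > 0.5)
    stop("fraction must lie in (0, 0.5]")
  d <- genes[!is.na(genes$enc), , drop = FALSE]
  n_set <- ceiling(fraction * nrow(d))
  if (2L * n_set > nrow(d))
    stop("too few genes (", nrow(d), ") for disjoint sets of ", n_set)
  ord <- order(d$enc, d$gene)
  list(high = d$gene[ord[seq_len(n_set)]],
       low = d$gene[ord[seq(nrow(d) - n_set + 1L, nrow(d))]])
}

#' Optimal codons from high/low expression datasets
#'
#' RSCU is computed on the concatenated counts of the high- and
#' low-expression sets; delta-RSCU = RSCU(high) - RSCU(low). A codon is
#' optimal when RSCU(high) > 1 and delta-RSCU > `threshold`. The stop
#' family participates in the screen; single-codon families (RSCU = 1)
#' never qualify.
#'
#' @param high_counts,low_counts Species-scope 64-codon count vectors of
#'   the two datasets.
#' @param threshold Minimum delta-RSCU (default 0.08).
#' @param rscu_min RSCU(high) cutoff (default 1).
#' @return List of class `optimal_codons`: `optimal` (character, sorted),
#'   `delta_rscu` (named over 64 codons), `rscu_high`, `rscu_low` (the two
#'   [rscu_rfsc()] tables).
#' @export
optimal_codons <- function(high_counts, low_counts, threshold = 0.08,
                           rscu_min = 1) {
  hi <- rscu_rfsc(high_counts)
  lo <- rscu_rfsc(low_counts)
  delta <- stats::setNames(hi$rscu - lo$rscu, hi$codon)
  opt <- hi$codon[hi$rscu > rscu_min & delta > threshold]
  structure(list(optimal = sort(opt), delta_rscu = delta,
                 rscu_high = hi, rscu_low = lo,
                 threshold = threshold),
            class = "optimal_codons")
}

#' @export
print.optimal_codons <- function(x, ...) {
  cat(length(x$optimal), "optimal codons (RSCU_high > 1, dRSCU >",
      x$threshold, "):\n ", paste(x$optimal, collapse = ", "), "\n")
  invisible(x)
}

#' ENC-plot table for a gene set
#'
#' Per-gene observed ENC against GC3s together with the expected ENC under
#' third-position composition alone; genes far below the curve indicate
#' selection on codon usage.
#'
#' @param indices Per-gene table from [gene_indices()].
#' @return data.frame `gene`, `gc3s`, `enc`, `expected_enc`.
#' @export
enc_plot_table <- function(indices) {
  stopifnot(all(c("gene", "gc3s", "enc") %in% names(indices)))
  data.frame(gene = indices$gene, gc3s = indices$gc3s, enc = indices$enc,
             expected_enc = enc_expected(indices$gc3s / 100),
             stringsAsFactors = FALSE)
}
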