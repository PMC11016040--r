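---
title: "Codon usage bias in chloroplast CDS sets: methods and design notes"
author: "chlorocub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias in chloroplast CDS sets: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chlorocub)
```

# The problem

Synonymous codons are not used evenly. In plant chloroplast genomes the
imbalance ("codon usage bias") reflects a mix of mutation pressure — which
shifts base composition, most visibly at the weakly constrained third codon
position — and natural selection on translation. Quantifying the bias and
attributing it to these sources matters for chloroplast transgene design:
an exogenous gene expressed in a plastid should use the codons the plastid
translation machinery prefers, and a heterologous expression host should
have a usage profile close to the gene's source.

`chlorocub` implements the complete analysis chain for this question:
CDS acquisition and quality filtering, composition and bias statistics
(positional GC, RSCU, RFSC, ENC, CAI), bias-source diagnostics (ENC-plot,
PR2-plot, neutrality regression, correspondence analysis), optimal-codon
determination from ENC-ranked expression datasets, and codon-frequency
comparison against model organisms. A seeded synthetic-CDS generator makes
every stage testable without genome downloads.

# CDS filtering

A coding sequence is analysed only if it passes five rules: length an
integer multiple of 3; length at least 300 nt; alphabet restricted to
A/C/G/T; an ATG start; a TAA/TAG/TGA stop; and no in-frame internal stop.
Two design choices needed fixing beyond the rules themselves:

* **Rule order.** Rejections report the *first* failed rule, so the
  evaluation order is fixed (divisibility, length, alphabet, start, stop,
  internal stop) to make reports deterministic.
* **Ambiguity codes.** Sequences containing IUPAC ambiguity letters (N, R,
  ...) fail the alphabet rule; they are reported, not raised as errors.
* **Duplicate gene names** (e.g. genes duplicated in the chloroplast
  inverted repeat) are kept as separate records; no deduplication is
  applied.

GenBank flat files are supported directly: `join(...)` locations are
spliced in feature order and `complement(...)` features
reverse-complemented, so every record reads 5'→3' from its start codon.
The standard genetic code is used throughout (the plastid code is
identical at the codon-assignment level used here).

# Composition statistics

For a codon count table, GC1/GC2/GC3 are the percentages of G+C at each
codon position, GC12 their first/second-position mean, and GC3s the
third-position G+C restricted to codons of *degenerate* sense families —
the 59 codons left after excluding ATG (Met), TGG (Trp) and the three
stops, whose third position carries no synonymous freedom. A table in
which every codon is excluded from the GC3s definition yields `NaN`, not
an error, so downstream tables can flag rather than fail.

# RSCU, RFSC and high-frequency codons

With $X_{ij}$ the count of codon $j$ in synonymous family $i$ and $n_i$
the family size (1–6; the three stops form one family of size 3):

$$\mathrm{RFSC}_{ij} = \frac{X_{ij}}{\sum_j X_{ij}}, \qquad
  \mathrm{RSCU}_{ij} = \mathrm{RFSC}_{ij} \times n_i .$$

RFSC sums to 1 within each observed family and RSCU to $n_i$; RSCU = 1
means unbiased use. Ser, Leu and Arg are treated as single six-codon
families, matching the convention under which six-fold RSCU values above 2
arise. Families with zero total count get RSCU = RFSC = 0 and an
`observed_family = FALSE` flag; they are excluded from high-frequency and
optimal-codon candidacy.

A codon is **high-frequency (HF)** when its RFSC exceeds 0.6, or exceeds
its family-average frequency $1/n_i$ by more than half of that average,
i.e. $\mathrm{RFSC} > 1.5/n_i$. The second clause is a deliberate
disambiguation: read literally as "more than 0.5 times the average", the
threshold $0.5/n_i$ would mark nearly every observed codon HF, which is
useless as a classifier; exceeding the average by 50% is the reading under
which HF sets have the expected size (about 1–2 per family). Both the 0.6
cutoff and the 1.5 multiplier are exposed as arguments.

```{r hf-example}
tab <- rscu_rfsc(count_codons("ATGGCTGCTGCAGCCTTATTAGATTAA"))
classify_hf_codons(tab)
```

# ENC and the expected curve

Per-gene codon-usage evenness is summarised by Wright's effective number
of codons. For each synonymous family with total count $n$ and
within-family frequencies $p_j$, the homozygosity estimate is
$\hat F = (n\sum_j p_j^2 - 1)/(n-1)$; $\hat F$ values are averaged within
degeneracy classes $k \in \{2,3,4,6\}$ and

$$\mathrm{ENC} = 2 + \frac{9}{\bar F_2} + \frac{1}{\bar F_3}
  + \frac{5}{\bar F_4} + \frac{3}{\bar F_6}.$$

Conventions, chosen for compatibility with the classical CodonW behaviour:

* families with $n < 2$, and $\hat F \le 0$ values (a small-$n$ artifact),
  are dropped from their class average;
* a missing 3-fold class (Ile unobserved) is imputed by harmonic
  interpolation between the 2- and 4-fold means,
  $1/\bar F_3 = (1/\bar F_2 + 1/\bar F_4)/2$;
* a gene missing an entire 2-, 4- or 6-fold class returns `NA` rather than
  a guess — such genes are rare and are flagged;
* the estimate is **capped at 61**. The cap is load-bearing: on a finite
  gene with exactly uniform usage, $\hat F = (m-1)/(km-1) < 1/k$ for a
  $k$-fold family with $m$ counts per codon, so the raw sum *exceeds* 61
  by sampling inflation; the cap returns the analytic limit 61 exactly.
  One codon per family gives $\hat F = 1$ in every family and ENC = 20
  exactly.

The ENC-plot compares observed ENC against the expectation under
third-position composition alone,
$\mathrm{ENC}^* = 2 + S + 29/(S^2 + (1-S)^2)$ with $S$ = GC3s. Genes near
the curve are consistent with mutation-driven bias; genes well below it
use fewer codons than their composition explains, indicating selection.

```{r enc-example}
enc(count_codons(uniform_usage_gene(5L)$sequence))
enc_expected(c(0, 0.5))
```

# CAI

Relative adaptiveness weights follow the Sharp & Li convention:
within each family $w_j = X_j / \max_{j'} X_{j'}$ computed on a reference
(putatively highly expressed) count table, zero counts smoothed to 0.5
before division; CAI of a gene is the geometric mean of $w$ over its
codons, excluding Met, Trp and stops. The source of the reference set is a
genuinely open choice — chloroplast genomes ship no expression atlas — so
the default takes the lowest-ENC fraction (10%) of the genes themselves as
the reference, the standard proxy of high expression, and
`gene_indices(reference = ...)` accepts any explicit reference table
instead.

# PR2 and neutrality

The parity-rule-2 point of a gene is $x = G_3/(G_3+C_3)$,
$y = A_3/(A_3+T_3)$ over the degenerate sense codons. Under mutation
pressure alone substitution symmetry keeps A≈T and G≈C at the third
position, so points sit near (0.5, 0.5); systematic displacement indicates
selective or strand-asymmetric effects. Coordinates with a zero
denominator are `NA`-flagged.

The neutrality plot regresses per-gene GC12 on GC3 (ordinary least
squares, percent scale — the slope is scale-invariant). Slope near 1:
first/second positions track third-position composition, i.e. mutation
pressure dominates; slope near 0: they are decoupled, i.e.
selection/constraint dominates. Following the conventional reading, the
slope is reported as the mutation-pressure share
(`mutation_pct` = 100 × slope) and its complement as selection.

# Optimal codons

High- and low-expression datasets are formed by ranking genes by ENC
(ascending) and taking the extreme `fraction` at each end — low ENC is
strong bias, the proxy of high expression. The split fraction behind
published optimal-codon counts is typically unstated; the default here is
the literature convention of 10% extremes, exposed as `extreme_fraction`,
and with ~50 genes per chloroplast genome this yields 5-gene sets, so
optimal-codon counts are sensitive to the choice — exact reproduction of
published per-species lists is not promised. Ties in ENC are broken by
gene id so the sets are deterministic. RSCU is computed on the
concatenated counts of each set, ΔRSCU = RSCU(high) − RSCU(low), and a
codon is optimal when RSCU(high) > 1 and ΔRSCU > 0.08. The stop family
participates in the screen (published optimal sets include TAA);
single-codon families can never qualify since their RSCU is identically 1.

# Correspondence analysis

Each gene is a 59-dimensional vector of per-gene RSCU values (CA on RSCU
rather than raw counts — the classical choice for codon tables, since RSCU
removes amino-acid composition; a count-based CA is available by passing
raw counts). Classical CA is computed from the SVD of the standardized
residuals $D_r^{-1/2}(P - rc^\top)D_c^{-1/2}$; axis $k$ carries inertia
fraction $\sigma_k^2/\sum \sigma^2$, row principal coordinates are
$D_r^{-1/2} U \Sigma$, and total inertia equals the table's Pearson
chi-square over its grand total (asserted against an independent
eigendecomposition oracle in the tests). Because an SVD is sign-ambiguous,
orientation is fixed deterministically: the first nonzero column loading
of each axis is made positive. Genes with fewer than 3 observed families
are dropped with a warning — near-empty RSCU rows carry extreme row
profiles that distort the chi-square geometry. Four axes are reported by
default; axis–index correlations (GC3s, CAI, ENC, amino-acid length,
overall GC) are Pearson by default with Spearman available, and the
overall gene GC (not GC3) is used for the GC column.

# Model-organism comparison

Host codon usage per thousand codons is compared codon-by-codon against a
model organism's table (Codon Usage Database "Kazusa" text format; U is
mapped to T, all 64 codons required). Both tables are renormalised to a
common per-thousand scale before the ratio is taken, so band counts are
invariant to a table's overall scaling; for valid per-thousand tables this
renormalisation is a negligible correction. Ratios ≥ 2 or ≤ 0.5
(boundaries inclusive, matching the printed operators) count a codon as
divergent; ratios strictly between 0.5 and 2 as similar; model-zero codons
are reported as undefined. All 64 codons participate, stops included.

The tables bundled under `inst/extdata/kazusa/` are **synthetic
stand-ins** generated by the package's own simulator (see the README in
that directory): they exercise the format and the band arithmetic
deterministically, but they are not the real organisms' usage — analyses
of real hosts should download the genuine tables.

# The synthetic-data generator

`generate_cds_set()` emulates the features of a chloroplast CDS set that
the pipeline is sensitive to: ~44–52 genes per genome, lengths ≥ 300 nt
and multiples of 3 (so generated sets pass the filters by construction),
AT-rich third positions (default GC3 target 27%, per-gene spread 2%), and
per-gene within-family preference vectors drawn from a symmetric Dirichlet
whose concentration is the one-knob bias control: small values give sharp,
selection-like preferences, `Inf` gives uniform (mutation-only)
preferences. Third-position composition is imposed by an exponential tilt
of the preference vectors whose factor is solved per gene (by `uniroot`)
so the *expected* GC3 equals the target — a naive multiplicative tilt
undershoots. Amino acids are drawn from a plastid-like protein composition
(`plastid_aa_frequencies()`: Leu/Ile/Ser/Phe-rich), which places GC1 and
GC2 in the range observed for chloroplast genes; drawing uniformly over
sense codons is available with `aa_freq = NULL`. Stop codons are chosen
uniformly from TAA/TAG/TGA.

`generate_neutrality_set()` plants a linear GC12–GC3 relationship:
third positions are sampled first, and GC12 is conditioned on the
*realised* GC3 of each gene. Conditioning on the realised value is
deliberate — conditioning on the target would add sampling noise to the
regressor and attenuate the recovered slope by
$1/(1 + \sigma^2_{noise}/\sigma^2_{GC3})$, about 10% at typical gene
lengths, turning a correct estimator into an apparent failure. Internal
stop codons are removed by resampling only their first two positions, so
the planted third-position composition is untouched.

What the generator does **not** emulate: real chloroplast gene families
and their shared functional constraints (photosystem genes are not
exchangeable with ribosomal-protein genes), inverted-repeat duplication,
between-gene correlation of preferences, amino-acid composition varying by
gene, and any phylogenetic structure across genomes. Passing tests
therefore demonstrate that the statistics are computed correctly and
recover planted structure — not that real genomes will show any particular
biological signal.

# Numerical choices and degenerate inputs

* Percentages and RSCU are reported to 2 decimals and slopes to 4 in the
  TSV reports (`gene_indices.tsv` keeps full precision); internal
  computation is always full precision.
* Empty count tables error; all-excluded GC3s yields `NaN`; undefined ENC
  yields `NA`; PR2 zero denominators yield `NA`; constant indices in the
  correlation table are marked `undefined`.
* CA drops zero-total columns (they carry no inertia) and treats singular
  values below `1e-12` (relative) as rank noise.
* ENC-ranking ties are broken lexicographically by gene id.
* All generators are bit-reproducible from their seed and restore the
  caller's RNG state.

# Problem sizes

The test suite runs entirely on synthetic data: 1000 random count tables
for the RSCU invariants, 200-gene sets for neutrality-slope recovery,
20×10 random tables for the CA oracle, and 9 × ~48-gene genomes in the
analysis workflow — sizes at which every check completes in seconds while
keeping estimator noise well below the asserted tolerances. The
`analysis/` scripts state their cohort in `results/simulated/cohort.tsv`.

# Known limitations

* Published per-species optimal-codon lists depend on an unstated
  expression-split convention; only the screen's definition is guaranteed.
* ENC class-imputation conventions can shift ENC by a few tenths for
  short genes; per-gene agreement with other implementations is expected
  only to that granularity.
* The GenBank reader covers the feature-location grammar used by plastid
  RefSeq records (`join`, `order`, `complement`, `<`/`>` markers); it is
  not a general GenBank parser.
* Band counts against the bundled synthetic model tables are
  illustrative; real host-choice conclusions require the genuine Codon
  Usage Database tables.
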