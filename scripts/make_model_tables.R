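#!/usr/bin/env Rscript
# Regenerates the synthetic model-organism codon usage tables under
# inst/extdata/kazusa/. These are stand-ins in Codon Usage Database text
# format, derived from the package's own synthetic genomes (not the real
# organisms' usage): they exercise the Kazusa parser and the ratio-band
# comparison deterministically and offline. Filenames carry the
# "_synthetic" suffix to make the provenance unmistakable.
library(chlorocub)

out_dir <- file.path("inst", "extdata", "kazusa")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# Each pseudo-organism differs in GC3 and preference sharpness so that
# comparisons against AT-rich chloroplast-like hosts span the ratio bands.
specs <- list(
  arabidopsis_thaliana_synthetic = list(gc3 = 0.40, conc = 2.0, seed = 101L),
  nicotiana_tabacum_synthetic    = list(gc3 = 0.38, conc = 2.5, seed = 102L),
  escherichia_coli_synthetic     = list(gc3 = 0.55, conc = 0.8, seed = 103L),
  saccharomyces_cerevisiae_synthetic =
                                   list(gc3 = 0.38, conc = 1.2, seed = 104L))

for (org in names(specs)) {
  p <- specs[[org]]
  genes <- generate_cds_set(n_genes = 200L, concentration = p$conc,
                            gc3_target = p$gc3, seed = p$seed,
                            species = org)
  tab <- per_thousand_frequencies(count_codons(genes), org)
  write_kazusa_table(tab, file.path(out_dir, paste0(org, ".txt")))
  message("wrote ", org, ".txt")
}
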