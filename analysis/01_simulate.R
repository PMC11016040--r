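#!/usr/bin/env Rscript
# Step 1: simulate a nine-genome cohort of chloroplast-like CDS sets.
#
# Each synthetic "species" mirrors the conditions of legume chloroplast
# genomes: 44-52 CDS per genome, lengths 300-2400 nt, AT-rich third codon
# positions (GC3 targets 26-29%), and species-specific codon-preference
# sharpness. Writes one multi-FASTA per species plus a cohort manifest.
suppressPackageStartupMessages(library(chlorocub))

out_dir <- file.path("results", "simulated")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cohort <- data.frame(
  species = sprintf("synth_sp%02d", 1:9),
  n_genes = c(50L, 44L, 47L, 50L, 48L, 48L, 52L, 52L, 51L),
  gc3_target = c(0.280, 0.270, 0.265, 0.260, 0.265, 0.272, 0.280, 0.292,
                 0.269),
  concentration = c(0.8, 1.0, 0.9, 1.1, 0.9, 1.0, 0.8, 1.0, 0.9),
  seed = 1000L + 1:9)

for (i in seq_len(nrow(cohort))) {
  rec <- generate_cds_set(n_genes = cohort$n_genes[i],
                          concentration = cohort$concentration[i],
                          gc3_target = cohort$gc3_target[i],
                          seed = cohort$seed[i],
                          species = cohort$species[i])
  write_cds_fasta(rec, file.path(out_dir,
                                 paste0(cohort$species[i], ".fasta")))
}
write.table(cohort, file.path(out_dir, "cohort.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("Simulated ", nrow(cohort), " species (",
        sum(cohort$n_genes), " CDS total) under ", out_dir)
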