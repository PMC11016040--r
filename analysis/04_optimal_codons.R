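#!/usr/bin/env Rscript
# Step 4: high-frequency and optimal codons. Reads the per-species RSCU and
# optimal-codon screens from step 2 and reports which codons are HF in
# every genome, the optimal-codon totals from the ENC-split delta-RSCU
# screen, and the A/T-ending preference of the optimal sets.
suppressPackageStartupMessages(library(chlorocub))

cohort <- read.delim(file.path("results", "simulated", "cohort.tsv"))

per_species <- lapply(cohort$species, function(sp) {
  dir <- file.path("results", "species", sp)
  list(rscu = read.delim(file.path(dir, "rscu_rfsc.tsv")),
       opt = read.delim(file.path(dir, "optimal_codons.tsv")))
})
names(per_species) <- cohort$species

hf_sets <- lapply(per_species, function(x) x$rscu$codon[x$rscu$hf_flag])
common_hf <- Reduce(intersect, hf_sets)
opt_sets <- lapply(per_species, function(x) x$opt$codon[x$opt$optimal])

endings <- substr(unlist(opt_sets), 3, 3)
summary <- data.frame(
  species = cohort$species,
  n_hf = lengths(hf_sets),
  n_optimal = lengths(opt_sets),
  optimal_at_ending = vapply(opt_sets, function(cod)
    sum(substr(cod, 3, 3) %in% c("A", "T")), integer(1)))
write.table(summary, file.path("results", "tables", "optimal_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("HF/optimal codon summary:")
print(summary, row.names = FALSE)
message("\nHF codons common to all nine genomes (", length(common_hf),
        "): ", paste(common_hf, collapse = ", "))
message("Total optimal codons over the cohort: ", sum(lengths(opt_sets)),
        "; common to all: ",
        paste(Reduce(intersect, opt_sets), collapse = ", "))
message(sprintf("A/T-ending share of optimal codons: %.2f%%",
                100 * mean(endings %in% c("A", "T"))))
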