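#!/usr/bin/env Rscript
# Step 6: host-vs-model codon usage frequency comparison. Each species'
# per-thousand codon usage (over its filtered CDS) is compared against the
# bundled model-organism tables; codons with usage ratio >= 2 or <= 0.5 are
# divergent, ratios strictly between 0.5 and 2 similar. Fewer divergent
# codons argue for that model organism as a heterologous expression host.
#
# NOTE: the bundled tables are synthetic stand-ins in Kazusa format (see
# inst/extdata/kazusa/README); swap in genuine Codon Usage Database files
# to compare against the real model organisms.
suppressPackageStartupMessages(library(chlorocub))

cohort <- read.delim(file.path("results", "simulated", "cohort.tsv"))
model_files <- list.files(system.file("extdata", "kazusa",
                                      package = "chlorocub"),
                          pattern = "\\.txt$", full.names = TRUE)
models <- lapply(model_files, parse_kazusa_table)

rows <- list()
for (sp in cohort$species) {
  rec <- parse_fasta_cds(file.path("results", "simulated",
                                   paste0(sp, ".fasta")), species = sp)
  kept <- filter_cds(rec)$kept
  host <- per_thousand_frequencies(count_codons(kept), sp)
  for (m in models) {
    cmp <- compare_frequencies(host, m)
    rows[[length(rows) + 1L]] <- data.frame(
      host = sp, model = cmp$model, divergent = cmp$n_divergent,
      similar = cmp$n_similar)
  }
}
bands <- do.call(rbind, rows)
write.table(bands, file.path("results", "tables", "model_comparison.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("Ratio-band counts (divergent = ratio >= 2 or <= 0.5):")
print(bands, row.names = FALSE)
best <- aggregate(divergent ~ model, bands, mean)
message("\nMean divergent codons per model (lower = better expression ",
        "host):")
print(best[order(best$divergent), ], row.names = FALSE)
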