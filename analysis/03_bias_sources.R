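#!/usr/bin/env Rscript
# Step 3: where does the bias come from? Summarises the three per-gene
# diagnostics written by step 2: the ENC-plot (observed ENC against the
# mutation-only expectation), the PR2-plot (third-position base balance)
# and the neutrality regression of GC12 on GC3.
suppressPackageStartupMessages(library(chlorocub))

cohort <- read.delim(file.path("results", "simulated", "cohort.tsv"))
tab_dir <- file.path("results", "tables")

rows <- lapply(cohort$species, function(sp) {
  dir <- file.path("results", "species", sp)
  ep <- read.delim(file.path(dir, "enc_plot.tsv"))
  pr2 <- read.delim(file.path(dir, "pr2.tsv"))
  neut <- read.delim(file.path(dir, "neutrality.tsv"))
  data.frame(
    species = sp,
    pct_below_curve = round(100 * mean(ep$enc < ep$expected_enc,
                                       na.rm = TRUE), 1),
    mean_enc_gap = round(mean(ep$expected_enc - ep$enc, na.rm = TRUE), 2),
    pr2_mean_x = round(mean(pr2$pr2_x, na.rm = TRUE), 3),
    pr2_mean_y = round(mean(pr2$pr2_y, na.rm = TRUE), 3),
    slope = neut$slope, r = neut$r,
    mutation_pct = neut$mutation_pct,
    selection_pct = neut$selection_pct)
})
summary <- do.call(rbind, rows)
write.table(summary, file.path(tab_dir, "bias_sources.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("Bias-source diagnostics per species:")
print(summary, row.names = FALSE)
message("\nGenes sitting below the expected ENC curve indicate ",
        "within-family preferences beyond composition (selection-like); ",
        "PR2 means off (0.5, 0.5) indicate unbalanced third-position ",
        "base use. The cohort generator plants no GC12-GC3 coupling, so ",
        "the neutrality slopes above hover around 0 (pure selection-like ",
        "reading).")

# Planted-slope recovery: a dedicated set with a known GC12-GC3 coupling
# in the middle of the range reported for legume chloroplast genomes.
rec <- generate_neutrality_set(b = 0.40, noise_sd = 0.02, n = 200L,
                               seed = 2024L)
fit <- neutrality_fit(gene_indices(rec))
message(sprintf("\nPlanted neutrality slope 0.40 recovered as %.4f ",
                fit$slope),
        sprintf("(SE %.4f, r = %.3f): mutation pressure %.1f%%, ",
                fit$se_slope, fit$r, fit$mutation_pct),
        sprintf("selection %.1f%%.", fit$selection_pct))
recovery <- data.frame(planted_b = 0.40, recovered = round(fit$slope, 4),
                       se = round(fit$se_slope, 4), r = round(fit$r, 3))
write.table(recovery, file.path(tab_dir, "neutrality_recovery.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
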