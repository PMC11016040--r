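#!/usr/bin/env Rscript
# Downloads nine legume chloroplast GenBank records via NCBI efetch into
# inst/extdata/accessions/. Requires network access; nothing in the package
# or its tests depends on this script having run, but the published-value
# blocks in tests/testthat/test-acceptance.R only pass once these files are
# present.
accessions <- c(
  trifolium_repens        = "NC_024036.1",
  melilotus_officinalis   = "NC_070051.1",
  galega_orientalis       = "NC_069214.1",
  clitoria_ternatea       = "NC_047365.1",
  astragalus_laxmannii    = "NC_052923.1",
  galega_officinalis      = "NC_051885.1",
  pisum_sativum           = "NC_014057.1",
  stylosanthes_guianensis = "NC_058691.1",
  medicago_sativa         = "NC_042841.1")

out_dir <- file.path("inst", "extdata", "accessions")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
base <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
               "?db=nuccore&rettype=gbwithparts&retmode=text&id=")
for (sp in names(accessions)) {
  dest <- file.path(out_dir, paste0(accessions[[sp]], ".gb"))
  if (file.exists(dest)) { message("have ", dest); next }
  message("fetching ", accessions[[sp]], " (", sp, ")")
  utils::download.file(paste0(base, accessions[[sp]]), dest, quiet = TRUE)
  Sys.sleep(0.5)
}
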