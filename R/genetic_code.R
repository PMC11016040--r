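#' Codon and synonymous-family lookup tables
#'
#' The standard genetic code (NCBI translation table 1; identical to the
#' plastid/bacterial table 11 at the level of codon-to-amino-acid
#' assignments used here). Synonymous families are the sets of codons
#' translated to the same amino acid; Ser, Leu and Arg are treated as single
#' six-codon families and the three stop codons form one family of size 3.
#'
#' @return `codon_table()` returns a data.frame with one row per codon and
#'   columns `codon`, `amino_acid` (one-letter, `*` for stop) and
#'   `family_size` (1-6). Rows are in alphabetical codon order.
#' @export
#' @examples
#' head(codon_table())
codon_table <- function() {
  .chlorocub_cache$codon_table
}

#' @rdname codon_table
#' @return `all_codons()` returns the 64 codons in alphabetical order.
#' @export
all_codons <- function() .chlorocub_cache$codons

#' @rdname codon_table
#' @return `sense_codons()` returns the 61 non-stop codons.
#' @export
sense_codons <- function() {
  tab <- codon_table()
  tab$codon[tab$amino_acid != "*"]
}

#' @rdname codon_table
#' @return `degenerate_codons()` returns the 59 codons belonging to
#'   degenerate sense families (all sense codons minus ATG and TGG).
#' @export
degenerate_codons <- function() {
  tab <- codon_table()
  tab$codon[tab$amino_acid != "*" & tab$family_size > 1L]
}

# Per-package cache built once at load; Biostrings::GENETIC_CODE is the
# authority for assignments.
.chlorocub_cache <- new.env(parent = emptyenv())

.build_codon_table <- function() {
  gc_map <- Biostrings::GENETIC_CODE
  codons <- sort(names(gc_map))
  aa <- unname(gc_map[codons])
  fam_size <- as.integer(table(aa)[aa])
  data.frame(codon = codons, amino_acid = aa, family_size = fam_size,
             stringsAsFactors = FALSE)
}

.onLoad <- function(libname, pkgname) {
  tab <- .build_codon_table()
  .chlorocub_cache$codon_table <- tab
  .chlorocub_cache$codons <- tab$codon
  .chlorocub_cache$families <- split(tab$codon, tab$amino_acid)
}

#' Synonymous codon families
#'
#' @return Named list mapping each amino-acid class (one-letter code, `*`
#'   for the stop class) to its codons.
#' @export
codon_families <- function() .chlorocub_cache$families
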