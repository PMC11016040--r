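# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Split an in-frame sequence into its codons.
split_codons <- function(sequence) {
  n <- nchar(sequence)
  if (n %% 3L != 0L)
    stop("sequence length ", n, " is not a multiple of 3")
  if (n == 0L) return(character(0))
  substring(sequence, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Write a data.frame as a TSV report with header, no quoting or row names.
write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_report <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

is_cds_records <- function(x) {
  is.data.frame(x) &&
    all(c("id", "species", "sequence", "length_nt", "source") %in% names(x))
}
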