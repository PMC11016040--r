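#' Parse a codon usage table in Kazusa format
#'
#' Reads the text format of the Codon Usage Database: codon entries
#' `CODON  freq  ( count )` laid out in multi-column blocks, RNA (U) or DNA
#' (T) alphabet. U is mapped to T. All 64 codons must appear exactly once.
#'
#' @param x Path to a table file, or the table text itself (character
#'   vector of lines or a single string).
#' @param organism Organism label stored on the result.
#' @return List of class `frequency_table` with `organism` and `freq`, a
#'   named numeric vector of per-thousand usage over all 64 codons.
#' @export
parse_kazusa_table <- function(x, organism = NA_character_) {
  text <- if (length(x) == 1L && file.exists(x)) {
    if (is.na(organism)) organism <- sub("\\.[^.]*$", "", basename(x))
    readLines(x, warn = FALSE)
  } else x
  text <- paste(text, collapse = "\n")
  pat <- "([ACGTUacgtu]{3})\\s+([0-9]+\\.?[0-9]*)\\s*\\(\\s*([0-9]+)\\s*\\)"
  m <- gregexpr(pat, text, perl = TRUE)
  hits <- regmatches(text, m)[[1]]
  if (length(hits) == 0L) stop("no Kazusa-style codon entries found")
  cod <- toupper(sub(pat, "\\1", hits, perl = TRUE))
  cod <- chartr("U", "T", cod)
  freq <- as.numeric(sub(pat, "\\2", hits, perl = TRUE))
  if (anyDuplicated(cod))
    stop("duplicate codon entries: ",
         paste(unique(cod[duplicated(cod)]), collapse = ", "))
  missing <- setdiff(all_codons(), cod)
  if (length(missing))
    stop("table is missing ", length(missing), " codon(s): ",
         paste(missing, collapse = ", "))
  structure(list(organism = organism,
                 freq = stats::setNames(freq, cod)[all_codons()]),
            class = "frequency_table")
}

#' Write a frequency table in Kazusa format
#'
#' Emits the four-entries-per-line layout with RNA codons, frequencies
#' per thousand and pseudo-counts scaled to `total` codons, round-trippable
#' through [parse_kazusa_table()].
#'
#' @param table `frequency_table` (see [parse_kazusa_table()]).
#' @param path Output path.
#' @param total Codon total used for the parenthesised counts.
#' @return `path`, invisibly.
#' @export
write_kazusa_table <- function(table, path, total = 1e5) {
  stopifnot(inherits(table, "frequency_table"))
  cods <- all_codons()
  rna <- chartr("T", "U", cods)
  entries <- sprintf("%s %.1f(%6d)", rna, table$freq[cods],
                     as.integer(round(table$freq[cods] * total / 1000)))
  lines <- vapply(split(entries, ceiling(seq_along(entries) / 4)),
                  paste, character(1), collapse = "  ")
  writeLines(c(paste0("# codon usage table: ", table$organism),
               "# fields: [triplet] [frequency: per thousand] ([number])",
               lines), path)
  invisible(path)
}

#' Per-thousand codon usage frequencies
#'
#' @param counts 64-codon count vector (species scope).
#' @param organism Organism label.
#' @return `frequency_table` with freq = 1000 x count / total; frequencies
#'   sum to exactly 1000 before any rounding.
#' @export
per_thousand_frequencies <- function(counts, organism = NA_character_) {
  counts <- .check_counts(counts)
  n <- sum(counts)
  if (n == 0) stop("empty codon count table")
  structure(list(organism = organism, freq = 1000 * counts / n),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat("Codon usage frequencies (per thousand) for", x$organism, "\n")
  print(round(x$freq, 1))
  invisible(x)
}

#' Compare host and model-organism codon usage frequencies
#'
#' Per-codon ratio host/model over all 64 codons. Ratios >= 2 or <= 0.5
#' (boundaries inclusive) mark a codon as divergent — large usage
#' difference, arguing against that model organism as a heterologous
#' expression host; ratios strictly between 0.5 and 2 mark it similar.
#' Codons with zero model frequency have an undefined ratio and are
#' reported separately.
#'
#' @param host,model `frequency_table` objects.
#' @return List of class `frequency_comparison`: `host`, `model`
#'   (organism labels), `n_divergent`, `n_similar`, `divergent_codons`,
#'   `undefined_codons`, `ratio` (named over 64 codons).
#' @export
compare_frequencies <- function(host, model) {
  stopifnot(inherits(host, "frequency_table"),
            inherits(model, "frequency_table"))
  # renormalise so band counts are invariant to a common rescaling
  h <- 1000 * host$freq[all_codons()] / sum(host$freq)
  m <- 1000 * model$freq[all_codons()] / sum(model$freq)
  ratio <- h / m
  undef <- m == 0
  div <- !undef & (ratio >= 2 | ratio <= 0.5)
  structure(list(host = host$organism, model = model$organism,
                 n_divergent = sum(div),
                 n_similar = sum(!undef & !div),
                 divergent_codons = sort(names(ratio)[div]),
                 undefined_codons = sort(names(ratio)[undef]),
                 ratio = ratio),
            class = "frequency_comparison")
}

#' @export
print.frequency_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: %d divergent (ratio >= 2 or <= 0.5), %d similar",
              x$host, x$model, x$n_divergent, x$n_similar))
  if (length(x$undefined_codons))
    cat(",", length(x$undefined_codons), "undefined")
  cat("\n")
  invisible(x)
}
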