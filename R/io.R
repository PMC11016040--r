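#' Construct a table of CDS records
#'
#' The package represents a set of coding sequences as a plain data.frame
#' with one row per CDS: `id`, `species`, `sequence` (uppercase nucleotide
#' string), `length_nt` and `source` (`"fasta"`, `"genbank"` or
#' `"synthetic"`). All downstream functions accept this shape.
#'
#' @param id Character vector of gene/locus identifiers.
#' @param sequence Character vector of nucleotide sequences (any case;
#'   stored uppercased).
#' @param species Species label recycled across records.
#' @param source Provenance label recycled across records.
#' @return A CDS-record data.frame.
#' @export
cds_records <- function(id, sequence, species = NA_character_,
                        source = "fasta") {
  sequence <- toupper(as.character(sequence))
  data.frame(id = as.character(id),
             species = rep_len(as.character(species), length(sequence)),
             sequence = sequence,
             length_nt = nchar(sequence),
             source = rep_len(source, length(sequence)),
             stringsAsFactors = FALSE)
}

#' Read coding sequences from a multi-FASTA file
#'
#' @param path Path to a nucleotide FASTA file.
#' @param species Species label attached to every record.
#' @return CDS-record data.frame (see [cds_records()]); one row per FASTA
#'   entry, in file order, sequences uppercased. An empty file yields zero
#'   rows.
#' @export
parse_fasta_cds <- function(path, species = NA_character_) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L)
    return(cds_records(character(0), character(0), species, "fasta"))
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("malformed FASTA: line ", nonblank[1],
         " is not a header ('>') line")
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  cds_records(ids, as.character(set), species, "fasta")
}

#' Write CDS records as multi-FASTA
#'
#' @param records CDS-record data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(records, path) {
  stopifnot(is_cds_records(records))
  set <- Biostrings::DNAStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Extract CDS features from a GenBank flat file
#'
#' Reads a GenBank flat file, locates CDS features and returns their
#' spliced nucleotide sequences in coding orientation: multi-interval
#' (`join(...)`) locations are concatenated in feature order and
#' minus-strand (`complement(...)`) features are reverse-complemented, so
#' every record reads 5'-to-3' from its start codon.
#'
#' @param path Path to a GenBank flat file (single entry or several
#'   concatenated entries).
#' @param species Species label; defaults to the entry ORGANISM (or the
#'   LOCUS name when absent).
#' @return CDS-record data.frame with `source = "genbank"`. Record ids come
#'   from the `/gene` qualifier, falling back to `/locus_tag`, then to a
#'   positional `CDS_<i>` label.
#' @export
extract_cds_from_genbank <- function(path, species = NULL) {
  if (!file.exists(path)) stop("GenBank file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  entry_starts <- grep("^LOCUS", lines)
  if (length(entry_starts) == 0L)
    stop("not a GenBank flat file (no LOCUS line): ", path)
  entry_ends <- c(entry_starts[-1] - 1L, length(lines))
  out <- vector("list", length(entry_starts))
  for (k in seq_along(entry_starts)) {
    out[[k]] <- .parse_genbank_entry(lines[entry_starts[k]:entry_ends[k]],
                                     species)
  }
  do.call(rbind, out)
}

.parse_genbank_entry <- function(lines, species = NULL) {
  locus_name <- trimws(sub("^LOCUS\\s+(\\S+).*$", "\\1", lines[1]))
  if (is.null(species)) {
    org <- grep("^\\s{2}ORGANISM\\s", lines, value = TRUE)
    species <- if (length(org)) trimws(sub("^\\s+ORGANISM\\s+", "", org[1]))
               else locus_name
  }

  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) == 0L)
    stop("GenBank entry ", locus_name, " has no ORIGIN sequence block")
  end_at <- grep("^//", lines)
  end_at <- if (length(end_at)) end_at[1] else length(lines) + 1L
  seq_lines <- lines[(origin_at[1] + 1L):(end_at - 1L)]
  genome <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feat_at <- grep("^FEATURES", lines)
  if (length(feat_at) == 0L)
    return(cds_records(character(0), character(0), species, "genbank"))
  feat_lines <- lines[(feat_at[1] + 1L):(origin_at[1] - 1L)]

  # Feature table: a new feature starts at column 6; continuation and
  # qualifier lines are indented to column 22.
  key <- sub("^\\s{5}(\\S+).*$", "\\1", feat_lines)
  is_new <- grepl("^\\s{5}\\S", feat_lines)
  feat_idx <- cumsum(is_new)
  cds_feats <- which(is_new & key == "CDS")

  ids <- character(0); seqs <- character(0)
  for (i in seq_along(cds_feats)) {
    block <- feat_lines[feat_idx == feat_idx[cds_feats[i]]]
    first <- sub("^\\s{5}\\S+\\s+", "", block[1])
    rest <- trimws(block[-1])
    qual_start <- which(startsWith(rest, "/"))
    loc_cont <- if (length(qual_start)) rest[seq_len(min(qual_start) - 1L)]
                else rest
    location <- paste0(trimws(first), paste(loc_cont, collapse = ""))
    quals <- rest[startsWith(rest, "/")]
    id <- .genbank_qualifier(quals, "gene")
    if (is.na(id)) id <- .genbank_qualifier(quals, "locus_tag")
    if (is.na(id)) id <- sprintf("CDS_%d", i)
    seqs <- c(seqs, .extract_location(location, genome, id))
    ids <- c(ids, id)
  }
  cds_records(ids, seqs, species, "genbank")
}

.genbank_qualifier <- function(quals, name) {
  hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
  if (length(hit) == 0L) return(NA_character_)
  gsub("\"", "", sub(paste0("^/", name, "="), "", hit[1]))
}

# Split a location string on top-level commas (paren-aware).
.split_toplevel <- function(x) {
  depth <- 0L; cuts <- integer(0)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") depth <- depth - 1L
    else if (chars[i] == "," && depth == 0L) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L); ends <- c(cuts - 1L, length(chars))
  vapply(seq_along(starts),
         function(k) paste(chars[starts[k]:ends[k]], collapse = ""),
         character(1))
}

# Evaluate a GenBank location (span, join, order, complement; < > partial
# markers stripped) against the genome sequence.
.extract_location <- function(loc, genome, feature_id) {
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(.*\\)$", loc)) {
    inner <- substr(loc, 12L, nchar(loc) - 1L)
    fwd <- .extract_location(inner, genome, feature_id)
    return(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(fwd))))
  }
  if (grepl("^(join|order)\\(.*\\)$", loc)) {
    inner <- sub("^(join|order)\\(", "", loc)
    inner <- substr(inner, 1L, nchar(inner) - 1L)
    parts <- vapply(.split_toplevel(inner),
                    .extract_location, character(1),
                    genome = genome, feature_id = feature_id)
    return(paste(parts, collapse = ""))
  }
  span <- gsub("[<>]", "", loc)
  if (!grepl("^\\d+(\\.\\.\\d+)?$", span))
    stop("unsupported location '", loc, "' for feature ", feature_id)
  ends <- as.integer(strsplit(span, "..", fixed = TRUE)[[1]])
  if (length(ends) == 1L) ends <- c(ends, ends)
  if (ends[1] < 1L || ends[2] > nchar(genome) || ends[1] > ends[2])
    stop("location ", span, " of feature ", feature_id,
         " lies outside the sequence (length ", nchar(genome), ")")
  substr(genome, ends[1], ends[2])
}

#' Filter CDS records by the five coding-sequence quality rules
#'
#' A record is kept if and only if its length is an integer multiple of 3
#' and at least `min_length` nt, its alphabet is a subset of {A,C,G,T}, it
#' starts with ATG, ends with TAA, TAG or TGA, and contains no in-frame
#' internal stop codon. Rejected records are reported with the first rule
#' they fail, evaluated in the fixed order `multiple_of_3`, `min_length`,
#' `alphabet`, `start_codon`, `stop_codon`, `internal_stop`.
#'
#' @param records CDS-record data.frame.
#' @param min_length Minimum length in nucleotides (default 300).
#' @return List with `kept` (CDS-record data.frame, original order) and
#'   `report`: a list of class `filter_report` with `n_input`, `n_kept` and
#'   `rejections` (data.frame `id`, `failed_rule`).
#' @export
filter_cds <- function(records, min_length = 300L) {
  stopifnot(is_cds_records(records))
  stops <- c("TAA", "TAG", "TGA")
  failed <- vapply(seq_len(nrow(records)), function(i) {
    s <- records$sequence[i]
    n <- nchar(s)
    if (n %% 3L != 0L) return("multiple_of_3")
    if (n < min_length) return("min_length")
    if (grepl("[^ACGT]", s)) return("alphabet")
    if (substr(s, 1L, 3L) != "ATG") return("start_codon")
    if (!substr(s, n - 2L, n) %in% stops) return("stop_codon")
    cods <- split_codons(s)
    if (any(cods[-length(cods)] %in% stops)) return("internal_stop")
    NA_character_
  }, character(1))
  keep <- is.na(failed)
  report <- structure(
    list(n_input = nrow(records), n_kept = sum(keep),
         rejections = data.frame(id = records$id[!keep],
                                 failed_rule = failed[!keep],
                                 stringsAsFactors = FALSE)),
    class = "filter_report")
  list(kept = records[keep, , drop = FALSE], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("CDS filter report:", x$n_kept, "of", x$n_input, "records kept\n")
  if (nrow(x$rejections)) {
    tab <- table(x$rejections$failed_rule)
    for (r in names(tab)) cat("  rejected by", r, ":", tab[[r]], "\n")
  }
  invisible(x)
}

#' Write a per-record filter report as TSV
#'
#' Columns `id`, `status` (`kept`/`rejected`) and `failed_rule` (empty for
#' kept records), covering every input record.
#'
#' @param records The unfiltered CDS-record data.frame.
#' @param result Return value of [filter_cds()] on `records`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(records, result, path) {
  rej <- result$report$rejections
  # row-wise match (ids may be duplicated across IR copies)
  status <- ifelse(rownames(records) %in% rownames(result$kept),
                   "kept", "rejected")
  rule <- rep("", nrow(records))
  rule[status == "rejected"] <- rej$failed_rule
  write_tsv_report(data.frame(id = records$id, status = status,
                              failed_rule = rule, stringsAsFactors = FALSE),
                   path)
}
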