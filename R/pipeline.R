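#' Run the full per-species codon-usage analysis
#'
#' Orchestrates every stage for one species: CDS loading (FASTA or GenBank),
#' quality filtering, composition summary, RSCU/RFSC with high-frequency
#' flags, per-gene indices (ENC, CAI, PR2, positional GC), ENC-plot table,
#' neutrality regression, ENC-ranked optimal-codon screen, and
#' correspondence analysis with axis-index correlations. Each stage's table
#' is written as a TSV report under `out_dir`; a stage failure is recorded
#' with its stage name and later stages are skipped.
#'
#' Reports round percentages and RSCU to 2 decimals and slopes to 4, the
#' usual table precision; `gene_indices.tsv` keeps full precision as the
#' machine-readable substrate.
#'
#' @param input CDS-record data.frame, or path to a FASTA/GenBank file.
#' @param species Species label (defaults to records' species or file name).
#' @param out_dir Output directory (created; NULL = no files written).
#' @param format `"auto"` (by extension), `"fasta"` or `"genbank"`.
#' @param extreme_fraction ENC-extreme fraction for the expression datasets.
#' @param delta_threshold delta-RSCU cutoff for optimal codons.
#' @param hf_cutoff,hf_multiplier HF-codon rule parameters
#'   (see [classify_hf_codons()]).
#' @param n_axes CA axes to report.
#' @param min_length Filter length threshold in nt.
#' @return List of class `species_report`: per-stage results (`records`,
#'   `filter`, `composition`, `rscu`, `hf_codons`, `indices`, `enc_plot`,
#'   `neutrality`, `expression_sets`, `optimal`, `coa`, `correlations`),
#'   plus `species`, `stages` (status per stage) and `files`.
#' @export
run_species <- function(input, species = NULL, out_dir = NULL,
                        format = c("auto", "fasta", "genbank"),
                        extreme_fraction = 0.1, delta_threshold = 0.08,
                        hf_cutoff = 0.6, hf_multiplier = 1.5,
                        n_axes = 4L, min_length = 300L) {
  format <- match.arg(format)
  stopifnot(extreme_fraction > 0, extreme_fraction <= 0.5,
            delta_threshold > 0)
  res <- list(species = species, stages = character(0), files = character(0))
  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      path <- file.path(out_dir, paste0(name, ".tsv"))
      write_tsv_report(df, path)
      res$files <<- c(res$files, path)
    }
  }
  run_stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      warning("stage '", name, "' failed: ", conditionMessage(e),
              "; later stages skipped", call. = FALSE)
      structure(list(stage = name, message = conditionMessage(e)),
                class = "stage_failure")
    })
    res$stages[name] <<- if (inherits(out, "stage_failure")) "failed"
                         else "ok"
    out
  }
  failed <- function(x) inherits(x, "stage_failure")
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  # -- load ----------------------------------------------------------------
  records <- run_stage("load", {
    if (is_cds_records(input)) input
    else {
      fmt <- if (format != "auto") format
        else if (grepl("\\.(gb|gbk|gbff|genbank)$", input,
                       ignore.case = TRUE)) "genbank" else "fasta"
      if (fmt == "genbank") extract_cds_from_genbank(input, species)
      else parse_fasta_cds(input, species %||% basename(input))
    }
  })
  if (failed(records)) return(.finish_species(res, records))
  if (is.null(species))
    species <- if (nrow(records)) records$species[1] else "unknown"
  res$species <- species
  records$species <- species
  res$records <- records

  # -- filter --------------------------------------------------------------
  filt <- run_stage("filter", filter_cds(records, min_length = min_length))
  if (failed(filt)) return(.finish_species(res, filt))
  res$filter <- filt$report
  kept <- filt$kept
  if (!is.null(out_dir)) {
    path <- file.path(out_dir, "filter_report.tsv")
    write_filter_report(records, filt, path)
    res$files <- c(res$files, path)
  }
  if (nrow(kept) == 0)
    return(.finish_species(res, structure(
      list(stage = "filter", message = "no CDS passed the filters"),
      class = "stage_failure")))
  res$kept <- kept

  # -- composition and RSCU ------------------------------------------------
  sp_counts <- run_stage("count", count_codons(kept))
  if (failed(sp_counts)) return(.finish_species(res, sp_counts))
  comp <- run_stage("composition",
                    composition_row(species, nrow(records), nrow(kept),
                                    sp_counts))
  if (failed(comp)) return(.finish_species(res, comp))
  res$composition <- comp
  emit(comp, "composition")

  rscu <- run_stage("rscu", {
    tab <- rscu_rfsc(sp_counts)
    hf <- classify_hf_codons(tab, hf_cutoff, hf_multiplier)
    tab$hf_flag <- tab$codon %in% hf
    tab
  })
  if (failed(rscu)) return(.finish_species(res, rscu))
  res$rscu <- rscu
  res$hf_codons <- rscu$codon[rscu$hf_flag]
  emit(data.frame(species = species, amino_acid = rscu$amino_acid,
                  codon = rscu$codon, count = rscu$count,
                  rscu = round(rscu$rscu, 2), rfsc = round(rscu$rfsc, 2),
                  hf_flag = rscu$hf_flag, stringsAsFactors = FALSE),
       "rscu_rfsc")

  # -- per-gene indices ----------------------------------------------------
  indices <- run_stage("indices",
                       gene_indices(kept,
                                    reference_fraction = extreme_fraction))
  if (failed(indices)) return(.finish_species(res, indices))
  res$indices <- indices
  emit(indices, "gene_indices")
  emit(data.frame(gene = indices$gene, pr2_x = indices$pr2_x,
                  pr2_y = indices$pr2_y, stringsAsFactors = FALSE), "pr2")
  ep <- run_stage("enc_plot", enc_plot_table(indices))
  if (!failed(ep)) { res$enc_plot <- ep; emit(ep, "enc_plot") }

  # -- neutrality ----------------------------------------------------------
  neut <- run_stage("neutrality", neutrality_fit(indices))
  if (failed(neut)) return(.finish_species(res, neut))
  res$neutrality <- neut
  emit(data.frame(species = species, slope = round(neut$slope, 4),
                  intercept = round(neut$intercept, 4),
                  r = round(neut$r, 4), p = signif(neut$p_value, 4),
                  n_genes = neut$n_genes,
                  mutation_pct = round(neut$mutation_pct, 2),
                  selection_pct = round(neut$selection_pct, 2),
                  stringsAsFactors = FALSE), "neutrality")

  # -- optimal codons ------------------------------------------------------
  opt <- run_stage("optimal", {
    sets <- select_expression_datasets(indices, extreme_fraction)
    hi <- count_codons(kept[kept$id %in% sets$high, , drop = FALSE])
    lo <- count_codons(kept[kept$id %in% sets$low, , drop = FALSE])
    oc <- optimal_codons(hi, lo, threshold = delta_threshold)
    oc$expression_sets <- sets
    oc
  })
  if (failed(opt)) return(.finish_species(res, opt))
  res$optimal <- opt
  res$expression_sets <- opt$expression_sets
  emit(data.frame(species = species,
                  codon = opt$rscu_high$codon,
                  rscu_high = round(opt$rscu_high$rscu, 2),
                  rscu_low = round(opt$rscu_low$rscu, 2),
                  delta_rscu = round(opt$delta_rscu, 4),
                  optimal = opt$rscu_high$codon %in% opt$optimal,
                  stringsAsFactors = FALSE), "optimal_codons")

  # -- correspondence analysis --------------------------------------------
  coa <- run_stage("coa", {
    m <- build_rscu_matrix(kept)
    correspondence_analysis(m, n_axes = n_axes)
  })
  if (failed(coa)) return(.finish_species(res, coa))
  res$coa <- coa
  emit(data.frame(gene = rownames(coa$row_coords),
                  round(coa$row_coords, 6),
                  gc_mean = round(indices$gc_mean[
                    match(rownames(coa$row_coords), indices$gene)], 2),
                  stringsAsFactors = FALSE, check.names = FALSE),
       "coa_genes")
  emit(data.frame(axis = seq_len(coa$n_axes),
                  inertia_pct = round(100 * coa$inertia_fraction, 2),
                  stringsAsFactors = FALSE), "coa_axes")
  corr <- run_stage("correlations",
                    axis_index_correlations(coa, indices))
  if (!failed(corr)) {
    res$correlations <- corr
    emit(data.frame(index = corr$index, axis = corr$axis,
                    r = round(corr$r, 4), p = signif(corr$p, 4),
                    mark = corr$mark, stringsAsFactors = FALSE),
         "coa_correlations")
  }
  .finish_species(res, NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.finish_species <- function(res, failure) {
  if (!is.null(failure)) res$failure <- failure
  class(res) <- "species_report"
  res
}

#' @export
print.species_report <- function(x, ...) {
  cat("Species report:", x$species %||% "?", "\n")
  cat("  stages:", paste(names(x$stages), x$stages, sep = "=",
                         collapse = ", "), "\n")
  if (!is.null(x$failure))
    cat("  failed at stage '", x$failure$stage, "': ",
        x$failure$message, "\n", sep = "")
  invisible(x)
}

#' Cross-species summary over per-species reports
#'
#' Aggregates several [run_species()] bundles: the high-frequency codon set
#' common to all species; per-species and total optimal-codon counts with
#' the common optimal set; the A/T-ending share of preferred codons
#' (RSCU > 1 per species); and, when model-organism tables are supplied,
#' the divergent/similar codon band counts of every species against every
#' model.
#'
#' @param reports List of `species_report` objects.
#' @param model_tables Optional list of `frequency_table` objects (e.g.
#'   from [parse_kazusa_table()]).
#' @param out_dir Optional output directory for TSV reports.
#' @return List of class `cross_species_report`: `common_hf`,
#'   `optimal_total`, `common_optimal`, `optimal_by_species`,
#'   `preferred` (per-species preferred codons and endings, with
#'   `at_share_pct`), and `model_comparison` (data.frame, or NULL).
#' @export
run_cross_species <- function(reports, model_tables = NULL,
                              out_dir = NULL) {
  stopifnot(length(reports) >= 2L,
            all(vapply(reports, inherits, logical(1), "species_report")))
  bad <- vapply(reports, function(r) !is.null(r$failure), logical(1))
  if (any(bad))
    stop("species with failed stages: ",
         paste(vapply(reports[bad], `[[`, character(1), "species"),
               collapse = ", "))
  species <- vapply(reports, `[[`, character(1), "species")
  names(reports) <- species

  common_hf <- Reduce(intersect, lapply(reports, `[[`, "hf_codons"))
  opt_sets <- lapply(reports, function(r) r$optimal$optimal)
  common_opt <- Reduce(intersect, opt_sets)
  opt_by_species <- data.frame(
    species = species,
    n_optimal = vapply(opt_sets, length, integer(1)),
    codons = vapply(opt_sets, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE, row.names = NULL)

  # preferred codons: RSCU > 1 on the species-scope table, sense codons
  preferred <- lapply(reports, function(r) {
    t <- r$rscu
    t$codon[t$rscu > 1 & t$amino_acid != "*"]
  })
  endings <- lapply(preferred, function(cod) substr(cod, 3L, 3L))
  n_pref <- sum(lengths(preferred))
  n_at <- sum(vapply(endings, function(e) sum(e %in% c("A", "T")),
                     integer(1)))
  pref_df <- data.frame(
    species = species,
    n_preferred = lengths(preferred),
    n_at_ending = vapply(endings, function(e) sum(e %in% c("A", "T")),
                         integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)

  model_cmp <- NULL
  if (!is.null(model_tables)) {
    rows <- list()
    for (r in reports) {
      # host frequencies computed over the filtered CDS set
      host <- per_thousand_frequencies(count_codons(r$kept), r$species)
      for (m in model_tables) {
        cmp <- compare_frequencies(host, m)
        rows[[length(rows) + 1L]] <- data.frame(
          host = cmp$host, model = cmp$model,
          n_divergent = cmp$n_divergent, n_similar = cmp$n_similar,
          n_undefined = length(cmp$undefined_codons),
          stringsAsFactors = FALSE)
      }
    }
    model_cmp <- do.call(rbind, rows)
  }

  out <- structure(list(common_hf = common_hf,
                        optimal_total = sum(lengths(opt_sets)),
                        common_optimal = common_opt,
                        optimal_by_species = opt_by_species,
                        preferred = pref_df,
                        at_share_pct = 100 * n_at / n_pref,
                        model_comparison = model_cmp),
                   class = "cross_species_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_report(data.frame(codon = common_hf),
                     file.path(out_dir, "common_hf_codons.tsv"))
    write_tsv_report(opt_by_species,
                     file.path(out_dir, "optimal_codons_by_species.tsv"))
    write_tsv_report(cbind(pref_df,
                           at_share_pct = round(out$at_share_pct, 2)),
                     file.path(out_dir, "preferred_codon_endings.tsv"))
    if (!is.null(model_cmp))
      write_tsv_report(model_cmp,
                       file.path(out_dir, "model_comparison.tsv"))
  }
  out
}

#' @export
print.cross_species_report <- function(x, ...) {
  cat("Cross-species summary (", nrow(x$preferred), " species)\n", sep = "")
  cat("  common HF codons (", length(x$common_hf), "): ",
      paste(x$common_hf, collapse = ", "), "\n", sep = "")
  cat("  optimal codons: total ", x$optimal_total, ", common: ",
      paste(x$common_optimal, collapse = ", "), "\n", sep = "")
  cat(sprintf("  preferred codons ending A/T: %.2f%%\n", x$at_share_pct))
  invisible(x)
}
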