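#' Per-gene RSCU matrix for correspondence analysis
#'
#' Represents each gene as a 59-dimensional RSCU vector over the degenerate
#' sense codons (the 64 codons minus ATG, TGG and the three stops).
#' Unobserved families contribute 0 entries. Genes with fewer than
#' `min_families` observed synonymous families are dropped with a warning
#' (near-empty rows distort the chi-square geometry).
#'
#' @param counts_list Named list of gene-scope 64-codon count vectors, or a
#'   CDS-record data.frame (counted per row).
#' @param min_families Minimum observed degenerate families per gene.
#' @return Numeric matrix, genes x 59 codons.
#' @export
build_rscu_matrix <- function(counts_list, min_families = 3L) {
  if (is_cds_records(counts_list)) {
    ids <- counts_list$id
    counts_list <- lapply(counts_list$sequence, count_codons)
    names(counts_list) <- ids
  }
  stopifnot(length(counts_list) > 0)
  if (is.null(names(counts_list)))
    names(counts_list) <- sprintf("gene_%d", seq_along(counts_list))
  cods <- degenerate_codons()
  rows <- lapply(counts_list, function(cc) {
    tab <- rscu_rfsc(cc)
    stats::setNames(tab$rscu, tab$codon)[cods]
  })
  m <- do.call(rbind, rows)
  colnames(m) <- cods
  tab <- codon_table()
  aa <- tab$amino_acid[match(cods, tab$codon)]
  n_fam <- apply(m, 1L, function(r) length(unique(aa[r > 0])))
  drop <- n_fam < min_families
  if (any(drop)) {
    warning(sum(drop), " gene(s) with fewer than ", min_families,
            " observed families dropped from the RSCU matrix: ",
            paste(utils::head(rownames(m)[drop], 5L), collapse = ", "))
    m <- m[!drop, , drop = FALSE]
  }
  if (nrow(m) == 0) stop("no genes left after dropping near-empty rows")
  m
}

#' Correspondence analysis of a genes-by-codons table
#'
#' Classical CA treating the matrix as a two-way contingency table:
#' P = X/total, row masses r and column masses c, standardized residuals
#' S = Dr^(-1/2) (P - r c') Dc^(-1/2), SVD S = U D V'. Axis k carries an
#' inertia fraction sigma_k^2 / sum(sigma^2); row principal coordinates are
#' Dr^(-1/2) U D. Total inertia equals the table's Pearson chi-square
#' statistic divided by its grand total. Columns with zero total are
#' dropped (they carry no inertia). Axis orientation is fixed by requiring
#' the first nonzero column loading of each axis to be positive.
#'
#' @param m Non-negative matrix (e.g. from [build_rscu_matrix()]).
#' @param n_axes Number of axes to report (default 4; capped at the rank).
#' @return List of class `coa_result`: `row_coords` (genes x n_axes),
#'   `col_coords` (columns x n_axes, principal coordinates),
#'   `inertia_fraction` (length n_axes), `singular_values`,
#'   `total_inertia`, `n_axes`.
#' @export
correspondence_analysis <- function(m, n_axes = 4L) {
  stopifnot(is.matrix(m), nrow(m) >= 2L, all(m >= 0))
  total <- sum(m)
  if (total <= 0) stop("matrix has no positive entries")
  keep_col <- colSums(m) > 0
  m <- m[, keep_col, drop = FALSE]
  p <- m / total
  r <- rowSums(p); cc <- colSums(p)
  s <- sweep(sweep(p - tcrossprod(r, cc), 1L, sqrt(r), "/"),
             2L, sqrt(cc), "/")
  dec <- svd(s)
  sv <- dec$d
  # numerical rank: discard axes with negligible singular values
  pos <- sv > max(sv[1], 0) * 1e-12 & sv > 1e-12
  k_all <- sum(pos)
  total_inertia <- sum(sv[pos]^2)
  n_axes <- min(n_axes, max(k_all, 1L))
  u <- dec$u[, seq_len(n_axes), drop = FALSE]
  v <- dec$v[, seq_len(n_axes), drop = FALSE]
  sv_used <- sv[seq_len(n_axes)]
  # deterministic orientation: first nonzero loading of each axis positive
  for (k in seq_len(n_axes)) {
    nz <- which(abs(v[, k]) > 1e-10)
    if (length(nz) && v[nz[1], k] < 0) {
      v[, k] <- -v[, k]; u[, k] <- -u[, k]
    }
  }
  row_coords <- sweep(u, 1L, sqrt(r), "/") %*% diag(sv_used, n_axes)
  col_coords <- sweep(v, 1L, sqrt(cc), "/") %*% diag(sv_used, n_axes)
  dimnames(row_coords) <- list(rownames(m),
                               paste0("axis", seq_len(n_axes)))
  dimnames(col_coords) <- list(colnames(m),
                               paste0("axis", seq_len(n_axes)))
  inertia_fraction <- if (total_inertia > 0)
    sv_used^2 / total_inertia else rep(0, n_axes)
  structure(list(row_coords = row_coords, col_coords = col_coords,
                 inertia_fraction = inertia_fraction,
                 singular_values = sv_used,
                 total_inertia = total_inertia, n_axes = n_axes),
            class = "coa_result")
}

#' @export
print.coa_result <- function(x, ...) {
  cat("Correspondence analysis:", nrow(x$row_coords), "genes,",
      x$n_axes, "axes\n")
  cat("  inertia fractions:",
      paste(sprintf("%.2f%%", 100 * x$inertia_fraction), collapse = ", "),
      "\n")
  invisible(x)
}

#' Correlations between CA axes and codon-usage indices
#'
#' Pearson (or Spearman) correlation of each per-gene index with the gene
#' coordinates on the leading CA axes, with two-sided p-values and the
#' usual significance marks (`**` p < 0.01, `*` p < 0.05).
#'
#' @param coords `coa_result` from [correspondence_analysis()], or a
#'   numeric matrix of row coordinates.
#' @param indices Per-gene table from [gene_indices()] with a `gene`
#'   column; rows are matched to coordinate rownames.
#' @param index_cols Index columns to correlate (default GC3s, CAI, ENC,
#'   L_aa and overall GC).
#' @param axes Axis numbers (default 1:2).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame `index`, `axis`, `r`, `p`, `mark`; `r` is NA (flagged
#'   by `mark = "undefined"`) for constant indices.
#' @export
axis_index_correlations <- function(coords, indices,
                                    index_cols = c("gc3s", "cai", "enc",
                                                   "l_aa", "gc_mean"),
                                    axes = 1:2, method = "pearson") {
  rc <- if (inherits(coords, "coa_result")) coords$row_coords else coords
  stopifnot(is.matrix(rc), "gene" %in% names(indices))
  idx <- indices[match(rownames(rc), indices$gene), , drop = FALSE]
  if (anyNA(idx$gene))
    stop("indices missing for genes: ",
         paste(utils::head(setdiff(rownames(rc), indices$gene), 5L),
               collapse = ", "))
  axes <- axes[axes <= ncol(rc)]
  out <- expand.grid(index = index_cols, axis = axes,
                     stringsAsFactors = FALSE)
  res <- t(mapply(function(index, axis) {
    v <- idx[[index]]
    a <- rc[, axis]
    ok <- !is.na(v)
    if (sum(ok) < 3L || stats::sd(v[ok]) == 0 || stats::sd(a[ok]) == 0)
      return(c(NA_real_, NA_real_))
    ct <- stats::cor.test(v[ok], a[ok], method = method, exact = FALSE)
    c(unname(ct$estimate), ct$p.value)
  }, out$index, out$axis))
  out$r <- res[, 1]; out$p <- res[, 2]
  out$mark <- ifelse(is.na(out$p), "undefined",
                     ifelse(out$p < 0.01, "**",
                            ifelse(out$p < 0.05, "*", "")))
  out
}
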