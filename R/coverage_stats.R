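#' Genome-wide coverage summary of a guide catalog
#'
#' Computes the knockout-coverage statistics of a design run: how many genes
#' of the annotated universe can be inactivated (a gene is editable when at
#' least one guide targets it), the per-gene distributions of available
#' guides and of editable codons, and the distribution of the relative
#' positions of the introduced stop codons within their genes.
#'
#' A gene's guide count is the number of distinct spacers targeting it;
#' its editable-codon count is the number of distinct codon indices with at
#' least one guide. By default only unique-spacer guides count.
#'
#' @param catalog A `guide_catalog` from [design_guides()].
#' @param genes The `gene_set` defining the gene universe (denominator).
#' @param unique_only Count unique-spacer guides only (default `TRUE`).
#' @param position_bins Number of equal-width bins on `[0, 1)` for the
#'   relative-position distribution.
#' @return A `coverage_summary` list: `total_genes`, `editable_genes`,
#'   `editable_fraction`, `guides_per_gene` (named vector over all genes),
#'   `guides_per_gene_binned` (bins `0,1,2,3,>=4`),
#'   `editable_codons_per_gene`, `editable_codons_binned`,
#'   `relative_position_counts` (per bin) and `n_editable_codons`.
#' @export
summarize_coverage <- function(catalog, genes, unique_only = TRUE,
                               position_bins = 10L) {
  cat_use <- catalog
  if (unique_only && nrow(cat_use) > 0L) {
    cat_use <- cat_use[cat_use$unique, , drop = FALSE]
  }
  total <- nrow(genes)
  per_gene <- setNames(integer(total), genes$gene_id)
  per_codon <- setNames(integer(total), genes$gene_id)
  if (nrow(cat_use) > 0L) {
    gcount <- tapply(cat_use$spacer, cat_use$gene_id,
                     function(x) length(unique(x)))
    ccount <- tapply(cat_use$codon_index, cat_use$gene_id,
                     function(x) length(unique(x)))
    per_gene[names(gcount)] <- as.integer(gcount)
    per_codon[names(ccount)] <- as.integer(ccount)
  }
  editable <- sum(per_gene >= 1L)

  bin_counts <- function(v) {
    b <- c(sum(v == 0L), sum(v == 1L), sum(v == 2L), sum(v == 3L), sum(v >= 4L))
    setNames(b, c("0", "1", "2", "3", ">=4"))
  }
  # relative positions of distinct editable codons (one mass per gene x codon)
  rel <- numeric(0)
  if (nrow(cat_use) > 0L) {
    key <- !duplicated(cat_use[, c("gene_id", "codon_index")])
    rel <- cat_use$relative_position[key]
  }
  breaks <- seq(0, 1, length.out = position_bins + 1L)
  pos_counts <- if (length(rel)) {
    table(cut(rel, breaks = breaks, right = FALSE, include.lowest = TRUE))
  } else {
    setNames(rep(0L, position_bins),
             levels(cut(numeric(0), breaks = breaks, right = FALSE)))
  }
  structure(list(
    total_genes = total,
    editable_genes = editable,
    editable_fraction = if (total > 0L) editable / total else NA_real_,
    guides_per_gene = per_gene,
    guides_per_gene_binned = bin_counts(per_gene),
    editable_codons_per_gene = per_codon,
    editable_codons_binned = bin_counts(per_codon),
    relative_position_counts = pos_counts,
    n_editable_codons = sum(per_codon),
    unique_only = unique_only
  ), class = "coverage_summary")
}

#' Number of genes with at least k available guides
#'
#' @param catalog A `guide_catalog`.
#' @param genes The gene universe.
#' @param k Minimum number of distinct spacers per gene; `k = 0` returns the
#'   total gene count and `k = 1` the editable-gene count.
#' @param unique_only Count unique-spacer guides only.
#' @return Integer count, non-increasing in `k`.
#' @export
genes_with_at_least <- function(catalog, genes, k, unique_only = TRUE) {
  stopifnot(k >= 0L)
  s <- summarize_coverage(catalog, genes, unique_only = unique_only)
  sum(s$guides_per_gene >= k)
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("coverage_summary: %d/%d genes editable (%.1f%%)%s\n",
              x$editable_genes, x$total_genes, 100 * x$editable_fraction,
              if (x$unique_only) " [unique-spacer guides]" else ""))
  cat("guides per gene:        ",
      paste(names(x$guides_per_gene_binned), x$guides_per_gene_binned,
            sep = ":", collapse = "  "), "\n")
  cat("editable codons per gene:",
      paste(names(x$editable_codons_binned), x$editable_codons_binned,
            sep = ":", collapse = "  "), "\n")
  invisible(x)
}

#' Write a coverage summary as a two-column TSV (statistic, value)
#'
#' @param summary A `coverage_summary`.
#' @param file Output path; `NULL` returns the lines invisibly.
#' @export
write_summary <- function(summary, file = NULL) {
  kv <- c(
    total_genes = summary$total_genes,
    editable_genes = summary$editable_genes,
    editable_fraction = sprintf("%.6f", summary$editable_fraction),
    n_editable_codons = summary$n_editable_codons,
    setNames(as.integer(summary$guides_per_gene_binned),
             paste0("genes_with_guides_", names(summary$guides_per_gene_binned))),
    setNames(as.integer(summary$editable_codons_binned),
             paste0("genes_with_codons_", names(summary$editable_codons_binned))),
    setNames(as.integer(summary$relative_position_counts),
             paste0("relpos_bin_", seq_along(summary$relative_position_counts)))
  )
  lines <- c("statistic\tvalue", paste(names(kv), kv, sep = "\t"))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
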