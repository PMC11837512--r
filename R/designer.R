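#' Designer configuration
#'
#' @param window Deamination window mode, `"canonical"` or `"extended"`
#'   (see [edit_window()]).
#' @param policy Edit-subset policy for [classify_site()].
#' @param max_relative_position Optional filter: drop guides whose premature
#'   stop lands beyond this fraction of the gene (e.g. `0.95`). Default
#'   `NULL` keeps every premature stop, including the penultimate codon.
#' @param circular Scan PAMs across the contig origin (circular chromosome).
#' @param unique_only Coverage statistics count unique-spacer guides only.
#' @return A `design_config` list.
#' @export
design_config <- function(window = c("canonical", "extended"),
                          policy = c("any-subset", "all-window-cs"),
                          max_relative_position = NULL,
                          circular = FALSE,
                          unique_only = TRUE) {
  window <- match.arg(window)
  policy <- match.arg(policy)
  structure(list(window = window, policy = policy,
                 max_relative_position = max_relative_position,
                 circular = circular, unique_only = unique_only),
            class = "design_config")
}

#' Genome-wide knockout guide design
#'
#' Scans every contig for protospacer+NGG sites, maps window cytosines onto
#' the reading frames of the validated genes, classifies each (site, gene)
#' pair with [classify_site()]'s engine, flags spacer uniqueness, and
#' returns the catalog of guides that introduce a premature stop codon.
#' Output is deterministic for fixed inputs: rows are sorted by contig,
#' protospacer start, strand and gene.
#'
#' @param genome `DNAStringSet` from [load_genome()].
#' @param genes `gene_set` from [load_annotation()].
#' @param config A [design_config()].
#' @param verbose Log per-stage counts to standard error (used by the CLI).
#' @return A `guide_catalog` data.frame; one row per (site, gene) pair with
#'   columns `gene_id`, `contig`, `strand`, `spacer_start`, `spacer_end`,
#'   `spacer`, `pam`, `edit_strand`, `codon_index`, `original_codon`,
#'   `edited_codon`, `stop_codon`, `edit_offsets`, `edit_positions`,
#'   `n_collateral`, `relative_position`, `unique`. Attribute `provenance`
#'   records the config and an MD5 checksum of the genome.
#' @export
design_guides <- function(genome, genes, config = design_config(),
                          verbose = FALSE) {
  window <- edit_window(config$window)
  sites <- find_pam_sites(genome, circular = config$circular)
  log_msg <- function(...) if (verbose) message(sprintf(...))
  log_msg("scanned %d contig(s): %d protospacer sites", length(genome), nrow(sites))
  catalog <- empty_catalog()

  design_genes <- genes[genes$validated, , drop = FALSE]
  if (nrow(sites) > 0L && nrow(design_genes) > 0L) {
    wc <- window_c_table(sites, window)
    pairs <- candidate_pairs(sites, wc, design_genes)
    log_msg("%d window cytosines in CDS; %d candidate (site, gene) pairs",
            nrow(pairs), length(unique(paste(pairs$site, pairs$gene))))
    catalog <- classify_pairs(sites, design_genes, genome, pairs, config$policy)
  }

  if (nrow(catalog) > 0L) {
    counts <- table(sites$spacer)
    catalog$unique <- as.integer(counts[catalog$spacer]) == 1L
    if (!is.null(config$max_relative_position)) {
      catalog <- catalog[catalog$relative_position <= config$max_relative_position, , drop = FALSE]
    }
    catalog <- catalog[!duplicated(catalog[, c("contig", "strand", "spacer_start", "gene_id")]), , drop = FALSE]
    catalog <- catalog[order(catalog$contig, catalog$spacer_start,
                             catalog$strand, catalog$gene_id), , drop = FALSE]
    rownames(catalog) <- NULL
  }
  log_msg("%d stop-introducing guides (%d unique-spacer)",
          nrow(catalog), sum(catalog$unique))
  structure(catalog,
            provenance = list(config = unclass(config),
                              genome_md5 = genome_checksum(genome),
                              n_sites = nrow(sites),
                              n_genes = nrow(genes),
                              n_design_genes = nrow(design_genes)),
            class = c("guide_catalog", "data.frame"))
}

empty_catalog <- function() {
  data.frame(gene_id = character(0), contig = character(0), strand = character(0),
             spacer_start = integer(0), spacer_end = integer(0),
             spacer = character(0), pam = character(0),
             edit_strand = character(0), codon_index = integer(0),
             original_codon = character(0), edited_codon = character(0),
             stop_codon = character(0), edit_offsets = character(0),
             edit_positions = character(0), n_collateral = integer(0),
             relative_position = double(0), unique = logical(0),
             stringsAsFactors = FALSE)
}

# overlap window cytosines with CDS intervals -> rows (wc row, gene index)
candidate_pairs <- function(sites, wc, genes) {
  if (nrow(wc) == 0L) {
    return(data.frame(site = integer(0), gene = integer(0),
                      position = integer(0), genome_coord = integer(0)))
  }
  gene_idx <- rep(seq_len(nrow(genes)), lengths(genes$cds_starts))
  cds_gr <- GenomicRanges::GRanges(
    seqnames = genes$contig[gene_idx],
    ranges = IRanges::IRanges(start = unlist(genes$cds_starts) + 1L,
                              end = unlist(genes$cds_ends)))
  c_gr <- GenomicRanges::GRanges(
    seqnames = sites$contig[wc$site],
    ranges = IRanges::IRanges(start = wc$genome_coord + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(c_gr, cds_gr)
  data.frame(site = wc$site[S4Vectors::queryHits(hits)],
             gene = gene_idx[S4Vectors::subjectHits(hits)],
             position = wc$position[S4Vectors::queryHits(hits)],
             genome_coord = wc$genome_coord[S4Vectors::queryHits(hits)])
}

classify_pairs <- function(sites, genes, genome, pairs, policy) {
  if (nrow(pairs) == 0L) return(empty_catalog())
  cds_cache <- vapply(seq_len(nrow(genes)), function(i) {
    coding_sequence(genes[i, ], genome)
  }, character(1))
  fstop <- vapply(cds_cache, first_stop_index, integer(1))

  # vectorized pre-filter: a pair can only qualify if one of its window
  # cytosines sits in a pre-stop codon (coding CGA/CAG/CAA, template TGG)
  # upstream of the native stop; everything else is dismissed wholesale
  pairs$cds_pos <- NA_integer_
  for (gi in unique(pairs$gene)) {
    sel <- pairs$gene == gi
    pairs$cds_pos[sel] <- genome_to_cds(genes[gi, ], pairs$genome_coord[sel])
  }
  ci <- pairs$cds_pos %/% 3L
  codon <- substring(cds_cache[pairs$gene], 3L * ci + 1L, 3L * ci + 3L)
  coding <- sites$strand[pairs$site] == genes$strand[pairs$gene]
  hot <- ifelse(coding, codon %in% c("CGA", "CAG", "CAA"), codon == "TGG") &
    ci < fstop[pairs$gene]
  key <- paste(pairs$site, pairs$gene)
  groups <- split(seq_len(nrow(pairs)), key)
  groups <- groups[unique(key[hot])]
  rows <- lapply(groups, function(ii) {
    si <- pairs$site[ii[1L]]
    gi <- pairs$gene[ii[1L]]
    gene <- genes[gi, ]
    wc <- data.frame(position = pairs$position[ii],
                     genome_coord = pairs$genome_coord[ii],
                     cds_pos = pairs$cds_pos[ii])
    wc <- wc[order(wc$position), , drop = FALSE]
    sg <- classify_core(sites[si, ], gene, cds_cache[gi], wc, policy)
    if (is.null(sg)) return(NULL)
    guide_row(sg)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty_catalog())
  do.call(rbind, rows)
}

guide_row <- function(sg) {
  data.frame(gene_id = sg$gene_id, contig = sg$contig, strand = sg$strand,
             spacer_start = sg$spacer_start, spacer_end = sg$spacer_end,
             spacer = sg$spacer, pam = sg$pam,
             edit_strand = sg$edit_strand,
             codon_index = sg$codon_index,
             original_codon = sg$original_codon,
             edited_codon = sg$edited_codon,
             stop_codon = sg$stop_codon,
             edit_offsets = paste(sg$edit_offsets, collapse = ","),
             edit_positions = paste(sg$edit_positions, collapse = ","),
             n_collateral = nrow(sg$collateral_edits),
             relative_position = sg$relative_position,
             unique = NA,
             stringsAsFactors = FALSE)
}

genome_checksum <- function(genome) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(names(genome), as.character(genome), sep = "\t"), f)
  unname(tools::md5sum(f))
}

#' Flag spacer uniqueness in a guide catalog
#'
#' A guide is unique when its exact 20-nt spacer immediately 5' of an NGG
#' PAM occurs exactly once in the genome, counting both strands. Non-unique
#' guides are retained but flagged.
#'
#' @param catalog A `guide_catalog`.
#' @param genome `DNAStringSet` the catalog was designed against.
#' @param circular Match the scan topology used at design time.
#' @return The catalog with its `unique` column recomputed.
#' @export
spacer_uniqueness <- function(catalog, genome, circular = FALSE) {
  sites <- find_pam_sites(genome, circular = circular)
  counts <- table(sites$spacer)
  catalog$unique <- as.integer(counts[catalog$spacer]) == 1L
  catalog
}

#' Write a guide catalog as TSV
#'
#' Deterministic tab-separated export (fixed column order, fixed numeric
#' formatting); two identical designs produce byte-identical files.
#'
#' @param catalog A `guide_catalog`.
#' @param file Output path; `NULL` returns the lines invisibly.
#' @export
write_catalog <- function(catalog, file = NULL) {
  df <- as.data.frame(catalog)
  df$relative_position <- sprintf("%.6f", df$relative_position)
  df$unique <- ifelse(df$unique, "1", "0")
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(df, sep = "\t")))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Read a guide catalog written by [write_catalog()]
#' @param file Path to the TSV.
#' @return A `guide_catalog` data.frame.
#' @export
read_catalog <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE,
                          colClasses = c(edit_offsets = "character",
                                         edit_positions = "character"))
  df$unique <- df$unique == 1L
  class(df) <- c("guide_catalog", "data.frame")
  df
}

#' @export
print.guide_catalog <- function(x, ...) {
  cat(sprintf("guide_catalog: %d guides (%d unique-spacer), %d gene(s)\n",
              nrow(x), sum(x$unique), length(unique(x$gene_id))))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}
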