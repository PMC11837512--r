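#' Load a genome from FASTA
#'
#' Reads a (possibly multi-contig) FASTA file or literal FASTA text into a
#' [Biostrings::DNAStringSet]. Sequences are uppercased and RNA `U` is mapped
#' to `T`. Characters outside `A,C,G,T,N` (IUPAC ambiguity codes included)
#' are an error in `strict` mode or masked to `N` otherwise.
#'
#' @param fasta Path to a FASTA file, or a character vector of FASTA text
#'   (detected by a leading `>`).
#' @param on_invalid `"error"` (default) rejects characters outside
#'   `A,C,G,T,N`; `"mask"` replaces them with `N`.
#' @return A named `DNAStringSet`; names are the contig ids (first
#'   whitespace-delimited token of each FASTA header).
#' @examples
#' g <- load_genome(c(">c1", "acgtn"))
#' as.character(g[["c1"]])
#' @export
load_genome <- function(fasta, on_invalid = c("error", "mask")) {
  on_invalid <- match.arg(on_invalid)
  path <- fasta
  if (length(fasta) > 1L || grepl("^>", fasta[1L])) {
    path <- tempfile(fileext = ".fa")
    on.exit(unlink(path))
    writeLines(fasta, path)
  }
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("FASTA contains no records")
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids)) {
    stop("duplicate contig ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(raw))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    if (on_invalid == "error") {
      stop("contig(s) ", paste(ids[bad], collapse = ", "),
           " contain characters outside A,C,G,T,N (use on_invalid = \"mask\")")
    }
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  if (any(nchar(seqs) == 0L)) stop("empty sequence for contig ", ids[nchar(seqs) == 0L][1L])
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write a genome back to FASTA text
#'
#' @param genome A named `DNAStringSet` from [load_genome()].
#' @param file Optional path; if `NULL` the FASTA text is returned invisibly
#'   as a character vector.
#' @param width Line width for sequence wrapping.
#' @export
write_genome <- function(genome, file = NULL, width = 70L) {
  lines <- unlist(lapply(names(genome), function(id) {
    s <- as.character(genome[[id]])
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  invisible(lines)
}

contig_string <- function(genome, contig) {
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  as.character(genome[[contig]])
}

#' Load gene models from GFF3
#'
#' Extracts CDS features from a GFF3 file and groups them into one gene model
#' per gene (grouping key: `Parent` attribute if present, else `ID`, else
#' `locus_tag`). GFF3 1-based inclusive coordinates are converted to the
#' package's 0-based half-open convention. Multi-segment CDS are kept as
#' ordered interval lists and joined in translation order by
#' [coding_sequence()]. Genes whose total CDS length is not a multiple of 3,
#' or whose CDS contains `N`, are retained in the gene universe but flagged
#' `validated = FALSE` and excluded from guide design.
#'
#' @param gff Path to a GFF3 file or character vector of GFF3 text.
#' @param genome `DNAStringSet` from [load_genome()]; used for bounds and
#'   sequence validation.
#' @return A `gene_set`: a data.frame with one row per gene and columns
#'   `gene_id`, `contig`, `strand`, `cds_starts`/`cds_ends` (list columns of
#'   0-based half-open interval bounds, sorted in genomic order),
#'   `cds_len`, `codon_count` and `validated`.
#' @export
load_annotation <- function(gff, genome) {
  path <- gff
  if (length(gff) > 1L || grepl("^##gff-version", gff[1L]) || grepl("\t", gff[1L])) {
    path <- tempfile(fileext = ".gff3")
    on.exit(unlink(path))
    writeLines(gff, path)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[!is.na(gr$type) & gr$type == "CDS"]
  if (length(cds) == 0L) {
    return(empty_gene_set())
  }
  pcol <- S4Vectors::mcols(cds)$Parent
  if (is.null(pcol)) {
    parent <- rep(NA_character_, length(cds))
  } else if (methods::is(pcol, "List") || is.list(pcol)) {
    parent <- vapply(as.list(pcol), function(x) {
      if (length(x)) as.character(x[[1L]]) else NA_character_
    }, character(1))
  } else {
    parent <- as.character(pcol)
  }
  parent[!is.na(parent) & parent == ""] <- NA_character_
  id <- S4Vectors::mcols(cds)$ID
  if (is.null(id)) id <- rep(NA_character_, length(cds))
  locus <- S4Vectors::mcols(cds)$locus_tag
  if (is.null(locus)) locus <- rep(NA_character_, length(cds))
  key <- ifelse(!is.na(parent), parent, ifelse(!is.na(id), id, locus))
  if (anyNA(key)) stop("CDS feature without Parent/ID/locus_tag attribute")
  key <- sub("^gene-", "", key)

  contig <- as.character(GenomicRanges::seqnames(cds))
  strand <- as.character(GenomicRanges::strand(cds))
  if (any(!strand %in% c("+", "-"))) stop("CDS with undefined strand")
  start0 <- GenomicRanges::start(cds) - 1L  # to 0-based
  end0 <- GenomicRanges::end(cds)           # half-open

  unknown <- setdiff(unique(contig), names(genome))
  if (length(unknown)) stop("CDS references unknown contig(s): ", paste(unknown, collapse = ", "))
  clen <- setNames(Biostrings::width(genome), names(genome))
  if (any(start0 < 0L | end0 > clen[contig])) stop("CDS interval out of contig bounds")

  ord <- order(key, contig, start0)
  key <- key[ord]; contig <- contig[ord]; strand <- strand[ord]
  start0 <- start0[ord]; end0 <- end0[ord]
  idx <- split(seq_along(key), key)

  rows <- lapply(names(idx), function(g) {
    i <- idx[[g]]
    if (length(unique(contig[i])) > 1L || length(unique(strand[i])) > 1L) {
      stop("gene ", g, " has CDS on multiple contigs/strands")
    }
    s <- start0[i]; e <- end0[i]
    if (length(i) > 1L && any(s[-1L] < e[-length(e)])) {
      stop("gene ", g, " has overlapping CDS intervals")
    }
    len <- sum(e - s)
    list(gene_id = g, contig = contig[i][1L], strand = strand[i][1L],
         cds_starts = s, cds_ends = e, cds_len = len,
         codon_count = len %/% 3L)
  })
  genes <- data.frame(
    gene_id = vapply(rows, `[[`, character(1), "gene_id"),
    contig = vapply(rows, `[[`, character(1), "contig"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    cds_len = vapply(rows, `[[`, integer(1), "cds_len"),
    codon_count = vapply(rows, `[[`, integer(1), "codon_count"),
    stringsAsFactors = FALSE
  )
  genes$cds_starts <- lapply(rows, `[[`, "cds_starts")
  genes$cds_ends <- lapply(rows, `[[`, "cds_ends")
  genes$validated <- genes$cds_len %% 3L == 0L & genes$cds_len > 0L
  # N anywhere in the CDS disqualifies the gene from design
  has_n <- vapply(seq_len(nrow(genes)), function(i) {
    grepl("N", coding_sequence(genes[i, ], genome), fixed = TRUE)
  }, logical(1))
  genes$validated <- genes$validated & !has_n
  genes <- genes[order(genes$contig, vapply(genes$cds_starts, min, double(1)), genes$gene_id), ]
  rownames(genes) <- NULL
  class(genes) <- c("gene_set", "data.frame")
  genes
}

empty_gene_set <- function() {
  genes <- data.frame(gene_id = character(0), contig = character(0),
                      strand = character(0), cds_len = integer(0),
                      codon_count = integer(0), stringsAsFactors = FALSE)
  genes$cds_starts <- list()
  genes$cds_ends <- list()
  genes$validated <- logical(0)
  class(genes) <- c("gene_set", "data.frame")
  genes
}

#' Extract the coding sequence of a gene
#'
#' Concatenates the CDS intervals in genomic order and reverse-complements
#' the result for minus-strand genes, yielding the mRNA-sense (coding strand)
#' sequence whose translation starts at position 0.
#'
#' @param gene One row of a `gene_set` (or a `gene_set` of length one).
#' @param genome `DNAStringSet` from [load_genome()].
#' @return A character string of length `cds_len`.
#' @export
coding_sequence <- function(gene, genome) {
  if (nrow(gene) != 1L) stop("coding_sequence() expects a single gene row")
  s <- contig_string(genome, gene$contig)
  pieces <- substring(s, gene$cds_starts[[1L]] + 1L, gene$cds_ends[[1L]])
  cds <- paste(pieces, collapse = "")
  if (gene$strand == "-") cds <- revcomp_chr(cds)
  cds
}

#' Write gene models back to GFF3 text
#'
#' Inverse of [load_annotation()] for round-trip checks: emits one `gene`
#' line and one `CDS` line per interval, converting back to 1-based
#' inclusive coordinates.
#'
#' @param genes A `gene_set`.
#' @param genome `DNAStringSet` (for `##sequence-region` headers).
#' @param file Optional output path.
#' @export
write_annotation <- function(genes, genome, file = NULL) {
  hdr <- c("##gff-version 3",
           paste("##sequence-region", names(genome), 1L, Biostrings::width(genome)))
  body <- unlist(lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    s <- g$cds_starts[[1L]]; e <- g$cds_ends[[1L]]
    gene_line <- paste(g$contig, "bestop", "gene", min(s) + 1L, max(e), ".",
                       g$strand, ".", paste0("ID=", g$gene_id), sep = "\t")
    cds_lines <- paste(g$contig, "bestop", "CDS", s + 1L, e, ".", g$strand, "0",
                       paste0("ID=cds-", g$gene_id, ";Parent=", g$gene_id), sep = "\t")
    c(gene_line, cds_lines)
  }))
  lines <- c(hdr, body)
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
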