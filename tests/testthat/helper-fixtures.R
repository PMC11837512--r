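# shared helpers for the test suite

# canonical identity of a guide / oracle row
guide_key <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  paste(df$contig, df$strand, df$spacer_start, df$gene_id)
}

# memoized small study-style fixture shared across test files
.fix_cache <- new.env(parent = emptyenv())
shared_fixture <- function(seed = 101, n_genes = 6, ...) {
  key <- paste0("s", seed, "_", n_genes)
  if (is.null(.fix_cache[[key]])) {
    .fix_cache[[key]] <- make_genome(n_genes = n_genes, seed = seed,
                                     codon_range = c(80L, 120L), ...)
  }
  .fix_cache[[key]]
}

# hand-built single-interval gene set (0-based half-open coordinates)
hand_genes <- function(gene_id, contig, strand, start, end) {
  g <- data.frame(gene_id = gene_id, contig = contig, strand = strand,
                  cds_len = end - start,
                  codon_count = (end - start) %/% 3L,
                  stringsAsFactors = FALSE)
  g$cds_starts <- as.list(as.integer(start))
  g$cds_ends <- as.list(as.integer(end))
  g$validated <- g$cds_len %% 3L == 0L
  class(g) <- c("gene_set", "data.frame")
  g
}

hand_genome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

# independent 23-mer scan used as an oracle for find_pam_sites(): checks every
# position of both strands with plain substring tests
scan_23mers <- function(s) {
  L <- nchar(s)
  out <- list()
  for (i in seq_len(max(L - 22L, 0L))) {
    w <- substr(s, i, i + 22L)
    if (grepl("N", w, fixed = TRUE)) next
    if (substr(w, 22L, 23L) == "GG") {
      out[[length(out) + 1L]] <- data.frame(
        strand = "+", spacer_start = i - 1L,
        spacer = substr(w, 1L, 20L), stringsAsFactors = FALSE)
    }
    if (substr(w, 1L, 2L) == "CC") {
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(w)))
      out[[length(out) + 1L]] <- data.frame(
        strand = "-", spacer_start = i + 2L,
        spacer = substr(rc, 1L, 20L), stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(strand = character(0), spacer_start = integer(0),
               spacer = character(0), stringsAsFactors = FALSE)
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}
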