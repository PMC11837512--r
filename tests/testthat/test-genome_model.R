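test_that("FASTA loading normalizes case, maps U to T, and validates the alphabet", {
  g <- load_genome(c(">c1 some description", "acgun"))
  expect_equal(names(g), "c1")
  expect_equal(as.character(g[["c1"]]), "ACGTN")

  g2 <- load_genome(c(">a", "ACG", "TTT", ">b", "GGGG"))
  expect_equal(as.character(g2[["a"]]), "ACGTTT")
  expect_equal(length(g2), 2L)

  expect_error(load_genome(c(">c1", "ACGT", ">c1", "TTTT")), "duplicate contig")
  expect_error(load_genome(c(">c1", "ACRT")), "outside")
  expect_equal(as.character(load_genome(c(">c1", "ACRT"), on_invalid = "mask")[[1]]),
               "ACNT")
})

test_that("GFF3 coordinates convert to 0-based half-open and strands are honored", {
  genome <- load_genome(c(">c1", "ATGAAACGATTTTTTTTTTT"))
  gff <- c("##gff-version 3",
           "c1\t.\tCDS\t1\t9\t.\t+\t0\tID=g1")
  genes <- load_annotation(gff, genome)
  expect_equal(nrow(genes), 1L)
  expect_equal(genes$cds_starts[[1]], 0L)
  expect_equal(genes$cds_ends[[1]], 9L)
  expect_equal(genes$codon_count, 3L)
  expect_true(genes$validated)
  expect_equal(coding_sequence(genes[1, ], genome), "ATGAAACGA")

  # reverse strand: CDS 4..12 (1-based) must read as revcomp(genome[3:12))
  gff_m <- c("##gff-version 3", "c1\t.\tCDS\t4\t12\t.\t-\t0\tID=gm")
  gm <- load_annotation(gff_m, genome)
  s <- as.character(genome[["c1"]])
  expect_equal(coding_sequence(gm[1, ], genome),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(s, 4, 12)))))
})

test_that("multi-interval CDS are joined in translation order", {
  genome <- load_genome(c(">c1", "AAATTTGGGCCC"))
  gff <- c("##gff-version 3",
           "c1\t.\tCDS\t1\t3\t.\t+\t0\tID=cds-gp;Parent=gp",
           "c1\t.\tCDS\t7\t9\t.\t+\t0\tID=cds-gp;Parent=gp",
           "c1\t.\tCDS\t1\t3\t.\t-\t0\tID=cds-gm;Parent=gm",
           "c1\t.\tCDS\t7\t9\t.\t-\t0\tID=cds-gm;Parent=gm")
  genes <- load_annotation(gff, genome)
  gp <- genes[genes$gene_id == "gp", ]
  gm <- genes[genes$gene_id == "gm", ]
  expect_equal(coding_sequence(gp, genome), "AAAGGG")
  # minus strand: genomic-order concatenation, then reverse complement
  expect_equal(coding_sequence(gm, genome), "CCCTTT")
})

test_that("invalid annotations are rejected and odd CDS lengths are flagged, not dropped", {
  genome <- load_genome(c(">c1", "ATGAAACGATTTTTTTTTTT"))
  expect_error(load_annotation(c("##gff-version 3", "cX\t.\tCDS\t1\t9\t.\t+\t0\tID=g1"),
                               genome), "unknown contig")
  expect_error(load_annotation(c("##gff-version 3", "c1\t.\tCDS\t1\t99\t.\t+\t0\tID=g1"),
                               genome), "out of contig bounds")
  genes <- load_annotation(c("##gff-version 3", "c1\t.\tCDS\t1\t8\t.\t+\t0\tID=g1"),
                           genome)
  expect_equal(nrow(genes), 1L)       # still in the gene universe
  expect_false(genes$validated)       # but excluded from design
})

test_that("fixture genomes round-trip through FASTA/GFF3 with identical models", {
  fix <- make_genome(n_genes = 4, seed = 5, n_contigs = 3,
                     codon_range = c(60L, 80L), decoys = FALSE)
  genome <- load_genome(fix$fasta)
  expect_equal(length(genome), 3L)
  expect_equal(as.character(genome), as.character(fix$genome))

  genes <- load_annotation(fix$gff3, genome)
  expect_setequal(genes$gene_id, fix$genes$gene_id)
  for (id in genes$gene_id) {
    a <- genes[genes$gene_id == id, ]
    b <- fix$genes[fix$genes$gene_id == id, ]
    expect_equal(a$strand, b$strand)
    expect_equal(a$cds_starts[[1]], b$cds_starts[[1]])
    expect_equal(a$cds_ends[[1]], b$cds_ends[[1]])
    cds <- coding_sequence(a, genome)
    expect_equal(nchar(cds), 3L * a$codon_count)
    # fixture CDSs are stop-free before the native stop
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1L)))
  }

  # second round trip: re-emitted text reloads to the same models
  genes2 <- load_annotation(write_annotation(genes, genome), genome)
  expect_equal(genes2$gene_id, genes$gene_id)
  expect_equal(genes2$cds_starts, genes$cds_starts)
  expect_equal(genes2$cds_ends, genes$cds_ends)
})
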