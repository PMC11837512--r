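test_that("fixture generation is a pure function of its seed", {
  a <- make_genome(n_genes = 4, seed = 3, codon_range = c(60L, 90L))
  b <- make_genome(n_genes = 4, seed = 3, codon_range = c(60L, 90L))
  expect_identical(a$fasta, b$fasta)
  expect_identical(a$gff3, b$gff3)
  expect_identical(a$manifest$planted, b$manifest$planted)
  c <- make_genome(n_genes = 4, seed = 4, codon_range = c(60L, 90L))
  expect_false(identical(a$fasta, c$fasta))
})

test_that("manifest entries are verifiable against the emitted sequences", {
  fix <- shared_fixture(seed = 101, n_genes = 6)
  for (i in seq_len(nrow(fix$manifest$planted))) {
    p <- fix$manifest$planted[i, ]
    gene <- fix$genes[fix$genes$gene_id == p$gene_id, ]
    cds <- coding_sequence(gene, fix$genome)
    expect_equal(substr(cds, 3 * p$codon_index + 1, 3 * p$codon_index + 3),
                 p$codon)
  }
  for (i in seq_len(nrow(fix$manifest$decoys))) {
    d <- fix$manifest$decoys[i, ]
    gene <- fix$genes[fix$genes$gene_id == d$gene_id, ]
    cds <- coding_sequence(gene, fix$genome)
    expect_equal(substr(cds, 3 * d$codon_index + 1, 3 * d$codon_index + 3),
                 d$codon)
  }
})

test_that("infeasible plant specifications are rejected", {
  expect_error(make_genome(2, 1, plant_spec = data.frame(gene = 1, codon = "CGA",
                                                         window_pos = -12)),
               "window position")
  expect_error(make_genome(2, 1, plant_spec = data.frame(gene = 1, codon = "AAA",
                                                         window_pos = -17)),
               "codon")
  expect_error(make_genome(2, 1, plant_spec = data.frame(gene = 5, codon = "CGA",
                                                         window_pos = -17)),
               "gene number")
})

test_that("an empty genome yields empty models and an empty manifest", {
  fix <- make_genome(n_genes = 0, seed = 8)
  expect_equal(nrow(fix$genes), 0L)
  expect_equal(nrow(fix$manifest$planted), 0L)
  expect_equal(nrow(fix$manifest$expected_guides$canonical), 0L)
  expect_equal(length(fix$genome), 1L)  # one CDS-free contig
})

test_that("a planted TGG exposes all three stop outcomes across edit subsets", {
  fix <- make_genome(n_genes = 1, seed = 13,
                     plant_spec = data.frame(gene = 1, codon = "TGG",
                                             window_pos = -17, codon_index = 12),
                     codon_range = c(50L, 50L), decoys = FALSE)
  detail <- brute_force_design(fix$genome, fix$genes, window = "canonical",
                               policy = "any-subset", all_subsets = TRUE)
  planted <- detail[detail$stop_codon_index == 12L, ]
  expect_setequal(unique(planted$stop_codon), c("TGA", "TAG", "TAA"))
})

test_that("decoy pre-stop codons are never targeted", {
  fix <- shared_fixture(seed = 101, n_genes = 6)
  expect_gt(nrow(fix$manifest$decoys), 0L)
  catalog <- design_guides(fix$genome, fix$genes, design_config("extended"))
  got <- paste(catalog$gene_id, catalog$codon_index)
  bad <- paste(fix$manifest$decoys$gene_id, fix$manifest$decoys$codon_index)
  expect_false(any(bad %in% got))
})

test_that("a stop-free gene with no NGG in reach yields nothing from the oracle", {
  genome <- hand_genome(c(c1 = paste0("ATGAAATAA", strrep("A", 40))))
  genes <- hand_genes("g1", "c1", "+", 0L, 9L)
  res <- brute_force_design(genome, genes, "extended", "any-subset")
  expect_equal(nrow(res), 0L)
})

test_that("requested plant geometry is realized in the designed guides", {
  fix <- make_genome(n_genes = 3, seed = 17,
                     plant_spec = data.frame(gene = 1:3,
                                             codon = c("CGA", "CAG", "CAA"),
                                             window_pos = c(-20, -17, -16)),
                     codon_range = c(80L, 100L), decoys = FALSE)
  catalog <- design_guides(fix$genome, fix$genes, design_config("canonical"))
  for (i in 1:3) {
    p <- fix$manifest$planted[i, ]
    rows <- catalog[catalog$gene_id == p$gene_id &
                      catalog$codon_index == p$codon_index, ]
    expect_gte(nrow(rows), 1L)
    # at least one guide edits the planted C at the requested window position
    expect_true(any(vapply(strsplit(rows$edit_positions, ","), function(x) {
      p$window_pos %in% as.integer(x)
    }, logical(1))))
  }
})

test_that("extended-only plants are invisible to the canonical window", {
  fix <- make_genome(n_genes = 2, seed = 19,
                     plant_spec = data.frame(gene = 1:2, codon = "CGA",
                                             window_pos = c(-14, -17)),
                     codon_range = c(80L, 100L), decoys = FALSE)
  can <- design_guides(fix$genome, fix$genes, design_config("canonical"))
  ext <- design_guides(fix$genome, fix$genes, design_config("extended"))
  p <- fix$manifest$planted
  expect_false(paste(p$gene_id[1], p$codon_index[1]) %in%
                 paste(can$gene_id, can$codon_index))
  expect_true(all(paste(p$gene_id, p$codon_index) %in%
                    paste(ext$gene_id, ext$codon_index)))
})
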