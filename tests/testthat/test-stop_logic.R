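test_that("codon edits follow the C:G -> T:A substitution model", {
  expect_equal(apply_ct_edits("CGA", 0, "coding"), "TGA")
  expect_equal(apply_ct_edits("CAG", 0, "coding"), "TAG")
  expect_equal(apply_ct_edits("CAA", 0, "coding"), "TAA")
  expect_equal(apply_ct_edits("TGG", 1, "template"), "TAG")
  expect_equal(apply_ct_edits("TGG", 2, "template"), "TGA")
  expect_equal(apply_ct_edits("TGG", c(1, 2), "template"), "TAA")
  expect_equal(apply_ct_edits("AAA", integer(0), "coding"), "AAA")
  expect_error(apply_ct_edits("AGA", 0, "coding"), "not C")
  expect_error(apply_ct_edits("CAA", 1, "template"), "not G")
})

test_that("the pre-stop codon closure is exactly {CGA, CAG, CAA, TGG}", {
  tab <- pre_stop_codons()
  expect_setequal(unique(tab$codon), c("CGA", "CAG", "CAA", "TGG"))
  cga <- tab[tab$codon == "CGA", ]
  expect_equal(nrow(cga), 1L)
  expect_equal(cga$edit_strand, "coding")
  expect_equal(cga$offsets, "0")
  expect_equal(cga$stop, "TGA")
  tgg <- tab[tab$codon == "TGG", ]
  expect_equal(nrow(tgg), 3L)
  expect_true(all(tgg$edit_strand == "template"))
  expect_setequal(tgg$stop, c("TGA", "TAG", "TAA"))
  # coding-strand entries are single-C edits at offset 0
  coding <- tab[tab$edit_strand == "coding", ]
  expect_setequal(coding$codon, c("CGA", "CAG", "CAA"))
  expect_true(all(coding$offsets == "0"))
})

test_that("template-strand convertibility equals coding-strand convertibility of the reverse complement", {
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  tab <- pre_stop_codons()
  template_ok <- unique(tab$codon[tab$edit_strand == "template"])
  bases <- c("A", "C", "G", "T")
  for (codon in apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")) {
    if (codon %in% c("TAA", "TAG", "TGA")) next
    # independent check: edit Cs of revcomp(codon) as coding C->T, read the
    # result back on the original strand, and ask whether it is a stop
    x <- rc(codon)
    cpos <- which(strsplit(x, "")[[1]] == "C")
    convertible <- FALSE
    if (length(cpos)) {
      for (m in seq_len(2L^length(cpos) - 1L)) {
        sel <- cpos[as.logical(bitwAnd(m, 2L^(seq_along(cpos) - 1L)))]
        v <- strsplit(x, "")[[1]]
        v[sel] <- "T"
        if (rc(paste(v, collapse = "")) %in% c("TAA", "TAG", "TGA")) convertible <- TRUE
      }
    }
    expect_equal(codon %in% template_ok, convertible, info = codon)
  }
})

test_that("classify_site recovers a planted target and reports its geometry", {
  fix <- make_genome(n_genes = 1, seed = 21,
                     plant_spec = data.frame(gene = 1, codon = "CGA",
                                             window_pos = -17, codon_index = 10),
                     codon_range = c(40L, 40L), decoys = FALSE)
  gene <- fix$genes[1, ]
  sites <- find_pam_sites(fix$genome)
  hits <- list()
  for (i in seq_len(nrow(sites))) {
    sg <- classify_site(sites[i, ], gene, fix$genome)
    if (!is.null(sg)) hits[[length(hits) + 1L]] <- sg
  }
  expect_equal(length(hits), 1L)
  sg <- hits[[1]]
  expect_equal(sg$gene_id, gene$gene_id)
  expect_equal(sg$stop_codon, "TGA")
  expect_equal(sg$stop_codon_index, 10L)
  expect_equal(sg$original_codon, "CGA")
  expect_equal(sg$edit_strand, "coding")
  expect_equal(sg$edit_positions, -17L)
  expect_equal(sg$relative_position, 10 / gene$codon_count)
})

test_that("sites without pre-stop potential or outside the CDS classify as NULL", {
  # gene of safe codons only; one NGG site inside it
  genome <- hand_genome(c(c1 = paste0("ATG", strrep("TTC", 10), "GGG",
                                      strrep("TTC", 5), "TAA", strrep("A", 30))))
  genes <- hand_genes("g1", "c1", "+", 0L, 3L + 30L + 3L + 15L + 3L)
  sites <- find_pam_sites(genome)
  for (i in seq_len(nrow(sites))) {
    expect_null(classify_site(sites[i, ], genes[1, ], genome))
  }
})

test_that("a site whose window only covers the native stop yields no guide", {
  # gene ends in TGG-like context? native stop TGA; a downstream NGG puts the
  # native stop codon inside the editing window -> no premature stop
  cds <- paste0("ATG", strrep("ATC", 8), "TGA")
  genome <- hand_genome(c(c1 = paste0(strrep("T", 10), cds, "TTTTTTTTTTTTTTGGTTT")))
  genes <- hand_genes("g1", "c1", "+", 10L, 10L + nchar(cds))
  sites <- find_pam_sites(genome)
  for (i in seq_len(nrow(sites))) {
    expect_null(classify_site(sites[i, ], genes[1, ], genome))
  }
})

test_that("both edit policies qualify the same (site, gene) pairs", {
  # with C->T chemistry a created stop contains no further editable C whose
  # co-edit could destroy it, so the policies agree on qualification
  for (seed in 1:3) {
    fix <- shared_fixture(seed = 200 + seed, n_genes = 5)
    a <- design_guides(fix$genome, fix$genes,
                       design_config("extended", "any-subset"))
    b <- design_guides(fix$genome, fix$genes,
                       design_config("extended", "all-window-cs"))
    expect_setequal(guide_key(a), guide_key(b))
  }
})
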