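PRE_STOP_SET <- c("CGA", "CAG", "CAA", "TGG")

# codons allowed as background filler: no stops (keeps CDSs stop-free) and no
# pre-stop codons (guarantees planted targets are the only possible guides)
safe_codons <- function() setdiff(all_codons(), c(STOP_CODONS, PRE_STOP_SET))

#' Generate a synthetic annotated genome with planted base-editing targets
#'
#' Builds a small multi-gene prokaryote-like genome (single-interval CDSs on
#' both strands separated by random intergenic spacers) in which every
#' possible knockout guide is known by construction: background CDS codons
#' are drawn from the 57 codons that are neither stops nor pre-stop codons,
#' so premature stops can only arise at the planted codons. For each planted
#' target a pre-stop codon (CGA, CAG, CAA or TGG) is positioned so that its
#' editable base falls at a requested protospacer window position of a
#' constructed NGG site (coding-strand C for CGA/CAG/CAA; template-strand C,
#' i.e. coding-strand G, for TGG).
#'
#' The generator self-checks with the independent [brute_force_design()]
#' oracle: every planted target must be recovered and every oracle guide
#' must hit a planted codon. Optional decoys plant pre-stop codons engineered
#' to be *untargetable* (editable base outside the extended window, or no
#' NGG in reach) and are verified to yield no guide.
#'
#' @param n_genes Number of genes (default 20, a study-sized fixture of
#'   roughly 30 kb with the default codon range).
#' @param seed Integer seed; the whole fixture is a pure function of its
#'   arguments.
#' @param plant_spec Optional data.frame with columns `gene` (1-based gene
#'   number), `codon` (CGA/CAG/CAA/TGG), `window_pos` (protospacer position
#'   of the editable base, -20..-13) and optionally `codon_index`. Default:
#'   one plant per gene with codon and canonical window position sampled.
#' @param n_contigs Number of contigs; genes are assigned round-robin.
#' @param codon_range Min/max codons per gene (start and stop included).
#' @param intergenic_range Min/max intergenic spacer length.
#' @param decoys Add near-miss decoys (default when `n_genes >= 4`).
#' @return A `synthetic_genome` list: `fasta` and `gff3` (character vectors
#'   of file lines), `genome` (`DNAStringSet`), `genes` (`gene_set`), and
#'   `manifest` (seed, gene table, `planted`, `decoys`, and
#'   `expected_guides` for both window modes, computed by the oracle).
#' @export
make_genome <- function(n_genes = 20L, seed = 1L, plant_spec = NULL,
                        n_contigs = 1L, codon_range = c(250L, 450L),
                        intergenic_range = c(150L, 400L),
                        decoys = n_genes >= 4L) {
  stopifnot(n_genes >= 0L, n_contigs >= 1L)
  set.seed(seed)
  safe <- safe_codons()

  if (n_genes == 0L) {
    len <- 500L
    seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    genome <- Biostrings::DNAStringSet(setNames(seq, "ctg1"))
    genes <- empty_gene_set()
    manifest <- list(seed = seed, n_genes = 0L,
                     genes = data.frame(), planted = data.frame(),
                     decoys = data.frame(),
                     expected_guides = list(canonical = data.frame(),
                                            extended = data.frame()))
    return(structure(list(fasta = write_genome(genome),
                          gff3 = write_annotation(genes, genome),
                          genome = genome, genes = genes, manifest = manifest),
                     class = "synthetic_genome"))
  }

  if (is.null(plant_spec)) {
    plant_spec <- data.frame(
      gene = seq_len(n_genes),
      codon = sample(PRE_STOP_SET, n_genes, replace = TRUE),
      window_pos = sample(-20:-16, n_genes, replace = TRUE),
      codon_index = NA_integer_,
      stringsAsFactors = FALSE)
  }
  if (is.null(plant_spec$codon_index)) plant_spec$codon_index <- NA_integer_
  if (any(plant_spec$window_pos < -20L | plant_spec$window_pos > -13L)) {
    stop("infeasible plant_spec: window position out of -20..-13")
  }
  if (any(!plant_spec$codon %in% PRE_STOP_SET)) {
    stop("infeasible plant_spec: codon must be one of ", paste(PRE_STOP_SET, collapse = ", "))
  }
  if (any(plant_spec$gene < 1L | plant_spec$gene > n_genes)) {
    stop("infeasible plant_spec: gene number out of range")
  }
  if (anyDuplicated(plant_spec$gene)) {
    stop("infeasible plant_spec: at most one plant per gene")
  }
  plant_spec$gene <- as.integer(plant_spec$gene)
  plant_spec$window_pos <- as.integer(plant_spec$window_pos)
  plant_spec$codon_index <- as.integer(plant_spec$codon_index)

  decoy_genes <- integer(0)
  if (isTRUE(decoys)) decoy_genes <- utils::head(setdiff(seq_len(n_genes), integer(0)), 2L)

  # per-gene construction in coding space
  built <- vector("list", n_genes)
  planted_rows <- list()
  decoy_rows <- list()
  for (g in seq_len(n_genes)) {
    N <- sample.int(codon_range[2L] - codon_range[1L] + 1L, 1L) + codon_range[1L] - 1L
    cods <- c("ATG", sample(safe, N - 2L, replace = TRUE),
              STOP_CODONS[sample.int(3L, 1L)])
    constraints <- list()
    plant_ci <- NA_integer_
    prow <- plant_spec[plant_spec$gene == g, , drop = FALSE]
    if (nrow(prow) == 1L) {
      ci <- prow$codon_index
      if (is.na(ci)) {
        cand <- seq(8L, N - 9L)
        ci <- cand[sample.int(length(cand), 1L)]
      }
      if (ci < 8L || ci > N - 9L) stop("infeasible plant_spec: codon_index too close to gene ends")
      plant_ci <- ci
      cods[ci + 1L] <- prow$codon
      k <- prow$window_pos
      if (prow$codon == "TGG") {
        # template-strand target: editable C (coding G) at codon offset 1;
        # minus-strand PAM appears as coding-strand CC at g1+k-2, g1+k-1
        g1 <- 3L * ci + 1L
        constraints <- c(constraints,
                         list(list(pos = g1 + k - 2L, allowed = "C"),
                              list(pos = g1 + k - 1L, allowed = "C")))
      } else {
        # coding-strand target: C at codon offset 0; NGG PAM downstream with
        # its GG at cds positions c_pos - k + 1 and c_pos - k + 2
        c_pos <- 3L * ci
        pam0 <- c_pos - k
        constraints <- c(constraints,
                         list(list(pos = pam0 + 1L, allowed = "G"),
                              list(pos = pam0 + 2L, allowed = "G")))
      }
      planted_rows[[length(planted_rows) + 1L]] <- data.frame(
        gene_id = gene_name(g), codon = prow$codon, codon_index = ci,
        window_pos = k,
        edit_strand = if (prow$codon == "TGG") "template" else "coding",
        canonical = plant_canonical(prow$codon, k),
        stringsAsFactors = FALSE)
    }
    if (g %in% decoy_genes) {
      type <- if (g == decoy_genes[1L]) "outside_window" else "no_pam"
      ci <- pick_decoy_index(N, plant_ci)
      c_pos <- 3L * ci
      if (type == "outside_window") {
        # CGA with its C at position -11 of a constructed NGG: inside the
        # protospacer but beyond the extended window; forbid any other G in
        # the stretch that could host a window-range PAM
        cods[ci + 1L] <- "CGA"
        constraints <- c(constraints,
                         list(list(pos = c_pos + 12L, allowed = "G"),
                              list(pos = c_pos + 13L, allowed = "G")),
                         lapply(14L:22L, function(d) list(pos = c_pos + d, allowed = c("A", "C", "T"))))
      } else {
        # CAG with no NGG anywhere in window reach of its C
        cods[ci + 1L] <- "CAG"
        constraints <- c(constraints,
                         lapply(13L:22L, function(d) list(pos = c_pos + d, allowed = c("A", "C", "T"))))
      }
      decoy_rows[[length(decoy_rows) + 1L]] <- data.frame(
        gene_id = gene_name(g), type = type,
        codon = cods[ci + 1L], codon_index = ci, stringsAsFactors = FALSE)
    }
    cods <- apply_codon_constraints(cods, constraints, safe,
                                    protected = c(0L, plant_ci, N - 1L))
    built[[g]] <- list(cods = cods, strand = sample(c("+", "-"), 1L),
                       contig = paste0("ctg", ((g - 1L) %% n_contigs) + 1L))
  }

  # assemble contigs: spacer, gene, spacer, gene, ..., spacer
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  ig_len <- function() sample.int(intergenic_range[2L] - intergenic_range[1L] + 1L, 1L) +
    intergenic_range[1L] - 1L
  contig_seq <- setNames(vector("list", n_contigs), paste0("ctg", seq_len(n_contigs)))
  gene_rows <- list()
  for (cn in names(contig_seq)) {
    parts <- character(0)
    at <- 0L
    for (g in seq_len(n_genes)) {
      b <- built[[g]]
      if (b$contig != cn) next
      ig <- rand_seq(ig_len())
      parts <- c(parts, ig)
      at <- at + nchar(ig)
      cds <- paste(b$cods, collapse = "")
      emb <- if (b$strand == "-") revcomp_chr(cds) else cds
      gene_rows[[length(gene_rows) + 1L]] <- list(
        gene_id = gene_name(g), contig = cn, strand = b$strand,
        start = at, end = at + nchar(cds), codon_count = length(b$cods))
      parts <- c(parts, emb)
      at <- at + nchar(cds)
    }
    parts <- c(parts, rand_seq(ig_len()))
    contig_seq[[cn]] <- paste(parts, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(vapply(contig_seq, identity, character(1)))

  genes <- data.frame(
    gene_id = vapply(gene_rows, `[[`, character(1), "gene_id"),
    contig = vapply(gene_rows, `[[`, character(1), "contig"),
    strand = vapply(gene_rows, `[[`, character(1), "strand"),
    cds_len = vapply(gene_rows, function(r) r$end - r$start, integer(1)),
    codon_count = vapply(gene_rows, `[[`, integer(1), "codon_count"),
    stringsAsFactors = FALSE)
  genes$cds_starts <- lapply(gene_rows, function(r) r$start)
  genes$cds_ends <- lapply(gene_rows, function(r) r$end)
  genes$validated <- TRUE
  genes <- genes[order(genes$contig, vapply(genes$cds_starts, min, double(1))), ]
  rownames(genes) <- NULL
  class(genes) <- c("gene_set", "data.frame")

  planted <- if (length(planted_rows)) do.call(rbind, planted_rows) else data.frame()
  decoy_df <- if (length(decoy_rows)) do.call(rbind, decoy_rows) else data.frame()

  expected <- list(
    canonical = brute_force_design(genome, genes, window = "canonical"),
    extended = brute_force_design(genome, genes, window = "extended"))
  check_fixture(planted, decoy_df, expected)

  manifest <- list(seed = seed, n_genes = n_genes,
                   genes = genes[, c("gene_id", "contig", "strand", "cds_len", "codon_count")],
                   planted = planted, decoys = decoy_df,
                   expected_guides = expected)
  structure(list(fasta = write_genome(genome),
                 gff3 = write_annotation(genes, genome),
                 genome = genome, genes = genes, manifest = manifest),
            class = "synthetic_genome")
}

gene_name <- function(i) sprintf("g%03d", i)

plant_canonical <- function(codon, k) {
  pos <- if (codon == "TGG") intersect(c(k, k - 1L), -20:-1) else k
  any(pos %in% -20:-16)
}

pick_decoy_index <- function(N, plant_ci) {
  cand <- seq(8L, N - 9L)
  if (!is.na(plant_ci)) cand <- cand[abs(cand - plant_ci) >= 20L]
  if (!length(cand)) stop("gene too short to host plant and decoy")
  cand[sample.int(length(cand), 1L)]
}

# resample the codons hit by base constraints from the safe pool; constraint:
# list(pos = 0-based CDS position, allowed = permitted bases at that position)
apply_codon_constraints <- function(cods, constraints, safe, protected) {
  if (!length(constraints)) return(cods)
  pos <- vapply(constraints, `[[`, integer(1), "pos")
  if (any(pos < 0L | pos >= 3L * length(cods))) stop("constraint outside CDS")
  for (j in unique(pos %/% 3L)) {
    if (j %in% protected) stop("internal: constraint collides with protected codon")
    sel <- which(pos %/% 3L == j)
    cands <- safe
    for (i in sel) {
      o <- pos[i] %% 3L
      cands <- cands[substr(cands, o + 1L, o + 1L) %in% constraints[[i]]$allowed]
    }
    if (!length(cands)) stop("unsatisfiable codon constraints")
    cods[j + 1L] <- cands[sample.int(length(cands), 1L)]
  }
  cods
}

check_fixture <- function(planted, decoys, expected) {
  pair <- function(df) if (nrow(df)) paste(df$gene_id, df$stop_codon_index) else character(0)
  ppair <- if (nrow(planted)) paste(planted$gene_id, planted$codon_index) else character(0)
  for (w in names(expected)) {
    got <- pair(expected[[w]])
    if (!all(got %in% ppair)) {
      stop("fixture self-check failed: oracle found a guide at an unplanted codon (",
           w, " window)")
    }
  }
  need_can <- ppair[planted$canonical]
  if (!all(need_can %in% pair(expected$canonical))) {
    stop("fixture self-check failed: planted canonical-window target not recovered")
  }
  if (!all(ppair %in% pair(expected$extended))) {
    stop("fixture self-check failed: planted target not recovered in extended window")
  }
  if (nrow(decoys)) {
    dpair <- paste(decoys$gene_id, decoys$codon_index)
    if (any(dpair %in% pair(expected$extended))) {
      stop("fixture self-check failed: decoy produced a guide")
    }
  }
  invisible(TRUE)
}

#' Write a synthetic fixture to disk
#'
#' Emits `<prefix>.fa`, `<prefix>.gff3` and `<prefix>.manifest.json`
#' (the manifest requires the jsonlite package).
#'
#' @param fix A `synthetic_genome` from [make_genome()].
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths.
#' @export
write_fixture <- function(fix, prefix) {
  fa <- paste0(prefix, ".fa")
  gff <- paste0(prefix, ".gff3")
  mj <- paste0(prefix, ".manifest.json")
  writeLines(fix$fasta, fa)
  writeLines(fix$gff3, gff)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    m <- fix$manifest
    m$genes <- as.data.frame(m$genes)
    jsonlite::write_json(m, mj, auto_unbox = TRUE, digits = NA)
  } else {
    mj <- NULL
  }
  invisible(c(fa, gff, mj))
}
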