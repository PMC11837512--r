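#' Apply C-to-T deamination edits to a codon
#'
#' The substitution model of the cytosine base editor is a net C:G -> T:A
#' conversion. On the coding strand this reads as C -> T at the edited
#' offsets; when the deaminated cytosines lie on the template strand, the
#' coding-strand consequence is G -> A.
#'
#' @param codon A 3-mer (coding-strand representation).
#' @param offsets Within-codon offsets to edit, a subset of `0:2`. An empty
#'   set returns the codon unchanged.
#' @param edit_strand `"coding"` (requires C at every offset) or
#'   `"template"` (requires G at every offset, coding-strand view).
#' @return The edited 3-mer.
#' @examples
#' apply_ct_edits("CGA", 0, "coding")        # "TGA"
#' apply_ct_edits("TGG", c(1, 2), "template") # "TAA"
#' @export
apply_ct_edits <- function(codon, offsets, edit_strand = c("coding", "template")) {
  edit_strand <- match.arg(edit_strand)
  if (nchar(codon) != 3L) stop("codon must be a 3-mer")
  if (length(offsets) == 0L) return(codon)
  offsets <- as.integer(offsets)
  if (any(offsets < 0L | offsets > 2L)) stop("offsets must be within 0..2")
  ch <- strsplit(codon, "", fixed = TRUE)[[1L]]
  need <- if (edit_strand == "coding") "C" else "G"
  sub <- if (edit_strand == "coding") "T" else "A"
  if (any(ch[offsets + 1L] != need)) {
    stop("base at edit offset is not ", need, " in codon ", codon)
  }
  ch[offsets + 1L] <- sub
  paste(ch, collapse = "")
}

#' Sense codons convertible to stop codons by base editing
#'
#' Exhaustively enumerates all 64 codons, both edit strands, and every
#' non-empty subset of editable offsets (C positions for coding-strand
#' edits, G positions for template-strand edits), and returns the edits
#' whose product is a stop codon. Codons that are already stops are not
#' "pre-stop" and are excluded.
#'
#' The closure of this enumeration is the four-codon rule set used for gene
#' inactivation: CGA -> TGA, CAG -> TAG, CAA -> TAA by coding-strand editing,
#' and TGG -> TGA/TAG/TAA by editing one or both cytosines of the CCA on the
#' template strand.
#'
#' @return data.frame with one row per (codon, edit_strand, offset subset):
#'   columns `codon`, `edit_strand`, `offsets` (comma-separated within-codon
#'   offsets), `n_edits`, `stop`.
#' @export
pre_stop_codons <- function() {
  if (!is.null(.bestop_cache$pre_stop)) return(.bestop_cache$pre_stop)
  rows <- list()
  for (codon in all_codons()) {
    if (is_stop_codon(codon)) next
    ch <- strsplit(codon, "", fixed = TRUE)[[1L]]
    for (strand in c("coding", "template")) {
      editable <- which(ch == if (strand == "coding") "C" else "G") - 1L
      if (length(editable) == 0L) next
      for (m in seq_len(2L^length(editable) - 1L)) {
        offs <- editable[as.logical(bitwAnd(m, 2L^(seq_along(editable) - 1L)))]
        res <- apply_ct_edits(codon, offs, strand)
        if (is_stop_codon(res)) {
          rows[[length(rows) + 1L]] <- data.frame(
            codon = codon, edit_strand = strand,
            offsets = paste(offs, collapse = ","),
            n_edits = length(offs), stop = res, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$codon, out$edit_strand, out$n_edits, out$offsets), ]
  rownames(out) <- NULL
  .bestop_cache$pre_stop <- out
  out
}

.bestop_cache <- new.env(parent = emptyenv())

# lookup list keyed by "codon|strand" -> data.frame of qualifying edit subsets
pre_stop_lookup <- function() {
  if (is.null(.bestop_cache$lookup)) {
    tab <- pre_stop_codons()
    .bestop_cache$lookup <- split(tab, paste(tab$codon, tab$edit_strand, sep = "|"))
  }
  .bestop_cache$lookup
}

# map 0-based plus-strand genome coordinates into 0-based CDS positions of a
# gene; returns NA for coordinates outside all CDS intervals
genome_to_cds <- function(gene, coords) {
  s <- gene$cds_starts[[1L]]
  e <- gene$cds_ends[[1L]]
  cum <- cumsum(c(0L, e - s))
  out <- rep(NA_integer_, length(coords))
  for (j in seq_along(s)) {
    in_j <- coords >= s[j] & coords < e[j]
    out[in_j] <- cum[j] + (coords[in_j] - s[j])
  }
  if (gene$strand == "-") out <- gene$cds_len - 1L - out
  out
}

# index of the first in-frame stop codon of a coding sequence (0-based),
# or codon_count if there is none; premature stops must land before it
first_stop_index <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (n == 0L) return(0L)
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  hit <- which(codons %in% STOP_CODONS)
  if (length(hit)) hit[1L] - 1L else n
}

#' Classify a protospacer site against a gene
#'
#' Maps each editable cytosine of `site` (see [editable_cs()]) onto the
#' gene's reading frame and decides whether window edits create a premature
#' stop codon. The edit strand is `"coding"` when the protospacer lies on
#' the gene's coding strand and `"template"` otherwise. Window cytosines
#' falling outside all CDS intervals are ignored.
#'
#' Under the `"any-subset"` policy the site qualifies if *some* non-empty
#' subset of its window edits creates a stop upstream of the gene's native
#' stop; the minimal such subset is recorded. Under `"all-window-cs"` every
#' window cytosine is assumed co-edited and the site qualifies if the fully
#' edited sequence carries a premature stop.
#'
#' @param site One row of a `pam_sites` data.frame.
#' @param gene One row of a `gene_set`.
#' @param genome `DNAStringSet`.
#' @param window An [edit_window()].
#' @param policy `"any-subset"` (default) or `"all-window-cs"`.
#' @return A `stop_guide` list (site and gene identifiers, `stop_codon`,
#'   `stop_codon_index`, `relative_position`, the codon edit, and collateral
#'   window edits), or `NULL` when no premature stop can be created.
#' @export
classify_site <- function(site, gene, genome, window = edit_window(),
                          policy = c("any-subset", "all-window-cs")) {
  policy <- match.arg(policy)
  if (nrow(site) != 1L || nrow(gene) != 1L) {
    stop("classify_site() expects single site and gene rows")
  }
  if (site$contig != gene$contig) stop("site and gene are on different contigs")
  wc <- editable_cs(site, window)
  if (nrow(wc) == 0L) return(NULL)
  wc$cds_pos <- genome_to_cds(gene, wc$genome_coord)
  wc <- wc[!is.na(wc$cds_pos), , drop = FALSE]
  if (nrow(wc) == 0L) return(NULL)
  cds <- coding_sequence(gene, genome)
  classify_core(site, gene, cds, wc, policy)
}

# shared engine behind classify_site() and design_guides(); `wc` carries
# columns position, genome_coord, cds_pos (all inside the CDS)
classify_core <- function(site, gene, cds, wc, policy) {
  edit_strand <- if (site$strand == gene$strand) "coding" else "template"
  threshold <- first_stop_index(cds)
  wc$codon_index <- wc$cds_pos %/% 3L
  wc$offset <- wc$cds_pos %% 3L
  lookup <- pre_stop_lookup()

  chosen <- NULL
  for (ci in sort(unique(wc$codon_index))) {
    if (ci >= threshold) next
    codon <- substr(cds, 3L * ci + 1L, 3L * ci + 3L)
    avail <- wc[wc$codon_index == ci, , drop = FALSE]
    if (policy == "all-window-cs") {
      edited <- apply_ct_edits(codon, avail$offset, edit_strand)
      if (is_stop_codon(edited)) {
        chosen <- list(ci = ci, codon = codon, edited = edited,
                       offsets = sort(avail$offset), rows = avail)
        break
      }
    } else {
      ent <- lookup[[paste(codon, edit_strand, sep = "|")]]
      if (is.null(ent)) next
      ok <- vapply(strsplit(ent$offsets, ",", fixed = TRUE), function(o) {
        all(as.integer(o) %in% avail$offset)
      }, logical(1))
      if (any(ok)) {
        ent <- ent[ok, , drop = FALSE]
        best <- ent[which.min(ent$n_edits), , drop = FALSE]
        offs <- as.integer(strsplit(best$offsets, ",", fixed = TRUE)[[1L]])
        chosen <- list(ci = ci, codon = codon, edited = best$stop,
                       offsets = offs,
                       rows = avail[avail$offset %in% offs, , drop = FALSE])
        break
      }
    }
  }
  if (is.null(chosen)) return(NULL)
  in_edit <- wc$codon_index == chosen$ci & wc$offset %in% chosen$offsets
  collateral <- wc[!in_edit, c("position", "genome_coord", "codon_index", "offset")]
  rownames(collateral) <- NULL
  structure(list(
    contig = site$contig, strand = site$strand,
    spacer_start = site$spacer_start, spacer_end = site$spacer_end,
    spacer = site$spacer, pam = site$pam,
    gene_id = gene$gene_id,
    edit_strand = edit_strand,
    codon_index = chosen$ci,
    original_codon = chosen$codon,
    edited_codon = chosen$edited,
    stop_codon = chosen$edited,
    stop_codon_index = chosen$ci,
    edit_offsets = chosen$offsets,
    edit_positions = sort(chosen$rows$position),
    relative_position = chosen$ci / gene$codon_count,
    collateral_edits = collateral
  ), class = "stop_guide")
}
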