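#' Brute-force knockout-guide design oracle
#'
#' An independent reference implementation used to validate
#' [design_guides()]: it enumerates every 23-mer NGG site on both strands,
#' literally applies each permitted combination of window edits to the
#' genome sequence (C->T for plus-protospacer sites, the complementary G->A
#' for minus sites), re-extracts and re-translates every overlapping CDS,
#' and reports the (site, gene) pairs whose edited sequence gains an
#' in-frame stop upstream of the gene's first native stop. It shares no code
#' with the codon-rule engine of [classify_site()] and is quadratic by
#' design; use it on small genomes only (<= ~100 kb).
#'
#' @param genome `DNAStringSet`.
#' @param genes `gene_set`; only validated genes are considered.
#' @param window `"canonical"` or `"extended"`.
#' @param policy `"any-subset"` tests every non-empty subset of window
#'   cytosines; `"all-window-cs"` tests only the full set.
#' @param all_subsets If `TRUE`, report one row per qualifying (site, gene,
#'   edit subset) with the stop codon it creates, instead of deduplicating
#'   to (site, gene) pairs.
#' @return data.frame: `contig`, `strand`, `spacer_start` (0-based),
#'   `gene_id`, `stop_codon`, `stop_codon_index`; with `all_subsets` also
#'   `edit_coords` (comma-separated 0-based genome coordinates).
#' @export
brute_force_design <- function(genome, genes,
                               window = c("canonical", "extended"),
                               policy = c("any-subset", "all-window-cs"),
                               all_subsets = FALSE) {
  window <- match.arg(window)
  policy <- match.arg(policy)
  wpos <- if (window == "canonical") -20:-16 else -20:-13
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  # stop detection from first principles: TAA / TAG / TGA in frame
  first_stop_of <- function(v) {
    n <- length(v) %/% 3L
    v1 <- v[3L * seq_len(n) - 2L]
    v2 <- v[3L * seq_len(n) - 1L]
    v3 <- v[3L * seq_len(n)]
    hit <- which(v1 == "T" &
                   ((v2 == "A" & (v3 == "A" | v3 == "G")) |
                      (v2 == "G" & v3 == "A")))
    if (length(hit)) hit[1L] - 1L else n
  }
  out <- list()

  for (contig in names(genome)) {
    s <- as.character(genome[[contig]])
    L <- nchar(s)
    if (L < 23L) next
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    gsel <- genes[genes$contig == contig & genes$validated, , drop = FALSE]
    if (nrow(gsel) == 0L) next

    ng <- nrow(gsel)
    gene_id <- gsel$gene_id
    minus <- gsel$strand == "-"
    # per gene: coding-strand characters and genome-coord -> coding-pos map
    vcache <- vector("list", ng)
    gmap <- vector("list", ng)
    native <- integer(ng)
    for (i in seq_len(ng)) {
      g <- gsel[i, ]
      idx <- unlist(mapply(function(a, b) seq.int(a + 1L, b),
                           g$cds_starts[[1L]], g$cds_ends[[1L]], SIMPLIFY = FALSE))
      if (minus[i]) idx <- rev(idx)
      v <- ch[idx]
      if (minus[i]) v <- unname(comp[v])
      m <- integer(L)
      m[idx] <- seq_along(idx)
      vcache[[i]] <- v
      gmap[[i]] <- m
      native[i] <- first_stop_of(v)
    }
    glo <- vapply(gsel$cds_starts, function(x) min(x) + 1L, integer(1))
    ghi <- vapply(gsel$cds_ends, max, integer(1))

    nxt <- c(ch[-1L], "")
    # plus-strand sites: 23-mer starting at 1-based i with GG at i+21, i+22
    plus_i <- which(ch == "G" & nxt == "G") - 21L
    plus_i <- plus_i[plus_i >= 1L]
    # minus-strand sites: CC at 1-based i, spacer at i+3 .. i+22
    minus_i <- which(ch == "C" & nxt == "C")
    minus_i <- minus_i[minus_i + 22L <= L]

    # a site can only matter if some window position carries an editable
    # base (C for plus sites, G for minus sites) inside a CDS span; edits
    # outside every CDS cannot change any translation
    in_cds <- rep(FALSE, L)
    for (i in seq_len(ng)) in_cds[glo[i]:ghi[i]] <- TRUE
    keep_sites <- function(idx, offs, base) {
      if (!length(idx)) return(idx)
      m <- outer(idx, offs, `+`)
      hit <- matrix(ch[m] == base & in_cds[m], nrow = length(idx))
      idx[rowSums(hit) > 0L]
    }
    plus_i <- keep_sites(plus_i, wpos + 20L, "C")
    minus_i <- keep_sites(minus_i, 2L - wpos, "G")

    eval_site <- function(i, strand) {
      if (any(ch[i:(i + 22L)] == "N")) return(NULL)
      if (strand == "+") {
        coords <- i + (wpos + 20L)      # 1-based genome coordinate at position k
        cs <- coords[ch[coords] == "C"]
        edit_plus <- "T"                 # C -> T on the plus strand
        spacer_start <- i - 1L
      } else {
        coords <- (i + 2L) - wpos
        cs <- coords[ch[coords] == "G"]  # template C = plus-strand G
        edit_plus <- "A"                 # G -> A on the plus strand
        spacer_start <- i + 2L
      }
      if (length(cs) == 0L) return(NULL)
      overl <- which(vapply(seq_len(ng), function(j) {
        any(cs >= glo[j] & cs <= ghi[j])
      }, logical(1)))
      if (length(overl) == 0L) return(NULL)

      subsets <- if (policy == "all-window-cs") {
        list(cs)
      } else {
        n <- length(cs)
        lapply(seq_len(2L^n - 1L), function(m) {
          cs[as.logical(bitwAnd(m, 2L^(seq_len(n) - 1L)))]
        })
      }
      rows <- list()
      for (j in overl) {
        base_cod <- if (minus[j]) unname(comp[edit_plus]) else edit_plus
        for (sub in subsets) {
          p <- gmap[[j]][sub]
          p <- p[p > 0L]
          if (length(p) == 0L) next    # edits all outside this CDS
          vv <- vcache[[j]]
          vv[p] <- base_cod
          s1 <- first_stop_of(vv)
          if (s1 < native[j]) {
            rows[[length(rows) + 1L]] <- data.frame(
              contig = contig, strand = strand, spacer_start = spacer_start,
              gene_id = gene_id[j],
              stop_codon = paste(vv[(3L * s1 + 1L):(3L * s1 + 3L)], collapse = ""),
              stop_codon_index = s1,
              edit_coords = paste(sort(sub) - 1L, collapse = ","),
              stringsAsFactors = FALSE)
            if (!all_subsets) break
          }
        }
      }
      if (length(rows)) do.call(rbind, rows) else NULL
    }

    for (i in plus_i) out[[length(out) + 1L]] <- eval_site(i, "+")
    for (i in minus_i) out[[length(out) + 1L]] <- eval_site(i, "-")
  }

  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(contig = character(0), strand = character(0),
                      spacer_start = integer(0), gene_id = character(0),
                      stop_codon = character(0), stop_codon_index = integer(0),
                      edit_coords = character(0), stringsAsFactors = FALSE)
  }
  if (!all_subsets) {
    res <- res[!duplicated(res[, c("contig", "strand", "spacer_start", "gene_id")]), ,
               drop = FALSE]
    res$edit_coords <- NULL
  }
  res <- res[order(res$contig, res$spacer_start, res$strand, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
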