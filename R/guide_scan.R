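#' Deamination window of a cytosine base editor
#'
#' Protospacer positions are numbered -20 (PAM-distal, 5' end of the spacer)
#' to -1 (PAM-proximal), with the NGG PAM at positions 0-2. The canonical
#' deaminase window covers -20..-16; the extended window adds -15..-13,
#' positions at which editing is still observed, at lower efficiency for -13.
#'
#' @param mode `"canonical"` (-20..-16, the default) or `"extended"`
#'   (-20..-13).
#' @return An `edit_window`: list with elements `mode` and `positions`.
#' @examples
#' edit_window("extended")$positions
#' @export
edit_window <- function(mode = c("canonical", "extended")) {
  mode <- match.arg(mode)
  positions <- if (mode == "canonical") -20:-16 else -20:-13
  structure(list(mode = mode, positions = positions), class = "edit_window")
}

#' Enumerate protospacer sites (20-nt spacer + NGG PAM) on both strands
#'
#' Finds every occurrence of `N20-NGG` on the plus strand and every
#' occurrence of `CCN-N20` on the plus strand (an NGG protospacer on the
#' minus strand). Overlapping PAMs (e.g. runs of G) each yield their own
#' site. Sites whose spacer or PAM contains `N` are dropped.
#'
#' @param genome A `DNAStringSet`, or a single contig as a character string.
#' @param contig Restrict the scan to one contig id (optional).
#' @param circular If `TRUE`, PAM scanning continues across the origin of
#'   each contig (coordinates of origin-spanning sites are reported modulo
#'   the contig length).
#' @return A `pam_sites` data.frame: `contig`, `strand`, `spacer_start`,
#'   `spacer_end`, `pam_start`, `pam_end` (0-based half-open plus-strand
#'   coordinates), `spacer` and `pam` (in protospacer orientation, so
#'   `pam` always matches `NGG`), and `contig_len`.
#' @export
find_pam_sites <- function(genome, contig = NULL, circular = FALSE) {
  if (is.character(genome)) {
    genome <- Biostrings::DNAStringSet(setNames(toupper(genome), "seq"))
  }
  ids <- if (is.null(contig)) names(genome) else contig
  out <- lapply(ids, function(id) {
    scan_contig(contig_string(genome, id), id, circular = circular)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty_sites()
  rownames(res) <- NULL
  class(res) <- c("pam_sites", "data.frame")
  res
}

empty_sites <- function() {
  data.frame(contig = character(0), strand = character(0),
             spacer_start = integer(0), spacer_end = integer(0),
             pam_start = integer(0), pam_end = integer(0),
             spacer = character(0), pam = character(0),
             contig_len = integer(0), stringsAsFactors = FALSE)
}

scan_contig <- function(s, id, circular = FALSE) {
  L <- nchar(s)
  if (L < 23L) return(NULL)
  # for circular contigs extend the scan window across the origin
  s2 <- if (circular) paste0(s, substr(s, 1L, 22L)) else s
  ch <- strsplit(s2, "", fixed = TRUE)[[1L]]
  n2 <- length(ch)
  nxt <- c(ch[-1L], "")
  gg <- which(ch == "G" & nxt == "G")  # 1-based i: ch[i..i+1] == "GG"
  cc <- which(ch == "C" & nxt == "C")

  # plus strand: PAM starts at 0-based p = i - 2; spacer [p-20, p)
  p <- gg - 2L
  p <- p[p >= 20L & p + 3L <= n2]
  if (circular) p <- p[p - 20L < L]  # spacer must start on the unextended contig
  # minus strand: plus-strand CCN at 0-based q; spacer [q+3, q+23)
  q <- cc - 1L
  q <- q[q >= 0L & q + 23L <= n2]
  if (circular) q <- q[q < L]

  rows <- list()
  if (length(p)) {
    spacer <- substring(s2, p - 19L, p)
    pam <- substring(s2, p + 1L, p + 3L)
    keep <- !grepl("N", paste0(spacer, pam), fixed = TRUE)
    rows$plus <- data.frame(
      contig = id, strand = "+",
      spacer_start = (p - 20L) %% L, spacer_end = (p - 20L) %% L + 20L,
      pam_start = p %% L, pam_end = p %% L + 3L,
      spacer = spacer, pam = pam, contig_len = L,
      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  }
  if (length(q)) {
    spacer <- revcomp_chr(substring(s2, q + 4L, q + 23L))
    pam <- revcomp_chr(substring(s2, q + 1L, q + 3L))
    keep <- !grepl("N", paste0(spacer, pam), fixed = TRUE)
    rows$minus <- data.frame(
      contig = id, strand = "-",
      spacer_start = (q + 3L) %% L, spacer_end = (q + 3L) %% L + 20L,
      pam_start = q %% L, pam_end = q %% L + 3L,
      spacer = spacer, pam = pam, contig_len = L,
      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  }
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) == 0L) return(NULL)
  res[order(pmin(res$spacer_start, res$pam_start), res$strand), , drop = FALSE]
}

#' Cytosines editable by the deaminase within a protospacer
#'
#' Returns the window positions of `site` whose spacer base is `C`, with
#' their genome coordinates, ordered 5' to 3' along the protospacer.
#'
#' @param site A single row of a `pam_sites` data.frame.
#' @param window An [edit_window()].
#' @return data.frame with columns `position` (protospacer numbering) and
#'   `genome_coord` (0-based plus-strand coordinate of the cytosine; for a
#'   minus-strand site this is the coordinate of the complementary G on the
#'   plus strand).
#' @examples
#' sites <- find_pam_sites("ACGTACGTACGTACGTACGTAGG")
#' editable_cs(sites[1, ], edit_window())
#' @export
editable_cs <- function(site, window = edit_window()) {
  if (nrow(site) != 1L) stop("editable_cs() expects a single site row")
  tab <- window_c_table(site, window)
  tab[, c("position", "genome_coord")]
}

# vectorized over all sites: one row per window cytosine
window_c_table <- function(sites, window) {
  if (nrow(sites) == 0L) {
    return(data.frame(site = integer(0), position = integer(0),
                      genome_coord = integer(0)))
  }
  k <- window$positions
  idx <- k + 21L  # 1-based index into the spacer string (position -20 -> 1)
  mat <- matrix(unlist(strsplit(sites$spacer, "", fixed = TRUE)),
                nrow = 20L)[idx, , drop = FALSE]
  hit <- which(mat == "C", arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    return(data.frame(site = integer(0), position = integer(0),
                      genome_coord = integer(0)))
  }
  site_i <- hit[, "col"]
  pos <- k[hit[, "row"]]
  plus <- sites$strand[site_i] == "+"
  coord <- ifelse(plus,
                  sites$spacer_start[site_i] + (pos + 20L),
                  sites$spacer_end[site_i] - 1L - (pos + 20L))
  coord <- coord %% sites$contig_len[site_i]
  out <- data.frame(site = as.integer(site_i), position = pos,
                    genome_coord = as.integer(coord))
  out <- out[order(out$site, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export protospacer spans as BED6 text
#'
#' One line per site covering the 20-nt protospacer (0-based half-open).
#'
#' @param sites A `pam_sites` data.frame (or a guide catalog, which carries
#'   the same coordinate columns).
#' @param names Optional feature names; defaults to `spacer|pam`.
#' @param file Optional output path.
#' @export
sites_bed <- function(sites, names = NULL, file = NULL) {
  if (is.null(names)) names <- paste0(sites$spacer, "|", sites$pam)
  lines <- paste(sites$contig, sites$spacer_start, sites$spacer_end,
                 names, 0L, sites$strand, sep = "\t")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
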