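#' Read a per-position base-frequency table
#'
#' The quantification input is a tab-separated table derived from a Sanger
#' trace (peak signal or base frequency per position), with columns
#' `position` (1-based along the sequenced amplicon), `ref` (reference base)
#' and `A`, `C`, `G`, `T` (non-negative signals). Column names are matched
#' case-insensitively; `reference_base` is accepted for `ref`.
#'
#' @param file Path to the TSV.
#' @return A validated `base_freq` data.frame.
#' @export
read_base_freq <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- sub("^reference_base$", "ref", tolower(names(df)))
  names(df)[names(df) %in% c("a", "c", "g", "t")] <-
    toupper(names(df)[names(df) %in% c("a", "c", "g", "t")])
  validate_base_freq(df)
}

validate_base_freq <- function(df) {
  need <- c("position", "ref", "A", "C", "G", "T")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("base-frequency table lacks column(s): ",
                            paste(missing, collapse = ", "))
  df$ref <- toupper(df$ref)
  if (any(!df$ref %in% c("A", "C", "G", "T"))) stop("ref must be one of A,C,G,T")
  sig <- as.matrix(df[, c("A", "C", "G", "T")])
  if (any(sig < 0)) stop("negative signal values")
  if (any(rowSums(sig) <= 0)) stop("zero total signal at position(s) ",
                                   paste(df$position[rowSums(sig) <= 0], collapse = ", "))
  if (is.unsorted(df$position, strictly = TRUE)) stop("positions must be strictly increasing")
  class(df) <- c("base_freq", "data.frame")
  df
}

#' C-to-T editing efficiency of target cytosines
#'
#' Defined as the occurrence frequency of T among the four base signals at
#' the position: `T / (A + T + C + G)`. Computed for positions whose
#' reference base is C.
#'
#' @param row One or more rows of a `base_freq` table (reference base must
#'   be C), or a data.frame with columns `A`, `C`, `G`, `T`.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' ct_efficiency(data.frame(ref = "C", A = 0, C = 75, G = 0, T = 25)) # 0.25
#' @export
ct_efficiency <- function(row) {
  base_frequency(row, "T")
}

#' C-to-G editing efficiency of target cytosines
#'
#' Defined as the occurrence frequency of G among the four base signals at
#' the position: `G / (A + T + C + G)`.
#'
#' @inheritParams ct_efficiency
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
cg_efficiency <- function(row) {
  base_frequency(row, "G")
}

base_frequency <- function(row, base) {
  if (!all(c("A", "C", "G", "T") %in% names(row))) {
    stop("expected columns A, C, G, T")
  }
  if ("ref" %in% names(row) && any(toupper(row$ref) != "C")) {
    stop("efficiency is defined for reference-base C positions")
  }
  total <- row$A + row$C + row$G + row$T
  if (any(total <= 0)) stop("zero total signal")
  row[[base]] / total
}

#' Editing efficiencies at target positions of a base-frequency table
#'
#' @param table A `base_freq` data.frame (see [read_base_freq()]).
#' @param target_positions Positions (matching the table's `position`
#'   column) of the targeted cytosines; each must exist and have reference
#'   base C.
#' @return data.frame with one row per target, in input order: `position`,
#'   `ref`, `ct_efficiency`, `cg_efficiency`.
#' @export
profile_target <- function(table, target_positions) {
  table <- validate_base_freq(as.data.frame(table))
  if (length(target_positions) == 0L) {
    return(data.frame(position = integer(0), ref = character(0),
                      ct_efficiency = double(0), cg_efficiency = double(0)))
  }
  idx <- match(target_positions, table$position)
  if (anyNA(idx)) stop("target position(s) absent from table: ",
                       paste(target_positions[is.na(idx)], collapse = ", "))
  rows <- table[idx, , drop = FALSE]
  if (any(rows$ref != "C")) stop("target position(s) with non-C reference: ",
                                 paste(rows$position[rows$ref != "C"], collapse = ", "))
  data.frame(position = rows$position, ref = rows$ref,
             ct_efficiency = ct_efficiency(rows),
             cg_efficiency = cg_efficiency(rows),
             row.names = NULL)
}

#' Write an efficiency profile as TSV
#' @param profile Output of [profile_target()].
#' @param file Output path; `NULL` returns lines invisibly.
#' @export
write_efficiency <- function(profile, file = NULL) {
  df <- profile
  df$ct_efficiency <- sprintf("%.6f", df$ct_efficiency)
  df$cg_efficiency <- sprintf("%.6f", df$cg_efficiency)
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(df, sep = "\t")))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
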