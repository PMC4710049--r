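#' Aligned X/Y homolog isoform set
#'
#' Holds pre-aligned transcript isoform sequences for an X/Y gametolog pair
#' (e.g. all RefSeq isoforms of PCDH11X versus PCDH11Y). Sequences must come
#' from one multiple alignment and therefore share one length; alignment
#' construction itself is delegated to standard tools.
#'
#' @param x_seqs,y_seqs Character vectors of aligned sequences
#'   (A/C/G/T/N/'-'), at least one per side, all the same length.
#' @return Object of class `xy_homolog_set`.
#' @export
homolog_set <- function(x_seqs, y_seqs) {
  x_seqs <- toupper(as.character(x_seqs))
  y_seqs <- toupper(as.character(y_seqs))
  if (length(x_seqs) < 1 || length(y_seqs) < 1) {
    stop("need at least one isoform per side")
  }
  lens <- unique(nchar(c(x_seqs, y_seqs)))
  if (length(lens) != 1) {
    stop("aligned sequences must all have the same length; got lengths ",
         paste(lens, collapse = ", "))
  }
  structure(list(x = x_seqs, y = y_seqs, length = lens),
            class = "xy_homolog_set")
}

#' Read an aligned homolog set from two FASTA files
#'
#' @param x_fasta,y_fasta Paths to FASTA files of aligned X and Y isoform
#'   sequences (gaps as '-').
#' @return An [homolog_set()].
#' @export
read_homolog_set <- function(x_fasta, y_fasta) {
  rd <- function(f) {
    s <- Biostrings::readBStringSet(f)
    stats::setNames(as.character(s), names(s))
  }
  homolog_set(rd(x_fasta), rd(y_fasta))
}

#' Single-nucleotide sites discriminating all X from all Y isoforms
#'
#' Returns every alignment column where all X isoforms carry one identical
#' unambiguous base, all Y isoforms carry one identical unambiguous base,
#' and the two bases differ: candidate padlock-probe ligation junctions,
#' since ligation tolerates no mismatch at the junction. Columns containing
#' gaps or N on either side are never discriminating. Positions are 1-based
#' alignment columns; per-isoform ungapped coordinates are attached for
#' probe placement.
#'
#' @param homologs An [homolog_set()].
#' @return Tibble with `position`, `x_base`, `y_base`, sorted ascending,
#'   with attributes `x_ungapped` and `y_ungapped` (site x isoform matrices
#'   of ungapped positions).
#' @export
find_discriminating_sites <- function(homologs) {
  stopifnot(inherits(homologs, "xy_homolog_set"))
  xm <- do.call(rbind, strsplit(homologs$x, ""))
  ym <- do.call(rbind, strsplit(homologs$y, ""))
  bases <- c("A", "C", "G", "T")
  x_base <- apply(xm, 2, function(col) {
    u <- unique(col)
    if (length(u) == 1 && u %in% bases) u else NA_character_
  })
  y_base <- apply(ym, 2, function(col) {
    u <- unique(col)
    if (length(u) == 1 && u %in% bases) u else NA_character_
  })
  pos <- which(!is.na(x_base) & !is.na(y_base) & x_base != y_base)
  out <- tibble(position = pos, x_base = x_base[pos], y_base = y_base[pos])
  ungapped <- function(m) {
    # per-isoform running count of non-gap characters at each column
    t(apply(m != "-", 1, cumsum))[, pos, drop = FALSE]
  }
  attr(out, "x_ungapped") <- if (length(pos)) t(ungapped(xm)) else
    matrix(integer(), 0, nrow(xm))
  attr(out, "y_ungapped") <- if (length(pos)) t(ungapped(ym)) else
    matrix(integer(), 0, nrow(ym))
  out
}

#' Pairwise percent identity of aligned sequences
#'
#' `100 *` (matching columns) / (columns where neither sequence is gapped).
#' `N` matches only `N`.
#'
#' @param seq_a,seq_b Aligned sequences of equal positive length.
#' @return Percentage in \[0, 100\].
#' @export
percent_identity <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b) || length(a) == 0) {
    stop("sequences must be aligned (equal, positive length)")
  }
  comparable <- a != "-" & b != "-"
  if (!any(comparable)) stop("no comparable (gap-free) columns")
  100 * sum(a[comparable] == b[comparable]) / sum(comparable)
}
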