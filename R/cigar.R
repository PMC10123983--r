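# CIGAR utilities. Parsing is delegated to GenomicAlignments; the projection
# of a spliced alignment onto (reference, query) coordinate pairs is the
# primitive every downstream per-site computation relies on.

QUERY_OPS <- c("M", "I", "S", "=", "X")
REF_OPS <- c("M", "D", "N", "=", "X")
ALN_OPS <- c("M", "=", "X")

#' Parse a CIGAR string into an operation table
#'
#' @param cigar A single CIGAR string (e.g. `"5S10M2I5M100N10M"`).
#' @return A tibble with columns `op` (character) and `len` (integer), one row
#'   per CIGAR operation in order.
#' @examples
#' parse_cigar("10M50N10M")
#' @export
parse_cigar <- function(cigar) {
  stopifnot(length(cigar) == 1L, !is.na(cigar))
  if (cigar == "*") {
    return(tibble(op = character(0), len = integer(0)))
  }
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
  tibble(op = ops, len = as.integer(lens))
}

#' Collapse an operation table back into a CIGAR string
#'
#' Adjacent operations of the same type are merged.
#'
#' @param ops A tibble with columns `op` and `len` as from [parse_cigar()].
#' @return A CIGAR string.
#' @export
cigar_string <- function(ops) {
  if (nrow(ops) == 0L) {
    return("*")
  }
  keep <- ops$len > 0L
  op <- ops$op[keep]
  len <- ops$len[keep]
  if (length(op) == 0L) {
    return("*")
  }
  # merge adjacent runs of the same op
  grp <- cumsum(c(TRUE, op[-1L] != op[-length(op)]))
  op <- tapply(op, grp, function(x) x[1L])
  len <- tapply(len, grp, sum)
  paste0(len, op, collapse = "")
}

cigar_query_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongQuerySpace(cigar)
}

cigar_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

#' Aligned (reference, query) base pairs of one alignment
#'
#' Projects an alignment onto its per-base correspondence: one row for every
#' query base placed on the reference by an M/=/X operation. Insertions,
#' deletions, skips (N), clips and padding contribute no pairs.
#'
#' @param cigar CIGAR string.
#' @param pos 1-based leftmost reference position of the alignment.
#' @return A tibble with integer columns `ref` and `query` (both 1-based),
#'   in query order.
#' @examples
#' cigar_aligned_pairs("5M3N5M", 101)
#' @export
cigar_aligned_pairs <- function(cigar, pos) {
  ops <- parse_cigar(cigar)
  ref <- as.integer(pos)
  qry <- 1L
  out <- vector("list", nrow(ops))
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]
    len <- ops$len[i]
    if (op %in% ALN_OPS) {
      out[[i]] <- cbind(seq.int(ref, length.out = len),
                        seq.int(qry, length.out = len))
      ref <- ref + len
      qry <- qry + len
    } else if (op %in% c("I", "S")) {
      qry <- qry + len
    } else if (op %in% c("D", "N")) {
      ref <- ref + len
    }
  }
  m <- do.call(rbind, c(out, list(matrix(integer(0), ncol = 2L))))
  tibble(ref = as.integer(m[, 1L]), query = as.integer(m[, 2L]))
}

# Reference-space ranges of selected ops for a vector of alignments.
# Returns a tibble: idx (row index into the input), start, end (1-based closed).
cigar_ref_ranges <- function(cigar, pos, ops = ALN_OPS) {
  rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = as.integer(pos), ops = ops
  )
  n <- S4Vectors::elementNROWS(rl)
  flat <- unlist(rl, use.names = FALSE)
  tibble(
    idx = rep(seq_along(rl), n),
    start = IRanges::start(flat),
    end = IRanges::end(flat)
  )
}
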