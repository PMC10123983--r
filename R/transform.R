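# Splitting spliced alignments at intron (N) CIGAR operations so that each
# exon becomes a distinct, contiguous alignment record, and restoring the
# original read's SAM flag to every fragment. This is the transformation that
# makes spliced long-read RNA-seq BAMs digestible by DNA variant callers:
# generic read splitters leave the primary-alignment flag on only one
# fragment and mark the rest supplementary, which degrades callers downstream.

CLIP_OPS <- c("S", "H")

# Split one record at its N ops. Returns a tibble of fragments (possibly one
# row, the unchanged input when no N is present) with a fragment_index column,
# or signals a condition of class "splicevar_malformed" for rejects.
split_one_alignment <- function(rec) {
  ops <- parse_cigar(rec$cigar)
  reject <- function(msg) {
    abort(sprintf("read '%s': %s", rec$qname, msg),
          class = "splicevar_malformed")
  }
  if (nrow(ops) == 0L) reject("record is unmapped (CIGAR '*')")
  if (ops$op[1L] == "N" || ops$op[nrow(ops)] == "N") {
    reject("CIGAR begins or ends with N")
  }
  if (any(ops$op[-1L] == "N" & ops$op[-nrow(ops)] == "N")) {
    reject("adjacent N operations in CIGAR")
  }
  qw <- sum(ops$len[ops$op %in% QUERY_OPS])
  if (!is.na(rec$seq) && rec$seq != "*" && qw != nchar(rec$seq)) {
    reject(sprintf("CIGAR query length %d != sequence length %d",
                   qw, nchar(rec$seq)))
  }
  nidx <- which(ops$op == "N")
  if (length(nidx) == 0L) {
    out <- as_tibble(rec)
    out$fragment_index <- 0L
    return(out)
  }
  ops <- ops[ops$op != "P", , drop = FALSE]
  nidx <- which(ops$op == "N")

  starts <- c(1L, nidx + 1L)
  ends <- c(nidx - 1L, nrow(ops))
  nseg <- length(starts)
  ref_cursor <- rec$pos
  query_cursor <- 1L
  frags <- vector("list", nseg)
  dropped <- 0L
  has_seq <- !is.na(rec$seq) && rec$seq != "*"
  has_qual <- !is.na(rec$qual) && rec$qual != "*"

  for (s in seq_len(nseg)) {
    seg <- ops[starts[s]:ends[s], , drop = FALSE]
    qspan <- sum(seg$len[seg$op %in% QUERY_OPS])
    # boundary cleanup at N-adjacent edges: D is trimmed (its length shifts
    # the next fragment's start), I becomes soft clip — fragments must open
    # and close on an aligned (M/=/X) op
    if (s > 1L) {
      repeat {
        j <- which(!seg$op %in% CLIP_OPS)[1L]
        if (is.na(j) || seg$op[j] %in% ALN_OPS) break
        if (seg$op[j] == "D") {
          ref_cursor <- ref_cursor + seg$len[j]
          seg <- seg[-j, , drop = FALSE]
        } else if (seg$op[j] == "I") {
          seg$op[j] <- "S"
        } else {
          break
        }
      }
    }
    trailing_ref <- 0L
    if (s < nseg) {
      repeat {
        nonclip <- which(!seg$op %in% CLIP_OPS)
        j <- if (length(nonclip)) nonclip[length(nonclip)] else NA_integer_
        if (is.na(j) || seg$op[j] %in% ALN_OPS) break
        if (seg$op[j] == "D") {
          trailing_ref <- trailing_ref + seg$len[j]
          seg <- seg[-j, , drop = FALSE]
        } else if (seg$op[j] == "I") {
          seg$op[j] <- "S"
        } else {
          break
        }
      }
    }
    if (any(seg$op %in% ALN_OPS)) {
      frag <- rec
      frag$pos <- ref_cursor
      frag$cigar <- cigar_string(seg)
      if (has_seq) {
        frag$seq <- substr(rec$seq, query_cursor, query_cursor + qspan - 1L)
      }
      if (has_qual) {
        frag$qual <- substr(rec$qual, query_cursor, query_cursor + qspan - 1L)
      }
      frags[[s]] <- as_tibble(frag)
    } else {
      dropped <- dropped + 1L
    }
    ref_cursor <- ref_cursor +
      sum(seg$len[seg$op %in% REF_OPS]) + trailing_ref +
      if (s < nseg) ops$len[nidx[s]] else 0L
    query_cursor <- query_cursor + qspan
  }
  out <- bind_rows(frags)
  out$fragment_index <- seq_len(nrow(out)) - 1L
  if ("tags" %in% names(out) && nrow(out) > 0L) {
    out$tags <- vapply(out$tags, strip_nm_md_tags, character(1L))
  }
  attr(out, "empty_fragments") <- dropped
  out
}

strip_nm_md_tags <- function(tags) {
  if (is.na(tags) || tags == "") return(tags)
  fields <- strsplit(tags, "\t", fixed = TRUE)[[1L]]
  keep <- !grepl("^(NM|MD):", fields)
  if (!any(keep)) NA_character_ else paste(fields[keep], collapse = "\t")
}

#' Split spliced alignments at intron (N) CIGAR operations
#'
#' Each record whose CIGAR contains N operations is replaced by one contiguous
#' alignment per exon; records without N pass through unchanged. The query
#' bases (sequence and qualities) are partitioned across fragments in read
#' order, leading clips stay on the first fragment and trailing clips on the
#' last, and every fragment keeps the parent record's flag and read name, so
#' no fragment is demoted to a supplementary alignment. Deletion operations
#' abutting an N are trimmed (shifting the next fragment's start accordingly)
#' and insertions abutting an N become soft clips, so fragments always open
#' and close on an aligned base. Segments left with no aligned base are
#' discarded and counted.
#'
#' @param aln A sam tibble (see [read_alignments()]).
#' @param on_error `"error"` (default) to stop on a malformed record
#'   (query-length mismatch, CIGAR beginning/ending with N), or `"drop"` to
#'   discard such records with a warning.
#' @return A tibble of fragment records with an extra integer column
#'   `fragment_index` (0-based within each parent read). Attributes
#'   `records_rejected` and `empty_fragments` carry counters.
#' @examples
#' aln <- tibble::tibble(
#'   qname = "r1", flag = 0L, rname = "chr1", pos = 101L, mapq = 60L,
#'   cigar = "10M50N10M", seq = strrep("A", 20), qual = strrep("I", 20)
#' )
#' split_spliced_alignments(aln)
#' @export
split_spliced_alignments <- function(aln, on_error = c("error", "drop")) {
  validate_sam_tbl(aln)
  on_error <- match.arg(on_error)
  out <- vector("list", nrow(aln))
  rejected <- 0L
  empty <- 0L
  for (i in seq_len(nrow(aln))) {
    res <- tryCatch(
      split_one_alignment(as.list(aln[i, ])),
      splicevar_malformed = function(cnd) cnd
    )
    if (inherits(res, "condition")) {
      if (on_error == "error") abort(conditionMessage(res))
      warn(paste("rejected:", conditionMessage(res)))
      rejected <- rejected + 1L
    } else {
      empty <- empty + (attr(res, "empty_fragments") %||% 0L)
      out[[i]] <- res
    }
  }
  res <- bind_rows(out)
  attr(res, "records_rejected") <- rejected
  attr(res, "empty_fragments") <- empty
  res
}

#' Restore the original read's flag to every split fragment
#'
#' Read splitters commonly leave the primary-alignment flag on only one
#' fragment of a split read and set the supplementary bit (0x800) on the
#' rest. This pass looks up each fragment's read name in the original
#' (pre-split) records and overwrites the fragment's flag with the original
#' one; nothing else is modified and record order is preserved.
#'
#' @param split A sam tibble of post-split fragment records.
#' @param original A sam tibble with exactly one record per read name
#'   (non-primary alignments already discarded).
#' @return `split` with its `flag` column replaced.
#' @export
correct_flags <- function(split, original) {
  validate_sam_tbl(split)
  validate_sam_tbl(original)
  dup <- unique(original$qname[duplicated(original$qname)])
  if (length(dup) > 0L) {
    abort(sprintf("duplicate read name(s) in `original` (ambiguous source flag): %s",
                  paste(head(dup, 5L), collapse = ", ")))
  }
  m <- match(split$qname, original$qname)
  if (anyNA(m)) {
    miss <- unique(split$qname[is.na(m)])
    abort(sprintf("read name(s) in `split` absent from `original`: %s",
                  paste(head(miss, 5L), collapse = ", ")))
  }
  split$flag <- original$flag[m]
  split
}

#' Transform spliced alignments for DNA variant calling
#'
#' One-pass composition of the two steps a spliced BAM needs before a DNA
#' variant caller will handle it well: split every retained record at its N
#' CIGAR operations and keep the parent's flag on each fragment. Secondary,
#' supplementary and unmapped records are discarded first by default.
#'
#' @inheritParams split_spliced_alignments
#' @param drop_nonprimary Discard secondary/supplementary/unmapped records
#'   before splitting (default `TRUE`).
#' @param mapq_remap Optionally remap MAPQ 255 ("unavailable") to 60; off by
#'   default, MAPQ is otherwise preserved unchanged.
#' @return A coordinate-sorted tibble of fragment records; attribute
#'   `counters` is a named integer vector of run statistics.
#' @export
transform_spliced_alignments <- function(aln, drop_nonprimary = TRUE,
                                         mapq_remap = FALSE,
                                         on_error = c("error", "drop")) {
  validate_sam_tbl(aln)
  n_in <- nrow(aln)
  if (drop_nonprimary) {
    aln <- aln[!flag_is_unmapped(aln$flag) & flag_is_primary(aln$flag), ]
  }
  out <- split_spliced_alignments(aln, on_error = on_error)
  n_rejected <- attr(out, "records_rejected") %||% 0L
  n_empty <- attr(out, "empty_fragments") %||% 0L
  if (mapq_remap && nrow(out) > 0L) {
    out$mapq[out$mapq == 255L] <- 60L
  }
  out <- arrange(out, .data$rname, .data$pos, .data$qname, .data$fragment_index)
  attr(out, "counters") <- c(
    records_in = n_in,
    records_retained = nrow(aln),
    fragments_written = nrow(out),
    records_rejected = n_rejected,
    empty_fragments = n_empty
  )
  out
}

#' File-level spliced-BAM transformation
#'
#' Reads a BAM/SAM, applies [transform_spliced_alignments()], and writes a
#' coordinate-sorted (and, for BAM, indexed) output.
#'
#' @param input,output Paths to `.bam`/`.sam` files.
#' @param refs Optional reference-length tibble passed to
#'   [write_alignments()].
#' @inheritParams transform_spliced_alignments
#' @return The counter vector, invisibly.
#' @export
transform_spliced_bam <- function(input, output, drop_nonprimary = TRUE,
                                  mapq_remap = FALSE, refs = NULL) {
  aln <- read_alignments(input)
  out <- transform_spliced_alignments(aln, drop_nonprimary = drop_nonprimary,
                                      mapq_remap = mapq_remap, on_error = "drop")
  write_alignments(out, output, refs = refs)
  counters <- attr(out, "counters")
  inform(paste(sprintf("%s=%d", names(counters), counters), collapse = " "))
  invisible(counters)
}

#' File-level flag correction
#'
#' Applies [correct_flags()] between an original (pre-split) and a split
#' BAM/SAM. Non-primary and unmapped records of the original are ignored when
#' building the read-name to flag lookup.
#'
#' @param original,split,output Paths to `.bam`/`.sam` files.
#' @param refs Optional reference-length tibble for the output header.
#' @return The output path, invisibly.
#' @export
flag_correct_files <- function(original, split, output, refs = NULL) {
  ori <- read_alignments(original)
  ori <- ori[!flag_is_unmapped(ori$flag) & flag_is_primary(ori$flag), ]
  spl <- read_alignments(split)
  out <- correct_flags(spl, ori)
  write_alignments(out, output, refs = refs)
  invisible(output)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
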