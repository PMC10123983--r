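# Alignment records as a tibble ("sam tibble"): one row per SAM record with
# columns qname, flag, rname, pos (1-based leftmost), mapq, cigar, seq, qual
# and an optional tags column (raw SAM tag fields, tab-separated). File I/O
# goes through Rsamtools; SAM text is converted with asBam on the way in.

SAM_COLS <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")

validate_sam_tbl <- function(aln, arg = "aln") {
  missing <- setdiff(SAM_COLS, names(aln))
  if (length(missing) > 0L) {
    abort(sprintf("`%s` lacks alignment column(s): %s",
                  arg, paste(missing, collapse = ", ")))
  }
  invisible(aln)
}

flag_has <- function(flag, bit) bitwAnd(as.integer(flag), bit) != 0L

#' SAM flag predicates
#'
#' Vectorised tests on SAM bit flags: unmapped (0x4), reverse strand (0x10),
#' secondary (0x100), supplementary (0x800).
#'
#' @param flag Integer vector of SAM flags.
#' @return Logical vector.
#' @export
flag_is_unmapped <- function(flag) flag_has(flag, 4L)

#' @rdname flag_is_unmapped
#' @export
flag_is_reverse <- function(flag) flag_has(flag, 16L)

#' @rdname flag_is_unmapped
#' @export
flag_is_secondary <- function(flag) flag_has(flag, 256L)

#' @rdname flag_is_unmapped
#' @export
flag_is_supplementary <- function(flag) flag_has(flag, 2048L)

#' @rdname flag_is_unmapped
#' @export
flag_is_primary <- function(flag) {
  !flag_is_secondary(flag) & !flag_is_supplementary(flag)
}

#' Read a BAM or SAM file into a tibble of alignment records
#'
#' SAM text input is converted with [Rsamtools::asBam()] first, so it must
#' carry a header. Optional SAM tags are not retrieved; see the package
#' vignette for the tag policy.
#'
#' @param path Path to a `.bam` or `.sam` file.
#' @return A tibble with columns `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `seq`, `qual`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("alignment file not found: %s", path))
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1L]]
  tibble(
    qname = res$qname,
    flag = as.integer(res$flag),
    rname = as.character(res$rname),
    pos = as.integer(res$pos),
    mapq = as.integer(res$mapq),
    cigar = res$cigar,
    seq = as.character(res$seq),
    qual = as.character(res$qual)
  )
}

sam_header_lines <- function(aln, refs = NULL) {
  if (is.null(refs)) {
    mapped <- aln[!is.na(aln$pos) & !is.na(aln$cigar) & aln$cigar != "*", ]
    if (nrow(mapped) == 0L) {
      abort("cannot infer reference lengths from unmapped records; supply `refs`")
    }
    ends <- mapped$pos + cigar_ref_width(mapped$cigar) - 1L
    refs <- mapped |>
      mutate(.end = ends) |>
      group_by(.data$rname) |>
      summarise(length = max(.data$.end), .groups = "drop") |>
      rename(name = "rname")
  }
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", refs$name, as.integer(refs$length)))
}

#' Write alignment records to SAM or BAM
#'
#' A `.bam` destination is produced via SAM text plus [Rsamtools::asBam()]
#' (coordinate-sorted and indexed); a `.sam` destination is written as text.
#'
#' @param aln A sam tibble (see [read_alignments()]); an optional `tags`
#'   column is appended verbatim to each record line.
#' @param path Output path ending in `.sam` or `.bam`.
#' @param refs Optional tibble with columns `name` and `length` for the
#'   `@SQ` header lines; inferred from the records when `NULL`.
#' @return The output path, invisibly.
#' @export
write_alignments <- function(aln, path, refs = NULL) {
  validate_sam_tbl(aln)
  hdr <- sam_header_lines(aln, refs)
  tags <- if ("tags" %in% names(aln)) aln$tags else rep(NA_character_, nrow(aln))
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
    aln$qname, as.integer(aln$flag), aln$rname, as.integer(aln$pos),
    as.integer(aln$mapq), aln$cigar, aln$seq, aln$qual
  )
  has_tags <- !is.na(tags) & tags != ""
  body[has_tags] <- paste(body[has_tags], tags[has_tags], sep = "\t")
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    tmp <- tempfile(fileext = ".sam")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(c(hdr, body), tmp)
    Rsamtools::asBam(tmp, sub("\\.bam$", "", path, ignore.case = TRUE),
                     overwrite = TRUE, indexDestination = TRUE)
  } else {
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}
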