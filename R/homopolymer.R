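# Homopolymer context of indels. Long-read chemistry loses accuracy inside
# single-base runs, so indel benchmarking is stratified by whether the event
# sits inside a homopolymer and by the run length.

#' Locate homopolymer runs in a sequence
#'
#' Maximal runs of a single repeated base with length at least `min_len`.
#'
#' @param seq A single nucleotide string.
#' @param min_len Minimum run length to report (default 3).
#' @return A tibble with `base`, `start`, `end` (1-based closed), `length`.
#' @examples
#' homopolymer_runs("ACGTTTTTGA")
#' @export
homopolymer_runs <- function(seq, min_len = 3L) {
  stopifnot(length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_len
  tibble(
    base = r$values[keep],
    start = starts[keep],
    end = ends[keep],
    length = r$lengths[keep]
  )
}

#' Homopolymer context of indel variants
#'
#' Classifies each indel as inside a homopolymer run (`hp`, with the run
#' length) or not (`non_hp`). A deletion is in a run when every deleted base
#' lies inside it; an insertion when its insertion point is inside or
#' immediately flanks the run and every inserted base equals the run base.
#' Records should be normalized (anchored, left-aligned; see
#' [normalize_variants()]) first. SNP or MNP input is an error — the
#' homopolymer stratification is defined for indels.
#'
#' @param variants A vcf tibble of indels, one alt per row.
#' @param ref_seq Named character vector (or coercible) of reference
#'   sequences keyed by chrom.
#' @param min_len Minimum homopolymer length (default 3).
#' @return `variants` with `hp_class` (`"non_hp"` or `"hp"`) and `hp_len`
#'   (run length, `NA` for `non_hp`) appended.
#' @export
homopolymer_context <- function(variants, ref_seq, min_len = 3L) {
  validate_vcf_tbl(variants)
  ref_seq <- as_ref_seq(ref_seq)
  is_ins <- nchar(variants$alt) > nchar(variants$ref)
  is_del <- nchar(variants$ref) > nchar(variants$alt)
  if (any(!is_ins & !is_del)) {
    abort("non-indel record(s) supplied; the homopolymer context is defined for indels only")
  }
  runs_by_chrom <- lapply(
    setNames(nm = unique(variants$chrom)),
    function(chr) {
      if (!chr %in% names(ref_seq)) {
        abort(sprintf("no reference sequence for chrom '%s'", chr))
      }
      homopolymer_runs(ref_seq[[chr]], min_len = min_len)
    }
  )
  variants$hp_class <- "non_hp"
  variants$hp_len <- NA_integer_
  for (i in seq_len(nrow(variants))) {
    runs <- runs_by_chrom[[variants$chrom[i]]]
    if (nrow(runs) == 0L) next
    pos <- variants$pos[i]
    if (is_del[i]) {
      event <- str_sub(variants$ref[i], nchar(variants$alt[i]) + 1L)
      from <- pos + nchar(variants$alt[i])
      to <- from + nchar(event) - 1L
      hit <- runs[runs$start <= from & runs$end >= to, , drop = FALSE]
    } else {
      event <- str_sub(variants$alt[i], nchar(variants$ref[i]) + 1L)
      bases <- unique(strsplit(toupper(event), "", fixed = TRUE)[[1L]])
      anchor <- pos + nchar(variants$ref[i]) - 1L  # insertion after this base
      hit <- runs[length(bases) == 1L & runs$base == bases[1L] &
                    runs$start - 1L <= anchor & anchor <= runs$end, , drop = FALSE]
    }
    if (nrow(hit) > 0L) {
      variants$hp_class[i] <- "hp"
      variants$hp_len[i] <- max(hit$length)
    }
  }
  variants
}
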