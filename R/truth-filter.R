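# Construction of the high-confidence truth set: drop variant-dense windows
# (mapping/assembly artifacts), require the site to be expressed (long-read
# exonic coverage), and bound the short-read DNA coverage (fixed thresholds
# or percentiles of the per-site depth distribution).

#' Remove variants in dense windows
#'
#' A variant is removed iff some window of `window` consecutive bases
#' containing it holds more than `max_vars` variants — equivalently, iff it
#' belongs to a run of at least `max_vars + 1` variants whose positional span
#' is at most `window - 1`. Chromosomes are evaluated independently.
#'
#' @param variants A vcf tibble.
#' @param window Window width in bp (default 201).
#' @param max_vars Maximum variants tolerated per window (default 3).
#' @return A list of tibbles `kept` and `removed`.
#' @export
density_filter <- function(variants, window = 201L, max_vars = 3L) {
  validate_vcf_tbl(variants)
  removed <- rep(FALSE, nrow(variants))
  for (chr in unique(variants$chrom)) {
    idx <- which(variants$chrom == chr)
    ord <- idx[order(variants$pos[idx])]
    pos <- variants$pos[ord]
    n <- length(pos)
    j <- 1L
    for (i in seq_len(n)) {
      if (j < i) j <- i
      while (j < n && pos[j + 1L] <= pos[i] + window - 1L) j <- j + 1L
      if (j - i + 1L > max_vars) removed[ord[i:j]] <- TRUE
    }
  }
  list(kept = variants[!removed, ], removed = variants[removed, ])
}

# Nearest-rank percentile: the smallest value with at least p% of the data
# at or below it.
nearest_rank <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 0L) abort("percentile of an empty depth distribution")
  x[min(n, max(1L, ceiling(p / 100 * n)))]
}

#' Depth of a coverage track at sites
#'
#' @param track A tibble (`chrom`, `start`, `end`, `depth`) of
#'   non-overlapping 1-based closed intervals; uncovered positions have
#'   depth 0.
#' @param sites A tibble with `chrom` and `pos`.
#' @return Integer vector of depths, one per site.
#' @export
track_depth_at <- function(track, sites) {
  validate_sites(sites)
  out <- integer(nrow(sites))
  for (chr in unique(sites$chrom)) {
    s_idx <- which(sites$chrom == chr)
    sub <- track[track$chrom == chr, , drop = FALSE]
    if (nrow(sub) == 0L) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(sites$pos[s_idx], width = 1L),
      IRanges::IRanges(sub$start, sub$end)
    )
    out[s_idx[S4Vectors::queryHits(hits)]] <- sub$depth[S4Vectors::subjectHits(hits)]
  }
  out
}

#' Per-base coverage track of contiguous aligned bases
#'
#' Depth of aligned (M/=/X) bases per position, as run-length intervals.
#'
#' @param aln A sam tibble.
#' @return A tibble (`chrom`, `start`, `end`, `depth`), zero-depth runs
#'   omitted.
#' @export
coverage_track <- function(aln) {
  validate_sam_tbl(aln)
  aln <- mapped_only(aln)
  out <- list()
  for (chr in unique(aln$rname)) {
    sub <- aln[aln$rname == chr, , drop = FALSE]
    mb <- cigar_ref_ranges(sub$cigar, sub$pos, ALN_OPS)
    cov <- IRanges::coverage(IRanges::IRanges(mb$start, mb$end))
    ends <- cumsum(S4Vectors::runLength(cov))
    starts <- ends - S4Vectors::runLength(cov) + 1L
    depth <- S4Vectors::runValue(cov)
    keep <- depth > 0L
    out[[chr]] <- tibble(chrom = chr, start = starts[keep],
                         end = ends[keep], depth = depth[keep])
  }
  bind_rows(out)
}

#' Coverage-based truth filters
#'
#' Keeps a variant iff its short-read depth lies within `[min_cov, max_cov]`
#' (inclusive on both ends) and, when long-read alignments are given, its
#' long-read exonic coverage is at least `min_lr_cov`. Bounds may be supplied
#' directly or as nearest-rank percentiles (`min_pctl`/`max_pctl`) of the
#' per-variant-site depth distribution. Sites outside the track have depth 0.
#'
#' @param variants A vcf tibble.
#' @param sr_track Short-read coverage track (see [coverage_track()]).
#' @param min_cov,max_cov Inclusive depth bounds (`NULL` to skip).
#' @param min_pctl,max_pctl Percentile alternatives to the fixed bounds.
#' @param lr_aln Optional sam tibble of long-read spliced alignments.
#' @param min_lr_cov Minimum long-read exonic coverage (default 1).
#' @return A list `kept`/`removed` of tibbles, each with `sr_depth` (and
#'   `lr_exonic_cov` when `lr_aln` is given) appended, plus the resolved
#'   `bounds`.
#' @export
coverage_filters <- function(variants, sr_track, min_cov = NULL, max_cov = NULL,
                             min_pctl = NULL, max_pctl = NULL,
                             lr_aln = NULL, min_lr_cov = 1L) {
  validate_vcf_tbl(variants)
  variants$sr_depth <- track_depth_at(sr_track, variants)
  if (!is.null(min_pctl)) min_cov <- nearest_rank(variants$sr_depth, min_pctl)
  if (!is.null(max_pctl)) max_cov <- nearest_rank(variants$sr_depth, max_pctl)
  keep <- rep(TRUE, nrow(variants))
  if (!is.null(min_cov)) keep <- keep & variants$sr_depth >= min_cov
  if (!is.null(max_cov)) keep <- keep & variants$sr_depth <= max_cov
  if (!is.null(lr_aln)) {
    prof <- site_read_profile(lr_aln, variants[, c("chrom", "pos")])
    variants$lr_exonic_cov <- prof$exonic_cov
    keep <- keep & variants$lr_exonic_cov >= min_lr_cov
  }
  list(kept = variants[keep, ], removed = variants[!keep, ],
       bounds = c(min_cov = min_cov %||% NA, max_cov = max_cov %||% NA))
}

#' High-confidence truth-set cascade
#'
#' Applies, in order: the dense-window filter, the long-read exonic coverage
#' requirement, and the short-read coverage bounds. The filters are
#' conjunctive, so the final kept set does not depend on the order; the
#' cascade is reported for inspection of how many sites each successive
#' filter retains.
#'
#' @inheritParams coverage_filters
#' @inheritParams density_filter
#' @return A list with `kept` (the surviving vcf tibble) and `cascade`
#'   (tibble of `step`, `n_kept`).
#' @export
truth_filter <- function(variants, lr_aln, sr_track,
                         window = 201L, max_vars = 3L,
                         min_cov = 20L, max_cov = NULL,
                         min_pctl = NULL, max_pctl = NULL, min_lr_cov = 1L) {
  validate_vcf_tbl(variants)
  steps <- list(all_variants = variants)
  dens <- density_filter(variants, window = window, max_vars = max_vars)
  steps$low_density <- dens$kept
  lr <- coverage_filters(dens$kept, sr_track = tibble(
    chrom = character(0), start = integer(0), end = integer(0), depth = integer(0)
  ), lr_aln = lr_aln, min_lr_cov = min_lr_cov)
  steps$exonic <- lr$kept
  cf <- coverage_filters(lr$kept, sr_track = sr_track,
                         min_cov = min_cov, max_cov = max_cov,
                         min_pctl = min_pctl, max_pctl = max_pctl)
  steps$high_coverage <- cf$kept
  list(
    kept = cf$kept,
    cascade = tibble(step = names(steps), n_kept = vapply(steps, nrow, 0L))
  )
}
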