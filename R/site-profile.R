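# Per-site read profiles over spliced alignments. "Coverage" here always
# means exonic coverage: a read counts toward a site's coverage only when an
# aligned (M/=/X) base covers it; a read whose N operation (intron) spans the
# site is an intron-containing (N-cigar) read and counts toward n_span_count
# instead. The proportion of N-cigar reads among all reads overlapping a site
# is the quantity that predicts degraded variant calling there.

mapped_only <- function(aln) {
  aln[!is.na(aln$pos) & !is.na(aln$cigar) & aln$cigar != "*", , drop = FALSE]
}

validate_sites <- function(sites, arg = "sites") {
  missing <- setdiff(c("chrom", "pos"), names(sites))
  if (length(missing) > 0L) {
    abort(sprintf("`%s` lacks column(s): %s", arg,
                  paste(missing, collapse = ", ")))
  }
  if (any(sites$pos < 1L)) abort("site positions must be >= 1")
  invisible(sites)
}

#' Exonic coverage and intron-containing-read proportion at sites
#'
#' For each site, counts reads whose aligned (M/=/X) bases cover the position
#' (`exonic_cov`) and reads whose N operation spans it (`n_span_count`);
#' reads not overlapping the position count toward neither.
#' `n_cigar_proportion` is `n_span_count / (exonic_cov + n_span_count)`,
#' `NA` when no read overlaps the site.
#'
#' @param aln A sam tibble of spliced alignments.
#' @param sites A tibble with columns `chrom` and `pos` (1-based).
#' @param refs Optional tibble (`name`, `length`); when given, sites beyond
#'   the reference bounds raise an error.
#' @return `sites` with `exonic_cov`, `n_span_count` and
#'   `n_cigar_proportion` appended.
#' @export
site_read_profile <- function(aln, sites, refs = NULL) {
  validate_sam_tbl(aln)
  validate_sites(sites)
  if (!is.null(refs)) {
    lens <- setNames(as.integer(refs$length), refs$name)
    bad <- is.na(lens[sites$chrom]) | sites$pos > lens[sites$chrom]
    if (any(bad)) {
      abort(sprintf("site(s) beyond reference bounds: %s",
                    paste(head(paste0(sites$chrom, ":", sites$pos)[bad], 5L),
                          collapse = ", ")))
    }
  }
  aln <- mapped_only(aln)
  sites$exonic_cov <- 0L
  sites$n_span_count <- 0L
  for (chr in unique(sites$chrom)) {
    s_idx <- which(sites$chrom == chr)
    sub <- aln[aln$rname == chr, , drop = FALSE]
    if (nrow(sub) == 0L) next
    q <- IRanges::IRanges(sites$pos[s_idx], width = 1L)
    mb <- cigar_ref_ranges(sub$cigar, sub$pos, ALN_OPS)
    nb <- cigar_ref_ranges(sub$cigar, sub$pos, "N")
    sites$exonic_cov[s_idx] <- IRanges::countOverlaps(
      q, IRanges::IRanges(mb$start, mb$end))
    sites$n_span_count[s_idx] <- IRanges::countOverlaps(
      q, IRanges::IRanges(nb$start, nb$end))
  }
  denom <- sites$exonic_cov + sites$n_span_count
  sites$n_cigar_proportion <- ifelse(denom > 0L, sites$n_span_count / denom, NA_real_)
  sites
}

#' Splice-junction proximity of sites
#'
#' A site is near a splice junction when, among the reads exonically covering
#' it, at least `min_frac` share the same junction (identical intron start
#' and end) and the site lies within `max_dist` bases of that junction's
#' nearest exonic edge. For each site the best-supported junction within
#' `max_dist` is reported (falling back to the best-supported junction
#' overall when none is that close); sites with no covering reads get
#' `near = FALSE` with `supporting_fraction = 0`.
#'
#' @inheritParams site_read_profile
#' @param max_dist Maximum distance in bp from site to the junction's exonic
#'   edge (default 20).
#' @param min_frac Minimum fraction of covering reads sharing the junction
#'   (default 0.5).
#' @return `sites` with `near`, `intron_start`, `intron_end`, `distance_bp`,
#'   `supporting_fraction` and `n_covering` appended. Intron coordinates are
#'   1-based closed.
#' @export
near_splice_junction <- function(aln, sites, max_dist = 20L, min_frac = 0.5) {
  validate_sam_tbl(aln)
  validate_sites(sites)
  aln <- mapped_only(aln)
  n <- nrow(sites)
  out <- tibble(
    near = logical(n), intron_start = NA_integer_, intron_end = NA_integer_,
    distance_bp = NA_integer_, supporting_fraction = 0, n_covering = 0L
  )
  for (chr in unique(sites$chrom)) {
    sub <- aln[aln$rname == chr, , drop = FALSE]
    if (nrow(sub) == 0L) next
    mb <- cigar_ref_ranges(sub$cigar, sub$pos, ALN_OPS)
    nb <- cigar_ref_ranges(sub$cigar, sub$pos, "N")
    for (i in which(sites$chrom == chr)) {
      p <- sites$pos[i]
      covering <- unique(mb$idx[mb$start <= p & mb$end >= p])
      out$n_covering[i] <- length(covering)
      if (length(covering) == 0L) next
      jx <- nb[nb$idx %in% covering, , drop = FALSE]
      if (nrow(jx) == 0L) next
      jx <- distinct(jx)  # one vote per read per junction
      tallied <- jx |>
        count(.data$start, .data$end, name = "support") |>
        mutate(
          fraction = .data$support / length(covering),
          distance = pmin(abs(p - (.data$start - 1L)), abs(p - (.data$end + 1L)))
        )
      in_reach <- tallied[tallied$distance <= max_dist, , drop = FALSE]
      best <- if (nrow(in_reach) > 0L) in_reach else tallied
      best <- best[order(-best$fraction, best$distance), ][1L, ]
      out$intron_start[i] <- best$start
      out$intron_end[i] <- best$end
      out$distance_bp[i] <- best$distance
      out$supporting_fraction[i] <- best$fraction
      out$near[i] <- best$fraction >= min_frac && best$distance <= max_dist
    }
  }
  bind_cols(sites, out)
}

#' Per-allele read counts at heterozygous SNP sites
#'
#' Counts, at each biallelic SNP site, aligned query bases equal to the
#' reference and to the alternative allele with base quality at least
#' `min_baseq`. Bases matching neither allele, N bases, low-quality bases and
#' reads whose deletion or intron spans the site contribute to neither count.
#' Sites with indel alleles are skipped with a message.
#'
#' @param aln A sam tibble (typically of contiguous short-read alignments).
#' @param sites A tibble with `chrom`, `pos`, `ref`, `alt` (single-base
#'   alleles).
#' @param min_baseq Minimum Phred base quality (default 20).
#' @return The SNP rows of `sites` with `ref_count` and `alt_count` appended.
#' @export
allele_counts <- function(aln, sites, min_baseq = 20L) {
  validate_sam_tbl(aln)
  validate_sites(sites)
  if (!all(c("ref", "alt") %in% names(sites))) {
    abort("`sites` must carry `ref` and `alt` allele columns")
  }
  is_snp <- nchar(sites$ref) == 1L & nchar(sites$alt) == 1L
  if (any(!is_snp)) {
    inform(sprintf("skipping %d site(s) with indel alleles", sum(!is_snp)))
    sites <- sites[is_snp, , drop = FALSE]
  }
  aln <- mapped_only(aln)
  sites$ref_count <- 0L
  sites$alt_count <- 0L
  for (chr in unique(sites$chrom)) {
    sub <- aln[aln$rname == chr, , drop = FALSE]
    if (nrow(sub) == 0L) next
    ref_end <- sub$pos + cigar_ref_width(sub$cigar) - 1L
    for (i in which(sites$chrom == chr)) {
      p <- sites$pos[i]
      cand <- which(sub$pos <= p & ref_end >= p)
      refn <- altn <- 0L
      for (r in cand) {
        pairs <- cigar_aligned_pairs(sub$cigar[r], sub$pos[r])
        qp <- pairs$query[pairs$ref == p]
        if (length(qp) == 0L) next  # intron or deletion spans the site
        base <- toupper(substr(sub$seq[r], qp, qp))
        bq <- utf8ToInt(substr(sub$qual[r], qp, qp)) - 33L
        if (is.na(bq) || bq < min_baseq) next
        if (base == toupper(sites$ref[i])) refn <- refn + 1L
        else if (base == toupper(sites$alt[i])) altn <- altn + 1L
      }
      sites$ref_count[i] <- refn
      sites$alt_count[i] <- altn
    }
  }
  sites
}
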