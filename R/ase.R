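# Allele-specific expression (ASE) calls from per-allele read counts.
# A site whose two alleles are expressed unequally is detected with a
# chi-squared goodness-of-fit test of equal allele frequencies, corrected
# across sites by Benjamini-Hochberg; such sites are a known blind spot for
# RNA-seq-based variant calling because the low-expression allele yields few
# reads.

#' Chi-squared goodness-of-fit statistic for allelic balance
#'
#' For counts `(ref, alt)` with `n = ref + alt`, the statistic against the
#' balanced 1:1 expectation is
#' `(ref - n/2)^2 / (n/2) + (alt - n/2)^2 / (n/2)`, with 1 degree of freedom.
#'
#' @param ref_count,alt_count Non-negative integer vectors.
#' @return Numeric vector of statistics (`NA` where `n == 0`).
#' @examples
#' allele_balance_chi2(30, 10)  # 10
#' @export
allele_balance_chi2 <- function(ref_count, alt_count) {
  n <- ref_count + alt_count
  e <- n / 2
  ifelse(n > 0, (ref_count - e)^2 / e + (alt_count - e)^2 / e, NA_real_)
}

#' Classify sites as allele-specifically expressed
#'
#' Applies the chi-squared goodness-of-fit test of equal reference and
#' alternative allele frequencies independently at each site, corrects the
#' p-values with Benjamini-Hochberg across the tested sites, and flags sites
#' with `q < alpha` as ASE. Sites below the short-read count floor
#' (`ref_count + alt_count < min_sr_cov`) or, when an `lr_cov` column is
#' present, below the long-read exonic coverage floor (`lr_cov <
#' min_lr_cov`), are excluded before testing and get `NA` statistics; the BH
#' pass runs only over the tested sites.
#'
#' @param counts A tibble with `ref_count` and `alt_count` (e.g. from
#'   [allele_counts()]) and optionally `lr_cov`.
#' @param alpha FDR threshold (default 0.05).
#' @param min_sr_cov Minimum total allele count (default 40).
#' @param min_lr_cov Minimum long-read exonic coverage (default 20; only
#'   applied when `counts$lr_cov` exists).
#' @return `counts` with `n`, `tested`, `chi2`, `p`, `q`, `is_ase` appended.
#' @export
ase_classify <- function(counts, alpha = 0.05, min_sr_cov = 40L,
                         min_lr_cov = 20L) {
  if (!all(c("ref_count", "alt_count") %in% names(counts))) {
    abort("`counts` must carry `ref_count` and `alt_count` columns")
  }
  if (any(counts$ref_count < 0 | counts$alt_count < 0)) {
    abort("allele counts must be non-negative")
  }
  counts$n <- counts$ref_count + counts$alt_count
  tested <- counts$n >= min_sr_cov & counts$n > 0L
  if ("lr_cov" %in% names(counts)) {
    tested <- tested & !is.na(counts$lr_cov) & counts$lr_cov >= min_lr_cov
  }
  counts$tested <- tested
  counts$chi2 <- NA_real_
  counts$p <- NA_real_
  counts$q <- NA_real_
  counts$chi2[tested] <- allele_balance_chi2(counts$ref_count[tested],
                                             counts$alt_count[tested])
  counts$p[tested] <- pchisq(counts$chi2[tested], df = 1L, lower.tail = FALSE)
  counts$q[tested] <- p.adjust(counts$p[tested], method = "BH")
  counts$is_ase <- counts$q < alpha
  counts
}
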