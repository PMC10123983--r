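# Variant records as a tibble ("vcf tibble"): chrom, pos (1-based), id, ref,
# alt (comma-separated for multiallelic sites), qual, filter, gt. Reading goes
# through vcfR; writing emits plain-text single-sample VCF 4.2.

VCF_COLS <- c("chrom", "pos", "ref", "alt", "qual")

validate_vcf_tbl <- function(x, arg = "variants") {
  missing <- setdiff(VCF_COLS, names(x))
  if (length(missing) > 0L) {
    abort(sprintf("`%s` lacks variant column(s): %s",
                  arg, paste(missing, collapse = ", ")))
  }
  invisible(x)
}

#' Read a VCF file into a tibble of variant records
#'
#' Single-sample VCFs only; the first sample's GT is extracted when present.
#'
#' @param path Path to a `.vcf` or `.vcf.gz` file.
#' @return A tibble with columns `chrom`, `pos`, `id`, `ref`, `alt`, `qual`,
#'   `filter`, `gt`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(sprintf("VCF not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- rep(NA_character_, nrow(fix))
  if (ncol(v@gt) >= 2L) {
    gt <- vcfR::extract.gt(v, element = "GT")[, 1L]
  }
  tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    id = fix$ID,
    ref = fix$REF,
    alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    filter = fix$FILTER,
    gt = unname(gt)
  )
}

#' Write a tibble of variant records as a plain-text VCF
#'
#' @param variants A vcf tibble (see [read_vcf()]).
#' @param path Output path.
#' @param contigs Optional tibble with `name` and `length` columns for
#'   `##contig` header lines.
#' @param sample Sample name for the genotype column.
#' @return The path, invisibly.
#' @export
write_vcf <- function(variants, path, contigs = NULL, sample = "sample1") {
  validate_vcf_tbl(variants)
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          contigs$name, as.integer(contigs$length)))
  }
  has_gt <- "gt" %in% names(variants) && any(!is.na(variants$gt))
  col_line <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", if (has_gt) c("FORMAT", sample)),
                    collapse = "\t")
  fmt_or_dot <- function(x, d = ".") ifelse(is.na(x), d, as.character(x))
  id <- if ("id" %in% names(variants)) variants$id else NA_character_
  flt <- if ("filter" %in% names(variants)) variants$filter else NA_character_
  body <- paste(
    variants$chrom, variants$pos, fmt_or_dot(id), variants$ref, variants$alt,
    fmt_or_dot(variants$qual), fmt_or_dot(flt, "PASS"), ".",
    sep = "\t"
  )
  if (has_gt) {
    body <- paste(body, "GT", fmt_or_dot(variants$gt, "./."), sep = "\t")
  }
  writeLines(c(hdr, col_line, body), path)
  invisible(path)
}

# Parse a GT string like "0/1" or "1|2" into integer allele indices (NA for .)
parse_gt <- function(gt) {
  if (is.na(gt) || gt == "") return(integer(0))
  parts <- strsplit(gt, "[/|]")[[1L]]
  suppressWarnings(as.integer(parts))
}

classify_one <- function(ref, alt, gt) {
  alts <- strsplit(alt, ",", fixed = TRUE)[[1L]]
  idx <- parse_gt(gt)
  called <- unique(idx[!is.na(idx) & idx > 0L])
  if (length(called) == 0L) called <- 1L  # no genotype: classify the first alt
  if (length(called) >= 2L) return("het_alt")
  a <- alts[called]
  if (is.na(a) || grepl("[<>\\[\\]]", a) || a == "*") return("other")
  if (nchar(ref) == 1L && nchar(a) == 1L) return("snp")
  if (nchar(ref) == nchar(a)) return("mnp")
  if (nchar(a) > nchar(ref) && str_sub(a, 1L, 1L) == str_sub(ref, 1L, 1L)) {
    return("insertion")
  }
  if (nchar(ref) > nchar(a) && str_sub(ref, 1L, 1L) == str_sub(a, 1L, 1L)) {
    return("deletion")
  }
  "other"
}

#' Classify variant records by type
#'
#' Assigns each record one of `snp`, `insertion`, `deletion`, `mnp`,
#' `het_alt`, `other`. A genotype carrying two distinct non-reference alleles
#' is `het_alt` regardless of the allele shapes (these records are ambiguous
#' between types and are filtered out of type-stratified analyses). Symbolic
#' alleles and breakends are `other`.
#'
#' @param variants A vcf tibble.
#' @return `variants` with a `type_class` character column appended.
#' @examples
#' v <- tibble::tibble(chrom = "chr1", pos = 100L, ref = "A",
#'                     alt = "AT", qual = 30, gt = "1/1")
#' classify_variants(v)$type_class
#' @export
classify_variants <- function(variants) {
  validate_vcf_tbl(variants)
  gt <- if ("gt" %in% names(variants)) variants$gt else rep(NA_character_, nrow(variants))
  variants$type_class <- vapply(
    seq_len(nrow(variants)),
    function(i) classify_one(variants$ref[i], variants$alt[i], gt[i]),
    character(1L)
  )
  variants
}

#' QUAL-filter and partition a callset into SNPs and indels
#'
#' Records below the QUAL threshold are dropped (the comparison is inclusive:
#' a record is kept iff `qual >= min_qual`). The survivors are partitioned by
#' [classify_variants()]: SNPs, indels (insertions and deletions), and a rest
#' bucket holding MNPs, heterozygous-alternative and other records.
#'
#' @param variants A vcf tibble.
#' @param min_qual QUAL threshold (default 15).
#' @return A list of tibbles `snps`, `indels`, `other`, `dropped`, each with
#'   `type_class` appended.
#' @export
filter_and_partition <- function(variants, min_qual = 15) {
  validate_vcf_tbl(variants)
  variants <- classify_variants(variants)
  if (anyNA(variants$qual)) {
    inform(sprintf("%d record(s) with missing QUAL treated as 0",
                   sum(is.na(variants$qual))))
    variants$qual[is.na(variants$qual)] <- 0
  }
  dropped <- variants[variants$qual < min_qual, ]
  kept <- variants[variants$qual >= min_qual, ]
  list(
    snps = kept[kept$type_class == "snp", ],
    indels = kept[kept$type_class %in% c("insertion", "deletion"), ],
    other = kept[!kept$type_class %in% c("snp", "insertion", "deletion"), ],
    dropped = dropped
  )
}

#' Merge SNP and indel callsets with QUAL-based same-site deduplication
#'
#' Combines SNPs called from the unmodified spliced BAM with indels called
#' from the split/flag-corrected BAM into a single callset (the "mixed"
#' calling strategy). When both callsets report a variant at the same
#' (chrom, pos), only the record with the higher QUAL survives; at equal QUAL
#' the SNP is kept (documented tie-break). The output is sorted by position
#' and position-unique.
#'
#' @param snps,indels vcf tibbles (typically from [filter_and_partition()]).
#' @return A tibble with a `source` column (`"snp"`/`"indel"`), sorted by
#'   `(chrom, pos)`, with at most one record per position.
#' @export
clair3_mix <- function(snps, indels) {
  validate_vcf_tbl(snps, "snps")
  validate_vcf_tbl(indels, "indels")
  merged <- bind_rows(
    mutate(snps, source = "snp"),
    mutate(indels, source = "indel")
  )
  if (nrow(merged) == 0L) return(merged)
  merged |>
    mutate(.pref = ifelse(.data$source == "snp", 1L, 0L)) |>
    group_by(.data$chrom, .data$pos) |>
    arrange(desc(.data$qual), desc(.data$.pref), .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    select(-".pref") |>
    arrange(.data$chrom, .data$pos)
}

#' File-level SNP/indel mixed merge
#'
#' Reads two VCFs, keeps SNPs (QUAL-filtered) from the first and indels from
#' the second, merges them with [clair3_mix()] and writes the result.
#'
#' @param snp_vcf,indel_vcf,output VCF paths.
#' @param min_qual QUAL threshold applied to both callsets before merging;
#'   `0` disables filtering.
#' @return The merged tibble, invisibly.
#' @export
clair3_mix_files <- function(snp_vcf, indel_vcf, output, min_qual = 0) {
  snps <- filter_and_partition(read_vcf(snp_vcf), min_qual)$snps
  indels <- filter_and_partition(read_vcf(indel_vcf), min_qual)$indels
  merged <- clair3_mix(snps, indels)
  write_vcf(merged, output)
  invisible(merged)
}

# name-preserving coercion of a reference container (named character vector,
# DNAStringSet, list) to a named character vector
as_ref_seq <- function(ref_seq) {
  nm <- names(ref_seq)
  out <- as.character(ref_seq)
  names(out) <- nm
  out
}

normalize_one <- function(chrom, pos, ref, alt, ref_seq) {
  get_base <- function(p) str_sub(ref_seq, p, p)
  span <- str_sub(ref_seq, pos, pos + nchar(ref) - 1L)
  if (!identical(toupper(span), toupper(ref))) {
    abort(sprintf(
      "record %s:%d REF '%s' does not match the reference context '%s'",
      chrom, pos, ref, span))
  }
  repeat {
    rn <- nchar(ref); an <- nchar(alt)
    if (rn > 0L && an > 0L &&
        str_sub(ref, rn, rn) == str_sub(alt, an, an) &&
        (rn > 1L || an > 1L)) {
      if ((rn == 1L || an == 1L) && pos == 1L) {
        break  # already at the contig start; cannot shift further left
      }
      ref <- str_sub(ref, 1L, rn - 1L)
      alt <- str_sub(alt, 1L, an - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        pos <- pos - 1L
        b <- get_base(pos)
        ref <- paste0(b, ref)
        alt <- paste0(b, alt)
      }
    } else if (nchar(ref) > 1L && nchar(alt) > 1L &&
               str_sub(ref, 1L, 1L) == str_sub(alt, 1L, 1L)) {
      ref <- str_sub(ref, 2L)
      alt <- str_sub(alt, 2L)
      pos <- pos + 1L
    } else {
      break
    }
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalize variant records against their reference context
#'
#' Trims shared trailing then leading bases (always keeping at least one
#' reference base) and left-aligns indels to their earliest equivalent
#' position, the canonical representation used for callset/truth matching.
#' Multiallelic records must be split to one alt per row first (see
#' [tidyr::separate_rows()]).
#'
#' @param variants A vcf tibble with a single alt allele per row.
#' @param ref_seq Named character vector (or coercible, e.g. a
#'   `Biostrings::DNAStringSet`) of reference sequences keyed by chrom.
#' @return `variants` with `pos`, `ref`, `alt` normalized.
#' @export
normalize_variants <- function(variants, ref_seq) {
  validate_vcf_tbl(variants)
  ref_seq <- as_ref_seq(ref_seq)
  if (any(grepl(",", variants$alt, fixed = TRUE))) {
    abort("multiallelic rows present; split alt alleles to one per row first")
  }
  bad <- setdiff(unique(variants$chrom), names(ref_seq))
  if (length(bad) > 0L) {
    abort(sprintf("no reference sequence for: %s", paste(bad, collapse = ", ")))
  }
  for (i in seq_len(nrow(variants))) {
    n <- normalize_one(variants$chrom[i], variants$pos[i],
                       variants$ref[i], variants$alt[i],
                       ref_seq[[variants$chrom[i]]])
    variants$pos[i] <- n$pos
    variants$ref[i] <- n$ref
    variants$alt[i] <- n$alt
  }
  variants
}
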