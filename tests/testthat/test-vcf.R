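# Variant classification, QUAL filtering, the SNP/indel mixed merge, and
# normalization.

vt <- function(pos, ref, alt, qual = 30, gt = "0/1", chrom = "chr1") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), id = NA_character_,
                 ref = ref, alt = alt, qual = qual, filter = "PASS", gt = gt)
}

test_that("variant types classify by allele shape and genotype", {
  expect_equal(classify_variants(vt(100, "A", "G"))$type_class, "snp")
  expect_equal(classify_variants(vt(100, "A", "AT", gt = "1/1"))$type_class,
               "insertion")
  expect_equal(classify_variants(vt(100, "AT", "A"))$type_class, "deletion")
  expect_equal(classify_variants(vt(100, "AT", "GC"))$type_class, "mnp")
  expect_equal(classify_variants(vt(100, "A", "G,AT", gt = "1/2"))$type_class,
               "het_alt")
  expect_equal(classify_variants(vt(100, "A", "<DEL>"))$type_class, "other")
})

test_that("the QUAL threshold is inclusive at 15", {
  recs <- dplyr::bind_rows(vt(100, "A", "G", qual = 14.9),
                           vt(200, "A", "G", qual = 15.0),
                           vt(300, "A", "G", qual = 30))
  parts <- filter_and_partition(recs, min_qual = 15)
  expect_equal(parts$dropped$pos, 100L)
  expect_equal(parts$snps$pos, c(200L, 300L))
})

test_that("partitioning conserves the record count", {
  set.seed(11)
  n <- 100
  recs <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    kind <- sample(c("snp", "ins", "del", "het_alt"), 1)
    switch(kind,
      snp = vt(i * 10, "A", "G", qual = runif(1, 0, 40)),
      ins = vt(i * 10, "A", "ATT", qual = runif(1, 0, 40), gt = "1/1"),
      del = vt(i * 10, "ATT", "A", qual = runif(1, 0, 40)),
      het_alt = vt(i * 10, "A", "G,T", qual = runif(1, 0, 40), gt = "1/2")
    )
  }))
  parts <- filter_and_partition(recs, min_qual = 15)
  expect_equal(
    nrow(parts$snps) + nrow(parts$indels) + nrow(parts$other) + nrow(parts$dropped),
    n
  )
  expect_true(all(parts$dropped$qual < 15))
  expect_true(all(parts$snps$qual >= 15))
})

test_that("missing QUAL is treated as zero with a message", {
  recs <- vt(100, "A", "G", qual = NA_real_)
  expect_message(parts <- filter_and_partition(recs, 15), "missing QUAL")
  expect_equal(nrow(parts$dropped), 1L)
})

test_that("same-site collisions keep the higher-QUAL record, SNP on ties", {
  snps <- vt(500, "A", "G", qual = 20)
  indels <- vt(500, "A", "AT", qual = 10)
  out <- clair3_mix(snps, indels)
  expect_equal(nrow(out), 1L)
  expect_equal(out$source, "snp")

  out2 <- clair3_mix(vt(500, "A", "G", qual = 10), vt(500, "AT", "A", qual = 20))
  expect_equal(out2$source, "indel")

  tie <- clair3_mix(vt(500, "A", "G", qual = 15), vt(500, "AT", "A", qual = 15))
  expect_equal(tie$source, "snp")

  disjoint <- clair3_mix(vt(c(900, 100), "A", "G"), vt(500, "AT", "A"))
  expect_equal(disjoint$pos, c(100L, 500L, 900L))
})

test_that("the mixed merge matches a brute-force merge on random collisions", {
  set.seed(12)
  for (rep in 1:50) {
    n_s <- sample(3:12, 1)
    n_i <- sample(3:12, 1)
    pool <- sample(seq(100, 400, by = 10))
    snps <- dplyr::bind_rows(lapply(seq_len(n_s), function(i) {
      vt(pool[i], "A", "G", qual = sample(seq(5, 40, 5), 1))
    }))
    # force collisions by drawing indel positions from the same small pool
    indels <- dplyr::bind_rows(lapply(seq_len(n_i), function(i) {
      vt(sample(pool[1:(n_s + 2)], 1), "AT", "A", qual = sample(seq(5, 40, 5), 1))
    })) |> dplyr::distinct(pos, .keep_all = TRUE)
    out <- clair3_mix(snps, indels)
    expect_equal(anyDuplicated(paste(out$chrom, out$pos)), 0L)
    want <- oracle_mix(as.data.frame(snps), as.data.frame(indels))
    expect_equal(out$pos, want$pos)
    expect_equal(out$qual, want$qual)
    expect_equal(out$source, want$source)
  }
})

test_that("normalization trims and left-aligns to the enumeration oracle", {
  refseq <- "GGCTTACGTACGTTTTAGCA"
  ref_named <- c(chr1 = refseq)
  # SNP is untouched
  snp <- normalize_variants(vt(6, "A", "T"), ref_named)
  expect_equal(snp[c("pos", "ref", "alt")], vt(6, "A", "T")[c("pos", "ref", "alt")])
  # trailing trim: CTT -> CT at the start of the T run
  v <- normalize_variants(vt(3, "CTT", "CT"), ref_named)
  expect_equal(v$pos, 3L)
  expect_equal(v$ref, "CT")
  expect_equal(v$alt, "C")
  # insertion of T inside the TTTT run left-aligns to before the run
  ins <- normalize_variants(vt(15, "T", "TT"), ref_named)
  want <- oracle_normalize(refseq, 15, "T", "TT")
  expect_equal(ins$pos, want$pos)
  expect_equal(ins$ref, want$ref)
  expect_equal(ins$alt, want$alt)
  expect_lt(ins$pos, 15L)
})

test_that("normalization is idempotent and preserves the edited haplotype", {
  set.seed(13)
  for (rep in 1:80) {
    refseq <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE,
                           prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
    p <- sample(5:30, 1)
    type <- sample(c("snp", "ins", "del"), 1)
    anchor <- substr(refseq, p, p)
    rec <- switch(type,
      snp = vt(p, anchor, sample(setdiff(c("A", "C", "G", "T"), anchor), 1)),
      ins = vt(p, anchor, paste0(anchor, paste(sample(c("A", "T"),
               sample(1:3, 1), replace = TRUE), collapse = ""))),
      del = vt(p, substr(refseq, p, p + sample(1:3, 1)), anchor)
    )
    ref_named <- c(chr1 = refseq)
    n1 <- normalize_variants(rec, ref_named)
    n2 <- normalize_variants(n1, ref_named)
    expect_equal(n1, n2)
    want <- oracle_normalize(refseq, rec$pos, rec$ref, rec$alt)
    expect_equal(n1$pos, want$pos)
    expect_equal(n1$ref, want$ref)
    expect_equal(n1$alt, want$alt)
    # the edited haplotype is unchanged by normalization
    apply_one <- function(v) {
      paste0(substr(refseq, 1, v$pos - 1), v$alt,
             substr(refseq, v$pos + nchar(v$ref), nchar(refseq)))
    }
    expect_equal(apply_one(n1), apply_one(rec))
  }
})

test_that("a REF allele inconsistent with the reference context errors", {
  expect_error(normalize_variants(vt(3, "AA", "A"), c(chr1 = "GGCTT")),
               "does not match")
})

test_that("VCF files round-trip through write and read", {
  recs <- dplyr::bind_rows(
    vt(100, "A", "G", qual = 21.5, gt = "0|1"),
    vt(250, "CT", "C", qual = 33, gt = "1|1")
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(recs, path, contigs = tibble::tibble(name = "chr1", length = 1000L))
  back <- read_vcf(path)
  expect_equal(back[c("chrom", "pos", "ref", "alt", "qual", "gt")],
               recs[c("chrom", "pos", "ref", "alt", "qual", "gt")])
})
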