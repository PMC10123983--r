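# Per-site profiles: exonic coverage vs intron-containing reads, junction
# proximity, allele counting.

test_that("the five-read worked example gives coverage 3 and proportion 0.4", {
  # three reads cover the site exonically, two span it with an intron
  aln <- aln_tbl(
    qname = paste0("r", 1:5),
    flag = 0L,
    pos = c(901L, 901L, 901L, 901L, 901L),
    cigar = c("200M", "200M", "200M",
              "50M100N50M", "50M100N50M")
  )
  site <- tibble::tibble(chrom = "chr1", pos = 1000L)
  prof <- site_read_profile(aln, site)
  expect_equal(prof$exonic_cov, 3L)
  expect_equal(prof$n_span_count, 2L)
  expect_equal(prof$n_cigar_proportion, 0.4)
})

test_that("proportion hits the 0 and 1 edges", {
  exonic <- aln_tbl(paste0("e", 1:4), 0L, rep(901L, 4), rep("200M", 4))
  site <- tibble::tibble(chrom = "chr1", pos = 1000L)
  expect_equal(site_read_profile(exonic, site)$n_cigar_proportion, 0)
  spanning <- aln_tbl(paste0("s", 1:3), 0L, rep(901L, 3), rep("50M100N50M", 3))
  prof <- site_read_profile(spanning, site)
  expect_equal(prof$exonic_cov, 0L)
  expect_equal(prof$n_cigar_proportion, 1)
  # no reads at all: proportion undefined
  none <- site_read_profile(exonic, tibble::tibble(chrom = "chr1", pos = 5000L))
  expect_true(is.na(none$n_cigar_proportion))
})

test_that("reads not overlapping the site count toward neither tally", {
  aln <- dplyr::bind_rows(
    aln_tbl("far", 0L, 5000L, "100M"),
    aln_tbl("cov", 0L, 990L, "50M")
  )
  prof <- site_read_profile(aln, tibble::tibble(chrom = "chr1", pos = 1000L))
  expect_equal(prof$exonic_cov, 1L)
  expect_equal(prof$n_span_count, 0L)
})

test_that("sites beyond the reference bounds error when bounds are known", {
  aln <- aln_tbl("r1", 0L, 1L, "100M")
  refs <- tibble::tibble(name = "chr1", length = 500L)
  expect_error(
    site_read_profile(aln, tibble::tibble(chrom = "chr1", pos = 501L), refs),
    "beyond reference bounds"
  )
})

test_that("profile tallies never exceed the overlapping read count", {
  fix <- default_fixture
  sites <- fix$expected[, c("chrom", "pos")]
  prof <- site_read_profile(fix$lr_aln, sites)
  ends <- fix$lr_aln$pos +
    GenomicAlignments::cigarWidthAlongReferenceSpace(fix$lr_aln$cigar) - 1L
  for (i in seq_len(nrow(prof))) {
    overlapping <- sum(fix$lr_aln$pos <= prof$pos[i] & ends >= prof$pos[i])
    expect_lte(prof$exonic_cov[i] + prof$n_span_count[i], overlapping)
  }
})

test_that("junction proximity needs both the shared-junction majority and 20 bp", {
  # four covering reads, three sharing intron [1011, 1100] (1-based), site 1001:
  # distance to the nearest exonic edge (1010) is 9
  aln <- dplyr::bind_rows(
    aln_tbl(paste0("j", 1:3), 0L, 911L, rep("100M90N100M", 3)),
    aln_tbl("plain", 0L, 911L, "290M")
  )
  site <- tibble::tibble(chrom = "chr1", pos = 1001L)
  ctx <- near_splice_junction(aln, site)
  expect_true(ctx$near)
  expect_equal(ctx$supporting_fraction, 0.75)
  expect_equal(ctx$distance_bp, 9L)
  expect_equal(ctx$intron_start, 1011L)
  expect_equal(ctx$intron_end, 1100L)

  # only 2 of 5 reads share the junction: fraction 0.4 < 0.5, not near
  aln2 <- dplyr::bind_rows(
    aln_tbl(paste0("j", 1:2), 0L, 911L, rep("95M90N100M", 2)),
    aln_tbl(paste0("p", 1:3), 0L, 911L, rep("290M", 3))
  )
  ctx2 <- near_splice_junction(aln2, tibble::tibble(chrom = "chr1", pos = 1001L))
  expect_false(ctx2$near)
  expect_equal(ctx2$supporting_fraction, 0.4)

  # covering reads without any N op are never near
  ctx3 <- near_splice_junction(aln_tbl("p", 0L, 911L, "290M"),
                               tibble::tibble(chrom = "chr1", pos = 1001L))
  expect_false(ctx3$near)
  expect_equal(ctx3$supporting_fraction, 0)
})

test_that("junction distance uses the nearest exonic edge and the 20 bp cap", {
  mk <- function(site_pos) {
    aln <- aln_tbl(paste0("j", 1:2), 0L, 901L, rep("100M100N100M", 2))
    near_splice_junction(aln, tibble::tibble(chrom = "chr1", pos = site_pos))
  }
  # intron is [1001, 1100]; exonic edges 1000 and 1101
  expect_equal(mk(1000L)$distance_bp, 0L)
  expect_true(mk(981L)$near)    # 19 bp from the left edge
  expect_true(mk(980L)$near)    # exactly 20 bp
  expect_false(mk(979L)$near)   # 21 bp: too far
  expect_equal(mk(1110L)$distance_bp, 9L)  # right edge side
})

test_that("N-spanning reads do not count as containing the site", {
  aln <- dplyr::bind_rows(
    aln_tbl(paste0("j", 1:2), 0L, 901L, rep("100M100N100M", 2)),
    aln_tbl(paste0("s", 1:5), 0L, 901L, rep("85M130N85M", 5))
  )
  # site 990 is covered exonically only by the two j reads (the s reads splice
  # out 986..1115); the junction fraction denominator must be 2, not 7
  ctx <- near_splice_junction(aln, tibble::tibble(chrom = "chr1", pos = 990L))
  expect_equal(ctx$n_covering, 2L)
  expect_true(ctx$near)
  expect_equal(ctx$supporting_fraction, 1)
})

test_that("allele counting respects alleles, base quality and gaps", {
  # pileup at pos 50: 12 ref A, 8 alt G, 1 N, 1 C -> (12, 8)
  mk_read <- function(i, base, q = "I") {
    r <- aln_tbl(sprintf("rd%02d", i), 0L, 41L, "20M")
    r$seq <- paste0(strrep("T", 9), base, strrep("T", 10))
    r$qual <- paste0(strrep("I", 9), q, strrep("I", 10))
    r
  }
  aln <- dplyr::bind_rows(c(
    lapply(1:12, mk_read, base = "A"),
    lapply(13:20, mk_read, base = "G"),
    list(mk_read(21, "N"), mk_read(22, "C"))
  ))
  sites <- tibble::tibble(chrom = "chr1", pos = 50L, ref = "A", alt = "G")
  out <- allele_counts(aln, sites)
  expect_equal(out$ref_count, 12L)
  expect_equal(out$alt_count, 8L)

  # a base below min_baseq is excluded ('5' is Phred 20, '3' is 18)
  lowq <- dplyr::bind_rows(mk_read(1, "A", q = "3"), mk_read(2, "G"))
  out2 <- allele_counts(lowq, sites, min_baseq = 20L)
  expect_equal(out2$ref_count, 0L)
  expect_equal(out2$alt_count, 1L)

  # deletion- and intron-spanning reads contribute to neither count
  gap <- aln_tbl("del", 0L, 41L, "5M10D5M")
  expect_equal(allele_counts(gap, sites)$ref_count, 0L)

  # zero depth
  out3 <- allele_counts(aln, tibble::tibble(chrom = "chr1", pos = 5000L,
                                            ref = "A", alt = "G"))
  expect_equal(out3$ref_count + out3$alt_count, 0L)

  # indel-allele sites are skipped with a message
  expect_message(
    skipped <- allele_counts(aln, tibble::tibble(chrom = "chr1", pos = 50L,
                                                 ref = "AT", alt = "A")),
    "indel"
  )
  expect_equal(nrow(skipped), 0L)
})

test_that("fixture pileups recover the planted allele at error-free sites", {
  cfg <- sim_config(seed = 9, error_rate = 0)
  fix <- sim_fixture(cfg)
  hom <- fix$meta[fix$meta$gt == "1|1" & fix$meta$kind == "snp", ]
  counts <- allele_counts(fix$lr_aln, hom[, c("chrom", "pos", "ref", "alt")])
  expect_gt(counts$alt_count, 0L)
  expect_equal(counts$ref_count, 0L)
})
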