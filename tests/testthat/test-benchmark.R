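# Callset-vs-truth matching, metrics, stratification, intersections, and the
# 2x2 independence test.

vk <- function(pos, ref = "A", alt = "G", chrom = "chr1") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), id = NA_character_,
                 ref = ref, alt = alt, qual = 50, filter = "PASS", gt = "0/1")
}

test_that("matching partitions by set algebra and ignores genotype", {
  called <- vk(c(1, 2, 3))
  truth <- dplyr::mutate(vk(c(2, 3, 4)), gt = "1/1")
  conf <- match_callset(called, truth)
  expect_setequal(conf$pos[conf$status == "tp"], c(2L, 3L))
  expect_equal(conf$pos[conf$status == "fp"], 1L)
  expect_equal(conf$pos[conf$status == "fn"], 4L)
  # tp + fn covers the truth exactly
  expect_equal(sum(conf$status %in% c("tp", "fn")), nrow(truth))

  ident <- match_callset(truth, truth)
  expect_true(all(ident$status == "tp"))
  disjoint <- match_callset(vk(1), vk(2))
  expect_equal(sum(disjoint$status == "tp"), 0L)
  # same position, different allele: no match
  allele <- match_callset(vk(5, alt = "G"), vk(5, alt = "T"))
  expect_equal(sort(allele$status), c("fn", "fp"))
})

test_that("precision/recall/F1 follow the formulas with flagged degenerates", {
  conf <- match_callset(vk(1:10), vk(c(1:8, 21, 22)))
  m <- prf_metrics(conf)
  expect_equal(c(m$precision, m$recall, m$f1), c(0.8, 0.8, 0.8))

  m2 <- prf_metrics(match_callset(vk(c(1:9, 30)), vk(c(1:9, 21, 22, 23))))
  expect_equal(m2$precision, 0.9)
  expect_equal(m2$recall, 0.75)
  expect_equal(m2$f1, 0.8182, tolerance = 1e-4)

  empty <- prf_metrics(match_callset(vk(integer(0)), vk(1:5)))
  expect_equal(c(empty$precision, empty$recall, empty$f1), c(0, 0, 0))
  expect_true(empty$degenerate)
})

test_that("glance and tidy expose the confusion partition broom-style", {
  conf <- match_callset(vk(1:3), vk(2:4))
  expect_equal(glance(conf), prf_metrics(conf))
  td <- tidy(conf)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "svc_confusion"))
})

test_that("a single all-covering stratum reproduces the plain metrics", {
  called <- vk(1:8)
  truth <- vk(3:10)
  ann <- tibble::tibble(chrom = "chr1", pos = 1:10, bucket = "all")
  sm <- stratified_metrics(called, truth, ann, by = "bucket")
  expect_equal(nrow(sm), 1L)
  expect_equal(sm$precision, prf_metrics(match_callset(called, truth))$precision)
  expect_equal(sm$n_true, nrow(truth))
})

test_that("a caller missing exactly the near-junction sites shows it in recall", {
  truth <- vk(1:20)
  ann <- tibble::tibble(chrom = "chr1", pos = 1:20,
                        near = rep(c("yes", "no"), each = 10))
  called <- vk(11:20)  # misses all 'yes' sites
  sm <- stratified_metrics(called, truth, ann, by = "near")
  expect_equal(sm$recall[sm$near == "yes"], 0)
  expect_equal(sm$recall[sm$near == "no"], 1)
  expect_equal(sm$n_true, c(10L, 10L))
  # stratified truth counts sum to the unstratified count
  expect_equal(sum(sm$n_tp + sm$n_fn), nrow(truth))
})

test_that("unannotated sites are an error naming the site", {
  truth <- vk(1:3)
  ann <- tibble::tibble(chrom = "chr1", pos = 1:2, bucket = "all")
  expect_error(stratified_metrics(vk(1), truth, ann, "bucket"), "chr1:3")
})

test_that("the coverage sweep at t = 0 equals the unstratified result", {
  called <- vk(c(1:6, 50))
  truth <- vk(1:10)
  ann <- tibble::tibble(chrom = "chr1", pos = c(1:10, 50),
                        exonic_cov = c(5, 5, 10, 10, 20, 20, 40, 40, 80, 80, 40))
  sw <- coverage_sweep_metrics(called, truth, ann, thresholds = c(0L, 20L, 80L))
  expect_equal(sw$recall[sw$min_coverage == 0],
               prf_metrics(match_callset(called, truth))$recall)
  expect_equal(sw$n_true, c(10L, 6L, 2L))
  expect_equal(sw$recall[sw$min_coverage == 20], 2 / 6)
})

test_that("intersection patterns enumerate memberships and conserve counts", {
  a <- vk(c(1, 2))
  b <- vk(c(2, 3))
  truth <- vk(c(2, 4))
  ic <- intersection_counts(list(A = a, B = b), truth)
  get <- function(p) ic$count[ic$pattern == p]
  expect_equal(get("A"), 1L)
  expect_equal(get("A&B&truth"), 1L)
  expect_equal(get("B"), 1L)
  expect_equal(get("truth"), 1L)
  expect_equal(sum(ic$count), 4L)  # |union|

  same <- intersection_counts(list(A = a, B = a), vk(integer(0)))
  expect_equal(same$pattern, "A&B")

  set.seed(71)
  sets <- lapply(1:3, function(i) vk(sample(1:30, 12)))
  names(sets) <- c("x", "y", "z")
  tr <- vk(sample(1:30, 10))
  ic2 <- intersection_counts(sets, tr)
  expect_equal(sum(ic2$count),
               length(unique(c(unlist(lapply(sets, function(s) s$pos)), tr$pos))))
  # marginal sums reproduce each callset's size
  mem <- attr(ic2, "membership")
  expect_equal(colSums(as.matrix(mem[, c("x", "y", "z")])),
               c(x = 12, y = 12, z = 12))
})

test_that("the 2x2 Pearson statistic matches the closed form and chisq.test", {
  even <- two_by_two_chi2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)

  skew <- two_by_two_chi2(matrix(c(30, 10, 10, 30), 2))
  expect_equal(skew$statistic, 20)
  ct <- chisq.test(matrix(c(30, 10, 10, 30), 2), correct = FALSE)
  expect_equal(skew$statistic, unname(ct$statistic))
  expect_equal(skew$p_value, unname(ct$p.value))

  yates <- two_by_two_chi2(matrix(c(30, 10, 10, 30), 2), correct = TRUE)
  ct2 <- chisq.test(matrix(c(30, 10, 10, 30), 2), correct = TRUE)
  expect_equal(yates$statistic, unname(ct2$statistic))

  expect_error(two_by_two_chi2(matrix(c(1, 0, 0, 0), 2)), "marginal")
})

test_that("FN/TP x ASE cross-tabulation counts truth sites only", {
  truth <- vk(1:6)
  called <- vk(1:3)  # misses 4..6
  conf <- match_callset(called, truth)
  ase <- tibble::tibble(chrom = "chr1", pos = 1:6,
                        is_ase = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE))
  tab <- ase_confusion_table(conf, ase)
  expect_equal(tab["fn", "ase"], 2L)
  expect_equal(tab["fn", "non_ase"], 1L)
  expect_equal(tab["tp", "ase"], 1L)
  expect_equal(tab["tp", "non_ase"], 2L)
  expect_equal(sum(tab), nrow(truth))
})

test_that("feeding the truth back as the callset is perfect in every stratum", {
  fix <- default_fixture
  truth <- normalize_variants(fix$truth, fix$ref)
  ann <- site_read_profile(fix$lr_aln, truth[, c("chrom", "pos")])
  ann <- near_splice_junction(fix$lr_aln, ann)
  ann$near_lab <- ifelse(ann$near, "yes", "no")
  sm <- stratified_metrics(truth, truth, ann, by = "near_lab")
  expect_true(all(sm$precision == 1))
  expect_true(all(sm$recall == 1))
  expect_true(all(sm$f1 == 1))
})
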