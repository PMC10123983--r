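# Benchmarking callsets against a truth set: confusion partitions on
# normalized (chrom, pos, ref, alt) keys, precision/recall/F1 overall, per
# categorical stratum and across minimum-coverage sweeps, UpSet-style
# intersection patterns, and the 2x2 chi-squared independence test used to
# relate miss rate to ASE status.

variant_key <- function(x) {
  paste(x$chrom, x$pos, toupper(x$ref), toupper(x$alt), sep = ":")
}

#' Match a callset against a truth set
#'
#' Partitions the union of the two sets into true positives (called and
#' true), false positives (called only) and false negatives (true only).
#' Matching is by exact (chrom, pos, ref, alt); genotype is ignored. Both
#' sets should be normalized ([normalize_variants()]) and single-alt first.
#'
#' @param called,truth vcf tibbles.
#' @return A tibble of class `svc_confusion` with columns `chrom`, `pos`,
#'   `ref`, `alt`, `status` (`"tp"`, `"fp"`, `"fn"`).
#' @export
match_callset <- function(called, truth) {
  validate_vcf_tbl(called, "called")
  validate_vcf_tbl(truth, "truth")
  ck <- variant_key(called)
  tk <- variant_key(truth)
  cols <- c("chrom", "pos", "ref", "alt")
  called <- distinct(called[, cols])
  truth <- distinct(truth[, cols])
  ck <- variant_key(called)
  tk <- variant_key(truth)
  out <- bind_rows(
    mutate(called, status = if_else(ck %in% tk, "tp", "fp")),
    mutate(truth[!tk %in% ck, , drop = FALSE], status = "fn")
  )
  class(out) <- c("svc_confusion", class(out))
  out
}

#' Precision, recall and F1 from a confusion partition
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`,
#' `f1 = 2PR / (P + R)`; an empty denominator yields 0 with
#' `degenerate = TRUE`.
#'
#' @param conf A confusion tibble from [match_callset()].
#' @return A one-row tibble: `n_tp`, `n_fp`, `n_fn`, `precision`, `recall`,
#'   `f1`, `degenerate`.
#' @export
prf_metrics <- function(conf) {
  tp <- sum(conf$status == "tp")
  fp <- sum(conf$status == "fp")
  fn <- sum(conf$status == "fn")
  degenerate <- (tp + fp) == 0L || (tp + fn) == 0L
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  tibble(n_tp = tp, n_fp = fp, n_fn = fn, precision = precision,
         recall = recall, f1 = f1, degenerate = degenerate)
}

#' @export
glance.svc_confusion <- function(x, ...) prf_metrics(x)

#' @export
tidy.svc_confusion <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "svc_confusion")
  out
}

join_annotation <- function(sites, annotations, what) {
  key <- paste(sites$chrom, sites$pos)
  akey <- paste(annotations$chrom, annotations$pos)
  m <- match(key, akey)
  if (anyNA(m)) {
    miss <- unique(key[is.na(m)])
    abort(sprintf("unannotated %s site(s): %s", what,
                  paste(head(sub(" ", ":", miss), 5L), collapse = ", ")))
  }
  m
}

#' Stratified precision/recall/F1 by a categorical annotation
#'
#' The truth set is restricted to each stratum before matching; called
#' records are assigned to strata by their own site's annotation, so false
#' positives contribute to the stratum of the site where they were called.
#' Every truth and called site must appear in `annotations`.
#'
#' @param called,truth vcf tibbles (normalized, single-alt).
#' @param annotations A tibble keyed by `chrom`, `pos` carrying the stratum
#'   column.
#' @param by Name of the stratum column in `annotations`.
#' @return A tibble with one row per stratum: the stratum value, `n_true`,
#'   and the [prf_metrics()] columns.
#' @export
stratified_metrics <- function(called, truth, annotations, by) {
  validate_vcf_tbl(called, "called")
  validate_vcf_tbl(truth, "truth")
  if (!by %in% names(annotations)) {
    abort(sprintf("no column '%s' in `annotations`", by))
  }
  truth$.stratum <- annotations[[by]][join_annotation(truth, annotations, "truth")]
  called$.stratum <- annotations[[by]][join_annotation(called, annotations, "called")]
  strata <- sort(unique(c(truth$.stratum, called$.stratum)), na.last = TRUE)
  out <- lapply(strata, function(s) {
    t_s <- truth[!is.na(truth$.stratum) & truth$.stratum == s, ]
    c_s <- called[!is.na(called$.stratum) & called$.stratum == s, ]
    bind_cols(tibble("{by}" := s, n_true = nrow(t_s)),
              prf_metrics(match_callset(c_s, t_s)))
  })
  bind_rows(out)
}

#' Precision/recall/F1 across a minimum-coverage sweep
#'
#' For each threshold `t`, the evaluation is restricted to sites whose
#' annotated coverage is at least `t` (both truth and called sides);
#' `t = 0` reproduces the unrestricted result.
#'
#' @inheritParams stratified_metrics
#' @param coverage_col Name of the coverage column in `annotations`
#'   (default `"exonic_cov"`).
#' @param thresholds Integer vector of minimum coverages.
#' @return A tibble with one row per threshold (`min_coverage`, `n_true`,
#'   metrics).
#' @export
coverage_sweep_metrics <- function(called, truth, annotations,
                                   thresholds = c(0L, 5L, 10L, 20L, 40L),
                                   coverage_col = "exonic_cov") {
  validate_vcf_tbl(called, "called")
  validate_vcf_tbl(truth, "truth")
  if (!coverage_col %in% names(annotations)) {
    abort(sprintf("no column '%s' in `annotations`", coverage_col))
  }
  truth$.cov <- annotations[[coverage_col]][join_annotation(truth, annotations, "truth")]
  called$.cov <- annotations[[coverage_col]][join_annotation(called, annotations, "called")]
  out <- lapply(thresholds, function(t) {
    t_s <- truth[truth$.cov >= t, ]
    c_s <- called[called$.cov >= t, ]
    bind_cols(tibble(min_coverage = t, n_true = nrow(t_s)),
              prf_metrics(match_callset(c_s, t_s)))
  })
  bind_rows(out)
}

#' Intersection (UpSet-style) pattern counts of callsets against truth
#'
#' Every variant key in the union of the callsets and the truth set is
#' assigned its membership pattern; counts per pattern are returned. Patterns
#' containing only `truth` are false negatives of every callset; patterns
#' without `truth` are false positives of the member callsets.
#'
#' @param callsets A named list of vcf tibbles.
#' @param truth A vcf tibble.
#' @return A tibble (`pattern`, `count`, `in_truth`), sorted by descending
#'   count, with a logical membership-matrix attribute `"membership"`.
#' @export
intersection_counts <- function(callsets, truth) {
  if (length(callsets) == 0L) abort("at least one callset is required")
  if (is.null(names(callsets)) || any(names(callsets) == "")) {
    abort("`callsets` must be a named list")
  }
  keysets <- c(lapply(callsets, variant_key), list(truth = variant_key(truth)))
  keysets <- lapply(keysets, unique)
  universe <- unique(unlist(keysets, use.names = FALSE))
  member <- vapply(keysets, function(k) universe %in% k,
                   logical(length(universe)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1L,
                                             dimnames = list(NULL, names(keysets)))
  pattern <- apply(member, 1L, function(row) {
    paste(colnames(member)[row], collapse = "&")
  })
  out <- tibble(pattern = pattern) |>
    count(.data$pattern, name = "count") |>
    mutate(in_truth = str_detect(.data$pattern, "(^|&)truth($|&)")) |>
    arrange(desc(.data$count))
  attr(out, "membership") <- as_tibble(cbind(tibble(key = universe),
                                             as.data.frame(member)))
  out
}

#' Pearson chi-squared test of independence on a 2x2 table
#'
#' Plain Pearson statistic with 1 degree of freedom; the continuity
#' correction is off by default (configurable). A zero row or column
#' marginal leaves the test undefined and raises an error.
#'
#' @param table A 2x2 matrix of non-negative counts.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return A one-row tibble: `statistic`, `p_value`, `df`.
#' @examples
#' two_by_two_chi2(matrix(c(30, 10, 10, 30), 2))
#' @export
two_by_two_chi2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) abort("a 2x2 table is required")
  if (any(table < 0)) abort("counts must be non-negative")
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) {
    abort("zero marginal: the independence test is undefined")
  }
  expected <- outer(rs, cs) / sum(table)
  dev <- abs(table - expected)
  if (correct) dev <- pmax(0, dev - 0.5)
  stat <- sum(dev^2 / expected)
  tibble(statistic = stat, p_value = pchisq(stat, df = 1L, lower.tail = FALSE),
         df = 1L)
}

#' Cross-tabulate call outcome against ASE status
#'
#' Builds the 2x2 table of false-negative vs true-positive truth sites by
#' ASE vs non-ASE status, the input to [two_by_two_chi2()].
#'
#' @param conf A confusion tibble from [match_callset()].
#' @param ase A tibble with `chrom`, `pos` and logical `is_ase` covering the
#'   truth sites.
#' @return A 2x2 integer matrix with rows `fn`/`tp` and columns
#'   `ase`/`non_ase`.
#' @export
ase_confusion_table <- function(conf, ase) {
  truth_sites <- conf[conf$status %in% c("tp", "fn"), , drop = FALSE]
  m <- join_annotation(truth_sites, ase, "truth")
  is_ase <- ase$is_ase[m]
  matrix(
    c(sum(truth_sites$status == "fn" & is_ase),
      sum(truth_sites$status == "tp" & is_ase),
      sum(truth_sites$status == "fn" & !is_ase),
      sum(truth_sites$status == "tp" & !is_ase)),
    nrow = 2L, dimnames = list(c("fn", "tp"), c("ase", "non_ase"))
  )
}
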