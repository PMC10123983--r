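# Deterministic synthetic fixtures: a toy multi-exon reference, planted
# het/hom SNPs and indels on two haplotypes, spliced long-read alignments
# with a controllable proportion of intron-containing reads per region, and
# contiguous short-read alignments for allele counting. Reads are emitted
# pre-aligned with truthful coordinates and CIGARs — no aligner is invoked —
# so every expected value is known by construction.

#' Fixture configuration
#'
#' Defaults describe the simulated study conditions: three genes of three
#' exons each, 50 full-length spliced reads per gene with a HiFi-like
#' substitution error rate, a 0.4 middle-exon skip fraction on the first
#' gene (so sites there see a 0.4 intron-containing-read proportion), one
#' allelically imbalanced gene (haplotype-1 fraction 0.9), and homopolymer
#' runs of length 5 and 6 embedded in the second gene.
#'
#' @param seed Integer seed; every stochastic step is derived from it.
#' @param genes List of gene structures, each `list(exons =, introns =)`
#'   (lengths in bp).
#' @param depth Spliced reads per gene.
#' @param error_rate Per-base substitution error rate of spliced reads.
#' @param skip_fraction Per-gene probability that a read skips the middle
#'   exon (the intron-containing-read proportion at middle-exon sites).
#' @param hap1_fraction Per-gene probability that a read comes from
#'   haplotype 1 (0.5 = balanced; away from 0.5 = allelic imbalance).
#' @param hp_runs List of homopolymer runs to embed:
#'   `list(base =, len =, gene =, exon =, offset =)`.
#' @param n_snps,n_indels Numbers of planted SNPs and indels (indels in
#'   excess of `length(hp_runs)` are planted outside homopolymers).
#' @param sr_depth,sr_read_len Short-read coverage target and read length.
#' @param contig Contig name.
#' @return A config list of class `sv_config`.
#' @export
sim_config <- function(seed = 1L,
                       genes = rep(list(list(exons = c(300L, 200L, 300L),
                                             introns = c(150L, 150L))), 3L),
                       depth = 50L,
                       error_rate = 0.001,
                       skip_fraction = c(0.4, 0, 0),
                       hap1_fraction = c(0.5, 0.5, 0.9),
                       hp_runs = list(
                         list(base = "T", len = 5L, gene = 2L, exon = 2L, offset = 50L),
                         list(base = "A", len = 6L, gene = 2L, exon = 2L, offset = 120L)
                       ),
                       n_snps = 6L, n_indels = 4L,
                       sr_depth = 60L, sr_read_len = 100L,
                       contig = "chrT") {
  stopifnot(depth >= 1L, error_rate >= 0, error_rate < 1,
            all(skip_fraction >= 0 & skip_fraction <= 1),
            all(hap1_fraction >= 0 & hap1_fraction <= 1))
  ng <- length(genes)
  skip_fraction <- rep_len(skip_fraction, ng)
  hap1_fraction <- rep_len(hap1_fraction, ng)
  for (g in genes) {
    stopifnot(all(g$exons > 0L), all(g$introns > 0L),
              length(g$introns) == length(g$exons) - 1L)
  }
  structure(
    list(seed = as.integer(seed), genes = genes, depth = as.integer(depth),
         error_rate = error_rate, skip_fraction = skip_fraction,
         hap1_fraction = hap1_fraction, hp_runs = hp_runs,
         n_snps = as.integer(n_snps), n_indels = as.integer(n_indels),
         sr_depth = as.integer(sr_depth), sr_read_len = as.integer(sr_read_len),
         contig = contig),
    class = "sv_config"
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build the toy reference and its exon/intron interval table
#'
#' Deterministic for a fixed config seed: the same config yields the same
#' sequence byte for byte. Requested homopolymer runs are embedded at
#' recorded exonic coordinates with non-run flanking bases; overlapping
#' requests are an error.
#'
#' @param config An [sim_config()] object.
#' @return A list with `ref` (named character vector), `refs`
#'   (name/length tibble), `intervals` (gene/feature/index/start/end), and
#'   `hp_runs` (embedded run coordinates).
#' @export
make_reference <- function(config) {
  withr::with_seed(config$seed, make_reference_impl(config))
}

make_reference_impl <- function(config) {
  lead <- 100L
  gap <- 200L
  rows <- list()
  cursor <- lead + 1L
  for (g in seq_along(config$genes)) {
    spec <- config$genes[[g]]
    k <- length(spec$exons)
    for (e in seq_len(k)) {
      rows[[length(rows) + 1L]] <- tibble(
        gene = g, feature = "exon", index = e,
        start = cursor, end = cursor + spec$exons[e] - 1L
      )
      cursor <- cursor + spec$exons[e]
      if (e < k) {
        rows[[length(rows) + 1L]] <- tibble(
          gene = g, feature = "intron", index = e,
          start = cursor, end = cursor + spec$introns[e] - 1L
        )
        cursor <- cursor + spec$introns[e]
      }
    }
    cursor <- cursor + gap
  }
  intervals <- bind_rows(rows)
  total <- max(intervals$end) + 100L
  seq <- random_dna(total)

  hp <- list()
  for (r in config$hp_runs) {
    ex <- intervals[intervals$gene == r$gene & intervals$feature == "exon" &
                      intervals$index == r$exon, ]
    if (nrow(ex) != 1L) abort("hp run refers to a gene/exon that does not exist")
    start <- ex$start + r$offset
    end <- start + r$len - 1L
    if (end > ex$end - 2L) abort("hp run does not fit inside its exon")
    hp[[length(hp) + 1L]] <- tibble(base = r$base, start = start, end = end,
                                    length = r$len, gene = r$gene)
  }
  hp <- bind_rows(hp)
  if (nrow(hp) > 1L) {
    o <- order(hp$start)
    if (any(hp$start[o][-1L] <= hp$end[o][-nrow(hp)] + 2L)) {
      abort("requested homopolymer runs overlap")
    }
  }
  flank <- function(b) if (b == "C") "G" else "C"
  for (i in seq_len(nrow(hp))) {
    str_sub(seq, hp$start[i], hp$end[i]) <- strrep(hp$base[i], hp$length[i])
    str_sub(seq, hp$start[i] - 1L, hp$start[i] - 1L) <- flank(hp$base[i])
    str_sub(seq, hp$end[i] + 1L, hp$end[i] + 1L) <- flank(hp$base[i])
  }
  list(
    ref = setNames(seq, config$contig),
    refs = tibble(name = config$contig, length = total),
    intervals = intervals,
    hp_runs = hp
  )
}

other_base <- function(b, avoid = character(0)) {
  sample(setdiff(c("A", "C", "G", "T"), c(b, avoid)), 1L)
}

#' Plant truth variants on two haplotypes
#'
#' Places SNPs and indels inside exons (at least 25 bp from any splice
#' junction, pairwise at least 10 bp apart), one indel inside each embedded
#' homopolymer run (alternating deletion/insertion of the run base) and the
#' remainder outside homopolymer context. The first SNP is homozygous-alt;
#' everything else is heterozygous with the alt allele phased onto one
#' haplotype. Deterministic for the config seed.
#'
#' @param refobj Output of [make_reference()].
#' @param config The [sim_config()] object.
#' @return A list with `truth` (vcf tibble with phased `gt`), `meta`
#'   (per-variant gene/exon/haplotype bookkeeping), and `haplotypes`
#'   (character vector of the two full haplotype sequences).
#' @export
plant_variants <- function(refobj, config) {
  withr::with_seed(config$seed + 1L, plant_variants_impl(refobj, config))
}

plant_variants_impl <- function(refobj, config) {
  seq <- refobj$ref[[1L]]
  chrom <- names(refobj$ref)[1L]
  exons <- refobj$intervals[refobj$intervals$feature == "exon", ]
  margin <- 25L
  occupied <- integer(0)
  base_at <- function(p) str_sub(seq, p, p)
  run_len_at <- function(p) {
    b <- base_at(p)
    l <- p
    while (l > 1L && base_at(l - 1L) == b) l <- l - 1L
    r <- p
    while (r < nchar(seq) && base_at(r + 1L) == b) r <- r + 1L
    r - l + 1L
  }
  free <- function(p, span = 1L) {
    all(!c((p - 9L):(p + span + 9L)) %in% occupied)
  }
  in_hp <- function(p) {
    nrow(refobj$hp_runs) > 0L &&
      any(refobj$hp_runs$start - 2L <= p & p <= refobj$hp_runs$end + 2L)
  }
  draw_pos <- function(exon_row, span = 1L, avoid_hp = TRUE) {
    lo <- exon_row$start + margin
    hi <- exon_row$end - margin - span
    for (attempt in 1:200) {
      p <- sample(lo:hi, 1L)
      if (!free(p, span)) next
      if (avoid_hp && (in_hp(p) || in_hp(p + span))) next
      return(p)
    }
    abort("could not place a variant; exons too small or too crowded")
  }
  vars <- list()
  add <- function(pos, ref, alt, gt, hap, kind, gene, exon) {
    occupied <<- c(occupied, seq.int(pos, pos + nchar(ref) - 1L))
    vars[[length(vars) + 1L]] <<- tibble(
      chrom = chrom, pos = pos, id = sprintf("v%02d", length(vars) + 1L),
      ref = ref, alt = alt, qual = 50, filter = "PASS", gt = gt,
      hap = as.character(hap), kind = kind, gene = gene, exon = exon
    )
  }

  # SNPs round-robin over exons, middle exons first so the intron-spanning
  # regime of gene 1 is always exercised
  exon_order <- exons[order(exons$index != 2L, exons$gene, exons$index), ]
  for (i in seq_len(config$n_snps)) {
    ex <- exon_order[((i - 1L) %% nrow(exon_order)) + 1L, ]
    p <- draw_pos(ex)
    refb <- base_at(p)
    altb <- other_base(refb)
    if (i == 1L) {
      add(p, refb, altb, "1|1", "both", "snp", ex$gene, ex$index)
    } else {
      hap <- if (i %% 2L == 0L) 1L else 2L
      add(p, refb, altb, if (hap == 1L) "1|0" else "0|1",
          hap, "snp", ex$gene, ex$index)
    }
  }

  # one indel per homopolymer run: deletion of one run base / insertion of one
  hp <- refobj$hp_runs
  for (i in seq_len(nrow(hp))) {
    anchor_pos <- hp$start[i] - 1L
    anchor <- base_at(anchor_pos)
    ex <- exons[exons$gene == hp$gene[i] &
                  exons$start <= anchor_pos & exons$end >= hp$end[i], ]
    hap <- if (i %% 2L == 0L) 1L else 2L
    gt <- if (hap == 1L) "1|0" else "0|1"
    if (i %% 2L == 1L) {
      add(anchor_pos, paste0(anchor, hp$base[i]), anchor, gt, hap,
          "hp_deletion", hp$gene[i], ex$index[1L])
    } else {
      add(anchor_pos, anchor, paste0(anchor, hp$base[i]), gt, hap,
          "hp_insertion", hp$gene[i], ex$index[1L])
    }
  }

  # remaining indels outside homopolymer context
  n_rest <- config$n_indels - nrow(hp)
  if (n_rest < 0L) abort("n_indels must be >= length(hp_runs)")
  plain_exons <- exons[order(exons$gene, exons$index), ]
  for (i in seq_len(n_rest)) {
    ex <- plain_exons[((i - 1L) %% nrow(plain_exons)) + 1L, ]
    repeat {
      p <- draw_pos(ex, span = 2L)
      # deleted/neighbour base must not sit in a run of >= 3
      if (run_len_at(p + 1L) <= 2L && run_len_at(p) <= 2L) break
    }
    anchor <- base_at(p)
    hap <- if (i %% 2L == 0L) 1L else 2L
    gt <- if (hap == 1L) "1|0" else "0|1"
    if (i %% 2L == 1L) {
      add(p, paste0(anchor, base_at(p + 1L)), anchor, gt, hap,
          "deletion", ex$gene, ex$index)
    } else {
      ins <- other_base(anchor, avoid = base_at(p + 1L))
      add(p, anchor, paste0(anchor, ins), gt, hap,
          "insertion", ex$gene, ex$index)
    }
  }

  all_vars <- bind_rows(vars) |> arrange(.data$pos)
  truth <- all_vars[, c("chrom", "pos", "id", "ref", "alt", "qual", "filter", "gt")]
  hap_seq <- function(h) {
    v <- all_vars[all_vars$hap %in% c(as.character(h), "both"), ]
    apply_variants(seq, v)
  }
  list(truth = truth, meta = all_vars,
       haplotypes = c(hap1 = hap_seq(1L), hap2 = hap_seq(2L)))
}

#' Apply variant records to a reference sequence
#'
#' Edits are applied right to left so earlier coordinates stay valid;
#' overlapping records are an error.
#'
#' @param seq A single reference sequence string.
#' @param variants A vcf tibble (anchored records, single alt per row).
#' @return The edited sequence.
#' @export
apply_variants <- function(seq, variants) {
  if (nrow(variants) == 0L) return(seq)
  v <- variants[order(-variants$pos), ]
  ends <- v$pos + nchar(v$ref) - 1L
  if (any(v$pos[-nrow(v)] <= ends[-1L])) {
    abort("overlapping variant records cannot be applied")
  }
  for (i in seq_len(nrow(v))) {
    if (!identical(str_sub(seq, v$pos[i], ends[i]), v$ref[i])) {
      abort(sprintf("REF mismatch at %d while applying variants", v$pos[i]))
    }
    str_sub(seq, v$pos[i], ends[i]) <- v$alt[i]
  }
  seq
}

# Haplotype-aware alignment of the reference interval [s, e]: sequence plus
# M/I/D ops for the variants of one haplotype inside the interval.
hap_segment <- function(seq, s, e, vars) {
  if (nrow(vars) > 0L) {
    keep <- vars$pos >= s & (vars$pos + nchar(vars$ref) - 1L) <= e
    vars <- vars[keep, , drop = FALSE]
    vars <- vars[order(vars$pos), , drop = FALSE]
  }
  pieces <- character(0)
  ops <- list()
  push <- function(op, len) {
    if (len > 0L) ops[[length(ops) + 1L]] <<- tibble(op = op, len = as.integer(len))
  }
  cursor <- s
  for (i in seq_len(nrow(vars))) {
    p <- vars$pos[i]
    ref <- vars$ref[i]
    alt <- vars$alt[i]
    if (nchar(ref) == 1L && nchar(alt) == 1L) {        # SNP
      pieces <- c(pieces, str_sub(seq, cursor, p - 1L), alt)
      push("M", p - cursor + 1L)
      cursor <- p + 1L
    } else if (nchar(ref) > nchar(alt)) {              # deletion (anchored)
      pieces <- c(pieces, str_sub(seq, cursor, p - 1L), alt)
      push("M", p - cursor + 1L)
      push("D", nchar(ref) - 1L)
      cursor <- p + nchar(ref)
    } else {                                           # insertion (anchored)
      pieces <- c(pieces, str_sub(seq, cursor, p), str_sub(alt, 2L))
      push("M", p - cursor + 1L)
      push("I", nchar(alt) - 1L)
      cursor <- p + 1L
    }
  }
  if (cursor <= e) {
    pieces <- c(pieces, str_sub(seq, cursor, e))
    push("M", e - cursor + 1L)
  }
  list(seq = paste(pieces, collapse = ""), ops = bind_rows(ops))
}

inject_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  hits <- which(stats::runif(n) < rate)
  for (p in hits) {
    str_sub(seq, p, p) <- other_base(str_sub(seq, p, p))
  }
  seq
}

#' Simulate spliced long-read alignments over the planted haplotypes
#'
#' Each gene receives `depth` full-length reads. A read draws its haplotype
#' from the gene's `hap1_fraction` and, with probability `skip_fraction`,
#' uses the isoform skipping the middle exon — such reads span middle-exon
#' sites with an N operation instead of covering them. CIGARs are exact
#' (M/I/D within exons, N across introns); substitution errors are injected
#' at `error_rate`; flags alternate 0/16.
#'
#' @param refobj Output of [make_reference()].
#' @param planted Output of [plant_variants()].
#' @param config The [sim_config()] object.
#' @return A list with `aln` (sam tibble) and `expected` (per planted site:
#'   the expected exonic coverage, intron-containing-read proportion and alt
#'   allele fraction implied by the configuration).
#' @export
simulate_spliced_alignments <- function(refobj, planted, config) {
  withr::with_seed(config$seed + 2L,
                   simulate_spliced_impl(refobj, planted, config))
}

simulate_spliced_impl <- function(refobj, planted, config) {
  seq <- refobj$ref[[1L]]
  chrom <- names(refobj$ref)[1L]
  exons <- refobj$intervals[refobj$intervals$feature == "exon", ]
  reads <- list()
  for (g in seq_along(config$genes)) {
    gx <- exons[exons$gene == g, ]
    k <- nrow(gx)
    mid <- if (k >= 3L) 2L else NA_integer_
    for (r in seq_len(config$depth)) {
      hap <- if (stats::runif(1L) < config$hap1_fraction[g]) 1L else 2L
      skip <- !is.na(mid) && stats::runif(1L) < config$skip_fraction[g]
      use <- if (skip) gx[gx$index != mid, ] else gx
      vars <- planted$meta[planted$meta$hap %in% c(as.character(hap), "both"), ]
      segs <- lapply(seq_len(nrow(use)), function(i) {
        hap_segment(seq, use$start[i], use$end[i], vars)
      })
      ops <- list()
      for (i in seq_along(segs)) {
        ops[[length(ops) + 1L]] <- segs[[i]]$ops
        if (i < length(segs)) {
          ops[[length(ops) + 1L]] <- tibble(
            op = "N", len = use$start[i + 1L] - use$end[i] - 1L)
        }
      }
      rseq <- inject_errors(paste(vapply(segs, `[[`, "", "seq"), collapse = ""),
                            config$error_rate)
      reads[[length(reads) + 1L]] <- tibble(
        qname = sprintf("g%d_read%04d", g, r),
        flag = if (r %% 2L == 0L) 16L else 0L,
        rname = chrom, pos = use$start[1L], mapq = 60L,
        cigar = cigar_string(bind_rows(ops)),
        seq = rseq, qual = strrep("I", nchar(rseq))
      )
    }
  }
  aln <- bind_rows(reads)

  meta <- planted$meta
  in_mid <- meta$exon == 2L &
    vapply(meta$gene, function(g) length(config$genes[[g]]$exons) >= 3L, TRUE)
  skip <- config$skip_fraction[meta$gene]
  alt_frac <- ifelse(meta$hap == "both", 1,
                     ifelse(meta$hap == "1", config$hap1_fraction[meta$gene],
                            1 - config$hap1_fraction[meta$gene]))
  expected <- tibble(
    chrom = meta$chrom, pos = meta$pos, id = meta$id, kind = meta$kind,
    gene = meta$gene, exon = meta$exon,
    expected_exonic_cov = config$depth * ifelse(in_mid, 1 - skip, 1),
    expected_n_cigar_proportion = ifelse(in_mid, skip, 0),
    expected_alt_fraction = alt_frac
  )
  list(aln = aln, expected = expected)
}

#' Simulate contiguous short-read alignments over exons
#'
#' Uniform random-start reads within each exon, drawn from the gene's
#' haplotype mixture, with exact M/I/D CIGARs and constant Q40 qualities;
#' used for allele counting and short-read coverage tracks.
#'
#' @inheritParams simulate_spliced_alignments
#' @return A sam tibble.
#' @export
simulate_short_reads <- function(refobj, planted, config) {
  withr::with_seed(config$seed + 3L,
                   simulate_short_impl(refobj, planted, config))
}

simulate_short_impl <- function(refobj, planted, config) {
  seq <- refobj$ref[[1L]]
  chrom <- names(refobj$ref)[1L]
  exons <- refobj$intervals[refobj$intervals$feature == "exon", ]
  len <- config$sr_read_len
  reads <- list()
  for (i in seq_len(nrow(exons))) {
    ex <- exons[i, ]
    if (ex$end - ex$start + 1L < len) next
    n <- ceiling(config$sr_depth * (ex$end - ex$start + 1L) / len)
    starts <- sample(ex$start:(ex$end - len + 1L), n, replace = TRUE)
    for (r in seq_len(n)) {
      hap <- if (stats::runif(1L) < config$hap1_fraction[ex$gene]) 1L else 2L
      vars <- planted$meta[planted$meta$hap %in% c(as.character(hap), "both"), ]
      sgm <- hap_segment(seq, starts[r], starts[r] + len - 1L, vars)
      reads[[length(reads) + 1L]] <- tibble(
        qname = sprintf("sr_e%02d_%04d", i, r),
        flag = if (r %% 2L == 0L) 16L else 0L,
        rname = chrom, pos = starts[r], mapq = 60L,
        cigar = cigar_string(sgm$ops),
        seq = sgm$seq, qual = strrep("I", nchar(sgm$seq))
      )
    }
  }
  bind_rows(reads)
}

#' Build the complete synthetic fixture
#'
#' Reference, planted truth variants, spliced long-read alignments and
#' contiguous short reads, all deterministic for the config seed.
#'
#' @param config An [sim_config()] object.
#' @return A list of class `sv_fixture`: `config`, `ref`, `refs`,
#'   `intervals`, `hp_runs`, `truth`, `meta`, `haplotypes`, `lr_aln`,
#'   `sr_aln`, `expected`.
#' @export
sim_fixture <- function(config = sim_config()) {
  refobj <- make_reference(config)
  planted <- plant_variants(refobj, config)
  lr <- simulate_spliced_alignments(refobj, planted, config)
  sr <- simulate_short_reads(refobj, planted, config)
  structure(
    list(config = config, ref = refobj$ref, refs = refobj$refs,
         intervals = refobj$intervals, hp_runs = refobj$hp_runs,
         truth = planted$truth, meta = planted$meta,
         haplotypes = planted$haplotypes,
         lr_aln = lr$aln, sr_aln = sr, expected = lr$expected),
    class = "sv_fixture"
  )
}

#' Write a fixture to disk
#'
#' Emits `ref.fa` (+ index), `reads_lr.bam`/`reads_sr.bam` (sorted and
#' indexed), `truth.vcf`, `intervals.bed` (0-based half-open) and
#' `expected_sites.tsv`.
#'
#' @param fix An `sv_fixture` from [sim_fixture()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "ref.fa")
  dna <- Biostrings::DNAStringSet(fix$ref)
  Biostrings::writeXStringSet(dna, fa)
  Rsamtools::indexFa(fa)
  write_alignments(fix$lr_aln, file.path(dir, "reads_lr.bam"), refs = fix$refs)
  write_alignments(fix$sr_aln, file.path(dir, "reads_sr.bam"), refs = fix$refs)
  write_vcf(fix$truth, file.path(dir, "truth.vcf"), contigs = fix$refs)
  bed <- fix$intervals |>
    mutate(name = sprintf("gene%d_%s%d", .data$gene, .data$feature, .data$index))
  readr::write_tsv(
    tibble(chrom = names(fix$ref)[1L], start = bed$start - 1L, end = bed$end,
           name = bed$name),
    file.path(dir, "intervals.bed"), col_names = FALSE
  )
  readr::write_tsv(fix$expected, file.path(dir, "expected_sites.tsv"))
  invisible(dir)
}
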