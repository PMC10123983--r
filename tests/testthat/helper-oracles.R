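# Independent brute-force oracles. These deliberately avoid the package's
# vectorised code paths: everything is a per-base walk or an exhaustive
# enumeration, so agreement with the implementation is meaningful.

# Per-base projection of a CIGAR onto (ref, query) pairs: walks the CIGAR one
# base at a time.
oracle_aligned_pairs <- function(cigar, pos) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  ref <- pos
  qry <- 1L
  out_ref <- integer(0)
  out_qry <- integer(0)
  for (k in seq_along(ops)) {
    for (b in seq_len(lens[k])) {
      if (ops[k] %in% c("M", "=", "X")) {
        out_ref <- c(out_ref, ref)
        out_qry <- c(out_qry, qry)
        ref <- ref + 1L
        qry <- qry + 1L
      } else if (ops[k] %in% c("I", "S")) {
        qry <- qry + 1L
      } else if (ops[k] %in% c("D", "N")) {
        ref <- ref + 1L
      }
    }
  }
  data.frame(ref = out_ref, query = out_qry)
}

# Random well-formed spliced CIGAR: interior segments always contain at least
# one M so no fragment is empty; clips only at the ends.
random_cigar <- function(max_ops = 12L) {
  n_seg <- sample(1:4, 1)
  segs <- replicate(n_seg, {
    n <- sample(1:3, 1)
    ops <- character(0)
    for (i in seq_len(n)) {
      ops <- c(ops, paste0(sample(2:20, 1), sample(c("M", "=", "X"), 1)))
      if (i < n) ops <- c(ops, paste0(sample(1:8, 1), sample(c("I", "D"), 1)))
    }
    paste(ops, collapse = "")
  })
  body <- paste(segs, collapse = "")
  if (n_seg > 1) {
    gaps <- replicate(n_seg - 1, paste0(sample(30:200, 1), "N"))
    body <- paste0(segs[1],
                   paste0(gaps, segs[-1], collapse = ""))
  }
  lead <- if (runif(1) < 0.3) paste0(sample(1:10, 1), "S") else ""
  trail <- if (runif(1) < 0.3) paste0(sample(1:10, 1), "S") else ""
  paste0(lead, body, trail)
}

# A sam-tibble record with sequence/quals matching a CIGAR.
record_for_cigar <- function(cigar, pos = 101L, qname = "r1", flag = 0L) {
  qw <- sum(as.integer(regmatches(cigar, gregexpr("[0-9]+(?=[MIS=X])",
                                                  cigar, perl = TRUE))[[1]]))
  tibble::tibble(
    qname = qname, flag = flag, rname = "chr1", pos = as.integer(pos),
    mapq = 60L,
    cigar = cigar,
    seq = paste(sample(c("A", "C", "G", "T"), qw, replace = TRUE), collapse = ""),
    qual = paste(rawToChar(as.raw(sample(33:73, qw, replace = TRUE))), collapse = "")
  )
}

# Exhaustive window enumeration for the density filter: a variant is removed
# iff one of the (window)-wide windows containing it holds more than max_vars
# variants.
oracle_density_removed <- function(pos, window = 201L, max_vars = 3L) {
  removed <- logical(length(pos))
  for (i in seq_along(pos)) {
    for (a in (pos[i] - window + 1L):pos[i]) {
      if (sum(pos >= a & pos <= a + window - 1L) > max_vars) {
        removed[i] <- TRUE
        break
      }
    }
  }
  removed
}

# Brute-force same-position merge: highest QUAL wins, SNP wins ties.
oracle_mix <- function(snps, indels) {
  all <- rbind(
    cbind(snps, source = "snp"),
    cbind(indels, source = "indel")
  )
  keys <- unique(all[, c("chrom", "pos")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    cand <- all[all$chrom == keys$chrom[i] & all$pos == keys$pos[i], ]
    best <- cand[cand$qual == max(cand$qual), ]
    if (nrow(best) > 1) best <- best[best$source == "snp", ][1, ]
    best
  })
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$pos), ]
}

# BH step-up q-values, straight from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  adj <- p[o] * m / seq_len(m)
  q[o] <- rev(cummin(rev(adj)))
  pmin(q, 1)
}

# Quadratic homopolymer-run scan: for every start, extend while equal.
oracle_hp_runs <- function(seq, min_len = 3L) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  runs <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && chars[j + 1L] == chars[i]) j <- j + 1L
    if (j - i + 1L >= min_len) {
      runs[[length(runs) + 1L]] <-
        data.frame(base = chars[i], start = i, end = j, length = j - i + 1L)
    }
    i <- j + 1L
  }
  do.call(rbind, c(runs, list(data.frame(base = character(0), start = integer(0),
                                         end = integer(0), length = integer(0)))))
}

# All representations of a variant equivalent to (pos, ref, alt) on refseq,
# by exhaustive enumeration over positions and spans: two records are
# equivalent iff applying them yields the same edited sequence. Returns the
# canonical one: shortest ref allele first (no padding bases), then leftmost
# position among the shortest.
oracle_normalize <- function(refseq, pos, ref, alt, max_span = 8L) {
  apply_one <- function(p, r, a) {
    paste0(substr(refseq, 1, p - 1), a,
           substr(refseq, p + nchar(r), nchar(refseq)))
  }
  target <- apply_one(pos, ref, alt)
  best <- NULL
  for (p in seq_len(nchar(refseq))) {
    for (rl in 1:max_span) {
      if (p + rl - 1L > nchar(refseq)) next
      r <- substr(refseq, p, p + rl - 1L)
      delta <- nchar(alt) - nchar(ref)
      al <- rl + delta
      if (al < 1L) next
      # candidate alts: any substring placement that reproduces the target
      cand_alt <- substr(target, p, p + al - 1L)
      if (apply_one(p, r, cand_alt) == target) {
        rec <- list(pos = p, ref = r, alt = cand_alt)
        if (is.null(best) || rl < nchar(best$ref) ||
            (rl == nchar(best$ref) && p < best$pos)) {
          best <- rec
        }
      }
    }
  }
  best
}
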